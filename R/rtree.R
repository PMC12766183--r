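# Minimal CART regression trees with bagging, used as the per-variable
# learner of the chained-equations imputer. Splits minimize within-node SSE;
# the split search is vectorized (sort + cumulative sums) per predictor.

fit_rtree <- function(y, X, max_depth = 3L, min_node = 20L) {
  nodes <- list()
  grow <- function(rows, depth) {
    id <- length(nodes) + 1L
    mu <- mean(y[rows])
    if (depth >= max_depth || length(rows) < 2L * min_node || stats::var(y[rows]) < 1e-12) {
      nodes[[id]] <<- list(leaf = TRUE, value = mu)
      return(id)
    }
    best <- find_best_split(y[rows], X[rows, , drop = FALSE], min_node)
    if (is.null(best)) {
      nodes[[id]] <<- list(leaf = TRUE, value = mu)
      return(id)
    }
    nodes[[id]] <<- list(leaf = FALSE, var = best$var, cut = best$cut,
                         left = NA_integer_, right = NA_integer_, value = mu)
    left <- rows[X[rows, best$var] <= best$cut]
    right <- rows[X[rows, best$var] > best$cut]
    lid <- grow(left, depth + 1L)
    rid <- grow(right, depth + 1L)
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    id
  }
  grow(seq_along(y), 0L)
  structure(list(nodes = nodes), class = "rtree")
}

find_best_split <- function(y, X, min_node) {
  n <- length(y)
  best <- NULL
  best_sse <- sum((y - mean(y))^2) - 1e-10
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    k <- seq_len(n - 1L)
    # candidate split after position k; require distinct x values and node sizes
    ok <- (xs[k] < xs[k + 1L]) & (k >= min_node) & ((n - k) >= min_node)
    if (!any(ok)) next
    sse_l <- cs2[k] - cs[k]^2 / k
    sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    tot <- sse_l + sse_r
    tot[!ok] <- Inf
    m <- which.min(tot)
    if (tot[m] < best_sse) {
      best_sse <- tot[m]
      best <- list(var = j, cut = (xs[m] + xs[m + 1L]) / 2)
    }
  }
  best
}

predict_rtree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (isTRUE(nd$leaf)) {
      out[rows] <<- nd$value
      return(invisible())
    }
    go_left <- X[rows, nd$var] <= nd$cut
    if (any(go_left)) walk(nd$left, rows[go_left])
    if (any(!go_left)) walk(nd$right, rows[!go_left])
  }
  if (nrow(X) > 0) walk(1L, seq_len(nrow(X)))
  out
}

# bagged ensemble: bootstrap rows, average tree predictions
fit_bagged_trees <- function(y, X, n_trees = 3L, max_depth = 3L, min_node = 20L) {
  n <- length(y)
  trees <- lapply(seq_len(n_trees), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    fit_rtree(y[rows], X[rows, , drop = FALSE], max_depth, min_node)
  })
  structure(list(trees = trees), class = "bagged_trees")
}

predict_bagged_trees <- function(fit, newdata) {
  preds <- vapply(fit$trees, function(tr) predict_rtree(tr, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) mean(preds) else rowMeans(matrix(preds, nrow = nrow(newdata)))
}
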