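#' Filter proteins on missingness and detection-limit fractions
#'
#' A protein is excluded iff its missing fraction exceeds `max_missing` or the
#' fraction of observed values below the limit of detection exceeds `max_lod`
#' (both strict inequalities: ties at the boundary are retained). Proteins
#' failing both rules are counted once, under the missingness reason.
#'
#' @param proteins participants x proteins matrix, `NA` = missing.
#' @param lod_flags logical matrix of the same shape flagging below-LOD values.
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @param max_lod maximum tolerated below-LOD fraction (default 0.25).
#' @return list with `retained` (protein names kept) and `report`
#'   (`filter_report`: proteins_in, proteins_excluded_missing,
#'   proteins_excluded_lod, proteins_retained).
#' @export
filter_proteins <- function(proteins, lod_flags, max_missing = 0.20, max_lod = 0.25) {
  check_proportion(max_missing, "max_missing")
  check_proportion(max_lod, "max_lod")
  p <- ncol(proteins)
  if (is.null(p) || p == 0L || nrow(proteins) == 0L) {
    rep <- filter_report(p %||% 0L, 0L, 0L, p %||% 0L)
    return(list(retained = character(0), report = rep))
  }
  stopifnot(all(dim(proteins) == dim(lod_flags)))
  miss_frac <- colMeans(is.na(proteins))
  obs_n <- colSums(!is.na(proteins))
  lod_frac <- ifelse(obs_n > 0, colSums(lod_flags & !is.na(proteins)) / obs_n, 0)
  fail_miss <- miss_frac > max_missing
  fail_lod <- lod_frac > max_lod
  keep <- !(fail_miss | fail_lod)
  nm <- colnames(proteins) %||% as.character(seq_len(p))
  list(
    retained = nm[keep],
    report = filter_report(p, sum(fail_miss), sum(fail_lod & !fail_miss), sum(keep))
  )
}

filter_report <- function(p_in, ex_miss, ex_lod, retained) {
  structure(list(proteins_in = as.integer(p_in),
                 proteins_excluded_missing = as.integer(ex_miss),
                 proteins_excluded_lod = as.integer(ex_lod),
                 proteins_retained = as.integer(retained)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d proteins in; %d excluded (missing), %d excluded (LOD); %d retained\n",
              x$proteins_in, x$proteins_excluded_missing, x$proteins_excluded_lod,
              x$proteins_retained))
  invisible(x)
}

#' Filter participants on row-wise protein missingness
#'
#' A participant is retained iff their fraction of missing protein values is
#' at most `max_missing` (strictly more is excluded).
#'
#' @param proteins participants x proteins matrix with row names as ids.
#' @param max_missing maximum tolerated row missing fraction (default 0.50).
#' @return character vector of retained participant identifiers (row indices
#'   as characters when the matrix has no row names).
#' @export
filter_participants <- function(proteins, max_missing = 0.50) {
  check_proportion(max_missing, "max_missing")
  if (nrow(proteins) == 0L) return(character(0))
  frac <- if (ncol(proteins) == 0L) rep(0, nrow(proteins)) else rowMeans(is.na(proteins))
  ids <- rownames(proteins) %||% as.character(seq_len(nrow(proteins)))
  ids[frac <= max_missing]
}

#' Single imputation by chained equations with bagged regression trees
#'
#' Iterates over incomplete columns (least-missing first), each time fitting a
#' small bagged ensemble of CART regression trees on the currently-completed
#' data and replacing that column's missing entries with ensemble predictions.
#' Predictors are the supplied covariate columns plus the `top_k` proteins
#' most correlated with the target. One completed matrix is returned (single
#' imputation); observed entries are never changed.
#'
#' @param proteins participants x proteins matrix with `NA`s to fill.
#' @param covariates optional data frame / matrix of complete numeric
#'   covariates aligned with the rows (factors are coerced to numeric codes).
#' @param n_iterations chained-equation sweeps (default 5).
#' @param n_trees,max_depth,min_node ensemble size and tree shape.
#' @param top_k number of correlated protein predictors per target.
#' @param seed integer seed.
#' @return completed numeric matrix, same dimnames as the input.
#' @export
impute_proteins <- function(proteins, covariates = NULL, n_iterations = 5L,
                            n_trees = 3L, max_depth = 3L, min_node = 20L,
                            top_k = 10L, seed = 1L) {
  stopifnot(is.matrix(proteins))
  if (!anyNA(proteins)) return(proteins)
  if (any(colSums(!is.na(proteins)) == 0L)) {
    stop("all-missing protein column: should have been filtered out", call. = FALSE)
  }
  n <- nrow(proteins)
  covm <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    num <- lapply(covariates, function(v) as.numeric(if (is.factor(v)) unclass(v) else v))
    covm <- do.call(cbind, num)
    keep <- apply(covm, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
    covm <- covm[, keep, drop = FALSE]
    if (ncol(covm) == 0L) covm <- NULL
  }

  miss <- is.na(proteins)
  targets <- which(colSums(miss) > 0L)
  targets <- targets[order(colSums(miss)[targets])]
  filled <- proteins
  mu <- colMeans(proteins, na.rm = TRUE)
  for (j in targets) filled[miss[, j], j] <- mu[j]

  # predictor pools fixed from the initialized matrix
  cm <- suppressWarnings(stats::cor(filled))
  pools <- lapply(targets, function(j) {
    r <- abs(cm[, j]); r[j] <- NA
    utils::head(order(r, decreasing = TRUE, na.last = NA), top_k)
  })
  names(pools) <- as.character(targets)

  set.seed(derive_seed(seed, 97L))
  for (it in seq_len(n_iterations)) {
    for (j in targets) {
      rows_na <- which(miss[, j])
      Xj <- cbind(filled[, pools[[as.character(j)]], drop = FALSE], covm)
      fit <- fit_bagged_trees(filled[!miss[, j], j], Xj[!miss[, j], , drop = FALSE],
                              n_trees = n_trees, max_depth = max_depth,
                              min_node = min_node)
      filled[rows_na, j] <- predict_bagged_trees(fit, Xj[rows_na, , drop = FALSE])
    }
  }
  filled
}

#' Sex-stratified random split into derivation and validation sets
#'
#' The split is drawn independently within each sex stratum so that the
#' derivation fraction is honored (within one participant) for males and
#' females separately. Deterministic given the seed.
#'
#' @param cohort a `cohort` object.
#' @param derivation_fraction target derivation proportion in (0,1).
#' @param seed integer seed.
#' @return `split_assignment`: list with `derivation_ids`, `validation_ids`,
#'   `seed`.
#' @export
split_cohort <- function(cohort, derivation_fraction = 0.70, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  stop_field(is.numeric(derivation_fraction) && length(derivation_fraction) == 1L &&
               derivation_fraction > 0 && derivation_fraction < 1,
             "derivation_fraction", "must lie strictly in (0,1)")
  cov <- cohort$covariates
  if (nrow(cov) == 0L) stop("cannot split an empty cohort", call. = FALSE)
  set.seed(derive_seed(seed, 11L))
  deriv <- character(0)
  for (s in levels(cov$sex)) {
    ids <- cov$id[cov$sex == s]
    k <- round(derivation_fraction * length(ids))
    deriv <- c(deriv, sample(ids, k))
  }
  structure(list(derivation_ids = sort(deriv),
                 validation_ids = sort(setdiff(cov$id, deriv)),
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' Standardize proteins against a reference subset
#'
#' Each protein is centered and scaled by the mean and SD computed on the
#' reference rows only (typically the derivation set), and the scaling
#' metadata is returned so validation data can be transformed identically.
#'
#' @param proteins participants x proteins matrix (row names = ids).
#' @param reference_ids identifiers of the reference rows (`NULL` = all rows).
#' @return list with `proteins` (standardized matrix over all rows),
#'   `center`, `scale` (named per-protein vectors).
#' @export
standardize_proteins <- function(proteins, reference_ids = NULL) {
  stopifnot(is.matrix(proteins))
  ids <- rownames(proteins) %||% as.character(seq_len(nrow(proteins)))
  ref <- if (is.null(reference_ids)) rep(TRUE, nrow(proteins)) else ids %in% reference_ids
  if (!any(ref)) stop("reference set is empty", call. = FALSE)
  ctr <- colMeans(proteins[ref, , drop = FALSE])
  scl <- apply(proteins[ref, , drop = FALSE], 2, stats::sd)
  bad <- which(!is.finite(scl) | scl <= 0)
  if (length(bad)) {
    stop(sprintf("zero-variance protein(s) in reference set: %s",
                 paste(colnames(proteins)[bad], collapse = ", ")), call. = FALSE)
  }
  out <- sweep(sweep(proteins, 2, ctr, "-"), 2, scl, "/")
  list(proteins = out, center = ctr, scale = scl)
}
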