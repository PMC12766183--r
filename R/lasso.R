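#' Selection configuration for bootstrap stability selection
#'
#' @param n_bootstrap number of bootstrap resamples (default 200).
#' @param n_folds cross-validation folds for the per-bootstrap lambda search
#'   (default 10; event-stratified).
#' @param frequency_threshold selection-frequency threshold in (0,1]; a
#'   protein is selected when its nonzero-coefficient count reaches
#'   `ceiling(threshold * n_bootstrap)` (default 0.95, i.e. 190 of 200).
#' @param lambda_grid `"auto"` (per-fit path from the largest
#'   all-zero lambda down `lambda_decades` decades over `n_lambda` points) or
#'   an explicit decreasing positive vector.
#' @param n_lambda,lambda_decades shape of the automatic grid (defaults 100
#'   points over 4 decades).
#' @param lambda_rule `"min"` (minimum mean cross-validated partial-likelihood
#'   deviance, the default) or `"1se"`.
#' @param penalize_score2_covariates if `FALSE` (default) the clinical risk
#'   covariates enter the design unpenalized, so proteins are selected for
#'   incremental signal over the base score.
#' @param seed master seed; bootstrap `b` uses a seed derived from it and `b`.
#' @return `selection_config` list.
#' @export
selection_config <- function(n_bootstrap = 200L, n_folds = 10L,
                             frequency_threshold = 0.95,
                             lambda_grid = "auto", n_lambda = 100L,
                             lambda_decades = 4, lambda_rule = c("min", "1se"),
                             penalize_score2_covariates = FALSE, seed = 1L) {
  stop_field(n_bootstrap >= 1, "n_bootstrap", "must be >= 1")
  stop_field(n_folds >= 2, "n_folds", "must be >= 2")
  stop_field(frequency_threshold > 0 && frequency_threshold <= 1,
             "frequency_threshold", "must lie in (0,1]")
  if (!identical(lambda_grid, "auto")) {
    stop_field(is.numeric(lambda_grid) && length(lambda_grid) > 0 &&
                 all(lambda_grid > 0), "lambda_grid",
               "must be \"auto\" or positive numbers")
    lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)
  }
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 n_folds = as.integer(n_folds),
                 frequency_threshold = frequency_threshold,
                 lambda_grid = lambda_grid, n_lambda = as.integer(n_lambda),
                 lambda_decades = lambda_decades,
                 lambda_rule = match.arg(lambda_rule),
                 penalize_score2_covariates = isTRUE(penalize_score2_covariates),
                 seed = as.integer(seed)),
            class = "selection_config")
}

check_surv_inputs <- function(X, time, event) {
  stopifnot(is.matrix(X), length(time) == nrow(X), length(event) == nrow(X))
  if (!all(is.finite(X)) || !all(is.finite(time))) {
    stop("non-finite values in design or follow-up times", call. = FALSE)
  }
  if (sum(event) < 1) stop("no events in the data", call. = FALSE)
  invisible(TRUE)
}

#' Fit a LASSO-penalized Cox model at a fixed penalty
#'
#' Minimizes the negative log Cox partial likelihood (Breslow ties) plus
#' `lambda * sum(|beta_j|)` over the penalized columns; columns listed in
#' `unpenalized` carry no penalty. Backed by the coordinate-descent path of
#' \pkg{glmnet} run down to the requested `lambda` with a tight convergence
#' threshold. Columns are used as supplied (no internal re-standardization).
#'
#' @param X numeric design matrix.
#' @param time,event follow-up times and 0/1 event indicators.
#' @param lambda nonnegative penalty.
#' @param unpenalized column names or indices exempt from the penalty.
#' @return named coefficient vector (one per column of `X`).
#' @export
fit_lasso_cox <- function(X, time, event, lambda, unpenalized = NULL) {
  check_surv_inputs(X, time, event)
  stop_field(is.numeric(lambda) && length(lambda) == 1L && is.finite(lambda) &&
               lambda >= 0, "lambda", "must be a single nonnegative number")
  pf <- penalty_factor(X, unpenalized)
  p_orig <- ncol(X)
  if (p_orig == 1L) {          # glmnet requires >= 2 columns
    X <- cbind(X, `..pad..` = 0)
    pf <- c(pf, 1)
  }
  y <- survival::Surv(time, event)
  lmax <- lambda_max_glmnet(X, y, pf)
  top <- max(lmax, lambda * 1.001, 1e-8)
  lseq <- unique(sort(c(exp(seq(log(top), log(max(lambda, top * 1e-4, 1e-10)),
                                length.out = 40)), lambda), decreasing = TRUE))
  fit <- glmnet::glmnet(X, y, family = "cox", lambda = lseq, standardize = FALSE,
                        penalty.factor = pf, thresh = 1e-12, maxit = 1e6)
  beta <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))[seq_len(p_orig)]
  names(beta) <- colnames(X)[seq_len(p_orig)]
  beta
}

penalty_factor <- function(X, unpenalized) {
  pf <- rep(1, ncol(X))
  if (!is.null(unpenalized) && length(unpenalized)) {
    idx <- if (is.character(unpenalized)) match(unpenalized, colnames(X)) else as.integer(unpenalized)
    if (anyNA(idx)) stop("unknown unpenalized column", call. = FALSE)
    pf[idx] <- 0
  }
  pf
}

lambda_max_glmnet <- function(X, y, pf) {
  f <- glmnet::glmnet(X, y, family = "cox", nlambda = 3, standardize = FALSE,
                      penalty.factor = pf)
  max(f$lambda)
}

# event-stratified fold labels, deterministic given seed
make_event_folds <- function(event, n_folds, seed) {
  set.seed(seed)
  foldid <- integer(length(event))
  for (g in c(0, 1)) {
    rows <- which(event == g)
    foldid[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
  }
  foldid
}

#' Select the LASSO penalty by cross-validated partial-likelihood deviance
#'
#' K-fold cross-validation with event-stratified, seeded folds; the selected
#' lambda minimizes the mean out-of-fold Cox partial-likelihood deviance
#' (or applies the one-standard-error rule when configured).
#'
#' @inheritParams fit_lasso_cox
#' @param config a [selection_config()] (folds, grid, rule, seed).
#' @param unpenalized column names or indices exempt from the penalty.
#' @param seed optional override of the fold seed.
#' @return list with `lambda` (the selected value), `lambda_min`,
#'   `lambda_1se`, `grid`, `cvm` (mean deviance per grid point).
#' @export
cv_select_lambda <- function(X, time, event, config = selection_config(),
                             unpenalized = NULL, seed = NULL) {
  check_surv_inputs(X, time, event)
  pf <- penalty_factor(X, unpenalized)
  y <- survival::Surv(time, event)
  foldid <- make_event_folds(event, config$n_folds, seed %||% config$seed)
  args <- list(x = X, y = y, family = "cox", foldid = foldid,
               type.measure = "deviance", standardize = FALSE,
               penalty.factor = pf, grouped = TRUE)
  if (identical(config$lambda_grid, "auto")) {
    args$nlambda <- config$n_lambda
    args$lambda.min.ratio <- 10^(-config$lambda_decades)
  } else {
    args$lambda <- config$lambda_grid
  }
  cv <- do.call(glmnet::cv.glmnet, args)
  lam <- if (config$lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  list(lambda = lam, lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
       grid = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd, fit = cv$glmnet.fit)
}
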