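score2_covariates <- c("age", "sbp", "tchol", "hdl", "smoker")

# design matrix for a single-sex stratum: clinical covariates first
# (unpenalized unless configured otherwise), then standardized proteins
stratum_design <- function(covariates, proteins) {
  clin <- as.matrix(covariates[, score2_covariates])
  X <- cbind(clin, proteins)
  colnames(X) <- c(score2_covariates, colnames(proteins))
  X
}

#' Bootstrap stability selection within one sex stratum
#'
#' For each of `n_bootstrap` resamples (drawn with replacement at the original
#' stratum size, seeded per bootstrap from the master seed), the LASSO penalty
#' is tuned by event-stratified ten-fold cross-validation on the resample and
#' the model is refit at the tuned penalty; proteins with nonzero coefficients
#' are recorded. A protein is selected when its count reaches
#' `ceiling(frequency_threshold * n_bootstrap)` (with the defaults, 190 of
#' 200 bootstrap samples). Clinical covariates are part of the design but
#' never counted as proteins; by default they are unpenalized.
#'
#' @param covariates data frame of the stratum with the clinical covariate,
#'   `time` and `event` columns.
#' @param proteins standardized protein matrix aligned with `covariates` rows.
#' @param config a [selection_config()].
#' @param sex_stratum label stored in the result.
#' @return `selection_result`: list with `sex_stratum`, `frequencies` (named
#'   per-protein bootstrap counts), `selected` (protein names),
#'   `n_bootstrap`, `threshold_count`, `per_bootstrap_lambda`.
#' @export
bootstrap_stability <- function(covariates, proteins, config = selection_config(),
                                sex_stratum = "all") {
  stopifnot(is.data.frame(covariates), is.matrix(proteins),
            nrow(covariates) == nrow(proteins))
  if (sum(covariates$event) == 0) stop("stratum has zero events", call. = FALSE)
  X <- stratum_design(covariates, proteins)
  unpen <- if (config$penalize_score2_covariates) NULL else score2_covariates
  n <- nrow(X)
  prot_names <- colnames(proteins)
  counts <- stats::setNames(integer(length(prot_names)), prot_names)
  lambdas <- numeric(config$n_bootstrap)

  for (b in seq_len(config$n_bootstrap)) {
    seed_b <- derive_seed(config$seed, 1000L + b)
    set.seed(seed_b)
    rows <- sample.int(n, n, replace = TRUE)
    tries <- 0L
    while (sum(covariates$event[rows]) < config$n_folds && tries < 50L) {
      # resample must support event-stratified folds; redraw deterministically
      tries <- tries + 1L
      set.seed(derive_seed(seed_b, tries))
      rows <- sample.int(n, n, replace = TRUE)
    }
    cv <- cv_select_lambda(X[rows, , drop = FALSE], covariates$time[rows],
                           covariates$event[rows], config,
                           unpenalized = unpen, seed = derive_seed(seed_b, 77L))
    # suppress benign lambda.interp warnings when a resample's path stops early
    beta <- as.numeric(suppressWarnings(stats::coef(cv$fit, s = cv$lambda)))
    names(beta) <- colnames(X)
    nz <- prot_names[abs(beta[prot_names]) > 0]
    counts[nz] <- counts[nz] + 1L
    lambdas[b] <- cv$lambda
  }

  threshold_count <- as.integer(ceiling(config$frequency_threshold * config$n_bootstrap))
  structure(list(sex_stratum = sex_stratum, frequencies = counts,
                 selected = names(counts)[counts >= threshold_count],
                 n_bootstrap = config$n_bootstrap,
                 threshold_count = threshold_count,
                 per_bootstrap_lambda = lambdas),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> stratum %s: %d/%d proteins selected (count >= %d of %d)\n",
              x$sex_stratum, length(x$selected), length(x$frequencies),
              x$threshold_count, x$n_bootstrap))
  if (length(x$selected)) {
    cat("  ", paste(sprintf("%s (%d)", x$selected, x$frequencies[x$selected]),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Independent protein selection per sex stratum
#'
#' Runs [bootstrap_stability()] separately on the male and female strata
#' (with stratum-specific seeds derived from the master seed) and summarizes
#' the overlap of the two selected sets as shared, male-only and female-only
#' proteins.
#'
#' @param covariates derivation-set data frame including `sex`, the clinical
#'   covariates, `time` and `event`.
#' @param proteins standardized protein matrix aligned with the rows.
#' @param config a [selection_config()].
#' @return list with `male` and `female` [bootstrap_stability()] results and
#'   `overlap` (`shared`, `male_only`, `female_only`).
#' @export
run_sex_specific_selection <- function(covariates, proteins,
                                       config = selection_config()) {
  stopifnot(is.data.frame(covariates), "sex" %in% names(covariates))
  res <- list()
  for (s in c("male", "female")) {
    rows <- which(covariates$sex == s)
    if (!length(rows)) stop(sprintf("empty %s stratum", s), call. = FALSE)
    # same master seed in both strata: swapping the sex labels swaps the two
    # results exactly, and copied strata select identically
    res[[s]] <- bootstrap_stability(covariates[rows, , drop = FALSE],
                                    proteins[rows, , drop = FALSE],
                                    config, sex_stratum = s)
  }
  list(male = res$male, female = res$female,
       overlap = list(
         shared = intersect(res$male$selected, res$female$selected),
         male_only = setdiff(res$male$selected, res$female$selected),
         female_only = setdiff(res$female$selected, res$male$selected)
       ))
}

#' Serialize a selection result
#'
#' Writes the per-protein bootstrap frequencies as TSV (protein, frequency,
#' selected) and, optionally, the full result as JSON.
#'
#' @param result a `selection_result`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return invisible `NULL`.
#' @export
write_selection_result <- function(result, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  if (!is.null(tsv_path)) {
    df <- data.frame(protein = names(result$frequencies),
                     frequency = as.integer(result$frequencies),
                     selected = names(result$frequencies) %in% result$selected)
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(result), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
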