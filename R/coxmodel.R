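#' Fit a Cox proportional hazards risk model with a Breslow baseline
#'
#' Maximum partial likelihood with Breslow tie handling (Efron available),
#' covariates centered at their means for numerical stability, and the
#' Breslow baseline cumulative hazard evaluated at the prediction horizon.
#' Standard errors come from the inverse observed information.
#'
#' @param X numeric covariate matrix (no constant columns).
#' @param time,event follow-up times (years) and 0/1 event indicators.
#' @param horizon prediction horizon in years (default 10).
#' @param sex_stratum label stored in the model.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return `risk_model`: list with `covariate_names`, `coefficients`, `se`,
#'   `vcov`, `baseline_cumhaz` (H0 at the horizon), `centering_values`,
#'   `horizon`, `loglik`, `sex_stratum`.
#' @export
fit_cox <- function(X, time, event, horizon = 10, sex_stratum = "all",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_surv_inputs(X, time, event)
  if (sum(event) < 2) stop("need at least two events", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers, "-")
  fit <- survival::coxph(survival::Surv(time, event) ~ Xc, ties = ties,
                         control = survival::coxph.control(eps = 1e-10, iter.max = 50))
  beta <- stats::coef(fit)
  if (!all(is.finite(beta))) stop("Cox fit did not converge (non-finite coefficients)", call. = FALSE)
  if (any(abs(beta) > 30)) {
    stop("monotone likelihood (perfect separation) suspected in Cox fit", call. = FALSE)
  }
  names(beta) <- colnames(X)
  V <- stats::vcov(fit)
  dimnames(V) <- list(colnames(X), colnames(X))
  bh <- survival::basehaz(fit, centered = FALSE)
  at <- bh$time <= horizon
  H0 <- if (any(at)) max(bh$hazard[at]) else 0
  structure(list(sex_stratum = sex_stratum, covariate_names = colnames(X),
                 coefficients = beta, se = sqrt(diag(V)), vcov = V,
                 baseline_cumhaz = H0, centering_values = centers,
                 horizon = horizon, loglik = fit$loglik[2], ties = ties),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> stratum %s: %d covariates, H0(%g y) = %.4g\n",
              x$sex_stratum, length(x$coefficients), x$horizon, x$baseline_cumhaz))
  print(round(stats::setNames(x$coefficients, x$covariate_names), 4))
  invisible(x)
}

#' Predict absolute event risk at the model horizon
#'
#' `risk = 1 - exp(-H0(horizon) * exp(lp))` with `lp` the centered linear
#' predictor; strictly increasing in `lp`.
#'
#' @param model a [fit_cox()] result.
#' @param X covariate matrix or data frame containing at least the model's
#'   covariates (matched by name).
#' @return numeric vector of risks in `[0,1]`.
#' @export
predict_risk <- function(model, X) {
  stopifnot(inherits(model, "risk_model"))
  if (is.data.frame(X)) X <- as.matrix(X[, intersect(model$covariate_names, names(X)), drop = FALSE])
  missing_cols <- setdiff(model$covariate_names, colnames(X))
  if (length(missing_cols)) {
    stop(sprintf("missing covariate(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  Xo <- X[, model$covariate_names, drop = FALSE]
  lp <- as.numeric(sweep(Xo, 2, model$centering_values, "-") %*% model$coefficients)
  1 - exp(-model$baseline_cumhaz * exp(lp))
}

# assemble the design for one stratum: clinical covariates (+ proteins)
model_design <- function(covariates, proteins = NULL, protein_set = character(0)) {
  X <- as.matrix(covariates[, score2_covariates])
  if (length(protein_set)) {
    miss <- setdiff(protein_set, colnames(proteins))
    if (length(miss)) stop(sprintf("unknown protein(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
    X <- cbind(X, proteins[, protein_set, drop = FALSE])
  }
  X
}

#' Fit base and protein-extended risk models per sex stratum
#'
#' For each sex, fits the base model on the clinical covariate set (age, SBP,
#' total cholesterol, HDL cholesterol, smoking) and the extended model adding
#' that stratum's selected proteins, both on the derivation rows.
#'
#' @param covariates derivation data frame (`sex`, clinical covariates,
#'   `time`, `event`).
#' @param proteins standardized protein matrix aligned with rows.
#' @param selection list with `male` and `female` `selection_result`s (or
#'   character vectors of protein names).
#' @param horizon prediction horizon in years.
#' @return list per sex: `list(base = risk_model, extended = risk_model)`.
#' @export
fit_base_and_extended <- function(covariates, proteins, selection, horizon = 10) {
  out <- list()
  for (s in c("male", "female")) {
    rows <- which(covariates$sex == s)
    sel <- selection[[s]]
    sel <- if (inherits(sel, "selection_result")) sel$selected else as.character(sel)
    cv <- covariates[rows, , drop = FALSE]
    base <- fit_cox(model_design(cv), cv$time, cv$event, horizon, sex_stratum = s)
    extended <- if (length(sel)) {
      fit_cox(model_design(cv, proteins[rows, , drop = FALSE], sel),
              cv$time, cv$event, horizon, sex_stratum = s)
    } else base
    out[[s]] <- list(base = base, extended = extended)
  }
  out
}

#' Per-protein adjusted hazard ratios with sex-interaction tests
#'
#' Each protein is added individually to a Cox model with the clinical
#' covariates, separately per sex stratum, yielding the hazard ratio per SD
#' (proteins are assumed standardized) with Wald 95% CI and p-value; a pooled
#' model with a protein-by-sex interaction supplies the interaction p-value.
#'
#' @param covariates validation data frame.
#' @param proteins standardized protein matrix aligned with rows.
#' @param protein_set protein names to test.
#' @return data frame with one row per protein and sex stratum:
#'   `protein`, `sex_stratum`, `hazard_ratio_per_sd`, `ci_low`, `ci_high`,
#'   `p_value`, `interaction_p`.
#' @export
protein_associations <- function(covariates, proteins, protein_set) {
  rows_list <- list(male = which(covariates$sex == "male"),
                    female = which(covariates$sex == "female"))
  out <- list()
  for (p in protein_set) {
    ip <- sex_interaction_test(covariates, proteins, p)
    for (s in names(rows_list)) {
      rows <- rows_list[[s]]
      cv <- covariates[rows, , drop = FALSE]
      X <- cbind(model_design(cv), protein = proteins[rows, p])
      fit <- survival::coxph(survival::Surv(cv$time, cv$event) ~ X, ties = "breslow")
      names(fit$coefficients) <- colnames(X)
      w <- wald_row(fit, "protein")
      out[[length(out) + 1L]] <- data.frame(
        protein = p, sex_stratum = s, hazard_ratio_per_sd = w$hr,
        ci_low = w$ci_low, ci_high = w$ci_high, p_value = w$p,
        interaction_p = ip, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Protein-by-sex interaction test
#'
#' Pooled (both-sex) Cox model with the clinical covariates, sex, the protein
#' and a protein-by-sex interaction term; returns the Wald p-value of the
#' interaction coefficient.
#'
#' @inheritParams protein_associations
#' @param protein a single protein name.
#' @return interaction p-value.
#' @export
sex_interaction_test <- function(covariates, proteins, protein) {
  stopifnot(protein %in% colnames(proteins))
  if (length(unique(covariates$sex)) < 2) stop("both sexes required", call. = FALSE)
  sexm <- as.numeric(covariates$sex == "male")
  X <- cbind(model_design(covariates), sexm = sexm,
             protein = proteins[, protein],
             protein_x_sex = proteins[, protein] * sexm)
  fit <- survival::coxph(survival::Surv(covariates$time, covariates$event) ~ X,
                         ties = "breslow")
  names(fit$coefficients) <- colnames(X)
  wald_row(fit, "protein_x_sex")$p
}

#' Serialize a risk model as JSON
#'
#' @param model a `risk_model`.
#' @param path output path.
#' @return invisible `NULL`.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(list(
    sex_stratum = model$sex_stratum, covariate_names = model$covariate_names,
    coefficients = as.list(model$coefficients),
    baseline_cumhaz = model$baseline_cumhaz,
    centering_values = as.list(model$centering_values),
    horizon = model$horizon), path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
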