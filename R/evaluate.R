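#' Full validation battery for base versus protein-extended models
#'
#' Computes, per sex stratum and for the pooled sample (each participant
#' scored by their own sex's models): Harrell's C for both models with 95%
#' CIs, the correlated C-index difference test, categorical NRI, IDI,
#' decile calibration of the extended model with its slope, horizon ROC AUCs
#' and the reclassification table.
#'
#' @param models result of [fit_base_and_extended()].
#' @param covariates validation data frame (`sex`, clinical covariates,
#'   `time`, `event`).
#' @param proteins standardized validation protein matrix.
#' @param cuts risk-category cut points for NRI / reclassification.
#' @param horizon evaluation horizon in years.
#' @param weighting censoring handling for NRI / IDI / ROC.
#' @param n_boot bootstrap replicates for NRI / IDI CIs.
#' @param seed bootstrap seed.
#' @return `eval_report`: per-stratum list (`male`, `female`, `overall`) of
#'   metric lists, plus `risks` (per-participant predictions).
#' @export
evaluate_models <- function(models, covariates, proteins,
                            cuts = c(0.05, 0.10), horizon = 10,
                            weighting = "km", n_boot = 1000L, seed = 1L) {
  risk_base <- numeric(nrow(covariates))
  risk_ext <- numeric(nrow(covariates))
  for (s in c("male", "female")) {
    rows <- which(covariates$sex == s)
    if (!length(rows)) next
    cv <- covariates[rows, , drop = FALSE]
    pm <- proteins[rows, , drop = FALSE]
    risk_base[rows] <- predict_risk(models[[s]]$base, model_design(cv))
    ext_prot <- setdiff(models[[s]]$extended$covariate_names, score2_covariates)
    risk_ext[rows] <- predict_risk(models[[s]]$extended, model_design(cv, pm, ext_prot))
  }

  strata <- list(male = which(covariates$sex == "male"),
                 female = which(covariates$sex == "female"),
                 overall = seq_len(nrow(covariates)))
  report <- lapply(strata, function(rows) {
    tm <- covariates$time[rows]; ev <- covariates$event[rows]
    rb <- risk_base[rows]; rn <- risk_ext[rows]
    cb <- harrell_c(tm, ev, rb)
    ce <- harrell_c(tm, ev, rn)
    cc <- compare_c(tm, ev, rb, rn)
    nri <- categorical_nri(rb, rn, tm, ev, cuts, horizon, weighting,
                           n_boot = n_boot, seed = seed)
    idi_est <- idi(rb, rn, tm, ev, horizon, weighting, n_boot = n_boot, seed = seed)
    cal <- calibration_deciles(rn, tm, ev, horizon)
    list(n = length(rows), events = sum(ev),
         c_base = cb, c_extended = ce, delta_c = cc$delta_c,
         delta_c_p = cc$p_value, nri = nri, idi = idi_est,
         calibration = cal, calibration_slope = calibration_slope(cal),
         auc_base = roc_at_horizon(rb, tm, ev, horizon, weighting)$auc,
         auc_extended = roc_at_horizon(rn, tm, ev, horizon, weighting)$auc,
         reclassification = reclassification_table(rb, rn, tm, ev, cuts,
                                                   horizon, weighting))
  })
  structure(c(report, list(risks = data.frame(
    id = covariates$id, sex = covariates$sex,
    base_risk = risk_base, extended_risk = risk_ext,
    stringsAsFactors = FALSE))), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (s in c("male", "female", "overall")) {
    r <- x[[s]]
    if (is.null(r)) next
    cat(sprintf("  %-7s n=%d events=%d  C %0.3f -> %0.3f (p=%.2g)  NRI %0.1f%%  IDI %0.3f\n",
                s, r$n, r$events, r$c_base$c, r$c_extended$c, r$delta_c_p,
                100 * r$nri$nri_total[["estimate"]], r$idi[["estimate"]]))
  }
  invisible(x)
}
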