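#' Decile calibration table
#'
#' Participants are ranked by predicted risk (ties broken by stable input
#' order) into ten near-equal groups; each row reports the group's mean
#' predicted risk and its Kaplan-Meier event probability at the horizon.
#'
#' @param risk predicted risks.
#' @param time,event follow-up times and event indicators.
#' @param horizon evaluation horizon in years.
#' @return data frame with `decile`, `n`, `mean_predicted`, `observed`.
#' @export
calibration_deciles <- function(risk, time, event, horizon = 10) {
  n <- length(risk)
  stopifnot(n >= 10, length(time) == n, length(event) == n)
  ord <- order(risk)                      # stable for ties
  sizes <- rep(n %/% 10L, 10L) + c(rep(1L, n %% 10L), rep(0L, 10L - n %% 10L))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(10L), sizes)
  out <- lapply(seq_len(10L), function(g) {
    sel <- grp == g
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    s_h <- c(1, sf$surv)[findInterval(horizon, sf$time) + 1L]
    data.frame(decile = g, n = sum(sel), mean_predicted = mean(risk[sel]),
               observed = 1 - s_h)
  })
  do.call(rbind, out)
}

#' Calibration slope across deciles
#'
#' Least-squares slope of observed event probability on mean predicted risk
#' over the ten calibration deciles; close to 1 for a well-calibrated model.
#'
#' @param cal a [calibration_deciles()] table.
#' @return the slope.
#' @export
calibration_slope <- function(cal) {
  unname(stats::coef(stats::lm(observed ~ mean_predicted, data = cal))[2])
}

#' ROC curve for event status at the horizon
#'
#' Receiver operating characteristic over horizon event status, using the
#' same Kaplan-Meier inverse-probability-of-censoring weighting as
#' [categorical_nri()] for participants censored before the horizon
#' (uncensored data reduce to the standard binary ROC). AUC by the
#' trapezoidal rule.
#'
#' @inheritParams calibration_deciles
#' @param weighting `"km"` or `"complete"`.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_at_horizon <- function(risk, time, event, horizon = 10,
                           weighting = c("km", "complete")) {
  weighting <- match.arg(weighting)
  hw <- horizon_weights(time, event, horizon, weighting)
  keep <- !is.na(hw$status) & hw$w > 0
  r <- risk[keep]; st <- hw$status[keep]; w <- hw$w[keep]
  if (!any(st == 1L) || !any(st == 0L)) {
    stop("need both events and non-events at the horizon", call. = FALSE)
  }
  ord <- order(r, decreasing = TRUE)
  r <- r[ord]; st <- st[ord]; w <- w[ord]
  we <- cumsum(w * (st == 1L)); wn <- cumsum(w * (st == 0L))
  last <- c(r[-1] != r[-length(r)], TRUE)    # one point per distinct threshold
  tpr <- c(0, we[last] / sum(w * (st == 1L)))
  fpr <- c(0, wn[last] / sum(w * (st == 0L)))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(threshold = c(Inf, r[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Per-protein incremental discrimination
#'
#' For each candidate protein, refits the base clinical model plus that
#' single protein on the derivation rows, predicts on the validation rows,
#' and reports the C-index gain over the base model with the correlated
#' C-index comparison p-value.
#'
#' @param cov_deriv,cov_valid derivation / validation data frames for one sex
#'   stratum (clinical covariates, `time`, `event`).
#' @param prot_deriv,prot_valid aligned standardized protein matrices.
#' @param protein_set proteins to evaluate.
#' @param horizon prediction horizon in years.
#' @return data frame `protein`, `c_base`, `c_with_protein`, `delta_c`,
#'   `p_value`.
#' @export
incremental_c <- function(cov_deriv, prot_deriv, cov_valid, prot_valid,
                          protein_set, horizon = 10) {
  base <- fit_cox(model_design(cov_deriv), cov_deriv$time, cov_deriv$event, horizon)
  risk_base <- predict_risk(base, model_design(cov_valid))
  out <- lapply(protein_set, function(p) {
    m <- fit_cox(model_design(cov_deriv, prot_deriv, p),
                 cov_deriv$time, cov_deriv$event, horizon)
    risk_p <- predict_risk(m, model_design(cov_valid, prot_valid, p))
    cc <- compare_c(cov_valid$time, cov_valid$event, risk_base, risk_p)
    data.frame(protein = p, c_base = cc$c_base, c_with_protein = cc$c_new,
               delta_c = cc$delta_c, p_value = cc$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
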