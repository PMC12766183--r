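# Horizon event status with inverse-probability-of-censoring (Kaplan-Meier)
# weights. Subjects with an event by the horizon are cases weighted by
# 1/G(T-); subjects followed beyond (or exactly to) the horizon are controls
# weighted by 1/G(horizon-); subjects censored before the horizon get weight
# zero. G is the Kaplan-Meier estimate of the censoring distribution.
horizon_weights <- function(time, event, horizon,
                            weighting = c("km", "complete")) {
  weighting <- match.arg(weighting)
  status <- rep(NA_integer_, length(time))
  status[time <= horizon & event == 1] <- 1L
  status[time >= horizon] <- 0L
  w <- numeric(length(time))
  if (weighting == "complete") {
    w[!is.na(status)] <- 1
  } else {
    sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
    g_minus <- function(t) c(1, sf$surv)[findInterval(t, sf$time, left.open = TRUE) + 1L]
    cases <- which(!is.na(status) & status == 1L)
    ctrls <- which(!is.na(status) & status == 0L)
    w[cases] <- 1 / pmax(g_minus(time[cases]), 1e-10)
    w[ctrls] <- 1 / pmax(g_minus(rep(horizon, length(ctrls))), 1e-10)
  }
  list(status = status, w = w)
}

#' Assign pre-specified risk categories
#'
#' Categories are `[0, cuts[1]]`, `(cuts[1], cuts[2]]`, `(cuts[2], 1]`
#' (left-open upper intervals): a risk exactly at a cut falls in the lower
#' category.
#'
#' @param risk risks in `[0,1]`.
#' @param cuts two increasing cut points (default `c(0.05, 0.10)`).
#' @return integer categories 1..3.
#' @export
risk_category <- function(risk, cuts = c(0.05, 0.10)) {
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2])
  1L + (risk > cuts[1]) + (risk > cuts[2])
}

nri_point <- function(cat_base, cat_new, status, w) {
  up <- cat_new > cat_base
  down <- cat_new < cat_base
  we <- w * (status == 1L); wn <- w * (status == 0L)
  we[is.na(status)] <- 0; wn[is.na(status)] <- 0
  se <- sum(we); sn <- sum(wn)
  if (se <= 0 || sn <= 0) stop("need both events and non-events at the horizon", call. = FALSE)
  ev <- (sum(we[up]) - sum(we[down])) / se
  ne <- (sum(wn[down]) - sum(wn[up])) / sn
  c(nri_events = ev, nri_nonevents = ne, nri_total = ev + ne)
}

#' Categorical net reclassification improvement
#'
#' Events reclassified upward minus downward, plus non-events reclassified
#' downward minus upward, across the pre-specified risk categories. Event
#' status at the horizon is estimated with Kaplan-Meier
#' inverse-probability-of-censoring weights by default (`weighting = "km"`);
#' `"complete"` drops participants censored before the horizon. Confidence
#' intervals come from a seeded participant bootstrap.
#'
#' @param risk_base,risk_new predicted risks in `[0,1]` from the two models.
#' @param time,event follow-up times and event indicators.
#' @param cuts two risk-category cut points (default `c(0.05, 0.10)`).
#' @param horizon evaluation horizon in years.
#' @param weighting `"km"` or `"complete"`.
#' @param n_boot bootstrap replicates for the CI (default 1000).
#' @param seed bootstrap seed.
#' @return list with `nri_total`, `nri_events`, `nri_nonevents`, each a
#'   vector `c(estimate, ci_low, ci_high)`.
#' @export
categorical_nri <- function(risk_base, risk_new, time, event,
                            cuts = c(0.05, 0.10), horizon = 10,
                            weighting = c("km", "complete"),
                            n_boot = 1000L, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(all(risk_base >= 0 & risk_base <= 1), all(risk_new >= 0 & risk_new <= 1))
  cb <- risk_category(risk_base, cuts)
  cn <- risk_category(risk_new, cuts)
  hw <- horizon_weights(time, event, horizon, weighting)
  est <- nri_point(cb, cn, hw$status, hw$w)
  boot <- boot_stat(length(time), n_boot, seed, function(rows) {
    hwb <- horizon_weights(time[rows], event[rows], horizon, weighting)
    tryCatch(nri_point(cb[rows], cn[rows], hwb$status, hwb$w),
             error = function(e) rep(NA_real_, 3))
  })
  out <- lapply(seq_along(est), function(k) {
    ci <- stats::quantile(boot[, k], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    c(estimate = unname(est[k]), ci_low = ci[1], ci_high = ci[2])
  })
  names(out) <- names(est)
  out[c("nri_total", "nri_events", "nri_nonevents")]
}

boot_stat <- function(n, n_boot, seed, fun) {
  set.seed(derive_seed(seed, 31L))
  k <- length(fun(seq_len(n)))
  res <- vapply(seq_len(n_boot), function(b) fun(sample.int(n, n, replace = TRUE)),
                numeric(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

idi_point <- function(risk_base, risk_new, status, w) {
  we <- w * (status == 1L); wn <- w * (status == 0L)
  we[is.na(status)] <- 0; wn[is.na(status)] <- 0
  if (sum(we) <= 0 || sum(wn) <= 0) stop("need both events and non-events at the horizon", call. = FALSE)
  slope <- function(r) sum(we * r) / sum(we) - sum(wn * r) / sum(wn)
  slope(risk_new) - slope(risk_base)
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes (mean predicted risk in events minus
#' non-events) between the new and the base model, with the same
#' censoring handling and bootstrap CI as [categorical_nri()].
#'
#' @inheritParams categorical_nri
#' @return vector `c(estimate, ci_low, ci_high)`.
#' @export
idi <- function(risk_base, risk_new, time, event, horizon = 10,
                weighting = c("km", "complete"), n_boot = 1000L, seed = 1L) {
  weighting <- match.arg(weighting)
  hw <- horizon_weights(time, event, horizon, weighting)
  est <- idi_point(risk_base, risk_new, hw$status, hw$w)
  boot <- boot_stat(length(time), n_boot, seed, function(rows) {
    hwb <- horizon_weights(time[rows], event[rows], horizon, weighting)
    tryCatch(idi_point(risk_base[rows], risk_new[rows], hwb$status, hwb$w),
             error = function(e) NA_real_)
  })
  ci <- stats::quantile(boot[, 1], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(estimate = est, ci_low = ci[1], ci_high = ci[2])
}

#' Reclassification cross-tabulation by event status
#'
#' 3x3 cross-tabulation of base-model versus new-model risk categories, split
#' into events and non-events at the horizon (Kaplan-Meier weighted counts by
#' default, so the uncensored case reduces to raw counts).
#'
#' @inheritParams categorical_nri
#' @return list with `events` and `nonevents` 3x3 matrices (rows = base
#'   category, columns = new category) and `cuts`.
#' @export
reclassification_table <- function(risk_base, risk_new, time, event,
                                   cuts = c(0.05, 0.10), horizon = 10,
                                   weighting = c("km", "complete")) {
  weighting <- match.arg(weighting)
  cb <- risk_category(risk_base, cuts)
  cn <- risk_category(risk_new, cuts)
  hw <- horizon_weights(time, event, horizon, weighting)
  tab <- function(status_val) {
    m <- matrix(0, 3, 3, dimnames = list(base = c("low", "mid", "high"),
                                         new = c("low", "mid", "high")))
    sel <- which(!is.na(hw$status) & hw$status == status_val)
    for (i in sel) m[cb[i], cn[i]] <- m[cb[i], cn[i]] + hw$w[i]
    m
  }
  list(events = tab(1L), nonevents = tab(0L), cuts = cuts)
}
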