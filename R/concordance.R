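# Per-subject pair sums for Harrell's concordance over usable pairs.
# A pair {i,j} is comparable when the earlier time is an event, or when the
# times are tied with exactly one event; the event subject should carry the
# higher predicted risk (ties in risk score 0.5). Computed in row blocks so
# memory stays O(block * n) while time is the exact O(n^2) enumeration.
pair_stats <- function(time, event, risks, block = 512L) {
  n <- length(time)
  m <- length(risks)
  P <- matrix(0, n, m)
  Q <- numeric(n)
  ev <- event == 1
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dt <- outer(time[idx], time, "-")
    tie <- dt == 0
    case_i <- (dt < 0 & ev[idx]) | (tie & ev[idx] & !rep(ev, each = length(idx)))
    case_j <- (dt > 0 & rep(ev, each = length(idx))) |
      (tie & !ev[idx] & rep(ev, each = length(idx)))
    q <- case_i | case_j
    Q[idx] <- Q[idx] + rowSums(q)
    for (k in seq_len(m)) {
      dr <- outer(risks[[k]][idx], risks[[k]], "-")
      sc <- matrix(0, length(idx), n)
      sc[case_i] <- (sign(dr[case_i]) + 1) / 2
      sc[case_j] <- (1 - sign(dr[case_j])) / 2
      P[idx, k] <- P[idx, k] + rowSums(sc)
    }
  }
  list(P = P, Q = Q, n = n)
}

# concordance point estimates plus the U-statistic (co)variance matrix of the
# estimators, via the Hajek projection of the ratio-of-U-statistics
c_stat_core <- function(time, event, risks) {
  stopifnot(length(time) >= 2)
  if (sum(event) < 1) stop("no events: no comparable pairs", call. = FALSE)
  ps <- pair_stats(time, event, risks)
  n <- ps$n
  SQ <- sum(ps$Q)
  if (SQ == 0) stop("no comparable pairs", call. = FALSE)
  C <- colSums(ps$P) / SQ
  qbar <- SQ / (n * (n - 1))
  gq <- ps$Q / (n - 1)
  W <- ps$P / (n - 1) - outer(gq, C)
  V <- (4 / n) * stats::cov(W) / qbar^2
  list(C = C, vcov = V, n = n)
}

#' Harrell's concordance index with a U-statistic confidence interval
#'
#' `C = (concordant + 0.5 * risk-tied) / comparable` over usable pairs: pairs
#' where the earlier time is an event, plus tied times with exactly one
#' event. The 95% CI uses the U-statistic (Hajek projection) variance of the
#' estimator.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param risk numeric risk scores (any monotone scale).
#' @return list with `c`, `se`, `ci_low`, `ci_high`, `n`.
#' @export
harrell_c <- function(time, event, risk) {
  core <- c_stat_core(time, event, list(risk))
  se <- sqrt(max(core$vcov[1, 1], 0))
  list(c = core$C[1], se = se,
       ci_low = core$C[1] - 1.959964 * se,
       ci_high = core$C[1] + 1.959964 * se, n = core$n)
}

#' Compare two correlated concordance indices
#'
#' Difference test for two C-indices computed on the same participants (and
#' thus the same comparable-pair set): the variance of
#' `delta = C_new - C_base` comes from the joint U-statistic covariance of
#' the two concordance estimators, and the p-value from a two-sided normal
#' approximation.
#'
#' @inheritParams harrell_c
#' @param risk_base,risk_new the two risk scores to compare.
#' @return list with `c_base`, `c_new`, `delta_c`, `se`, `z`, `p_value`.
#' @export
compare_c <- function(time, event, risk_base, risk_new) {
  stopifnot(length(risk_base) == length(time), length(risk_new) == length(time))
  if (isTRUE(all.equal(risk_base, risk_new, tolerance = 0))) {
    core <- c_stat_core(time, event, list(risk_base))
    return(list(c_base = core$C[1], c_new = core$C[1], delta_c = 0,
                se = 0, z = 0, p_value = 1))
  }
  core <- c_stat_core(time, event, list(risk_base, risk_new))
  delta <- core$C[2] - core$C[1]
  v <- core$vcov[1, 1] + core$vcov[2, 2] - 2 * core$vcov[1, 2]
  if (v <= 1e-20) return(list(c_base = core$C[1], c_new = core$C[2],
                              delta_c = delta, se = 0, z = 0, p_value = 1))
  z <- delta / sqrt(v)
  list(c_base = core$C[1], c_new = core$C[2], delta_c = delta,
       se = sqrt(v), z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
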