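# Small survival fixtures used across test files.

# single-covariate survival data with known per-SD log hazard ratio
toy_surv <- function(n, beta = 0, base_rate = 0.05, cens_rate = 0.03,
                     horizon = 10, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  t_ev <- rexp(n, base_rate * exp(beta * x))
  t_cn <- if (cens_rate > 0) rexp(n, cens_rate) else rep(Inf, n)
  list(x = x,
       time = pmin(t_ev, t_cn, horizon),
       event = as.numeric(t_ev <= pmin(t_cn, horizon)))
}

# a small complete cohort for pipeline-level tests
tiny_sim <- function(n = 800, seed = 5, ...) {
  sim_config(n_participants = n, n_proteins = 12, protein_block_size = 4,
             protein_block_correlation = 0.2,
             informative_male = c("1" = log(2)),
             informative_female = c("1" = log(2)),
             baseline_hazard_rate = 0.006,
             missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
             seed = seed, ...)
}

# brute-force Harrell C over usable pairs (independent O(n^2) loop oracle)
brute_c <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    case <- NULL
    if (time[i] < time[j] && event[i] == 1) case <- c(i, j)
    if (time[j] < time[i] && event[j] == 1) case <- c(j, i)
    if (time[i] == time[j] && event[i] + event[j] == 1) {
      case <- if (event[i] == 1) c(i, j) else c(j, i)
    }
    if (is.null(case)) next
    den <- den + 1
    d <- risk[case[1]] - risk[case[2]]
    num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
  }
  num / den
}

# brute-force binary AUC by pair counting
brute_auc <- function(label, score) {
  pos <- which(label == 1); neg <- which(label == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# negative log partial likelihood, Breslow ties
neg_log_pl <- function(beta, x, time, event) {
  eta <- as.numeric(as.matrix(x) %*% beta)
  s <- 0
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    rs <- which(time >= t)
    s <- s - sum(eta[d]) + length(d) * log(sum(exp(eta[rs])))
  }
  s
}
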