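test_that("harrell_c handles the degenerate and perfect orderings", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  expect_identical(harrell_c(time, event, rep(0.3, 6))$c, 0.5)
  # risk perfectly inversely ordered with uncensored event times
  expect_identical(harrell_c(1:6, rep(1, 6), 6:1 / 10)$c, 1)
  expect_error(harrell_c(c(1, 2), c(0, 0), c(0.1, 0.2)), "no events|no comparable")
})

test_that("harrell_c equals exhaustive pair enumeration on censored toys", {
  for (s in 1:5) {
    set.seed(s)
    n <- 8
    time <- sample(1:6, n, replace = TRUE) + ifelse(s %% 2, 0, 0.5)
    event <- c(rep(1, 6), 0, 0)[sample(n)]
    risk <- round(rnorm(n), 1)  # induces some risk ties
    if (sum(event[time < max(time)]) == 0) next
    expect_equal(harrell_c(time, event, risk)$c, brute_c(time, event, risk),
                 tolerance = 1e-14)
  }
})

test_that("C is invariant under monotone transforms and flips under negation", {
  d <- toy_surv(120, beta = 0.8, seed = 61)
  c1 <- harrell_c(d$time, d$event, d$x)$c
  expect_equal(harrell_c(d$time, d$event, exp(3 * d$x))$c, c1, tolerance = 1e-14)
  expect_equal(harrell_c(d$time, d$event, -d$x)$c, 1 - c1, tolerance = 1e-14)
})

test_that("compare_c is exact for identical inputs and antisymmetric", {
  d <- toy_surv(150, beta = 0.5, seed = 62)
  same <- compare_c(d$time, d$event, d$x, d$x)
  expect_identical(same$delta_c, 0)
  expect_identical(same$p_value, 1)

  z <- rnorm(150)
  ab <- compare_c(d$time, d$event, d$x, z)
  ba <- compare_c(d$time, d$event, z, d$x)
  expect_equal(ab$delta_c, -ba$delta_c, tolerance = 1e-14)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("compare_c detects a real discrimination difference", {
  set.seed(63)
  n <- 2000
  x <- rnorm(n)
  t_ev <- rexp(n, 0.05 * exp(0.9 * x))
  time <- pmin(t_ev, 10); event <- as.numeric(t_ev <= 10)
  res <- compare_c(time, event, rnorm(n), x)
  expect_gt(res$delta_c, 0)
  expect_lt(res$p_value, 0.001)
})

test_that("risk categories use left-open upper boundaries", {
  expect_identical(risk_category(c(0, 0.05, 0.05 + 1e-9, 0.10, 0.10 + 1e-9, 1)),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
})

test_that("categorical NRI matches the hand-worked uncensored toy", {
  # 10 events: 3 up, 1 down; 10 non-events: 2 down, 1 up
  cat_to_risk <- c(0.03, 0.08, 0.2)
  base_ev <- c(1, 1, 1, 2, 2, 2, 2, 2, 2, 3)
  new_ev  <- c(2, 1, 1, 3, 2, 2, 2, 2, 1, 3)   # ups rows 1,4; need 3 up 1 down
  new_ev[7] <- 3                                # third up
  base_ne <- c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3)
  new_ne  <- c(1, 2, 2, 2, 2, 1, 3, 3, 3, 2)   # 1 up (row 2), 2 down (rows 6, 10)
  risk_base <- cat_to_risk[c(base_ev, base_ne)]
  risk_new <- cat_to_risk[c(new_ev, new_ne)]
  time <- rep(11, 20)        # everyone followed past the horizon...
  event <- rep(0, 20)
  time[1:10] <- 5; event[1:10] <- 1   # ...except the events
  nri <- categorical_nri(risk_base, risk_new, time, event, n_boot = 10, seed = 1)
  expect_equal(nri$nri_events[["estimate"]], 0.2, tolerance = 1e-12)
  expect_equal(nri$nri_nonevents[["estimate"]], 0.1, tolerance = 1e-12)
  expect_equal(nri$nri_total[["estimate"]], 0.3, tolerance = 1e-12)

  zero <- categorical_nri(risk_base, risk_base, time, event, n_boot = 10, seed = 1)
  expect_identical(zero$nri_total[["estimate"]], 0)
  expect_error(categorical_nri(risk_base, risk_new, time, rep(0, 20)),
               "events")
})

test_that("IDI matches hand arithmetic and vanishes for identical models", {
  risk_base <- c(0.2, 0.3, 0.2, 0.2)
  risk_new <- c(0.4, 0.5, 0.1, 0.1)
  time <- c(4, 6, 11, 11); event <- c(1, 1, 0, 0)
  out <- idi(risk_base, risk_new, time, event, n_boot = 10, seed = 2)
  expect_equal(out[["estimate"]], (0.45 - 0.1) - (0.25 - 0.2), tolerance = 1e-12)
  expect_identical(idi(risk_base, risk_base, time, event, n_boot = 10)[["estimate"]], 0)
})

test_that("calibration deciles partition the sample with stable tie handling", {
  set.seed(64)
  n <- 105L
  risk <- runif(n)
  time <- rexp(n, 0.1); event <- as.numeric(time < 10); time <- pmin(time, 10)
  cal <- calibration_deciles(risk, time, event)
  expect_identical(sum(cal$n), n)
  expect_lte(diff(range(cal$n)), 1)
  expect_true(all(diff(cal$mean_predicted) > 0))
  const <- calibration_deciles(rep(0.2, 50), time[1:50], event[1:50])
  expect_true(all(const$mean_predicted == 0.2))
})

test_that("horizon ROC equals pair-counting AUC on uncensored data", {
  set.seed(65)
  n <- 60
  risk <- round(runif(n), 2)
  event <- rbinom(n, 1, 0.4)
  time <- ifelse(event == 1, 5, 11)  # uncensored at the 10-year horizon
  roc <- roc_at_horizon(risk, time, event)
  expect_equal(roc$auc, brute_auc(event, risk), tolerance = 1e-12)
  # perfect separation
  perfect <- roc_at_horizon(c(rep(0.9, 5), rep(0.1, 5)),
                            c(rep(5, 5), rep(11, 5)), c(rep(1, 5), rep(0, 5)))
  expect_identical(perfect$auc, 1)
})

test_that("reclassification tables stay on the diagonal for identical models and sum to n", {
  set.seed(66)
  n <- 40
  risk <- runif(n, 0, 0.3)
  event <- rbinom(n, 1, 0.3)
  time <- ifelse(event == 1, 4, 12)
  tab <- reclassification_table(risk, risk, time, event)
  expect_identical(sum(tab$events) + sum(tab$nonevents), as.numeric(n))
  expect_identical(sum(tab$events * (1 - diag(3))), 0)

  # internal consistency with the NRI components in the uncensored case
  risk2 <- pmin(pmax(risk + runif(n, -0.05, 0.05), 0), 1)
  tab2 <- reclassification_table(risk, risk2, time, event)
  up_e <- sum(tab2$events[upper.tri(tab2$events)])
  dn_e <- sum(tab2$events[lower.tri(tab2$events)])
  up_n <- sum(tab2$nonevents[upper.tri(tab2$nonevents)])
  dn_n <- sum(tab2$nonevents[lower.tri(tab2$nonevents)])
  nri <- categorical_nri(risk, risk2, time, event, n_boot = 10, seed = 3)
  expect_equal(nri$nri_events[["estimate"]],
               (up_e - dn_e) / sum(tab2$events), tolerance = 1e-12)
  expect_equal(nri$nri_nonevents[["estimate"]],
               (dn_n - up_n) / sum(tab2$nonevents), tolerance = 1e-12)
})

test_that("KM weighting reduces to complete-case on uncensored data and handles censoring", {
  d <- toy_surv(400, beta = 0.7, base_rate = 0.05, cens_rate = 0.05, seed = 67)
  risk_new <- 1 / (1 + exp(-d$x))
  risk_base <- rep(0.08, 400)
  km <- categorical_nri(risk_base, risk_new, d$time, d$event,
                        weighting = "km", n_boot = 20, seed = 4)
  cc <- categorical_nri(risk_base, risk_new, d$time, d$event,
                        weighting = "complete", n_boot = 20, seed = 4)
  expect_true(is.finite(km$nri_total[["estimate"]]))
  expect_true(is.finite(cc$nri_total[["estimate"]]))
  # uncensored: identical
  du <- toy_surv(200, beta = 0.7, base_rate = 0.05, cens_rate = 0, seed = 68)
  rb <- runif(200, 0, 0.3); rn <- runif(200, 0, 0.3)
  expect_equal(categorical_nri(rb, rn, du$time, du$event, weighting = "km",
                               n_boot = 10, seed = 5)$nri_total[["estimate"]],
               categorical_nri(rb, rn, du$time, du$event, weighting = "complete",
                               n_boot = 10, seed = 5)$nri_total[["estimate"]],
               tolerance = 1e-12)
})

test_that("incremental C flags informative proteins and ignores redundant ones", {
  cfg <- sim_config(n_participants = 5000, male_fraction = 1, n_proteins = 3,
                    protein_block_correlation = 0,
                    informative_male = c("1" = log(2)),
                    informative_female = c("1" = log(2)),
                    baseline_hazard_rate = 0.006,
                    missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
                    seed = 55)
  co <- generate_cohort(cfg)
  prot <- standardize_proteins(co$proteins)$proteins
  half <- seq_len(2500)
  inc <- incremental_c(co$covariates[half, ], prot[half, ],
                       co$covariates[-half, ], prot[-half, ],
                       c("P001", "P002"))
  expect_gt(inc$delta_c[inc$protein == "P001"], 0.02)
  expect_lt(inc$p_value[inc$protein == "P001"], 0.01)
  expect_lt(abs(inc$delta_c[inc$protein == "P002"]), 0.02)
  expect_gt(inc$p_value[inc$protein == "P002"], 0.05)
  expect_gt(inc$delta_c[inc$protein == "P001"],
            max(inc$delta_c[inc$protein != "P001"]))
})
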