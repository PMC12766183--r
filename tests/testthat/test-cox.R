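test_that("fit_cox maximizes the Breslow partial likelihood (1-D oracle)", {
  set.seed(3)
  n <- 30
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.2 * exp(0.8 * x)) + seq_len(n) * 1e-8
  event <- rep(1, n)
  m <- fit_cox(cbind(x = x), time, event)
  grid <- seq(-3, 3, by = 1e-3)
  obj <- vapply(grid, function(b) neg_log_pl(b, cbind(x), time, event), numeric(1))
  expect_lt(abs(m$coefficients[["x"]] - grid[which.min(obj)]), 2e-3)
})

test_that("duplicating every row leaves the coefficients unchanged", {
  d <- toy_surv(80, beta = 0.6, seed = 12)
  X <- cbind(x = d$x)
  m1 <- fit_cox(X, d$time, d$event)
  m2 <- fit_cox(rbind(X, X), c(d$time, d$time), c(d$event, d$event))
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-6)
})

test_that("null-covariate confidence intervals have nominal coverage", {
  hits <- 0L
  for (r in 1:200) {
    set.seed(5000 + r)
    n <- 120
    x <- rnorm(n)
    t_ev <- rexp(n, 0.08)
    time <- pmin(t_ev, 10); event <- as.numeric(t_ev <= 10)
    m <- fit_cox(cbind(x = x), time, event)
    ci <- m$coefficients[["x"]] + c(-1, 1) * 1.959964 * m$se[["x"]]
    hits <- hits + (ci[1] < 0 && ci[2] > 0)
  }
  # exact binomial 99% band around 0.95 with 200 draws
  expect_gte(hits, qbinom(0.005, 200, 0.95))
  expect_lte(hits, qbinom(0.995, 200, 0.95))
})

test_that("risk prediction follows the Breslow absolute-risk formula", {
  d <- toy_surv(500, beta = log(2), base_rate = 0.03, seed = 33)
  m <- fit_cox(cbind(x = d$x), d$time, d$event)
  # reference individual (lp = 0): risk is 1 - exp(-H0)
  r0 <- predict_risk(m, cbind(x = m$centering_values[["x"]]))
  expect_equal(r0, 1 - exp(-m$baseline_cumhaz), tolerance = 1e-12)
  # +1 unit with beta doubles the cumulative hazard exactly when exp(beta) = 2
  x0 <- m$centering_values[["x"]]
  r <- predict_risk(m, cbind(x = c(x0, x0 + 1)))
  expect_equal(log(1 - r[2]) / log(1 - r[1]), exp(m$coefficients[["x"]]),
               tolerance = 1e-10)
  # degenerate baseline
  m0 <- m; m0$baseline_cumhaz <- 0
  expect_identical(unique(predict_risk(m0, cbind(x = rnorm(5)))), 0)
  # monotone in a positive-coefficient covariate, bounded in [0,1]
  rr <- predict_risk(m, cbind(x = seq(-3, 3, length.out = 50)))
  expect_true(all(diff(rr) > 0) && all(rr >= 0 & rr <= 1))
  expect_error(predict_risk(m, cbind(y = 1)), "missing covariate")
})

test_that("base and extended models nest correctly", {
  cfg <- tiny_sim(n = 900, seed = 41)
  co <- generate_cohort(cfg)
  prot <- standardize_proteins(co$proteins)$proteins
  sel <- list(male = "P001", female = "P001")
  fits <- fit_base_and_extended(co$covariates, prot, sel)
  for (s in c("male", "female")) {
    expect_gte(fits[[s]]$extended$loglik, fits[[s]]$base$loglik)
    expect_identical(fits[[s]]$extended$covariate_names,
                     c("age", "sbp", "tchol", "hdl", "smoker", "P001"))
  }
  # empty selected set: extended model is the base model
  fits0 <- fit_base_and_extended(co$covariates, prot,
                                 list(male = character(0), female = character(0)))
  expect_identical(fits0$male$extended, fits0$male$base)
})

test_that("extended models recover injected per-SD effects", {
  cover <- 0L; total <- 0L
  for (r in 1:20) {
    cfg <- sim_config(n_participants = 4000, n_proteins = 6,
                      protein_block_correlation = 0,
                      informative_male = c("1" = log(1.8), "2" = log(1.5)),
                      informative_female = c("1" = log(1.8), "3" = log(1.5)),
                      baseline_hazard_rate = 0.004,
                      missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
                      seed = 6000 + r)
    co <- generate_cohort(cfg)
    prot <- co$proteins  # already unit-scale by construction
    sel <- list(male = c("P001", "P002"), female = c("P001", "P003"))
    fits <- fit_base_and_extended(co$covariates, prot, sel)
    truth <- list(male = c(P001 = log(1.8), P002 = log(1.5)),
                  female = c(P001 = log(1.8), P003 = log(1.5)))
    for (s in c("male", "female")) for (p in names(truth[[s]])) {
      b <- fits[[s]]$extended$coefficients[[p]]
      se <- fits[[s]]$extended$se[[p]]
      total <- total + 1L
      cover <- cover + (abs(b - truth[[s]][[p]]) < 1.959964 * se)
    }
  }
  expect_gte(cover / total, 0.90)
})

test_that("protein association HRs are scale-invariant and recover the truth", {
  cfg <- sim_config(n_participants = 8000, n_proteins = 4,
                    protein_block_correlation = 0,
                    informative_male = c("1" = log(1.5)),
                    informative_female = c("1" = log(1.5)),
                    baseline_hazard_rate = 0.004,
                    missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
                    seed = 71)
  co <- generate_cohort(cfg)
  prot <- standardize_proteins(co$proteins)$proteins
  a <- protein_associations(co$covariates, prot, "P001")
  for (s in c("male", "female")) {
    row <- a[a$sex_stratum == s, ]
    expect_true(row$ci_low <= 1.5 && 1.5 <= row$ci_high)
    expect_true(row$ci_low <= row$hazard_ratio_per_sd &&
                  row$hazard_ratio_per_sd <= row$ci_high)
  }
  # rescaling a protein then re-standardizing leaves HR per SD unchanged
  prot2 <- prot; prot2[, "P001"] <- prot2[, "P001"] * 7
  prot2 <- standardize_proteins(prot2)$proteins
  a2 <- protein_associations(co$covariates, prot2, "P001")
  expect_equal(a2$hazard_ratio_per_sd, a$hazard_ratio_per_sd, tolerance = 1e-8)
})

test_that("the sex-interaction test is symmetric and calibrated at small scale", {
  cfg <- sim_config(n_participants = 3000, n_proteins = 2,
                    protein_block_correlation = 0,
                    informative_male = c("1" = log(1.6)),
                    informative_female = c("1" = log(1.6)),
                    baseline_hazard_rate = 0.005,
                    missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
                    seed = 81)
  co <- generate_cohort(cfg)
  prot <- standardize_proteins(co$proteins)$proteins
  p1 <- sex_interaction_test(co$covariates, prot, "P001")
  swapped <- co$covariates
  swapped$sex <- factor(ifelse(swapped$sex == "male", "female", "male"),
                        c("male", "female"))
  p2 <- sex_interaction_test(swapped, prot, "P001")
  expect_equal(p1, p2, tolerance = 1e-6)
  expect_gt(p1, 0.001)  # equal effects: no interaction signal expected here
})
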