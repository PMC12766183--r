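# small single-sex stratum with one strong protein among noise
stability_fixture <- function(n = 500, seed = 13, beta = log(2.5), p_null = 5) {
  cfg <- sim_config(n_participants = n, male_fraction = 1,
                    n_proteins = p_null + 1, protein_block_correlation = 0,
                    informative_male = c("1" = beta),
                    informative_female = c("1" = beta),
                    baseline_hazard_rate = 0.012,
                    missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
                    seed = seed)
  co <- generate_cohort(cfg)
  list(cov = co$covariates, prot = standardize_proteins(co$proteins)$proteins)
}

test_that("selection threshold rule and frequency bounds hold", {
  d <- stability_fixture()
  cfg <- selection_config(n_bootstrap = 10L, n_lambda = 20L, lambda_decades = 2,
                          seed = 5)
  res <- bootstrap_stability(d$cov, d$prot, cfg, sex_stratum = "male")
  expect_identical(res$threshold_count, as.integer(ceiling(0.95 * 10)))
  expect_true(all(res$frequencies >= 0 & res$frequencies <= 10))
  expect_setequal(res$selected,
                  names(res$frequencies)[res$frequencies >= res$threshold_count])
  expect_length(res$per_bootstrap_lambda, 10L)
  # the planted protein should dominate even at this small scale
  expect_identical(unname(which.max(res$frequencies)), 1L)
})

test_that("a single bootstrap reduces to the nonzero set of that one fit", {
  d <- stability_fixture(n = 400, seed = 14)
  cfg <- selection_config(n_bootstrap = 1L, n_lambda = 20L, lambda_decades = 2,
                          seed = 9)
  res <- bootstrap_stability(d$cov, d$prot, cfg)
  expect_setequal(res$selected, names(res$frequencies)[res$frequencies == 1L])
  expect_identical(res$threshold_count, 1L)
})

test_that("selection is monotone in the frequency threshold", {
  d <- stability_fixture(n = 400, seed = 15)
  base <- selection_config(n_bootstrap = 8L, frequency_threshold = 0.5,
                           n_lambda = 20L, lambda_decades = 2, seed = 3)
  strict <- base; strict$frequency_threshold <- 1
  lo <- bootstrap_stability(d$cov, d$prot, base)
  hi <- bootstrap_stability(d$cov, d$prot, strict)
  expect_identical(lo$frequencies, hi$frequencies)  # same resamples
  expect_true(all(hi$selected %in% lo$selected))
})

test_that("selection is invariant to protein column order", {
  d <- stability_fixture(n = 400, seed = 16, p_null = 3)
  cfg <- selection_config(n_bootstrap = 5L, n_lambda = 20L, lambda_decades = 2,
                          seed = 8)
  a <- bootstrap_stability(d$cov, d$prot, cfg)
  perm <- c(3, 1, 4, 2)
  b <- bootstrap_stability(d$cov, d$prot[, perm], cfg)
  expect_identical(a$frequencies[colnames(d$prot)[perm]], b$frequencies)
  expect_setequal(a$selected, b$selected)
})

test_that("zero-event strata are rejected", {
  d <- stability_fixture(n = 100, seed = 17)
  d$cov$event <- 0
  expect_error(bootstrap_stability(d$cov, d$prot, selection_config(n_bootstrap = 1L)),
               "zero events")
})

test_that("per-sex runs are independent, symmetric and overlap-summarized", {
  cfg <- sim_config(n_participants = 700, male_fraction = 0.5, n_proteins = 4,
                    protein_block_correlation = 0,
                    informative_male = c("1" = log(2.5)),
                    informative_female = c("1" = log(2.5)),
                    baseline_hazard_rate = 0.012,
                    missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
                    seed = 23)
  co <- generate_cohort(cfg)
  prot <- standardize_proteins(co$proteins)$proteins
  scfg <- selection_config(n_bootstrap = 4L, n_lambda = 20L, lambda_decades = 2,
                           seed = 6)

  # identical strata (females replaced by a copy of the males) select identically
  cov2 <- co$covariates
  males <- which(cov2$sex == "male")
  females <- which(cov2$sex == "female")[seq_along(males)]
  cov_dup <- rbind(cov2[males, ], transform(cov2[males, ], sex = factor("female", c("male", "female"))))
  prot_dup <- rbind(prot[males, ], prot[males, ])
  dup <- run_sex_specific_selection(cov_dup, prot_dup, scfg)
  expect_identical(dup$male$frequencies, dup$female$frequencies)
  expect_setequal(dup$overlap$shared, dup$male$selected)
  expect_length(dup$overlap$male_only, 0)

  # swapping the sex labels swaps the two results exactly
  a <- run_sex_specific_selection(co$covariates, prot, scfg)
  swapped <- co$covariates
  swapped$sex <- factor(ifelse(swapped$sex == "male", "female", "male"),
                        c("male", "female"))
  b <- run_sex_specific_selection(swapped, prot, scfg)
  expect_identical(a$male$frequencies, b$female$frequencies)
  expect_identical(a$female$frequencies, b$male$frequencies)
})

test_that("the 1-SE rule recovers an exact sex-specific partition", {
  # companion to the acceptance recovery criteria: under the one-standard-
  # error lambda rule the shared / male-only / female-only partition is
  # recovered exactly (the CV-min default trades this sparsity for fidelity
  # to the published tuning rule; see the vignette)
  cfg <- sim_config(n_participants = 8000, male_fraction = 0.5,
                    n_proteins = 30, protein_block_size = 5,
                    protein_block_correlation = 0.3,
                    informative_male = c("1" = log(1.8), "6" = log(1.8),
                                         "11" = log(1.8), "16" = log(1.8)),
                    informative_female = c("1" = log(1.8), "6" = log(1.8),
                                           "21" = log(1.8), "26" = log(1.8)),
                    missing_rate_range = c(0, 0), lod_quantile_range = c(0, 0),
                    seed = 501)
  co <- generate_cohort(cfg)
  prot <- standardize_proteins(co$proteins)$proteins
  sel <- run_sex_specific_selection(co$covariates, prot,
                                    selection_config(n_bootstrap = 30L,
                                                     n_lambda = 15L,
                                                     lambda_decades = 1.5,
                                                     lambda_rule = "1se",
                                                     seed = 501))
  expect_setequal(sel$overlap$shared, c("P001", "P006"))
  expect_setequal(sel$overlap$male_only, c("P011", "P016"))
  expect_setequal(sel$overlap$female_only, c("P021", "P026"))
})

test_that("selection results serialize to TSV and JSON", {
  d <- stability_fixture(n = 300, seed = 19, p_null = 2)
  res <- bootstrap_stability(d$cov, d$prot,
                             selection_config(n_bootstrap = 2L, n_lambda = 15L,
                                              lambda_decades = 2, seed = 1))
  dir <- withr::local_tempdir()
  write_selection_result(res, file.path(dir, "sel.tsv"), file.path(dir, "sel.json"))
  tsv <- read.delim(file.path(dir, "sel.tsv"))
  expect_identical(tsv$protein, names(res$frequencies))
  expect_identical(tsv$frequency, as.integer(res$frequencies))
  js <- jsonlite::read_json(file.path(dir, "sel.json"), simplifyVector = TRUE)
  expect_identical(js$selected, res$selected)
})
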