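#' Baseline-characteristics table by event status
#'
#' Mean (SD) for continuous variables with t-test p-values and N (%) for
#' categorical variables with chi-squared (no continuity correction)
#' p-values, comparing participants with and without an event — the classic
#' cohort "Table 1" layout.
#'
#' @param covariates data frame with `sex`, `age`, `sbp`, `tchol`, `hdl`,
#'   `smoker`, `event`.
#' @return data frame with one row per characteristic.
#' @export
baseline_table <- function(covariates) {
  ev <- covariates$event == 1
  cont <- c(age = "Age (years)", sbp = "Systolic blood pressure (mmHg)",
            tchol = "Total cholesterol (mmol/L)", hdl = "HDL cholesterol (mmol/L)")
  cat_vars <- list(male = covariates$sex == "male", smoker = covariates$smoker == 1)
  cat_labels <- c(male = "Male sex, N (%)", smoker = "Current smoker, N (%)")
  rows <- list()
  fmt_ms <- function(x) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  fmt_np <- function(x) sprintf("%d (%.1f)", sum(x), 100 * mean(x))
  for (v in names(cat_vars)) {
    x <- cat_vars[[v]]
    p <- if (length(unique(x)) > 1 && any(ev) && any(!ev)) {
      stats::chisq.test(table(x, ev), correct = FALSE)$p.value
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = cat_labels[[v]], total = fmt_np(x),
      no_event = fmt_np(x[!ev]), event = fmt_np(x[ev]), p_value = p,
      stringsAsFactors = FALSE)
  }
  for (v in names(cont)) {
    x <- covariates[[v]]
    p <- if (any(ev) && any(!ev)) stats::t.test(x[ev], x[!ev])$p.value else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = cont[[v]], total = fmt_ms(x),
      no_event = fmt_ms(x[!ev]), event = fmt_ms(x[ev]), p_value = p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

fmt_ci <- function(est, lo, hi, digits = 3) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"), est, lo, hi)
}

#' Render a markdown summary report of a pipeline run
#'
#' Produces a plain-markdown document with the baseline-characteristics
#' table, the per-stratum performance table (C-indices, NRI, IDI), the
#' per-SD hazard-ratio forest data of the selected proteins, and the
#' per-protein incremental C-index table. Regeneration from the same
#' pipeline result is byte-identical.
#'
#' @param result a [run_pipeline()] result.
#' @param path optional file to write to.
#' @return the report as a character vector of lines (invisibly when `path`
#'   is given).
#' @export
make_report <- function(result, path = NULL) {
  need <- c("cohort", "evaluation", "selection")
  miss <- need[!need %in% names(result)]
  if (length(miss)) stop(sprintf("missing pipeline artifact(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  L <- c("# Pipeline summary", "",
         sprintf("Analyzed participants: %d (derivation %d, validation %d).",
                 result$manifest$n_analyzed, result$manifest$n_derivation,
                 result$manifest$n_validation), "")

  L <- c(L, "## Baseline characteristics by 10-year event status", "")
  bt <- baseline_table(result$cohort$covariates)
  L <- c(L, "| Characteristic | Total | No event | Event | P-value |",
         "|---|---|---|---|---|",
         sprintf("| %s | %s | %s | %s | %.3g |", bt$characteristic, bt$total,
                 bt$no_event, bt$event, bt$p_value), "")

  L <- c(L, "## Selected proteins", "")
  for (s in c("male", "female")) {
    sel <- result$selection[[s]]$selected
    L <- c(L, sprintf("- %s: %s", s,
                      if (length(sel)) paste(sel, collapse = ", ")
                      else "no proteins selected"))
  }
  ov <- result$selection$overlap
  L <- c(L, sprintf("- shared: %s | male-only: %s | female-only: %s",
                    if (length(ov$shared)) paste(ov$shared, collapse = ", ") else "none",
                    if (length(ov$male_only)) paste(ov$male_only, collapse = ", ") else "none",
                    if (length(ov$female_only)) paste(ov$female_only, collapse = ", ") else "none"),
         "")

  L <- c(L, "## Predictive performance (validation set)", "",
         "| Metric | Male | Female | Overall |", "|---|---|---|---|")
  ev <- result$evaluation
  g <- function(f) vapply(c("male", "female", "overall"), function(s) f(ev[[s]]), character(1))
  L <- c(L,
         paste0("| C (base) | ", paste(g(function(r) fmt_ci(r$c_base$c, r$c_base$ci_low, r$c_base$ci_high)), collapse = " | "), " |"),
         paste0("| C (+proteins) | ", paste(g(function(r) fmt_ci(r$c_extended$c, r$c_extended$ci_low, r$c_extended$ci_high)), collapse = " | "), " |"),
         paste0("| P (C comparison) | ", paste(g(function(r) sprintf("%.2g", r$delta_c_p)), collapse = " | "), " |"),
         paste0("| NRI total (%) | ", paste(g(function(r) fmt_ci(100 * r$nri$nri_total[["estimate"]], 100 * r$nri$nri_total[["ci_low"]], 100 * r$nri$nri_total[["ci_high"]], 1)), collapse = " | "), " |"),
         paste0("| NRI events (%) | ", paste(g(function(r) fmt_ci(100 * r$nri$nri_events[["estimate"]], 100 * r$nri$nri_events[["ci_low"]], 100 * r$nri$nri_events[["ci_high"]], 1)), collapse = " | "), " |"),
         paste0("| NRI non-events (%) | ", paste(g(function(r) fmt_ci(100 * r$nri$nri_nonevents[["estimate"]], 100 * r$nri$nri_nonevents[["ci_low"]], 100 * r$nri$nri_nonevents[["ci_high"]], 1)), collapse = " | "), " |"),
         paste0("| IDI | ", paste(g(function(r) fmt_ci(r$idi[["estimate"]], r$idi[["ci_low"]], r$idi[["ci_high"]])), collapse = " | "), " |"),
         paste0("| Calibration slope | ", paste(g(function(r) sprintf("%.2f", r$calibration_slope)), collapse = " | "), " |"),
         "")

  L <- c(L, "## Protein associations (per SD, validation set)", "")
  if (is.null(result$associations)) {
    L <- c(L, "No proteins selected; no association models fitted.", "")
  } else {
    a <- result$associations
    L <- c(L, "| Protein | Stratum | HR per SD (95% CI) | P | P interaction |",
           "|---|---|---|---|---|",
           sprintf("| %s | %s | %s | %.2g | %.2g |", a$protein, a$sex_stratum,
                   fmt_ci(a$hazard_ratio_per_sd, a$ci_low, a$ci_high, 2),
                   a$p_value, a$interaction_p), "")
  }

  L <- c(L, "## Incremental discrimination per protein", "")
  if (is.null(result$incremental)) {
    L <- c(L, "No proteins selected; no incremental models fitted.", "")
  } else {
    ic <- result$incremental
    L <- c(L, "| Protein | Stratum | Delta C | P |", "|---|---|---|---|",
           sprintf("| %s | %s | %.4f | %.2g |", ic$protein, ic$sex_stratum,
                   ic$delta_c, ic$p_value), "")
  }

  if (!is.null(path)) {
    writeLines(L, path)
    return(invisible(L))
  }
  L
}
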