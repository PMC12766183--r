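#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `sim` (a [sim_config()]) or `input_dir` (a directory
#' written by [write_cohort()]) supplies the cohort.
#'
#' @param sim a [sim_config()], or `NULL` when reading files.
#' @param input_dir cohort directory, or `NULL` when simulating.
#' @param max_missing_protein,max_lod protein filter thresholds.
#' @param max_missing_participant participant filter threshold.
#' @param impute_iterations chained-equation sweeps.
#' @param derivation_fraction sex-stratified derivation split fraction.
#' @param selection a [selection_config()].
#' @param cuts,horizon,n_boot evaluation options.
#' @param out_dir optional artifact directory.
#' @param seed master seed fanned out to every stochastic stage.
#' @return `run_config` list.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       max_missing_protein = 0.20, max_lod = 0.25,
                       max_missing_participant = 0.50,
                       impute_iterations = 5L, derivation_fraction = 0.70,
                       selection = selection_config(n_bootstrap = 100L,
                                                    n_lambda = 20L,
                                                    lambda_decades = 2),
                       cuts = c(0.05, 0.10), horizon = 10, n_boot = 1000L,
                       out_dir = NULL, seed = 1L) {
  if (is.null(sim) == is.null(input_dir)) {
    stop("exactly one of `sim` and `input_dir` must be given", call. = FALSE)
  }
  structure(list(sim = sim, input_dir = input_dir,
                 max_missing_protein = check_proportion(max_missing_protein, "max_missing_protein"),
                 max_lod = check_proportion(max_lod, "max_lod"),
                 max_missing_participant = check_proportion(max_missing_participant, "max_missing_participant"),
                 impute_iterations = as.integer(impute_iterations),
                 derivation_fraction = derivation_fraction,
                 selection = selection, cuts = cuts, horizon = horizon,
                 n_boot = as.integer(n_boot), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# deterministic 32-bit FNV-1a hash of the deparsed config (minus the artifact
# location, which does not affect results), for the manifest
config_hash <- function(config) {
  config$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full discovery-and-validation pipeline
#'
#' Simulate (or load) -> participant/protein filters -> chained-equations
#' imputation -> sex-stratified split -> derivation-referenced
#' standardization -> per-sex bootstrap stability selection -> base and
#' extended Cox models -> validation battery, per-protein associations and
#' incremental discrimination. Every stochastic stage is seeded from the
#' master seed, so a rerun with the same config reproduces all outputs
#' exactly; if `out_dir` is set all artifacts plus a manifest are written.
#'
#' @param config a [run_config()].
#' @return list with `cohort`, `filter_report`, `split`, `selection`,
#'   `models`, `evaluation`, `associations`, `incremental`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- derive_seed(seed, 1L)
      inject_missingness(generate_cohort(sim), sim)
    } else {
      read_cohort(config$input_dir)
    }
  })

  filt <- stage("filter", {
    keep_ids <- filter_participants(cohort$proteins, config$max_missing_participant)
    rows <- cohort$covariates$id %in% keep_ids
    cohort$covariates <- cohort$covariates[rows, , drop = FALSE]
    cohort$proteins <- cohort$proteins[rows, , drop = FALSE]
    cohort$lod_flags <- cohort$lod_flags[rows, , drop = FALSE]
    fp <- filter_proteins(cohort$proteins, cohort$lod_flags,
                          config$max_missing_protein, config$max_lod)
    cohort$proteins <- cohort$proteins[, fp$retained, drop = FALSE]
    cohort$lod_flags <- cohort$lod_flags[, fp$retained, drop = FALSE]
    fp$report$participants_excluded <- sum(!rows)
    fp$report
  })

  proteins <- stage("impute", {
    impute_proteins(cohort$proteins,
                    cohort$covariates[, c(score2_covariates, "sex")],
                    n_iterations = config$impute_iterations,
                    seed = derive_seed(seed, 2L))
  })

  split <- stage("split", split_cohort(cohort, config$derivation_fraction,
                                       seed = derive_seed(seed, 3L)))
  std <- stage("standardize", standardize_proteins(proteins, split$derivation_ids))

  deriv_rows <- cohort$covariates$id %in% split$derivation_ids
  cov_d <- cohort$covariates[deriv_rows, , drop = FALSE]
  cov_v <- cohort$covariates[!deriv_rows, , drop = FALSE]
  prot_d <- std$proteins[deriv_rows, , drop = FALSE]
  prot_v <- std$proteins[!deriv_rows, , drop = FALSE]

  sel_cfg <- config$selection
  sel_cfg$seed <- derive_seed(seed, 4L)
  selection <- stage("select", run_sex_specific_selection(cov_d, prot_d, sel_cfg))

  models <- stage("fit", fit_base_and_extended(cov_d, prot_d, selection,
                                               horizon = config$horizon))
  evaluation <- stage("evaluate", evaluate_models(
    models, cov_v, prot_v, cuts = config$cuts, horizon = config$horizon,
    n_boot = config$n_boot, seed = derive_seed(seed, 5L)))

  all_selected <- union(selection$male$selected, selection$female$selected)
  associations <- stage("associations", {
    if (length(all_selected)) protein_associations(cov_v, prot_v, all_selected) else NULL
  })
  incremental <- stage("incremental", {
    out <- list()
    for (s in c("male", "female")) {
      sel <- selection[[s]]$selected
      if (!length(sel)) next
      dr <- cov_d$sex == s; vr <- cov_v$sex == s
      inc <- incremental_c(cov_d[dr, , drop = FALSE], prot_d[dr, , drop = FALSE],
                           cov_v[vr, , drop = FALSE], prot_v[vr, , drop = FALSE],
                           sel, horizon = config$horizon)
      inc$sex_stratum <- s
      out[[s]] <- inc
    }
    if (length(out)) do.call(rbind, out) else NULL
  })

  manifest <- list(
    config_hash = config_hash(config), master_seed = seed,
    sub_seeds = list(simulate = derive_seed(seed, 1L), impute = derive_seed(seed, 2L),
                     split = derive_seed(seed, 3L), select = derive_seed(seed, 4L),
                     evaluate = derive_seed(seed, 5L)),
    n_analyzed = nrow(cohort$covariates),
    n_derivation = length(split$derivation_ids),
    n_validation = length(split$validation_ids),
    selected = list(male = selection$male$selected,
                    female = selection$female$selected,
                    shared = selection$overlap$shared))

  result <- list(cohort = cohort, proteins = std$proteins,
                 standardization = std[c("center", "scale")],
                 filter_report = filt, split = split, selection = selection,
                 models = models, evaluation = evaluation,
                 associations = associations, incremental = incremental,
                 manifest = manifest, config = config)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(result$filter_report), file.path(dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(result$split), file.path(dir, "split.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in c("male", "female")) {
    write_selection_result(result$selection[[s]],
                           tsv_path = file.path(dir, sprintf("selection_%s.tsv", s)),
                           json_path = file.path(dir, sprintf("selection_%s.json", s)))
    write_risk_model(result$models[[s]]$base,
                     file.path(dir, sprintf("model_base_%s.json", s)))
    write_risk_model(result$models[[s]]$extended,
                     file.path(dir, sprintf("model_extended_%s.json", s)))
  }
  utils::write.csv(result$evaluation$risks, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  ev <- result$evaluation
  jsonlite::write_json(
    lapply(ev[c("male", "female", "overall")], function(r) {
      r$calibration <- as.list(r$calibration)
      r$reclassification$events <- as.data.frame(r$reclassification$events)
      r$reclassification$nonevents <- as.data.frame(r$reclassification$nonevents)
      r
    }), file.path(dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$associations)) {
    utils::write.csv(result$associations, file.path(dir, "associations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$incremental)) {
    utils::write.csv(result$incremental, file.path(dir, "incremental_c.csv"),
                     row.names = FALSE)
  }
  for (s in c("male", "female", "overall")) {
    utils::write.csv(ev[[s]]$calibration,
                     file.path(dir, sprintf("calibration_%s.csv", s)), row.names = FALSE)
  }
  invisible(dir)
}
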