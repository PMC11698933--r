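# Pipeline entry points: each stage reads its inputs, runs the package
# functions, and writes plain CSV/JSON artifacts into an output
# directory. The Rscript wrapper in inst/scripts/fluorisk.R exposes these
# as shell subcommands; within R they are ordinary functions. All outputs
# embed the package version, the seed and the resolved configuration, and
# contain no timestamps, so a rerun with identical inputs is
# byte-identical.

run_meta <- function(seed = NULL, config = NULL) {
  meta <- list(package = "fluorisk",
               version = as.character(packageVersion("fluorisk")))
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  if (!is.null(config)) meta$config <- config
  meta
}

resolve_sites <- function(sites) {
  if (is.null(sites)) return(fluoride_sites())
  if (is.character(sites)) return(read_sites(sites))
  check_sites(sites)
}

resolve_cohorts <- function(params) {
  if (is.null(params)) return(default_cohorts())
  if (is.character(params)) return(read_cohorts(params))
  lapply(params, as_cohort)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Deterministic hazard-quotient pipeline
#'
#' Computes the full exposure table (TDI/CDI/HQ per site, cohort and
#' min/mean/max variant) and the district concentration summary, and
#' writes `exposure_table.csv` and `district_summary.json` to `out_dir`.
#'
#' @param sites Site CSV path, list of [site_record()] objects, or `NULL`
#'   for the packaged survey.
#' @param params Cohort parameter file (YAML/JSON), list of
#'   [age_group_params()], or `NULL` for [default_cohorts()].
#' @param out_dir Output directory (created if absent).
#' @param threshold Exceedance threshold, mg/L.
#' @return Invisibly, a list with the computed `table`, `summary` and
#'   output `paths`.
#' @export
run_hq <- function(sites = NULL, params = NULL, out_dir = ".",
                   threshold = 1.5) {
  sites <- resolve_sites(sites)
  cohorts <- resolve_cohorts(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- exposure_table(sites, cohorts)
  summ <- district_summary(sites, threshold = threshold)

  csv_path <- file.path(out_dir, "exposure_table.csv")
  out <- as.data.frame(tab)
  out$HQ_display <- round_half_up(out$HQ, 2)
  out$TDI_display <- round_half_up(out$TDI, 3)
  write.csv(out, csv_path, row.names = FALSE, quote = FALSE)

  json_path <- file.path(out_dir, "district_summary.json")
  write_json_file(c(unclass(summ), list(meta = run_meta(config = list(threshold = threshold)))),
                  json_path)

  invisible(list(table = tab, summary = summ,
                 paths = c(exposure_table = csv_path, district_summary = json_path)))
}

#' Fluorosis prevalence pipeline
#'
#' Runs [classify_sites()] on the deterministic exposure table and writes
#' `prevalence_<endpoint>.csv` and `.json`.
#'
#' @inheritParams run_hq
#' @param endpoint An [endpoint_config()] (default: dental, threshold 1).
#' @return Invisibly, the `prevalence_report` and output paths.
#' @export
run_prevalence <- function(sites = NULL, params = NULL, out_dir = ".",
                           endpoint = endpoint_config()) {
  sites <- resolve_sites(sites)
  cohorts <- resolve_cohorts(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- classify_sites(exposure_table(sites, cohorts), endpoint)
  csv_path <- file.path(out_dir, sprintf("prevalence_%s.csv", endpoint$name))
  json_path <- file.path(out_dir, sprintf("prevalence_%s.json", endpoint$name))
  write_prevalence(report, csv_path = csv_path, json_path = json_path)
  invisible(list(report = report,
                 paths = c(csv = csv_path, json = json_path)))
}

#' Monte Carlo risk pipeline
#'
#' Simulates the HQ distribution and the sensitivity report for every
#' cohort under the default (or supplied) input specification, and writes
#' `mcs_risk.json` (percentiles, moments, convergence) plus
#' `mcs_tornado.csv` (input, rho, contribution) to `out_dir`.
#'
#' @inheritParams run_hq
#' @param spec_file Optional YAML/JSON Monte Carlo spec
#'   (see [read_mcs_specs()]); by default [default_mcs_specs()] is built
#'   per cohort from the sites.
#' @param n Iterations per cohort.
#' @param seed Integer seed (mandatory).
#' @return Invisibly, per-cohort `risk_distribution` and
#'   `sensitivity_report` objects and the output paths.
#' @export
run_mcs <- function(sites = NULL, params = NULL, spec_file = NULL,
                    n = 10000, seed, out_dir = ".") {
  if (missing(seed)) stop_usage("'seed' is required for the MCS stage")
  sites <- resolve_sites(sites)
  cohorts <- resolve_cohorts(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  user_specs <- if (!is.null(spec_file)) read_mcs_specs(spec_file) else NULL

  sims <- list(); sens <- list()
  for (cohort in cohorts) {
    specs <- if (is.null(user_specs)) default_mcs_specs(sites, cohort) else user_specs
    sims[[cohort$name]] <- simulate_hq(specs, cohort, n = n, seed = seed)
    sens[[cohort$name]] <- sensitivity(specs, cohort, n = n, seed = seed)
  }

  risk <- lapply(sims, function(sim) {
    conv <- if (sim$n >= 2000) convergence_check(sim, block = max(1000, sim$n %/% 10)) else NULL
    list(cohort = sim$cohort, n_iterations = sim$n,
         percentiles = as.list(sim$percentiles),
         mean = sim$mean, var = sim$var,
         p95_max_drift_pct = if (is.null(conv)) NA else conv$max_drift_pct)
  })
  json_path <- file.path(out_dir, "mcs_risk.json")
  write_json_file(list(meta = run_meta(seed = seed, config = list(n = n)),
                       cohorts = risk), json_path)

  tornado <- do.call(rbind, lapply(names(sens), function(nm) {
    d <- as.data.frame(sens[[nm]])
    cbind(cohort = nm, d)
  }))
  csv_path <- file.path(out_dir, "mcs_tornado.csv")
  write.csv(tornado, csv_path, row.names = FALSE, quote = FALSE)

  invisible(list(simulations = sims, sensitivity = sens,
                 paths = c(risk = json_path, tornado = csv_path)))
}

#' Surrogate training pipeline
#'
#' Generates (or accepts) the study, builds and standardizes the dataset,
#' runs the hyperparameter grid search, trains the selected candidate over
#' `n_seeds` seeds, and writes `ann_model.json` (best model),
#' `ann_metrics.json` and `ann_history.csv`.
#'
#' @inheritParams run_hq
#' @param study List of replicate-bearing `site_record`s; by default a
#'   synthetic study is generated from the packaged survey summaries.
#' @param config A [surrogate_config()].
#' @param seed Integer seed for study generation and dataset assembly.
#' @param n_seeds Number of final-training seeds (best kept).
#' @return Invisibly: `dataset`, `grid`, `runs` (see
#'   [train_over_seeds()]), `best` model and output paths.
#' @export
run_ann <- function(study = NULL, params = NULL, config = surrogate_config(),
                    seed, n_seeds = 5, out_dir = ".") {
  if (missing(seed)) stop_usage("'seed' is required for the ANN stage")
  cohorts <- resolve_cohorts(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(study)) study <- generate_study(seed = seed)

  dataset <- standardize(build_dataset(study, cohorts,
                                       fractions = config$fractions, seed = seed))
  grid <- grid_search(dataset, config)
  runs <- train_over_seeds(dataset, grid, config,
                           seeds = seed + seq_len(n_seeds) - 1L)
  best <- runs$best

  model_path <- file.path(out_dir, "ann_model.json")
  write_surrogate(best, model_path)
  metrics_path <- file.path(out_dir, "ann_metrics.json")
  write_json_file(list(
    meta = run_meta(seed = seed,
                    config = list(n_seeds = n_seeds,
                                  selected = list(hidden = best$hidden, l2 = best$l2,
                                                  learning_rate = best$learning_rate))),
    per_seed = runs$metrics,
    best = best$metrics
  ), metrics_path)
  history_path <- file.path(out_dir, "ann_history.csv")
  write.csv(as.data.frame(best$history), history_path, row.names = FALSE, quote = FALSE)

  invisible(list(dataset = dataset, grid = grid, runs = runs, best = best,
                 paths = c(model = model_path, metrics = metrics_path,
                           history = history_path)))
}

#' Synthetic study generation pipeline
#'
#' Generates replicate concentrations for every packaged (or supplied)
#' site specification and writes them as a replicate-mode site CSV that
#' [run_hq()] can read back.
#'
#' @param specs List of [site_spec()] objects
#'   (default [fluoride_site_specs()]).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, the study and the CSV path.
#' @export
run_simulate <- function(specs = fluoride_site_specs(), seed, out_dir = ".") {
  if (missing(seed)) stop_usage("'seed' is required for study generation")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_study(specs, seed = seed)
  path <- file.path(out_dir, "synthetic_sites.csv")
  write_sites(study, path, mode = "replicates")
  invisible(list(study = study, paths = c(sites = path)))
}

#' Consolidated run report
#'
#' Collects whatever stage outputs are present in `out_dir`
#' (district summary, exposure table, prevalence, MCS, ANN metrics) into
#' a single `report.json`; absent stages are marked `"absent"` rather
#' than failing.
#'
#' @param out_dir Directory holding stage outputs.
#' @return Invisibly, the report list and its path.
#' @export
run_report <- function(out_dir = ".") {
  if (!dir.exists(out_dir)) stop_usage(sprintf("output directory not found: %s", out_dir))
  grab_json <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else "absent"
  }
  grab_csv <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) read.csv(p, stringsAsFactors = FALSE) else "absent"
  }
  prevalence_files <- list.files(out_dir, "^prevalence_.*\\.json$")
  report <- list(
    meta = run_meta(),
    district_summary = grab_json("district_summary.json"),
    exposure_table = grab_csv("exposure_table.csv"),
    prevalence = if (length(prevalence_files)) {
      stats::setNames(lapply(prevalence_files, grab_json), prevalence_files)
    } else "absent",
    mcs = grab_json("mcs_risk.json"),
    sensitivity = grab_csv("mcs_tornado.csv"),
    ann = grab_json("ann_metrics.json")
  )
  path <- file.path(out_dir, "report.json")
  write_json_file(report, path)
  invisible(list(report = report, paths = c(report = path)))
}
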