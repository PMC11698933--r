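# Fluorosis endpoint classification and prevalence.

#' Fluorosis endpoint configuration
#'
#' An endpoint pairs a hazard-quotient threshold (default 1, the
#' conventional non-carcinogenic risk boundary) with an optional
#' endpoint-specific reference-dose override. Only the dental endpoint
#' ships as a default; reference doses for bone and skeletal fluorosis are
#' not published for this exposure model, so those endpoints must be
#' configured explicitly by the user.
#'
#' @param name Endpoint label (`"dental"`, `"bone"`, `"skeletal"`, or any
#'   custom string).
#' @param hq_threshold HQ threshold; a site exceeds the endpoint when its
#'   HQ is strictly greater than this value.
#' @param rfd_override Optional endpoint-specific RfD (mg/kg/day) replacing
#'   the cohort RfD.
#' @return An object of class `endpoint_config`.
#' @export
endpoint_config <- function(name = "dental", hq_threshold = 1,
                            rfd_override = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_domain("'name' must be a non-empty string")
  }
  check_number(hq_threshold, "hq_threshold", positive = TRUE)
  if (!is.null(rfd_override)) check_number(rfd_override, "rfd_override", positive = TRUE)
  structure(
    list(name = name, hq_threshold = hq_threshold, rfd_override = rfd_override),
    class = "endpoint_config"
  )
}

#' Endpoint-specific hazard quotient
#'
#' [compute_hq()] with the endpoint's reference-dose override applied when
#' present; with no override this is identical to the cohort HQ.
#'
#' @inheritParams compute_hq
#' @param config An [endpoint_config()].
#' @return Dimensionless hazard quotient.
#' @export
endpoint_hq <- function(C, params, config) {
  params <- as_cohort(params)
  if (!inherits(config, "endpoint_config")) {
    stop_usage("'config' must be an endpoint_config object")
  }
  rfd <- if (is.null(config$rfd_override)) params$RfD else config$rfd_override
  compute_cdi(C, params) / rfd
}

#' Classify sites against a fluorosis endpoint
#'
#' Counts, per cohort, the sites whose mean-concentration HQ strictly
#' exceeds the endpoint threshold, and reports the exceedance fraction as a
#' percentage. When the endpoint carries an RfD override the HQ is
#' recomputed as `CDI / rfd_override` from the table's CDI column.
#'
#' @param results Exposure table from [exposure_table()] (mean-variant rows
#'   are used).
#' @param config An [endpoint_config()].
#' @return An object of class `prevalence_report`: a list with `endpoint`,
#'   `threshold`, `table` (tibble: `endpoint`, `cohort`, `n_exceed`,
#'   `n_total`, `fraction_pct` unrounded, `fraction_display` rounded to the
#'   nearest integer) and `exceeding` (named list of exceeding site ids per
#'   cohort).
#' @export
#' @examples
#' tab <- exposure_table(fluoride_sites(), default_cohorts())
#' classify_sites(tab, endpoint_config("dental"))
classify_sites <- function(results, config = endpoint_config()) {
  results <- check_exposure_results(results)
  if (!inherits(config, "endpoint_config")) {
    stop_usage("'config' must be an endpoint_config object")
  }
  rows <- results[results$variant == "mean", , drop = FALSE]
  if (nrow(rows) == 0L) stop_usage("'results' has no mean-variant rows")
  if (any(is.na(rows$cohort)) || any(!nzchar(rows$cohort))) {
    stop_usage("exposure rows must carry cohort labels")
  }
  hq <- if (is.null(config$rfd_override)) {
    rows$HQ
  } else {
    if (!"CDI" %in% names(rows)) {
      stop_usage("RfD override requires a CDI column in the exposure table")
    }
    rows$CDI / config$rfd_override
  }

  cohorts <- unique(rows$cohort)
  exceeding <- lapply(cohorts, function(g) {
    sel <- rows$cohort == g
    rows$site_id[sel & hq > config$hq_threshold]
  })
  names(exceeding) <- cohorts
  n_total <- vapply(cohorts, function(g) sum(rows$cohort == g), integer(1))
  n_exceed <- vapply(exceeding, length, integer(1))
  frac <- 100 * n_exceed / n_total

  structure(
    list(
      endpoint = config$name,
      threshold = config$hq_threshold,
      table = tibble::tibble(
        endpoint = config$name,
        cohort = cohorts,
        n_exceed = unname(n_exceed),
        n_total = unname(n_total),
        fraction_pct = unname(frac),
        fraction_display = unname(round_half_up(frac, 0))
      ),
      exceeding = exceeding
    ),
    class = "prevalence_report"
  )
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat(sprintf("<prevalence_report> endpoint '%s', HQ threshold %g\n",
              x$endpoint, x$threshold))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s %d/%d sites (%g%%)\n", tab$cohort[i],
                tab$n_exceed[i], tab$n_total[i], tab$fraction_display[i]))
  }
  invisible(x)
}

#' Serialize a prevalence report
#'
#' Writes the tidy per-cohort table to CSV and the full report (including
#' exceeding site ids) to JSON.
#'
#' @param report A `prevalence_report` from [classify_sites()].
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return Invisibly, the written paths.
#' @export
write_prevalence <- function(report, csv_path = NULL, json_path = NULL) {
  if (!inherits(report, "prevalence_report")) {
    stop_usage("'report' must be a prevalence_report")
  }
  if (!is.null(csv_path)) {
    write.csv(as.data.frame(report$table), csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(endpoint = report$endpoint, threshold = report$threshold,
           cohorts = report$table, exceeding = report$exceeding),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(c(csv = csv_path, json = json_path))
}
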