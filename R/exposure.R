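# USEPA exposure algebra: total daily intake, chronic daily intake,
# hazard quotient, and dataset-level summaries.

#' Total daily intake of fluoride
#'
#' Mass of fluoride ingested per day through drinking water,
#' `TDI = C * IR` (mg/day). This is the per-day intake before
#' normalisation by body weight and averaging time.
#'
#' @param C Fluoride concentration, mg/L (vectorised, `>= 0`).
#' @param IR Water ingestion rate, L/day (`> 0`).
#' @return TDI in mg/day.
#' @export
#' @examples
#' compute_tdi(0.58, 0.78) # 0.4524 mg/day
compute_tdi <- function(C, IR) {
  if (!is.numeric(C) || any(!is.finite(C))) stop_domain("'C' must be finite")
  if (any(C < 0)) stop_domain("'C' (concentration) must be >= 0")
  check_number(IR, "IR", positive = TRUE)
  C * IR
}

#' Chronic daily intake of fluoride
#'
#' Body-weight-normalised chronic intake over the averaging period,
#' `CDI = C * IR * EF * ED / (BW * AT)` in mg/kg/day. When the cohort
#' satisfies `EF * ED = AT` (true for all shipped cohorts) this reduces to
#' `C * IR / BW`.
#'
#' @param C Fluoride concentration, mg/L (vectorised, `>= 0`).
#' @param params An [age_group_params()] object.
#' @return CDI in mg/kg/day.
#' @export
#' @examples
#' compute_cdi(0.58, default_cohorts()$children)
compute_cdi <- function(C, params) {
  params <- as_cohort(params)
  if (!is.numeric(C) || any(!is.finite(C))) stop_domain("'C' must be finite")
  if (any(C < 0)) stop_domain("'C' (concentration) must be >= 0")
  C * params$IR * params$EF * params$ED / (params$BW * params$AT)
}

#' Hazard quotient for fluoride ingestion
#'
#' `HQ = CDI / RfD`, dimensionless. HQ above 1 flags potential
#' non-carcinogenic risk.
#'
#' @inheritParams compute_cdi
#' @return Dimensionless hazard quotient.
#' @export
#' @examples
#' compute_hq(3.80, default_cohorts()$children) # about 3.29
compute_hq <- function(C, params) {
  params <- as_cohort(params)
  compute_cdi(C, params) / params$RfD
}

#' Deterministic exposure table over sites and cohorts
#'
#' Evaluates TDI, CDI and HQ for every (site, cohort) pair at the site's
#' minimum, mean and maximum concentration. The output is tidy: one row per
#' site x cohort x variant, in input order.
#'
#' @param sites List of [site_record()] objects.
#' @param cohorts List of [age_group_params()] objects.
#' @return A tibble with columns `site_id`, `location_name`, `cohort`,
#'   `variant` (`"min"`, `"mean"`, `"max"`), `C` (mg/L), `TDI` (mg/day),
#'   `CDI` (mg/kg/day) and `HQ` (dimensionless).
#' @export
#' @examples
#' tab <- exposure_table(fluoride_sites(), default_cohorts())
#' head(tab)
exposure_table <- function(sites, cohorts) {
  sites <- check_sites(sites)
  if (inherits(cohorts, "age_group_params")) cohorts <- list(cohorts)
  if (!is.list(cohorts) || length(cohorts) == 0L) {
    stop_usage("'cohorts' must be a non-empty list of age_group_params")
  }
  cohorts <- lapply(cohorts, as_cohort)
  variants <- c("min", "mean", "max")

  rows <- vector("list", length(sites) * length(cohorts))
  k <- 0L
  for (site in sites) {
    for (params in cohorts) {
      C <- vapply(variants, function(v) site$summary[[v]], numeric(1))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        site_id = site$site_id,
        location_name = site$location_name,
        cohort = params$name,
        variant = variants,
        C = unname(C),
        TDI = compute_tdi(unname(C), params$IR),
        CDI = compute_cdi(unname(C), params),
        HQ = compute_hq(unname(C), params)
      )
    }
  }
  do.call(rbind, rows)
}

#' District-level concentration summary
#'
#' Summarises a set of sites: overall minimum (over site minima), overall
#' maximum (over site maxima), the unweighted mean of site means, and the
#' exceedance fraction -- the percentage of site means strictly greater
#' than `threshold`. Exceedance is computed on site means because the
#' published survey reports summaries per site; a replicate-level fraction
#' is also returned when every site carries replicates.
#'
#' @param sites List of [site_record()] objects.
#' @param threshold Concentration threshold, mg/L (default 1.5, the
#'   BIS/WHO permissible limit for fluoride).
#' @return A list of class `district_summary`: `n_sites`, `min`, `max`,
#'   `mean_of_site_means`, `threshold`, `n_exceed`, `exceedance_pct`
#'   (unrounded), `replicate_exceedance_pct` (or `NA`), and `display`
#'   with the conventional rounded figures (mean to 2 decimals,
#'   percentage to 1).
#' @export
#' @examples
#' district_summary(fluoride_sites())
district_summary <- function(sites, threshold = 1.5) {
  sites <- check_sites(sites)
  check_number(threshold, "threshold", positive = TRUE)
  means <- vapply(sites, function(s) s$summary$mean, numeric(1))
  n_exceed <- sum(means > threshold)
  all_samples <- unlist(lapply(sites, function(s) s$samples))
  rep_pct <- if (length(all_samples) &&
                 !any(vapply(sites, function(s) is.null(s$samples), logical(1)))) {
    100 * base::mean(all_samples > threshold)
  } else {
    NA_real_
  }
  out <- list(
    n_sites = length(sites),
    min = base::min(vapply(sites, function(s) s$summary$min, numeric(1))),
    max = base::max(vapply(sites, function(s) s$summary$max, numeric(1))),
    mean_of_site_means = base::mean(means),
    threshold = threshold,
    n_exceed = n_exceed,
    exceedance_pct = 100 * n_exceed / length(sites),
    replicate_exceedance_pct = rep_pct
  )
  out$display <- list(
    mean_of_site_means = round_half_up(out$mean_of_site_means, 2),
    exceedance_pct = round_half_up(out$exceedance_pct, 1)
  )
  class(out) <- "district_summary"
  out
}

#' @export
print.district_summary <- function(x, ...) {
  cat(sprintf(
    "<district_summary> %d sites: %.2f-%.2f mg/L, mean of site means %.2f mg/L\n",
    x$n_sites, x$min, x$max, x$display$mean_of_site_means
  ))
  cat(sprintf("  site means > %.2f mg/L: %d/%d (%.1f%%)\n",
              x$threshold, x$n_exceed, x$n_sites, x$display$exceedance_pct))
  invisible(x)
}

#' Cohort-wise mean hazard quotient
#'
#' Arithmetic mean over sites of the mean-concentration HQ, per cohort.
#' Averages the unrounded HQ values.
#'
#' @param results Exposure table from [exposure_table()].
#' @return Tibble with columns `cohort`, `n_sites`, `mean_hq`.
#' @export
mean_hq_by_cohort <- function(results) {
  results <- check_exposure_results(results)
  mean_rows <- results[results$variant == "mean", , drop = FALSE]
  if (nrow(mean_rows) == 0L) stop_usage("'results' has no mean-variant rows")
  cohorts <- unique(mean_rows$cohort)
  tibble::tibble(
    cohort = cohorts,
    n_sites = vapply(cohorts, function(g) sum(mean_rows$cohort == g),
                     integer(1), USE.NAMES = FALSE),
    mean_hq = vapply(cohorts, function(g) base::mean(mean_rows$HQ[mean_rows$cohort == g]),
                     numeric(1), USE.NAMES = FALSE)
  )
}

check_exposure_results <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop_usage("'results' must be a non-empty exposure table")
  }
  need <- c("site_id", "cohort", "variant", "HQ")
  missing <- setdiff(need, names(results))
  if (length(missing)) {
    stop_usage(sprintf("exposure table lacks column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  results
}
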