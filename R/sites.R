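# Sampling-site records: replicate fluoride concentrations and summary stats.

#' Create a sampling-site record
#'
#' A site record holds the fluoride concentrations (mg/L) measured at one
#' sampling location, either as raw replicate values, as a min/max/mean/std
#' summary, or both. When replicates are given the summary is recomputed
#' from them; a supplied summary that disagrees with recomputed statistics
#' by more than `tol` (for min/max/mean) is an error, while a discrepant
#' standard deviation only warns (published summaries are rounded and a
#' small replicate set cannot always match all four statistics at once).
#'
#' @param site_id Short site label, e.g. `"S15"`.
#' @param location_name Free-text location name; defaults to `site_id`.
#' @param samples Optional numeric vector of replicate concentrations, mg/L.
#' @param min,max,mean,std Optional summary statistics, mg/L.
#' @param tol Agreement tolerance between supplied and recomputed
#'   min/max/mean (default 0.005, half a 2-decimal rounding unit).
#' @return An object of class `site_record` with fields `site_id`,
#'   `location_name`, `samples` and `summary` (list with min/max/mean/std).
#' @export
#' @examples
#' site_record("S1", "Nadrai Gate", min = 0.50, max = 0.70,
#'             mean = 0.58, std = 0.08)
site_record <- function(site_id, location_name = site_id, samples = NULL,
                        min = NULL, max = NULL, mean = NULL, std = NULL,
                        tol = 0.005) {
  if (!is.character(site_id) || length(site_id) != 1L || !nzchar(site_id)) {
    stop_domain("'site_id' must be a non-empty string")
  }
  supplied <- list(min = min, max = max, mean = mean, std = std)
  has_summary <- !all(vapply(supplied, is.null, logical(1)))

  if (!is.null(samples)) {
    if (!is.numeric(samples) || length(samples) < 1L || any(!is.finite(samples))) {
      stop_domain(sprintf("site %s: 'samples' must be finite numbers", site_id))
    }
    if (any(samples < 0)) {
      stop_domain(sprintf("site %s: concentrations must be >= 0", site_id))
    }
    computed <- list(
      min = base::min(samples),
      max = base::max(samples),
      mean = base::mean(samples),
      std = if (length(samples) > 1L) stats::sd(samples) else 0
    )
    if (has_summary) {
      for (f in c("min", "max", "mean")) {
        if (!is.null(supplied[[f]]) &&
            abs(supplied[[f]] - computed[[f]]) > tol + 1e-12) {
          stop_domain(sprintf(
            "site %s: supplied %s (%g) disagrees with recomputed value (%g)",
            site_id, f, supplied[[f]], computed[[f]]
          ))
        }
      }
      if (!is.null(supplied$std) && supplied$std > 0 &&
          abs(supplied$std - computed$std) > 0.35 * supplied$std) {
        warning(sprintf(
          "site %s: supplied std (%g) differs from recomputed std (%g)",
          site_id, supplied$std, computed$std
        ))
      }
    }
    summary <- computed
  } else {
    if (!has_summary) {
      stop_domain(sprintf("site %s: need either samples or a summary", site_id))
    }
    for (f in c("min", "max", "mean", "std")) {
      if (is.null(supplied[[f]])) {
        stop_domain(sprintf("site %s: summary mode requires min, max, mean and std", site_id))
      }
      check_number(supplied[[f]], f, nonneg = TRUE)
    }
    if (supplied$min > supplied$mean + 1e-12 || supplied$mean > supplied$max + 1e-12) {
      stop_domain(sprintf("site %s: need min <= mean <= max", site_id))
    }
    summary <- supplied
  }

  structure(
    list(site_id = site_id, location_name = location_name,
         samples = samples, summary = summary),
    class = "site_record"
  )
}

#' @export
print.site_record <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<site_record> %s (%s): min %.3g, mean %.3g, max %.3g mg/L%s\n",
    x$site_id, x$location_name, s$min, s$mean, s$max,
    if (is.null(x$samples)) " [summary only]"
    else sprintf(" [%d replicates]", length(x$samples))
  ))
  invisible(x)
}

#' Tabulate site summaries
#'
#' @param sites List of [site_record()] objects.
#' @return A tibble with one row per site: `site_id`, `location_name`,
#'   `n_samples`, `min`, `max`, `mean`, `std` (mg/L).
#' @export
site_summary_table <- function(sites) {
  sites <- check_sites(sites)
  tibble::tibble(
    site_id = vapply(sites, function(s) s$site_id, character(1)),
    location_name = vapply(sites, function(s) s$location_name, character(1)),
    n_samples = vapply(sites, function(s) length(s$samples), integer(1)),
    min = vapply(sites, function(s) s$summary$min, numeric(1)),
    max = vapply(sites, function(s) s$summary$max, numeric(1)),
    mean = vapply(sites, function(s) s$summary$mean, numeric(1)),
    std = vapply(sites, function(s) s$summary$std, numeric(1))
  )
}

check_sites <- function(sites) {
  if (inherits(sites, "site_record")) sites <- list(sites)
  if (!is.list(sites) || length(sites) == 0L) {
    stop_usage("'sites' must be a non-empty list of site_record objects")
  }
  if (!all(vapply(sites, inherits, logical(1), "site_record"))) {
    stop_usage("'sites' must contain only site_record objects")
  }
  sites
}

#' Read site records from CSV
#'
#' Two dialects are accepted, detected from the header. Replicate mode has
#' columns `site_id,location_name,sample_1,...,sample_k`; summary mode has
#' `site_id,location_name,min,max,mean,std`. Concentrations are mg/L,
#' decimal point, comma separated, header mandatory.
#'
#' @param path Path to a CSV file.
#' @return List of [site_record()] objects.
#' @seealso [write_sites()], [fluoride_sites()]
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("site file not found: %s", path))
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_usage(sprintf("malformed site CSV '%s': %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) stop_usage(sprintf("site CSV '%s' has no data rows", path))
  cols <- names(df)
  if (!all(c("site_id", "location_name") %in% cols)) {
    stop_usage("site CSV must have 'site_id' and 'location_name' columns")
  }
  sample_cols <- grep("^sample_[0-9]+$", cols, value = TRUE)
  summary_mode <- all(c("min", "max", "mean", "std") %in% cols)
  if (!summary_mode && length(sample_cols) == 0L) {
    stop_usage("site CSV must have either sample_1..sample_k or min/max/mean/std columns")
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    if (summary_mode) {
      for (f in c("min", "max", "mean", "std")) {
        if (!is.numeric(row[[f]]) || is.na(row[[f]])) {
          stop_usage(sprintf("site CSV row %d: column '%s' is not numeric", i, f))
        }
      }
      site_record(row$site_id, row$location_name,
                  min = row$min, max = row$max, mean = row$mean, std = row$std)
    } else {
      vals <- unlist(row[sample_cols], use.names = FALSE)
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L || !is.numeric(vals)) {
        stop_usage(sprintf("site CSV row %d: no numeric replicate values", i))
      }
      site_record(row$site_id, row$location_name, samples = as.numeric(vals))
    }
  })
}

#' Write site records to CSV
#'
#' @param sites List of [site_record()] objects.
#' @param path Output path.
#' @param mode `"replicates"` (requires samples on every site) or
#'   `"summary"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, mode = c("replicates", "summary")) {
  sites <- check_sites(sites)
  mode <- match.arg(mode)
  if (mode == "replicates") {
    if (any(vapply(sites, function(s) is.null(s$samples), logical(1)))) {
      stop_usage("mode 'replicates' requires samples on every site")
    }
    k <- max(vapply(sites, function(s) length(s$samples), integer(1)))
    rows <- lapply(sites, function(s) {
      vals <- c(s$samples, rep(NA_real_, k - length(s$samples)))
      c(list(site_id = s$site_id, location_name = s$location_name),
        as.list(stats::setNames(vals, paste0("sample_", seq_len(k)))))
    })
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  } else {
    df <- as.data.frame(site_summary_table(sites)[
      , c("site_id", "location_name", "min", "max", "mean", "std")])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged Kasganj fluoride survey summaries
#'
#' Loads the published per-site fluoride summary statistics for the 17
#' Kasganj (Uttar Pradesh, India) groundwater sampling locations: min, max,
#' mean and standard deviation in mg/L for each site. This is the default
#' input for the deterministic hazard-quotient pipeline and the anchor for
#' the synthetic replicate generator.
#'
#' @return List of 17 summary-mode [site_record()] objects.
#' @export
#' @examples
#' sites <- fluoride_sites()
#' site_summary_table(sites)
fluoride_sites <- function() {
  read_sites(system.file("extdata", "kasganj_fluoride_summary.csv",
                         package = "fluorisk", mustWork = TRUE))
}
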