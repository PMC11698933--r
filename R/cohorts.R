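# Age-cohort exposure parameter sets.

#' Exposure parameters for one age cohort
#'
#' Bundles the USEPA exposure-model parameters for a single age cohort:
#' averaging time (AT, days), exposure frequency (EF, days/year), exposure
#' duration (ED, years), body weight (BW, kg), drinking-water ingestion rate
#' (IR, L/day) and the oral reference dose (RfD, mg/kg/day).
#'
#' All parameters must be strictly positive and EF cannot exceed 366
#' days/year. When `EF * ED != AT` a warning (not an error) is raised:
#' the shipped cohorts all satisfy the identity exactly, and under it the
#' hazard quotient reduces to `C * IR / (BW * RfD)`.
#'
#' @param name Cohort label, e.g. `"children"`.
#' @param AT Averaging time, days.
#' @param EF Exposure frequency, days/year.
#' @param ED Exposure duration, years.
#' @param BW Body weight, kg.
#' @param IR Water ingestion rate, L/day.
#' @param RfD Reference dose, mg/kg/day.
#' @return An object of class `age_group_params`.
#' @seealso [default_cohorts()] for the shipped parameter sets.
#' @export
#' @examples
#' age_group_params("children", AT = 1460, EF = 365, ED = 4,
#'                  BW = 15, IR = 0.78, RfD = 0.06)
age_group_params <- function(name, AT, EF, ED, BW, IR, RfD) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_domain("'name' must be a non-empty string")
  }
  check_number(AT, "AT", positive = TRUE)
  check_number(EF, "EF", positive = TRUE)
  check_number(ED, "ED", positive = TRUE)
  check_number(BW, "BW", positive = TRUE)
  check_number(IR, "IR", positive = TRUE)
  check_number(RfD, "RfD", positive = TRUE)
  if (EF > 366) stop_domain("'EF' cannot exceed 366 days/year")
  if (abs(EF * ED - AT) > 1e-8 * AT) {
    warning(sprintf(
      "cohort '%s': EF * ED (%g) differs from AT (%g); HQ will not reduce to C*IR/(BW*RfD)",
      name, EF * ED, AT
    ))
  }
  structure(
    list(name = name, AT = AT, EF = EF, ED = ED, BW = BW, IR = IR, RfD = RfD),
    class = "age_group_params"
  )
}

#' @export
print.age_group_params <- function(x, ...) {
  cat(sprintf(
    "<age_group_params> %s: AT=%g d, EF=%g d/y, ED=%g y, BW=%g kg, IR=%g L/d, RfD=%g mg/kg/d\n",
    x$name, x$AT, x$EF, x$ED, x$BW, x$IR, x$RfD
  ))
  invisible(x)
}

#' Default age-cohort parameter sets
#'
#' The three cohorts used throughout the package: children (2-6 y),
#' teenagers (7-18 y) and adults (18-62 y), with the fluoride oral
#' reference dose of 0.06 mg/kg/day. For every cohort `EF * ED = AT`.
#'
#' @return Named list of [age_group_params()] objects
#'   (`children`, `teenagers`, `adults`).
#' @export
default_cohorts <- function() {
  list(
    children = age_group_params("children",
      AT = 1460, EF = 365, ED = 4, BW = 15, IR = 0.78, RfD = 0.06),
    teenagers = age_group_params("teenagers",
      AT = 4745, EF = 365, ED = 13, BW = 50, IR = 2, RfD = 0.06),
    adults = age_group_params("adults",
      AT = 14600, EF = 365, ED = 40, BW = 78, IR = 2.5, RfD = 0.06)
  )
}

#' Read cohort parameters from a YAML or JSON file
#'
#' The document must be a mapping keyed by cohort name, each entry holding
#' the fields `AT`, `EF`, `ED`, `BW`, `IR`, `RfD` (see [age_group_params()]
#' for units).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of `age_group_params` objects.
#' @export
read_cohorts <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("cohort file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop_usage("cohort file must be a mapping keyed by cohort name")
  }
  out <- lapply(names(raw), function(nm) {
    fields <- raw[[nm]]
    need <- c("AT", "EF", "ED", "BW", "IR", "RfD")
    missing <- setdiff(need, names(fields))
    if (length(missing)) {
      stop_usage(sprintf("cohort '%s' is missing field(s): %s",
                         nm, paste(missing, collapse = ", ")))
    }
    age_group_params(nm, AT = fields$AT, EF = fields$EF, ED = fields$ED,
                     BW = fields$BW, IR = fields$IR, RfD = fields$RfD)
  })
  names(out) <- names(raw)
  out
}

# accept either an age_group_params or a bare named list with the fields
as_cohort <- function(params) {
  if (inherits(params, "age_group_params")) return(params)
  if (is.list(params) && all(c("AT", "EF", "ED", "BW", "IR", "RfD") %in% names(params))) {
    nm <- if (!is.null(params$name)) params$name else "cohort"
    return(age_group_params(nm, params$AT, params$EF, params$ED,
                            params$BW, params$IR, params$RfD))
  }
  stop_domain("'params' must be an age_group_params object")
}
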