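# Parametric distribution specifications for Monte Carlo inputs.
#
# Families: point, uniform, triangular, truncnorm, lognormal, plus a
# finite mixture (used for the site-mixture concentration default). All
# supports must be non-negative; sampling uses inverse-CDF transforms so a
# given RNG state maps deterministically to draws.

new_dist_spec <- function(family, pars) {
  structure(c(list(family = family), pars), class = "dist_spec")
}

#' Distribution specifications for Monte Carlo inputs
#'
#' Constructors for the parametric families accepted by [sample_inputs()]:
#' a degenerate point mass, uniform, triangular, normal truncated to
#' `[lower, upper]`, lognormal (optionally truncated) and a finite mixture
#' of other specs. Supports must be non-negative since every exposure
#' input is a physical quantity.
#'
#' @param value Point-mass value (`dist_point`).
#' @param min,max Support bounds (`dist_uniform`, `dist_triangular`).
#' @param mode Triangular mode, `min <= mode <= max`.
#' @param mean,sd Normal mean and standard deviation before truncation.
#' @param meanlog,sdlog Lognormal log-scale parameters.
#' @param lower,upper Truncation bounds.
#' @param components List of `dist_spec` objects (`dist_mixture`).
#' @param weights Mixture weights, recycled to equal weights when omitted.
#' @return An object of class `dist_spec`.
#' @name dist_spec
#' @examples
#' dist_triangular(0.5, 0.58, 0.7)
#' dist_truncnorm(15, 1.8, lower = 0)
NULL

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  check_number(value, "value", nonneg = TRUE)
  new_dist_spec("point", list(value = value))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max) {
  check_number(min, "min", nonneg = TRUE)
  check_number(max, "max", nonneg = TRUE)
  if (min > max) stop_domain("uniform: need min <= max")
  new_dist_spec("uniform", list(min = min, max = max))
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max) {
  check_number(min, "min", nonneg = TRUE)
  check_number(mode, "mode", nonneg = TRUE)
  check_number(max, "max", nonneg = TRUE)
  if (min > mode || mode > max) stop_domain("triangular: need min <= mode <= max")
  new_dist_spec("triangular", list(min = min, mode = mode, max = max))
}

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(mean, sd, lower = 0, upper = Inf) {
  check_number(mean, "mean")
  check_number(sd, "sd", nonneg = TRUE)
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    stop_domain("truncnorm: need lower < upper")
  }
  if (lower < 0) stop_domain("truncnorm: support must be non-negative")
  new_dist_spec("truncnorm", list(mean = mean, sd = sd, lower = lower, upper = upper))
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog, lower = 0, upper = Inf) {
  check_number(meanlog, "meanlog")
  check_number(sdlog, "sdlog", nonneg = TRUE)
  if (lower < 0 || lower >= upper) stop_domain("lognormal: need 0 <= lower < upper")
  new_dist_spec("lognormal", list(meanlog = meanlog, sdlog = sdlog,
                                  lower = lower, upper = upper))
}

#' @rdname dist_spec
#' @export
dist_mixture <- function(components, weights = NULL) {
  if (!is.list(components) || length(components) == 0L ||
      !all(vapply(components, inherits, logical(1), "dist_spec"))) {
    stop_domain("mixture: 'components' must be a non-empty list of dist_spec")
  }
  if (is.null(weights)) weights <- rep(1, length(components))
  if (length(weights) != length(components) || any(weights < 0) || sum(weights) <= 0) {
    stop_domain("mixture: invalid weights")
  }
  new_dist_spec("mixture", list(components = components,
                                weights = weights / sum(weights)))
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  if (x$family == "mixture") {
    cat(sprintf("<dist_spec> mixture of %d components\n", length(x$components)))
  } else {
    cat(sprintf("<dist_spec> %s(%s)\n", x$family,
                paste(sprintf("%s=%g", names(pars), unlist(pars)), collapse = ", ")))
  }
  invisible(x)
}

is_point <- function(spec) {
  if (spec$family == "point") return(TRUE)
  if (spec$family == "mixture") return(all(vapply(spec$components, is_point, logical(1))))
  FALSE
}

# Draw n values using the current RNG state.
sample_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) stop_usage("expected a dist_spec object")
  switch(spec$family,
    point = rep(spec$value, n),
    uniform = runif(n, spec$min, spec$max),
    triangular = {
      a <- spec$min; c <- spec$mode; b <- spec$max
      if (a == b) return(rep(a, n))
      u <- runif(n)
      fc <- (c - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (c - a)),
             b - sqrt((1 - u) * (b - a) * (b - c)))
    },
    truncnorm = {
      if (spec$sd == 0) return(rep(spec$mean, n))
      plo <- pnorm(spec$lower, spec$mean, spec$sd)
      phi <- pnorm(spec$upper, spec$mean, spec$sd)
      if (phi - plo < 1e-12) {
        stop_domain("truncnorm: truncation interval has negligible probability mass")
      }
      qnorm(runif(n, plo, phi), spec$mean, spec$sd)
    },
    lognormal = {
      if (spec$sdlog == 0) return(rep(exp(spec$meanlog), n))
      plo <- stats::plnorm(spec$lower, spec$meanlog, spec$sdlog)
      phi <- stats::plnorm(spec$upper, spec$meanlog, spec$sdlog)
      if (phi - plo < 1e-12) {
        stop_domain("lognormal: truncation interval has negligible probability mass")
      }
      qlnorm(runif(n, plo, phi), spec$meanlog, spec$sdlog)
    },
    mixture = {
      idx <- sample.int(length(spec$components), n, replace = TRUE,
                        prob = spec$weights)
      out <- numeric(n)
      for (j in seq_along(spec$components)) {
        sel <- idx == j
        if (any(sel)) out[sel] <- sample_dist(spec$components[[j]], sum(sel))
      }
      out
    },
    stop_usage(sprintf("unsupported distribution family: '%s'", spec$family))
  )
}

# Build a dist_spec from a plain list (YAML/JSON round trip).
dist_from_list <- function(x) {
  if (!is.list(x) || is.null(x$family)) {
    stop_usage("distribution spec must be a list with a 'family' field")
  }
  switch(x$family,
    point = dist_point(x$value),
    uniform = dist_uniform(x$min, x$max),
    triangular = dist_triangular(x$min, x$mode, x$max),
    truncnorm = dist_truncnorm(x$mean, x$sd,
                               lower = x$lower %||% 0, upper = x$upper %||% Inf),
    lognormal = dist_lognormal(x$meanlog, x$sdlog,
                               lower = x$lower %||% 0, upper = x$upper %||% Inf),
    mixture = dist_mixture(lapply(x$components, dist_from_list), x$weights),
    stop_usage(sprintf("unsupported distribution family: '%s'", x$family))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
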