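# Dataset assembly and standardization for the HQ surrogate.

SURROGATE_FEATURES <- c("C", "EF", "IR", "ED", "BW", "AT")

#' Build a surrogate dataset from sites and cohorts
#'
#' One row per water sample (site replicate). Each sample is assigned to a
#' single age cohort uniformly at random (seeded), which makes all six
#' exposure features vary across rows; the regression target is the
#' analytic hazard quotient of that row. Rows are then randomly
#' partitioned into train/validation/test splits: validation and test
#' sizes are the rounded fractions, training takes the remainder (85 rows
#' at 80/10/10 gives 69/8/8).
#'
#' @param sites List of [site_record()] objects carrying replicates.
#' @param cohorts List of [age_group_params()] objects.
#' @param fractions Named numeric vector `c(train=, validation=, test=)`
#'   summing to 1.
#' @param seed Integer RNG seed (drives cohort assignment and the split).
#' @return An object of class `surrogate_dataset`: list with `data`
#'   (tibble: `site_id`, `cohort`, the six features, `HQ`, `split`),
#'   `feature_names`, `fractions`, `seed` and `scaler`
#'   (`NULL` until [standardize()]).
#' @export
#' @examples
#' study <- generate_study(seed = 1)
#' ds <- build_dataset(study, default_cohorts(), seed = 1)
#' table(ds$data$split)
build_dataset <- function(sites, cohorts,
                          fractions = c(train = 0.8, validation = 0.1, test = 0.1),
                          seed) {
  sites <- check_sites(sites)
  if (inherits(cohorts, "age_group_params")) cohorts <- list(cohorts)
  cohorts <- lapply(cohorts, as_cohort)
  if (!is.numeric(fractions) || length(fractions) != 3L ||
      any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop_usage("'fractions' must be three non-negative numbers summing to 1")
  }
  names(fractions) <- c("train", "validation", "test")
  check_number(seed, "seed")
  if (any(vapply(sites, function(s) is.null(s$samples), logical(1)))) {
    stop_usage("all sites need replicate samples; generate them first (see generate_study)")
  }

  site_id <- unlist(lapply(sites, function(s) rep(s$site_id, length(s$samples))))
  C <- unlist(lapply(sites, function(s) s$samples))
  n <- length(C)
  if (n < 20L) stop_usage(sprintf("need at least 20 samples, got %d", n))

  set.seed(as.integer(seed))
  cidx <- sample.int(length(cohorts), n, replace = TRUE)
  get <- function(field) vapply(cidx, function(i) cohorts[[i]][[field]], numeric(1))
  hq <- mapply(function(conc, i) compute_hq(conc, cohorts[[i]]), C, cidx)

  n_val <- round(n * fractions[["validation"]])
  n_test <- round(n * fractions[["test"]])
  split <- rep("train", n)
  perm <- sample.int(n)
  if (n_val > 0) split[perm[seq_len(n_val)]] <- "validation"
  if (n_test > 0) split[perm[n_val + seq_len(n_test)]] <- "test"

  data <- tibble::tibble(
    site_id = site_id,
    cohort = vapply(cidx, function(i) cohorts[[i]]$name, character(1)),
    C = C,
    EF = get("EF"),
    IR = get("IR"),
    ED = get("ED"),
    BW = get("BW"),
    AT = get("AT"),
    HQ = unname(hq),
    split = split
  )
  structure(
    list(data = data, feature_names = SURROGATE_FEATURES,
         fractions = fractions, seed = as.integer(seed), scaler = NULL),
    class = "surrogate_dataset"
  )
}

#' @export
print.surrogate_dataset <- function(x, ...) {
  tab <- table(x$data$split)
  cat(sprintf("<surrogate_dataset> %d rows (%s)%s\n", nrow(x$data),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              if (is.null(x$scaler)) "" else ", standardized"))
  invisible(x)
}

#' Fit a feature standardization on the training split
#'
#' Computes per-feature mean and standard deviation on training rows only
#' and stores them on the dataset; validation and test rows are
#' transformed with the same statistics, so no information leaks out of
#' the training split. Features that are constant on the training split
#' (zero sd) are centred but not rescaled and flagged in
#' `scaler$constant`. The target is left on its raw HQ scale.
#'
#' @param dataset A `surrogate_dataset` from [build_dataset()].
#' @return The dataset with `scaler` set
#'   (`list(center, scale, constant)`).
#' @export
standardize <- function(dataset) {
  if (!inherits(dataset, "surrogate_dataset")) {
    stop_usage("'dataset' must be a surrogate_dataset")
  }
  tr <- dataset$data[dataset$data$split == "train", dataset$feature_names]
  if (nrow(tr) < 2L) stop_usage("training split too small to fit a scaler")
  center <- vapply(tr, base::mean, numeric(1))
  scale <- vapply(tr, stats::sd, numeric(1))
  constant <- scale < 1e-12
  scale[constant] <- 1
  dataset$scaler <- list(center = center, scale = scale, constant = constant)
  dataset
}

# raw feature matrix for a split (NULL = all rows)
feature_matrix <- function(dataset, split = NULL) {
  d <- dataset$data
  if (!is.null(split)) d <- d[d$split == split, , drop = FALSE]
  as.matrix(d[, dataset$feature_names])
}

# z-scored features using the stored scaler
scaled_features <- function(dataset, split = NULL) {
  if (is.null(dataset$scaler)) stop_usage("dataset has no scaler; call standardize() first")
  X <- feature_matrix(dataset, split)
  sweep(sweep(X, 2, dataset$scaler$center), 2, dataset$scaler$scale, "/")
}

# inverse of scaled_features for a raw matrix of scaled values
unscale_features <- function(scaler, Xs) {
  sweep(sweep(Xs, 2, scaler$scale, "*"), 2, scaler$center, "+")
}

split_target <- function(dataset, split = NULL) {
  d <- dataset$data
  if (!is.null(split)) d <- d[d$split == split, , drop = FALSE]
  d$HQ
}
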