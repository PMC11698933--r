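# Published reference values used as reproduction oracles.

site_ids <- paste0("S", 1:17)

# Deterministic hazard quotients at site-mean concentrations, 2 decimals
# (children, teenagers, adults).
hq_reference <- matrix(c(
  0.50, 0.39, 0.31,
  1.21, 0.93, 0.75,
  1.56, 1.20, 0.96,
  1.56, 1.20, 0.96,
  1.56, 1.20, 0.96,
  2.08, 1.60, 1.28,
  1.56, 1.20, 0.96,
  2.25, 1.73, 1.39,
  2.17, 1.67, 1.34,
  2.41, 1.85, 1.49,
  2.17, 1.67, 1.34,
  1.94, 1.49, 1.20,
  2.95, 2.27, 1.82,
  2.10, 1.61, 1.29,
  3.29, 2.53, 2.03,
  2.30, 1.77, 1.42,
  2.31, 1.77, 1.42
), ncol = 3, byrow = TRUE,
dimnames = list(site_ids, c("children", "teenagers", "adults")))

# Total daily intake (mg/day) at site min/max/mean concentration,
# 3 decimals, one block per cohort.
tdi_reference <- list(
  children = matrix(c(
    0.390, 0.546, 0.452,
    1.030, 1.154, 1.092,
    1.342, 1.482, 1.404,
    1.287, 1.482, 1.404,
    1.326, 1.466, 1.404,
    1.466, 2.184, 1.872,
    1.287, 1.482, 1.404,
    1.872, 2.262, 2.028,
    1.404, 2.418, 1.950,
    1.794, 2.418, 2.168,
    1.794, 2.184, 1.950,
    0.858, 2.184, 1.747,
    2.262, 3.042, 2.652,
    1.248, 2.340, 1.888,
    2.808, 3.120, 2.964,
    1.716, 2.418, 2.067,
    1.950, 2.184, 2.075
  ), ncol = 3, byrow = TRUE, dimnames = list(site_ids, c("min", "max", "mean"))),
  teenagers = matrix(c(
    1.000, 1.400, 1.160,
    2.640, 2.960, 2.800,
    3.440, 3.800, 3.600,
    3.300, 3.800, 3.600,
    3.400, 3.760, 3.600,
    3.760, 5.600, 4.800,
    3.300, 3.800, 3.600,
    4.800, 5.800, 5.200,
    3.600, 6.200, 5.000,
    4.600, 6.200, 5.560,
    4.600, 5.600, 5.000,
    2.200, 5.600, 4.480,
    5.800, 7.800, 6.800,
    3.200, 6.000, 4.840,
    7.200, 8.000, 7.600,
    4.400, 6.200, 5.300,
    5.000, 5.600, 5.320
  ), ncol = 3, byrow = TRUE, dimnames = list(site_ids, c("min", "max", "mean"))),
  adults = matrix(c(
    1.250, 1.750, 1.450,
    3.300, 3.700, 3.500,
    4.300, 4.750, 4.500,
    4.125, 4.750, 4.500,
    4.250, 4.700, 4.500,
    4.700, 7.000, 6.000,
    4.125, 4.750, 4.500,
    6.000, 7.250, 6.500,
    4.500, 7.750, 6.250,
    5.750, 7.750, 6.950,
    5.750, 7.000, 6.250,
    2.750, 7.000, 5.600,
    7.250, 9.750, 8.500,
    4.000, 7.500, 6.050,
    9.000, 10.000, 9.500,
    5.500, 7.750, 6.625,
    6.250, 7.000, 6.650
  ), ncol = 3, byrow = TRUE, dimnames = list(site_ids, c("min", "max", "mean")))
)

# quick toy sites for unit tests
toy_sites <- function(means = c(1, 2, 3)) {
  lapply(seq_along(means), function(i) {
    site_record(sprintf("T%d", i), min = means[i], max = means[i],
                mean = means[i], std = 0)
  })
}

# exposure-table-shaped tibble from a bare HQ vector (one cohort)
toy_results <- function(hq, cohort = "children") {
  tibble::tibble(
    site_id = sprintf("T%d", seq_along(hq)),
    cohort = cohort,
    variant = "mean",
    C = hq, TDI = hq, CDI = hq * 0.06, HQ = hq
  )
}
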