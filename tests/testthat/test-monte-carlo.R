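children <- default_cohorts()$children

point_specs <- function(C = 3.80) {
  list(C = dist_point(C), IR = dist_point(children$IR),
       EF = dist_point(children$EF), ED = dist_point(children$ED),
       BW = dist_point(children$BW), AT = dist_point(children$AT))
}

test_that("point-mass specs collapse to the deterministic hazard quotient", {
  draws <- sample_inputs(point_specs(), n = 50, seed = 1)
  expect_equal(nrow(unique(draws)), 1L)

  sim <- simulate_hq(point_specs(), children, n = 200, seed = 1)
  expect_true(all(sim$hq == compute_hq(3.80, children)))
  expect_equal(round_half_up(sim$percentiles[["P95"]], 2), 3.29)
  expect_equal(sim$percentiles[["P95"]], sim$percentiles[["P50"]])
})

test_that("sampled moments match closed forms", {
  n <- 20000
  u <- sample_inputs(c(point_specs()[-1], list(C = dist_uniform(0, 1))),
                     n = n, seed = 7)[, "C"]
  se <- sqrt(1 / 12 / n)
  expect_lt(abs(mean(u) - 0.5), 3 * se)
  expect_true(all(u >= 0 & u <= 1))

  ln <- sample_inputs(c(point_specs()[-1], list(C = dist_lognormal(0.3, 0.4))),
                      n = n, seed = 8)[, "C"]
  expect_lt(abs(median(ln) - exp(0.3)), 0.03)

  tr <- sample_inputs(c(point_specs()[-1],
                        list(C = dist_triangular(1, 2, 4))), n = n, seed = 9)[, "C"]
  expect_true(all(tr >= 1 & tr <= 4))
  expect_lt(abs(mean(tr) - (1 + 2 + 4) / 3), 0.02)  # mean = (a+c+b)/3
})

test_that("uniform concentration gives the closed-form P95 of a linear map", {
  a <- 1; b <- 4; n <- 10000
  specs <- list(C = dist_uniform(a, b))
  sim <- simulate_hq(specs, children, n = n, seed = 11)
  slope <- children$IR / (children$BW * children$RfD)
  expected <- slope * (a + 0.95 * (b - a))
  se <- sqrt(0.95 * 0.05 / n) * slope * (b - a)  # quantile SE, f = 1/range
  expect_lt(abs(sim$percentiles[["P95"]] - expected), 3 * se)
})

test_that("simulation is deterministic under a fixed seed", {
  specs <- list(C = dist_triangular(0.5, 0.58, 0.7),
                BW = dist_truncnorm(15, 1.5, lower = 0))
  s1 <- simulate_hq(specs, children, n = 2000, seed = 99)
  s2 <- simulate_hq(specs, children, n = 2000, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_hq(specs, children, n = 2000, seed = 100)
  expect_false(identical(s1$hq, s3$hq))
})

test_that("percentiles are monotone and HQ non-negative on random specs", {
  set.seed(303)
  for (i in 1:10) {
    a <- runif(1, 0, 2); b <- a + runif(1, 0.1, 3)
    specs <- list(C = dist_uniform(a, b),
                  BW = dist_truncnorm(15, runif(1, 0.5, 4), lower = 1))
    sim <- simulate_hq(specs, children, n = 500, seed = i)
    p <- sim$percentiles
    expect_true(all(diff(p) >= 0))
    expect_true(all(sim$hq >= 0))
  }
})

test_that("scaling the concentration distribution scales every percentile", {
  k <- 2.5
  s1 <- simulate_hq(list(C = dist_uniform(1, 3)), children, n = 5000, seed = 5)
  s2 <- simulate_hq(list(C = dist_uniform(k * 1, k * 3)), children,
                    n = 5000, seed = 5)
  expect_equal(s2$percentiles, k * s1$percentiles)
})

test_that("sensitivity contributions are normalized and attribute variance correctly", {
  # single stochastic input takes all the variance
  sen <- sensitivity(list(C = dist_uniform(1, 3)), children, n = 2000, seed = 2)
  expect_equal(sen$contribution_pct[sen$input == "C"], 100)
  expect_equal(sum(sen$contribution_pct), 100)

  # symmetric log-variances split 50/50
  sen2 <- sensitivity(
    list(C = dist_lognormal(log(2.3), 0.3),
         BW = dist_lognormal(log(15), 0.3)),
    children, n = 10000, seed = 3
  )
  expect_equal(sum(sen2$contribution_pct), 100)
  cC <- sen2$contribution_pct[sen2$input == "C"]
  cBW <- sen2$contribution_pct[sen2$input == "BW"]
  expect_lt(abs(cC - 50), 5)
  expect_lt(abs(cBW - 50), 5)
  # point-mass inputs contribute nothing
  expect_equal(sen2$contribution_pct[sen2$input == "IR"], 0)

  expect_error(sensitivity(point_specs(), children, n = 100, seed = 1),
               class = "fluorisk_usage_error")
})

test_that("default specification ranks concentration above body weight above intake", {
  sites <- fluoride_sites()
  for (seed in c(1, 7, 42)) {
    sen <- sensitivity(default_mcs_specs(sites, children), children,
                       n = 10000, seed = seed)
    ord <- attr(sen, "ordering")
    expect_equal(ord[1:3], c("C", "BW", "IR"))
  }
})

test_that("P95 risk preserves the cohort ordering", {
  sites <- fluoride_sites()
  coh <- default_cohorts()
  p95 <- vapply(coh, function(cohort) {
    simulate_hq(default_mcs_specs(sites, cohort), cohort,
                n = 10000, seed = 21)$percentiles[["P95"]]
  }, numeric(1))
  expect_true(p95[["children"]] > p95[["teenagers"]])
  expect_true(p95[["teenagers"]] > p95[["adults"]])
})

test_that("convergence check flags drift correctly", {
  sim <- simulate_hq(point_specs(), children, n = 4000, seed = 1)
  conv <- convergence_check(sim, block = 1000)
  expect_equal(conv$max_drift_pct, 0)
  expect_false(conv$flagged)

  sim2 <- simulate_hq(list(C = dist_uniform(1, 4)), children,
                      n = 10000, seed = 2)
  conv2 <- convergence_check(sim2, block = 1000)
  expect_lt(conv2$max_drift_pct, 2)

  expect_error(convergence_check(sim, block = 3000),
               class = "fluorisk_usage_error")
})

test_that("spec construction and file parsing reject bad input", {
  expect_error(dist_uniform(-1, 2), class = "fluorisk_domain_error")
  expect_error(dist_triangular(1, 0.5, 2), class = "fluorisk_domain_error")
  expect_error(dist_from_list_error <- read_mcs_specs("no/such/file.yaml"),
               class = "fluorisk_usage_error")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "C: {family: triangular, min: 0.5, mode: 0.58, max: 0.7}",
    "BW: {family: truncnorm, mean: 15, sd: 1.5}"
  ), path)
  specs <- read_mcs_specs(path)
  expect_s3_class(specs$C, "dist_spec")
  expect_equal(specs$C$mode, 0.58)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("C: {family: beta, a: 1, b: 2}", bad)
  expect_error(read_mcs_specs(bad), "family", class = "fluorisk_usage_error")
})
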