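test_that("intake algebra matches hand-computed values", {
  # TDI = C * IR
  expect_equal(compute_tdi(3.80, 2.5), 9.50)
  expect_equal(round_half_up(compute_tdi(0.58, 0.78), 3), 0.452)
  expect_equal(compute_tdi(0, 1), 0)

  children <- default_cohorts()$children
  adults <- default_cohorts()$adults
  # CDI reduces to C*IR/BW when EF*ED = AT
  expect_equal(compute_cdi(0.58, children), 0.58 * 0.78 / 15)
  expect_equal(compute_cdi(0.58, children), 0.03016, tolerance = 1e-6)
  expect_equal(compute_cdi(0, children), 0)
  expect_equal(compute_cdi(3.80, adults), 3.80 * 2.5 * 365 * 40 / (78 * 14600))
  expect_equal(compute_cdi(3.80, adults), 0.12179, tolerance = 1e-4)
})

test_that("hazard quotients reproduce the published headline values", {
  coh <- default_cohorts()
  expect_equal(round_half_up(compute_hq(3.80, coh$children), 2), 3.29)
  expect_equal(round_half_up(compute_hq(0.58, coh$adults), 2), 0.31)
  expect_equal(round_half_up(compute_hq(3.80, coh$teenagers), 2), 2.53)
  expect_equal(compute_hq(0, coh$children), 0)
})

test_that("intake functions reject out-of-domain inputs", {
  expect_error(compute_tdi(-1, 1), "C", class = "fluorisk_domain_error")
  expect_error(compute_tdi(1, 0), "IR", class = "fluorisk_domain_error")
  expect_error(compute_cdi(-0.5, default_cohorts()$adults),
               class = "fluorisk_domain_error")
  expect_error(
    age_group_params("x", AT = 100, EF = 365, ED = 1, BW = 0, IR = 1, RfD = 0.06),
    "BW", class = "fluorisk_domain_error"
  )
  expect_warning(
    age_group_params("x", AT = 100, EF = 365, ED = 1, BW = 10, IR = 1, RfD = 0.06),
    "EF \\* ED"
  )
})

test_that("exposure table reproduces the published HQ matrix at 2 decimals", {
  tab <- exposure_table(fluoride_sites(), default_cohorts())
  for (cohort in colnames(hq_reference)) {
    got <- tab$HQ[tab$cohort == cohort & tab$variant == "mean"]
    expect_equal(round_half_up(got, 2), unname(hq_reference[, cohort]),
                 info = cohort)
  }
})

test_that("exposure table reproduces the published intake blocks at 3 decimals", {
  tab <- exposure_table(fluoride_sites(), default_cohorts())
  for (cohort in names(tdi_reference)) {
    for (variant in c("min", "max", "mean")) {
      got <- tab$TDI[tab$cohort == cohort & tab$variant == variant]
      expect_equal(round_half_up(got, 3), unname(tdi_reference[[cohort]][, variant]),
                   info = paste(cohort, variant))
    }
  }
})

test_that("degenerate site yields identical min/mean/max variants", {
  tab <- exposure_table(toy_sites(2)[1], default_cohorts()["children"])
  expect_equal(length(unique(tab$HQ)), 1L)
  expect_equal(length(unique(tab$TDI)), 1L)
})

test_that("exposure table is pure and order-preserving", {
  sites <- fluoride_sites()
  coh <- default_cohorts()
  expect_identical(exposure_table(sites, coh), exposure_table(sites, coh))
  tab <- exposure_table(sites, coh)
  expect_equal(unique(tab$site_id), site_ids)
  expect_error(exposure_table(list(), coh), class = "fluorisk_usage_error")
})

test_that("HQ is linear in concentration and monotone in each parameter", {
  set.seed(101)
  base <- default_cohorts()$children
  for (i in 1:20) {
    C <- runif(1, 0.1, 5)
    k <- runif(1, 0, 3)
    expect_equal(compute_hq(k * C, base), k * compute_hq(C, base))

    bump <- function(field, f) {
      p <- unclass(base)
      p[[field]] <- p[[field]] * f
      suppressWarnings(as_fields <- age_group_params(p$name, p$AT, p$EF, p$ED,
                                                     p$BW, p$IR, p$RfD))
      as_fields
    }
    up <- 1 + runif(1, 0.01, 0.5)
    expect_lt(compute_hq(C, bump("BW", up)), compute_hq(C, base))
    expect_lt(compute_hq(C, bump("RfD", up)), compute_hq(C, base))
    expect_gt(compute_hq(C, bump("IR", up)), compute_hq(C, base))
    expect_gt(compute_hq(C, bump("ED", up)), compute_hq(C, base))
  }
})

test_that("HQ reduces to C*IR/(BW*RfD) when EF*ED equals AT", {
  for (params in default_cohorts()) {
    C <- c(0.5, 1.23, 3.8)
    expect_equal(compute_hq(C, params),
                 C * params$IR / (params$BW * params$RfD))
  }
})

test_that("district summary reproduces the survey-level statistics", {
  ds <- district_summary(fluoride_sites(), threshold = 1.5)
  expect_equal(ds$display$mean_of_site_means, 2.30)
  expect_equal(ds$n_exceed, 15L)
  expect_equal(ds$display$exceedance_pct, 88.2)
  expect_equal(ds$min, 0.50)
  expect_equal(ds$max, 4.00)
})

test_that("district summary on toy data matches a brute-force count", {
  sites <- toy_sites(c(1, 2, 3))
  ds <- district_summary(sites, threshold = 1.5)
  expect_equal(ds$mean_of_site_means, 2)
  expect_equal(ds$exceedance_pct, 100 * 2 / 3)
  # strict inequality: sites exactly at the threshold do not exceed it
  at <- district_summary(toy_sites(c(1.5, 1.5)), threshold = 1.5)
  expect_equal(at$exceedance_pct, 0)
})

test_that("cohort mean HQ matches the published averages", {
  tab <- exposure_table(fluoride_sites(), default_cohorts())
  m <- mean_hq_by_cohort(tab)
  expect_equal(round_half_up(m$mean_hq[m$cohort == "children"], 2), 1.99)
  expect_equal(round_half_up(m$mean_hq[m$cohort == "teenagers"], 2), 1.53)
  expect_equal(round_half_up(m$mean_hq[m$cohort == "adults"], 2), 1.23)

  single <- exposure_table(fluoride_sites()[1], default_cohorts()["children"])
  ms <- mean_hq_by_cohort(single)
  expect_equal(ms$mean_hq, single$HQ[single$variant == "mean"])
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(2.305, 2), 2.31)
  expect_equal(round_half_up(-2.305, 2), -2.31)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(1.9953, 2), 2.00)
})
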