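test_that("dental prevalence matches the published percentages", {
  tab <- exposure_table(fluoride_sites(), default_cohorts())
  rep <- classify_sites(tab, endpoint_config("dental"))
  t <- rep$table
  expect_equal(t$fraction_display[t$cohort == "children"], 94)
  expect_equal(t$fraction_display[t$cohort == "teenagers"], 88)
  expect_equal(t$fraction_display[t$cohort == "adults"], 65)
  expect_equal(t$n_exceed[t$cohort == "children"], 16L)
  expect_equal(t$n_exceed[t$cohort == "adults"], 11L)
  expect_equal(t$n_total, rep(17L, 3))
  # listed sites are consistent with the counts
  expect_equal(lengths(rep$exceeding)[["children"]], 16L)
  expect_false("S1" %in% rep$exceeding$children)
})

test_that("threshold comparison is strict", {
  res <- toy_results(rep(1, 5))
  rep <- classify_sites(res, endpoint_config(hq_threshold = 1))
  expect_equal(rep$table$fraction_pct, 0)
  expect_equal(rep$exceeding$children, character(0))
})

test_that("classification agrees with an element-by-element loop oracle", {
  set.seed(202)
  for (i in 1:20) {
    hq <- runif(sample(3:30, 1), 0, 3)
    thr <- runif(1, 0.2, 2.5)
    rep <- classify_sites(toy_results(hq), endpoint_config(hq_threshold = thr))
    # oracle: count strictly exceeding elements one by one
    count <- 0L
    for (v in hq) if (v > thr) count <- count + 1L
    expect_equal(rep$table$n_exceed, count)
    expect_equal(rep$table$fraction_pct, 100 * count / length(hq))
  }
})

test_that("prevalence is monotone non-increasing in the threshold", {
  tab <- exposure_table(fluoride_sites(), default_cohorts())
  thresholds <- seq(0.2, 3.5, by = 0.3)
  for (cohort in c("children", "adults")) {
    fr <- vapply(thresholds, function(thr) {
      r <- classify_sites(tab, endpoint_config(hq_threshold = thr))
      r$table$fraction_pct[r$table$cohort == cohort]
    }, numeric(1))
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("endpoint HQ honours the reference-dose override", {
  children <- default_cohorts()$children
  dental <- endpoint_config("dental")
  expect_equal(endpoint_hq(3.80, children, dental), compute_hq(3.80, children))
  expect_equal(round_half_up(endpoint_hq(3.80, children, dental), 2), 3.29)

  halved <- endpoint_config("custom", rfd_override = 2 * children$RfD)
  expect_equal(endpoint_hq(3.80, children, halved),
               compute_hq(3.80, children) / 2)
  same <- endpoint_config("custom", rfd_override = children$RfD)
  expect_equal(endpoint_hq(3.80, children, same), compute_hq(3.80, children))
})

test_that("override classification recomputes HQ from CDI", {
  tab <- exposure_table(fluoride_sites(), default_cohorts())
  base <- classify_sites(tab, endpoint_config())
  same <- classify_sites(tab, endpoint_config(rfd_override = 0.06))
  expect_equal(same$table$n_exceed, base$table$n_exceed)
  # a much laxer reference dose clears every site
  lax <- classify_sites(tab, endpoint_config(rfd_override = 10))
  expect_equal(lax$table$n_exceed, rep(0L, 3))
})

test_that("classification demands cohort labels", {
  res <- toy_results(c(1, 2))
  res$cohort <- NULL
  expect_error(classify_sites(res, endpoint_config()),
               class = "fluorisk_usage_error")
})
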