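# helpers shared across blocks: a small standardized dataset and a quick config
quick_dataset <- function(seed = 3) {
  standardize(build_dataset(generate_study(seed = seed), default_cohorts(),
                            seed = seed))
}
quick_config <- function(max_epochs = 600, patience = 60) {
  surrogate_config(hidden_layers = list(c(16, 8)), l2 = 0.001,
                   learning_rate = 0.01, cv_max_epochs = 150, cv_patience = 20,
                   max_epochs = max_epochs, patience = patience, seed = 3)
}

test_that("metrics agree with the closed-form definitions", {
  m <- fluorisk:::metric_set(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$r2, 0.5)
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-10)
  expect_equal(round(m$rmse, 4), 0.5774)

  expect_equal(fluorisk:::metric_set(c(1, 2, 3), c(1, 2, 3))$r2, 1)
  expect_equal(fluorisk:::metric_set(c(1, 2, 3), rep(2, 3))$r2, 0)

  set.seed(404)
  for (i in 1:10) {
    y <- rnorm(20); p <- rnorm(20)
    m <- fluorisk:::metric_set(y, p)
    expect_equal(m$r2, 1 - sum((y - p)^2) / sum((y - mean(y))^2))
    expect_equal(m$mse, mean((y - p)^2))
  }
})

test_that("the 85-row dataset splits 69/8/8 and fractions are validated", {
  ds <- build_dataset(generate_study(seed = 2), default_cohorts(), seed = 2)
  expect_equal(as.vector(table(ds$data$split)[c("train", "validation", "test")]),
               c(69L, 8L, 8L))

  all_train <- build_dataset(generate_study(seed = 2), default_cohorts(),
                             fractions = c(1, 0, 0), seed = 2)
  expect_true(all(all_train$data$split == "train"))

  expect_error(build_dataset(generate_study(seed = 2), default_cohorts(),
                             fractions = c(0.8, 0.3, 0.1), seed = 2),
               class = "fluorisk_usage_error")
})

test_that("reseeding permutes the partition but keeps the sample multiset", {
  study <- generate_study(seed = 2)
  d1 <- build_dataset(study, default_cohorts(), seed = 10)$data
  d2 <- build_dataset(study, default_cohorts(), seed = 20)$data
  expect_equal(sort(d1$C), sort(d2$C))
  expect_false(identical(d1$split, d2$split))
})

test_that("standardization is fitted on training rows only", {
  ds <- quick_dataset()
  Xtr <- fluorisk:::scaled_features(ds, "train")
  expect_true(all(abs(colMeans(Xtr)) < 1e-10))
  live <- !ds$scaler$constant
  expect_true(all(abs(apply(Xtr[, live], 2, sd) - 1) < 1e-10))
  # EF is 365 days/year for every cohort: constant, centred, flagged
  expect_true(ds$scaler$constant[["EF"]])
  expect_equal(ds$scaler$scale[["EF"]], 1)

  # leakage guard: scaler differs from one fitted on all rows
  all_center <- colMeans(fluorisk:::feature_matrix(ds))
  expect_false(isTRUE(all.equal(unname(all_center),
                                unname(ds$scaler$center))))

  # round trip recovers raw features
  back <- fluorisk:::unscale_features(ds$scaler, fluorisk:::scaled_features(ds))
  expect_equal(unname(back), unname(fluorisk:::feature_matrix(ds)),
               tolerance = 1e-12)
})

test_that("training is seed-deterministic and history tracks the optimum", {
  ds <- quick_dataset()
  cfg <- quick_config()
  m1 <- train_final(ds, list(hidden = c(16, 8), l2 = 0.001, learning_rate = 0.01),
                    cfg, seed = 5)
  m2 <- train_final(ds, list(hidden = c(16, 8), l2 = 0.001, learning_rate = 0.01),
                    cfg, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$metrics, m2$metrics)

  expect_equal(m1$best_epoch, which.min(m1$history$val_mse))
  expect_lte(nrow(m1$history), cfg$max_epochs)
})

test_that("a degenerate zero target is fitted to near-zero error", {
  ds <- quick_dataset()
  ds$data$HQ <- 0
  m <- suppressWarnings(
    train_final(ds, list(hidden = c(8), l2 = 0, learning_rate = 0.01),
                quick_config(), seed = 1)
  )
  expect_lt(m$metrics$train$mse, 1e-4)
  expect_lt(max(abs(predict_hq(m, ds$data[1:10, ]))), 0.05)
})

test_that("grid search ranks a moderate penalty above a crippling one", {
  ds <- quick_dataset()
  cfg <- surrogate_config(hidden_layers = list(c(16, 8)), l2 = c(0.001, 50),
                          learning_rate = 0.01, cv_max_epochs = 150,
                          cv_patience = 20, seed = 3)
  grid <- grid_search(ds, cfg)
  expect_equal(nrow(grid), 2L)
  expect_equal(grid$l2[grid$rank == 1], 0.001)

  single <- grid_search(ds, quick_config())
  expect_equal(nrow(single), 1L)
  expect_false(single$failed)

  expect_error(surrogate_config(k_folds = 1), class = "fluorisk_usage_error")
})

test_that("the surrogate learns the exposure equation to high fidelity", {
  ds <- quick_dataset()
  cfg <- quick_config(max_epochs = 1500, patience = 100)
  runs <- train_over_seeds(ds, list(hidden = c(16, 8), l2 = 0.001,
                                    learning_rate = 0.01), cfg, seeds = 1:3)
  expect_gte(max(runs$metrics$test_r2), 0.98)
})

test_that("prediction respects the training hull and tracks analytic HQ", {
  ds <- quick_dataset()
  m <- train_final(ds, list(hidden = c(16, 8), l2 = 0.001, learning_rate = 0.01),
                   quick_config(max_epochs = 1500, patience = 100), seed = 2)
  train_rows <- ds$data[ds$data$split == "train", ]
  pred <- predict_hq(m, train_rows)
  rmse <- m$metrics$train$rmse
  expect_lt(max(abs(pred - train_rows$HQ)), max(10 * rmse, 0.3))

  # doubling C inside the hull raises the prediction
  row <- train_rows[which.min(train_rows$C), ]
  row2 <- row; row2$C <- 2 * row$C
  expect_gt(predict_hq(m, row2), predict_hq(m, row))

  far <- row; far$C <- 50
  expect_warning(predict_hq(m, far), "hull")
})

test_that("models survive a JSON round trip", {
  ds <- quick_dataset()
  m <- train_final(ds, list(hidden = c(16, 8), l2 = 0.001, learning_rate = 0.01),
                   quick_config(), seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(m, path)
  m2 <- read_surrogate(path)
  X <- ds$data[1:15, ]
  expect_equal(predict_hq(m2, X), predict_hq(m, X), tolerance = 1e-12)
  # stored metrics are recomputable from the reloaded weights
  re <- evaluate(m2, ds, "test")
  expect_equal(re$r2, m$metrics$test$r2, tolerance = 1e-10)
})
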