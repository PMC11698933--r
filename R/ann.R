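# Feed-forward neural-network surrogate for the hazard quotient.
#
# Plain matrix implementation: ReLU hidden layers, linear output, L2
# penalty on hidden-layer weights, full-batch Adam, early stopping on
# validation MSE with best-weight restoration. The networks involved are
# tiny (tens of inputs, <=3 hidden layers), so everything runs in
# vectorised base R.

#' Surrogate training configuration
#'
#' Hyperparameter search space and training controls for the HQ surrogate.
#' Defaults follow the reference protocol: four candidate architectures
#' (64-32-16, 128-64-32, 64-32, 128-64), L2 strengths 0.01 and 0.1,
#' learning rates 0.01 and 0.001, 5-fold cross-validation inside the
#' training split, and an 80/10/10 train/validation/test partition.
#' Cross-validation folds train with a shorter epoch budget
#' (`cv_max_epochs`/`cv_patience`) than the final fit.
#'
#' @param hidden_layers List of integer vectors, one per candidate
#'   architecture (neurons per hidden layer).
#' @param l2 Numeric vector of L2 penalty strengths.
#' @param learning_rate Numeric vector of Adam learning rates.
#' @param k_folds Folds for cross-validation (`>= 2`).
#' @param max_epochs,patience Epoch cap and early-stopping patience for
#'   the final fit.
#' @param cv_max_epochs,cv_patience Same, for cross-validation folds.
#' @param fractions Train/validation/test fractions, summing to 1.
#' @param seed Integer seed controlling fold assignment and weight
#'   initialisation.
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(hidden_layers = list(c(64, 32, 16), c(128, 64, 32),
                                                  c(64, 32), c(128, 64)),
                             l2 = c(0.01, 0.1),
                             learning_rate = c(0.01, 0.001),
                             k_folds = 5,
                             max_epochs = 2000, patience = 100,
                             cv_max_epochs = 400, cv_patience = 40,
                             fractions = c(train = 0.8, validation = 0.1,
                                           test = 0.1),
                             seed = 1) {
  if (!is.list(hidden_layers) || length(hidden_layers) == 0L) {
    stop_usage("'hidden_layers' must be a non-empty list of integer vectors")
  }
  if (any(vapply(hidden_layers, function(h) any(h < 1), logical(1)))) {
    stop_usage("hidden layer sizes must be >= 1")
  }
  if (!is.numeric(l2) || length(l2) == 0L || any(l2 < 0)) {
    stop_usage("'l2' must be non-negative")
  }
  if (!is.numeric(learning_rate) || length(learning_rate) == 0L ||
      any(learning_rate <= 0)) {
    stop_usage("'learning_rate' must be positive")
  }
  check_number(k_folds, "k_folds", positive = TRUE)
  if (k_folds < 2) stop_usage("'k_folds' must be >= 2")
  if (abs(sum(fractions) - 1) > 1e-8) stop_usage("'fractions' must sum to 1")
  structure(
    list(hidden_layers = hidden_layers, l2 = l2,
         learning_rate = learning_rate, k_folds = as.integer(k_folds),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         cv_max_epochs = as.integer(cv_max_epochs),
         cv_patience = as.integer(cv_patience),
         fractions = fractions, seed = as.integer(seed)),
    class = "surrogate_config"
  )
}

# ---- network primitives -------------------------------------------------

relu <- function(x) x * (x > 0)

nn_init <- function(n_in, hidden, n_out = 1L) {
  dims <- c(n_in, hidden, n_out)
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialisation, appropriate for ReLU units
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b, dims = dims)
}

nn_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < L) relu(Z[[l]]) else Z[[l]]
  }
  list(A = A, Z = Z)
}

nn_predict <- function(net, X) {
  L <- length(net$W)
  A <- X
  for (l in seq_len(L)) {
    A <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) A <- relu(A)
  }
  drop(A)
}

n_params <- function(hidden, n_in, n_out = 1L) {
  dims <- c(n_in, hidden, n_out)
  sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
}

# Full-batch Adam with early stopping on validation MSE. Returns the
# best-validation weights, the per-epoch history, and bookkeeping.
nn_train <- function(Xtr, ytr, Xval, yval, hidden, l2, lr,
                     max_epochs, patience, seed) {
  set.seed(as.integer(seed))
  net <- nn_init(ncol(Xtr), hidden)
  L <- length(net$W)
  n <- nrow(Xtr)
  ytr <- matrix(ytr, ncol = 1)
  has_val <- !is.null(Xval) && nrow(Xval) > 0L

  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(x) x * 0); vb <- mb

  best_val <- Inf; best_net <- net; best_epoch <- 0L; wait <- 0L
  hist_train <- numeric(max_epochs); hist_val <- numeric(max_epochs)
  epoch <- 0L

  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    fw <- nn_forward(net, Xtr)
    pred <- fw$A[[L + 1L]]
    delta <- 2 * (pred - ytr) / n
    for (l in seq.int(L, 1L)) {
      gW <- crossprod(fw$A[[l]], delta)
      if (l < L) gW <- gW + 2 * l2 * net$W[[l]]  # penalty on hidden weights
      gb <- colSums(delta)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^epoch; corr2 <- 1 - beta2^epoch
      net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
      net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * (fw$Z[[l - 1L]] > 0)
    }
    train_mse <- base::mean((pred - ytr)^2)
    monitor <- if (has_val) base::mean((nn_predict(net, Xval) - yval)^2) else train_mse
    hist_train[epoch] <- train_mse
    hist_val[epoch] <- if (has_val) monitor else NA_real_
    if (!is.finite(monitor)) break  # diverged
    if (monitor < best_val - 1e-12) {
      best_val <- monitor
      best_net <- net
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  list(
    net = best_net,
    best_val_mse = best_val,
    best_epoch = best_epoch,
    n_epochs = epoch,
    converged = epoch < max_epochs || wait >= patience,
    history = {
      idx <- seq_len(epoch)
      tibble::tibble(epoch = idx, train_mse = hist_train[idx],
                     val_mse = hist_val[idx])
    }
  )
}

# ---- grid search --------------------------------------------------------

#' Cross-validated hyperparameter search
#'
#' Trains every (architecture x L2 x learning-rate) candidate with k-fold
#' cross-validation on the training split and ranks candidates by mean
#' fold-validation MSE (ascending), breaking ties by parameter count. A
#' candidate that diverges in any fold is marked failed and ranked last
#' rather than aborting the search. The dataset is standardized first if
#' it is not already.
#'
#' @param dataset A `surrogate_dataset`.
#' @param config A [surrogate_config()].
#' @return Tibble, one row per candidate, ranked: `rank`, `hidden`
#'   (list-column), `l2`, `learning_rate`, `mean_cv_mse`, `n_params`,
#'   `failed`.
#' @export
grid_search <- function(dataset, config = surrogate_config()) {
  if (!inherits(dataset, "surrogate_dataset")) {
    stop_usage("'dataset' must be a surrogate_dataset")
  }
  if (!inherits(config, "surrogate_config")) {
    stop_usage("'config' must be a surrogate_config")
  }
  if (is.null(dataset$scaler)) dataset <- standardize(dataset)
  X <- scaled_features(dataset, "train")
  y <- split_target(dataset, "train")
  k <- config$k_folds
  if (nrow(X) < 2 * k) stop_usage("training split too small for k-fold CV")

  set.seed(config$seed)
  fold <- sample(rep(seq_len(k), length.out = nrow(X)))

  grid <- expand.grid(arch = seq_along(config$hidden_layers),
                      l2 = config$l2, lr = config$learning_rate,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    hidden <- config$hidden_layers[[grid$arch[i]]]
    fold_mse <- vapply(seq_len(k), function(j) {
      tr <- fold != j
      fit <- nn_train(X[tr, , drop = FALSE], y[tr],
                      X[!tr, , drop = FALSE], y[!tr],
                      hidden = hidden, l2 = grid$l2[i], lr = grid$lr[i],
                      max_epochs = config$cv_max_epochs,
                      patience = config$cv_patience,
                      seed = config$seed + 1000L * i + j)
      fit$best_val_mse
    }, numeric(1))
    failed <- any(!is.finite(fold_mse))
    npar <- n_params(hidden, ncol(X))
    tibble::tibble(
      hidden = list(hidden),
      l2 = grid$l2[i],
      learning_rate = grid$lr[i],
      mean_cv_mse = if (failed) Inf else base::mean(fold_mse),
      n_params = npar,
      failed = failed
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(out$mean_cv_mse, out$n_params), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "hidden", "l2", "learning_rate", "mean_cv_mse",
          "n_params", "failed")]
}

as_candidate <- function(candidate) {
  if (is.data.frame(candidate)) {
    row <- candidate[1, ]
    return(list(hidden = row$hidden[[1]], l2 = row$l2,
                learning_rate = row$learning_rate))
  }
  if (is.list(candidate) &&
      all(c("hidden", "l2", "learning_rate") %in% names(candidate))) {
    return(candidate[c("hidden", "l2", "learning_rate")])
  }
  stop_usage("'candidate' must be a grid_search result or a list(hidden, l2, learning_rate)")
}

#' Train the final surrogate model
#'
#' Trains the selected candidate on the full training split, with early
#' stopping monitored on the held-out validation split (the weights of
#' the best validation epoch are restored). With an empty validation
#' split the training MSE is monitored instead. A model that exhausts
#' `max_epochs` without the early-stopping criterion firing is returned
#' with `converged = FALSE` and a warning.
#'
#' @param dataset A `surrogate_dataset`.
#' @param candidate A row of [grid_search()] output (the first row is
#'   used), or `list(hidden =, l2 =, learning_rate =)`.
#' @param config A [surrogate_config()].
#' @param seed Training seed; defaults to `config$seed`.
#' @return An object of class `surrogate_model`: architecture and
#'   hyperparameters, `weights`, `scaler`, per-epoch `history`, `metrics`
#'   (R2/RMSE/MSE on train/validation/test), training-hull feature ranges,
#'   `best_epoch`, `converged`, `seed`.
#' @export
train_final <- function(dataset, candidate, config = surrogate_config(),
                        seed = NULL) {
  if (!inherits(dataset, "surrogate_dataset")) {
    stop_usage("'dataset' must be a surrogate_dataset")
  }
  cand <- as_candidate(candidate)
  if (is.null(seed)) seed <- config$seed
  if (is.null(dataset$scaler)) dataset <- standardize(dataset)

  Xtr <- scaled_features(dataset, "train")
  ytr <- split_target(dataset, "train")
  has_val <- any(dataset$data$split == "validation")
  Xval <- if (has_val) scaled_features(dataset, "validation") else NULL
  yval <- if (has_val) split_target(dataset, "validation") else NULL

  fit <- nn_train(Xtr, ytr, Xval, yval, hidden = cand$hidden, l2 = cand$l2,
                  lr = cand$learning_rate, max_epochs = config$max_epochs,
                  patience = config$patience, seed = seed)
  if (!fit$converged) {
    warning("surrogate training hit max_epochs without early stopping")
  }

  raw_tr <- feature_matrix(dataset, "train")
  model <- structure(
    list(
      hidden = cand$hidden, l2 = cand$l2, learning_rate = cand$learning_rate,
      weights = fit$net, scaler = dataset$scaler,
      feature_names = dataset$feature_names,
      hull = list(lower = apply(raw_tr, 2, base::min),
                  upper = apply(raw_tr, 2, base::max)),
      history = fit$history, best_epoch = fit$best_epoch,
      converged = fit$converged, seed = as.integer(seed)
    ),
    class = "surrogate_model"
  )
  model$metrics <- list(
    train = evaluate(model, dataset, "train"),
    validation = if (has_val) evaluate(model, dataset, "validation") else NULL,
    test = if (any(dataset$data$split == "test")) evaluate(model, dataset, "test") else NULL
  )
  model
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> hidden %s, l2 %g, lr %g (seed %d, best epoch %d)\n",
              paste(x$hidden, collapse = "-"), x$l2, x$learning_rate,
              x$seed, x$best_epoch))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    if (!is.null(m)) {
      cat(sprintf("  %-10s R2 %.4f, RMSE %.4f\n", nm, m$r2, m$rmse))
    }
  }
  invisible(x)
}

#' Repeat final training over several seeds
#'
#' Re-trains the selected candidate under each seed and tabulates the
#' resulting metrics; the model with the highest test R2 is returned as
#' `best`, implementing the best-of-seeds reproduction protocol for a
#' stochastically trained network.
#'
#' @inheritParams train_final
#' @param seeds Integer vector of training seeds.
#' @return List with `metrics` (tibble: seed, per-split R2/RMSE),
#'   `models` (list of `surrogate_model`) and `best`.
#' @export
train_over_seeds <- function(dataset, candidate, config = surrogate_config(),
                             seeds = 1:5) {
  models <- lapply(seeds, function(s) train_final(dataset, candidate, config, seed = s))
  metrics <- tibble::tibble(
    seed = as.integer(seeds),
    train_r2 = vapply(models, function(m) m$metrics$train$r2, numeric(1)),
    test_r2 = vapply(models, function(m) m$metrics$test$r2, numeric(1)),
    test_rmse = vapply(models, function(m) m$metrics$test$rmse, numeric(1))
  )
  list(metrics = metrics, models = models,
       best = models[[which.max(metrics$test_r2)]])
}

# ---- evaluation and prediction ------------------------------------------

metric_set <- function(y, pred) {
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - base::mean(y))^2)
  mse <- base::mean((y - pred)^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-24) 1 else NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  list(r2 = r2, rmse = sqrt(mse), mse = mse)
}

#' Evaluate a surrogate model on a dataset split
#'
#' Computes `R2 = 1 - SS_res / SS_tot`, RMSE and MSE on the raw
#' (unstandardized) HQ scale.
#'
#' @param model A `surrogate_model`.
#' @param dataset A `surrogate_dataset` (its own scaler is ignored; the
#'   model's stored scaler is applied).
#' @param split `"train"`, `"validation"` or `"test"`.
#' @return List with `r2`, `rmse`, `mse`.
#' @export
evaluate <- function(model, dataset, split = "test") {
  if (!inherits(model, "surrogate_model")) stop_usage("'model' must be a surrogate_model")
  if (!inherits(dataset, "surrogate_dataset")) {
    stop_usage("'dataset' must be a surrogate_dataset")
  }
  sel <- dataset$data$split == split
  if (!any(sel)) stop_usage(sprintf("split '%s' is empty", split))
  X <- as.matrix(dataset$data[sel, model$feature_names])
  Xs <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
  metric_set(dataset$data$HQ[sel], nn_predict(model$weights, Xs))
}

#' Predict hazard quotients with a trained surrogate
#'
#' Standardizes the supplied features with the model's stored scaler and
#' runs the forward pass. Features more than 20% (of the training range)
#' outside the training hull trigger an extrapolation warning; the value
#' is still returned.
#'
#' @param model A `surrogate_model`.
#' @param features A data frame / matrix with the model's feature columns,
#'   or a single named numeric vector.
#' @return Numeric vector of predicted HQ values.
#' @export
predict_hq <- function(model, features) {
  if (!inherits(model, "surrogate_model")) stop_usage("'model' must be a surrogate_model")
  if (is.numeric(features) && !is.null(names(features))) {
    features <- as.data.frame(as.list(features))
  }
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) {
    stop_usage(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(features[, model$feature_names, drop = FALSE])

  lo <- model$hull$lower; hi <- model$hull$upper
  span <- hi - lo
  span[span == 0] <- pmax(abs(hi[span == 0]), 1e-8)  # constant features
  outside <- sweep(X, 2, lo - 0.2 * span, "<") | sweep(X, 2, hi + 0.2 * span, ">")
  if (any(outside)) {
    bad <- model$feature_names[apply(outside, 2, any)]
    warning(sprintf("features outside the training hull (+/-20%%): %s; prediction is an extrapolation",
                    paste(bad, collapse = ", ")))
  }

  Xs <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
  unname(nn_predict(model$weights, Xs))
}

# ---- serialization ------------------------------------------------------

#' Serialize a surrogate model to JSON
#'
#' Writes architecture, hyperparameters, scaler statistics, weight
#' matrices, hull and metrics as plain JSON -- no binary formats -- so a
#' model can be stored, diffed and reloaded with [read_surrogate()].
#'
#' @param model A `surrogate_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(model, path) {
  if (!inherits(model, "surrogate_model")) stop_usage("'model' must be a surrogate_model")
  payload <- list(
    package = "fluorisk",
    version = as.character(packageVersion("fluorisk")),
    hidden = model$hidden, l2 = model$l2, learning_rate = model$learning_rate,
    seed = model$seed, best_epoch = model$best_epoch, converged = model$converged,
    feature_names = model$feature_names,
    scaler = list(center = as.list(model$scaler$center),
                  scale = as.list(model$scaler$scale),
                  constant = as.list(model$scaler$constant)),
    hull = list(lower = as.list(model$hull$lower),
                upper = as.list(model$hull$upper)),
    weights = model$weights$W,
    biases = model$weights$b,
    dims = model$weights$dims,
    metrics = model$metrics
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a surrogate model from JSON
#'
#' @param path Path written by [write_surrogate()].
#' @return A `surrogate_model` (without training history).
#' @export
read_surrogate <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("model file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(p$dims)
  W <- lapply(seq_along(p$weights), function(l) {
    w <- p$weights[[l]]
    # JSON matrices are row-major; a single-row matrix simplifies to a vector
    if (is.null(dim(w))) w <- matrix(w, nrow = dims[l], byrow = TRUE)
    w <- as.matrix(w)
    dimnames(w) <- NULL
    w
  })
  b <- if (is.list(p$biases)) lapply(p$biases, as.numeric) else list(as.numeric(p$biases))
  structure(
    list(
      hidden = as.integer(p$hidden), l2 = p$l2, learning_rate = p$learning_rate,
      weights = list(W = W, b = b, dims = dims),
      scaler = list(center = unlist(p$scaler$center),
                    scale = unlist(p$scaler$scale),
                    constant = unlist(p$scaler$constant)),
      feature_names = p$feature_names,
      hull = list(lower = unlist(p$hull$lower), upper = unlist(p$hull$upper)),
      history = NULL, best_epoch = p$best_epoch, converged = p$converged,
      seed = p$seed, metrics = p$metrics
    ),
    class = "surrogate_model"
  )
}
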