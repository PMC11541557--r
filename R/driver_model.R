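#' Configuration for the boosted-tree driver analysis
#'
#' Hyperparameter protocol for the gradient-boosted regression trees:
#' learning rates are scanned from fast to slow until some tree depth
#' sustains at least `min_trees` trees at its cross-validation optimum (the
#' standard way to ensure enough trees at the chosen rate), with squared-error
#' loss, row subsampling at `bag_fraction`, and `k_folds`-fold
#' cross-validation throughout.
#'
#' @param learning_rates Candidate shrinkage rates, scanned in the given
#'   order (default a geometric ladder 0.01, 0.005, 0.0025, 0.001).
#' @param tree_depths Candidate tree complexities (interaction depths).
#' @param bag_fraction Row subsampling fraction per tree.
#' @param min_trees Minimum acceptable number of trees at the CV optimum.
#' @param k_folds Cross-validation folds.
#' @param max_trees Hard cap on boosting rounds at the smallest learning
#'   rate (scaled by 0.01/eta for faster rates).
#' @param drop_tolerance Maximum loss in cross-validated R2 a predictor
#'   removal may cost during model simplification.
#' @param r_max Pairwise-correlation screen threshold.
#' @param vif_max Variance-inflation screen threshold.
#' @param seed Seed controlling fold assignment and subsampling.
#' @return Object of class `model_config` (a validated list).
#' @export
model_config <- function(learning_rates = c(0.01, 0.005, 0.0025, 0.001),
                         tree_depths = 3:5, bag_fraction = 0.5,
                         min_trees = 1000, k_folds = 10, max_trees = 10000,
                         drop_tolerance = 0.005, r_max = 0.6, vif_max = 4,
                         seed = 1) {
  stopifnot(bag_fraction > 0, bag_fraction <= 1, min_trees >= 1, k_folds >= 2,
            all(learning_rates > 0), all(tree_depths >= 1))
  structure(list(learning_rates = learning_rates, tree_depths = tree_depths,
                 bag_fraction = bag_fraction, min_trees = min_trees,
                 k_folds = k_folds, max_trees = max_trees,
                 drop_tolerance = drop_tolerance, r_max = r_max,
                 vif_max = vif_max, seed = seed),
            class = "model_config")
}

.as_feature_matrix <- function(features, feature_names = NULL) {
  X <- as.data.frame(features)
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, names(X))
    if (length(missing)) stopf("missing predictor(s): %s",
                               paste(missing, collapse = ", "))
    X <- X[feature_names]
  }
  m <- as.matrix(X)
  if (!is.numeric(m)) stopf("predictors must be numeric")
  if (anyNA(m)) stopf("predictors contain missing values")
  m
}

.xgb_params <- function(eta, depth, config) {
  list(objective = "reg:squarederror", eta = eta, max_depth = depth,
       subsample = config$bag_fraction, tree_method = "exact", nthread = 1)
}

# One CV run at (eta, depth); returns best iteration and CV mean squared error.
.cv_point <- function(dtrain, eta, depth, config, cap = NULL) {
  nrounds <- min(config$max_trees, ceiling(25 / eta), cap %||% Inf)
  cv <- with_seed(config$seed, {
    xgboost::xgb.cv(params = .xgb_params(eta, depth, config), data = dtrain,
                    nrounds = nrounds, nfold = config$k_folds,
                    early_stopping_rounds = 40, verbose = 0)
  })
  best <- cv$early_stop$best_iteration %||% cv$niter
  rmse <- cv$evaluation_log$test_rmse_mean[best]
  list(eta = eta, depth = depth, n_trees = best, cv_mse = rmse^2)
}

#' Fit a gradient-boosted regression model of bleaching severity
#'
#' Trains boosted regression trees with squared-error loss under the
#' hyperparameter protocol of [model_config]: learning rates are tried from
#' fastest to slowest and, at the first rate where some tree depth reaches
#' `min_trees` trees at the cross-validation optimum, the (rate, depth) point
#' with the smallest CV deviance is selected and the final ensemble refit on
#' the full data at the optimal number of trees. If no grid point sustains
#' `min_trees` trees (e.g. signal-free data), the overall best point is used
#' with a warning. `cv_r2` is the cross-validated fraction of variance
#' explained, `1 - CV deviance / null deviance`.
#'
#' @param features Data.frame or matrix of numeric predictors (no missing
#'   values).
#' @param response Numeric response (bleaching severity, 0-100).
#' @param config A [model_config].
#' @param eta,depth Optional fixed hyperparameters; when both are given the
#'   scan is skipped and a single CV run determines the number of trees
#'   (used internally during model simplification for speed and
#'   comparability).
#' @return Object of class `bleach_gbm`: list with the fitted `booster`,
#'   `feature_names`, `eta`, `depth`, `n_trees`, `cv_r2`, `cv_mse`,
#'   `null_mse`, `data` (training features as data.frame), `response`,
#'   `config`, `scan` (CV log of the scan).
#' @export
fit_gbm <- function(features, response, config = model_config(),
                    eta = NULL, depth = NULL, nrounds_cap = NULL) {
  X <- .as_feature_matrix(features)
  y <- as.numeric(response)
  if (length(y) != nrow(X)) stopf("response length does not match features")
  if (nrow(X) < 5 * config$k_folds) {
    stopf("need at least %d observations for %d-fold CV",
          5 * config$k_folds, config$k_folds)
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  scan <- list()
  if (!is.null(eta) && !is.null(depth)) {
    scan[[1]] <- .cv_point(dtrain, eta, depth, config, cap = nrounds_cap)
    chosen <- scan[[1]]
  } else {
    # Tree complexity is compared at the fastest learning rate; the rate is
    # then lowered at the chosen complexity until the ensemble sustains
    # min_trees trees at its CV optimum (the conventional boosted-tree
    # protocol for guaranteeing a slow-enough learning rate).
    probes <- lapply(config$tree_depths, function(d) {
      .cv_point(dtrain, config$learning_rates[1], d, config)
    })
    scan <- probes
    ok <- Filter(function(p) p$n_trees >= config$min_trees, probes)
    if (length(ok)) {
      chosen <- ok[[which.min(vapply(ok, `[[`, 0.0, "cv_mse"))]]
    } else {
      chosen <- NULL
      best <- probes[[which.min(vapply(probes, `[[`, 0.0, "cv_mse"))]]
      for (e in config$learning_rates[-1]) {
        cap_e <- ceiling(2.5 * best$n_trees * config$learning_rates[1] / e) + 100L
        pt <- .cv_point(dtrain, e, best$depth, config, cap = cap_e)
        scan <- c(scan, list(pt))
        if (pt$n_trees >= config$min_trees) {
          chosen <- pt
          break
        }
      }
      if (is.null(chosen)) {
        warnf("no (learning rate, depth) point reached %d trees at its CV optimum; using the best available point (consider a smaller learning rate)",
              config$min_trees)
        chosen <- scan[[which.min(vapply(scan, `[[`, 0.0, "cv_mse"))]]
      }
    }
  }
  booster <- with_seed(config$seed, {
    xgboost::xgb.train(params = .xgb_params(chosen$eta, chosen$depth, config),
                       data = dtrain, nrounds = chosen$n_trees, verbose = 0)
  })
  null_mse <- mean((y - mean(y))^2)
  structure(list(booster = booster, feature_names = colnames(X),
                 eta = chosen$eta, depth = chosen$depth,
                 n_trees = chosen$n_trees,
                 cv_r2 = 1 - chosen$cv_mse / null_mse,
                 cv_mse = chosen$cv_mse, null_mse = null_mse,
                 data = as.data.frame(X), response = y, config = config,
                 scan = scan),
            class = "bleach_gbm")
}

#' @export
predict.bleach_gbm <- function(object, newdata, ...) {
  m <- .as_feature_matrix(newdata, object$feature_names)
  predict(object$booster, m)
}

#' @export
print.bleach_gbm <- function(x, ...) {
  cat(sprintf("<bleach_gbm> %d predictors, eta %.3g, depth %d, %d trees, CV R2 = %.3f\n",
              length(x$feature_names), x$eta, x$depth, x$n_trees, x$cv_r2))
  invisible(x)
}

#' Relative influence of each predictor
#'
#' Split-improvement-based importance of the boosted ensemble, normalized to
#' sum to 100. Predictors never used by a split have influence 0.
#'
#' @param model A fitted [fit_gbm] model.
#' @return Named numeric vector (percent), sorted decreasing.
#' @export
relative_influence <- function(model) {
  if (length(model$feature_names) == 1L) {
    return(setNames(100, model$feature_names))
  }
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- setNames(numeric(length(model$feature_names)), model$feature_names)
  out[imp$Feature] <- imp$Gain
  if (sum(out) <= 0) out[] <- 1  # no splits (constant response): uniform
  sort(100 * out / sum(out), decreasing = TRUE)
}

#' Predict bleaching severity for new reefs
#'
#' @param model A fitted [fit_gbm] model (or the `model` element of a
#'   [simplify_model] result).
#' @param metrics Data.frame containing at least the model's selected
#'   predictors (extra columns and column order are ignored).
#' @return Data.frame with `raw` (ensemble output) and `predicted` (clipped
#'   to the 0-100 severity scale for reporting).
#' @export
predict_bleaching <- function(model, metrics) {
  raw <- predict(model, metrics)
  data.frame(raw = raw, predicted = pmin(100, pmax(0, raw)))
}

#' Simplify the global driver model
#'
#' The full driver-identification workflow: (1) fit the global boosted model
#' on all candidate metrics; (2) rank predictors by relative influence;
#' (3) screen out collinear predictors (|r| >= `r_max`, keeping the more
#' influential member of each pair) and then predictors with variance
#' inflation factors >= `vif_max`; (4) iteratively drop the least influential
#' remaining predictor while the removal costs at most `drop_tolerance` of
#' cross-validated R2, refitting each round at the hyperparameters selected
#' for the global model; (5) refit and report the final model with relative
#' influence, partial dependence curves, pairwise interaction statistics and
#' residuals.
#'
#' @param features Data.frame of all candidate metrics.
#' @param response Bleaching severity vector.
#' @param config A [model_config].
#' @param compute_h Compute the pairwise interaction (H) matrix (the most
#'   expensive diagnostic).
#' @param n_pd_grid Grid resolution of the partial dependence curves.
#' @return Object of class `driver_model_result`: list with
#'   `selected_predictors`, `relative_influence` (percent, sums to 100),
#'   `cv_r2`, `n_trees`, `model` (the final [fit_gbm] fit), `pd_curves`
#'   (named list of data.frames), `h_matrix` (symmetric matrix or `NULL`),
#'   `residuals`, `fitted`, `screen` (what was dropped where), `global_cv_r2`.
#' @export
simplify_model <- function(features, response, config = model_config(),
                           compute_h = TRUE, n_pd_grid = 50) {
  X <- as.data.frame(features)
  if (ncol(X) < 2L) stopf("need at least 2 candidate predictors")
  global <- fit_gbm(X, response, config)
  infl <- relative_influence(global)
  cs <- collinearity_screen(X, r_max = config$r_max, ranking = names(infl))
  vs <- vif_screen(X[cs$kept], vif_max = config$vif_max)
  # The drop-loop refits compare candidate predictor sets, so they only need
  # a consistent CV criterion, not the final-model tree count; they run at
  # the faster of the selected rate and 0.005, and the final model is refit
  # at the selected protocol point.
  loop_eta <- max(global$eta, 0.005)
  cap <- max(1500L, 2L * ceiling(global$n_trees * global$eta / loop_eta))
  current <- fit_gbm(X[vs$kept], response, config,
                     eta = loop_eta, depth = global$depth,
                     nrounds_cap = cap)
  # Drop low-influence predictors while the removal costs at most
  # drop_tolerance of CV R2. Candidates are tried in batches of the least
  # influential predictors (halved on rejection) so the refit count grows
  # logarithmically; a batch must clear the same tolerance as a single drop,
  # which is conservative.
  drop_log <- character(0)
  repeat {
    k <- length(current$feature_names)
    if (k <= 2L) break
    ri <- sort(relative_influence(current))  # ascending influence
    batch_size <- max(1L, min(k - 2L, floor(k / 2), sum(ri < 2)))
    accepted <- FALSE
    while (batch_size >= 1L) {
      batch <- names(ri)[seq_len(batch_size)]
      candidate <- fit_gbm(current$data[setdiff(current$feature_names, batch)],
                           response, config, eta = loop_eta,
                           depth = global$depth, nrounds_cap = cap)
      if (candidate$cv_r2 >= current$cv_r2 - config$drop_tolerance) {
        drop_log <- c(drop_log, batch)
        current <- candidate
        accepted <- TRUE
        break
      }
      batch_size <- floor(batch_size / 2)
    }
    if (!accepted) break
  }
  if (loop_eta != global$eta) {
    current <- fit_gbm(current$data, response, config, eta = global$eta,
                       depth = global$depth)
  }
  selected <- current$feature_names
  if (length(selected) == 0L) stopf("all predictors eliminated")
  ri <- relative_influence(current)
  fitted <- predict(current, current$data)
  pd <- lapply(setNames(selected, selected), function(v) {
    partial_dependence(current, current$data, v, n_grid = n_pd_grid)
  })
  h <- NULL
  if (compute_h && length(selected) > 1L) {
    h <- matrix(0, length(selected), length(selected),
                dimnames = list(selected, selected))
    for (a in seq_along(selected)) {
      for (b in seq_len(a - 1L)) {
        h[a, b] <- h[b, a] <- friedman_h(current, current$data,
                                         c(selected[a], selected[b]))
      }
    }
  }
  structure(list(selected_predictors = names(ri),
                 relative_influence = ri,
                 cv_r2 = current$cv_r2, n_trees = current$n_trees,
                 model = current, pd_curves = pd, h_matrix = h,
                 residuals = response - fitted, fitted = fitted,
                 screen = list(collinearity = cs$dropped, vif = vs$dropped,
                               contribution = drop_log),
                 global_cv_r2 = global$cv_r2),
            class = "driver_model_result")
}

#' @export
print.driver_model_result <- function(x, ...) {
  cat(sprintf("<driver_model_result> CV R2 = %.3f (global %.3f), %d trees\n",
              x$cv_r2, x$global_cv_r2, x$n_trees))
  cat("Relative influence (%):\n")
  for (v in names(x$relative_influence)) {
    cat(sprintf("  %-14s %6.2f\n", v, x$relative_influence[[v]]))
  }
  if (!is.null(x$h_matrix)) {
    cat(sprintf("Max pairwise interaction H = %.3f\n", max(x$h_matrix)))
  }
  invisible(x)
}
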