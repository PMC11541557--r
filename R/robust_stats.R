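#' Trimmed mean
#'
#' Mean after removing `floor(trim * n)` values at each tail of the sorted
#' sample.
#'
#' @param x Numeric vector.
#' @param trim Trimming fraction per tail, in `[0, 0.5)`.
#' @export
trimmed_mean <- function(x, trim) {
  if (trim < 0 || trim >= 0.5) stopf("trim must be in [0, 0.5)")
  x <- sort(x)
  g <- floor(trim * length(x))
  kept <- x[(g + 1):(length(x) - g)]
  if (length(kept) == 0L) stopf("no observations left after trimming")
  mean(kept)
}

# Winsorized variance: replace the g smallest/largest values by the adjacent
# order statistics, then take the ordinary sample variance.
.winsorized_var <- function(x, trim) {
  x <- sort(x)
  n <- length(x)
  g <- floor(trim * n)
  if (g > 0) {
    x[seq_len(g)] <- x[g + 1]
    x[(n - g + 1):n] <- x[n - g]
  }
  var(x)
}

# Consistency constant c(trim): sd of a standard normal winsorized at the
# trim quantiles, so that winsorized sd / c estimates sigma under normality
# (0.642 at 20% trim, 1 at zero trim).
.winsor_consistency <- function(trim) {
  if (trim == 0) return(1)
  z <- qnorm(1 - trim)
  sqrt((1 - 2 * trim) - 2 * z * dnorm(z) + 2 * trim * z^2)
}

#' Align two yearly samples into a paired sample by site id
#'
#' Sites present in only one of the two samples are excluded with a warning,
#' so paired comparisons use only re-sampled sites.
#'
#' @param ids_x,x Identifiers and values of the first sample.
#' @param ids_y,y Identifiers and values of the second sample.
#' @return List with aligned `x`, `y` and `ids`.
#' @export
paired_sample <- function(ids_x, x, ids_y, y) {
  common <- intersect(ids_x, ids_y)
  n_drop <- (length(ids_x) - length(common)) + (length(ids_y) - length(common))
  if (n_drop > 0) warnf("excluding %d site(s) not sampled in both groups", n_drop)
  if (length(common) == 0L) stopf("no sites in common")
  list(x = x[match(common, ids_x)], y = y[match(common, ids_y)], ids = common)
}

#' Yuen's trimmed-means test for paired samples
#'
#' Robust paired comparison: the trimmed mean of the paired differences is
#' tested against zero using the winsorized variance of the differences, with
#' `h - 1` degrees of freedom where `h` is the number of observations left
#' after trimming. At `trim = 0` this is exactly the classical paired t-test.
#' The effect size is a robust standardized measure on the differences
#' (trimmed mean divided by the winsorized standard deviation rescaled by the
#' normal-consistency constant), analogous to Cohen's d.
#'
#' @param x,y Equal-length numeric vectors (e.g. the same sites surveyed in
#'   two years). Pairs with missing values are dropped.
#' @param ids Optional identifiers; when given, x and y are matched by id and
#'   unpaired entries are excluded with a warning.
#' @param trim Trimming fraction per tail (default 0.10, removing 10% of the
#'   most extreme differences on each side).
#' @return Object of class `yuen_paired`: list with `statistic`, `df`,
#'   `p.value`, `effect_size`, `trimmed_mean_diff`, `n`, `trim`.
#' @export
yuen_paired <- function(x, y, ids = NULL, trim = 0.10) {
  if (trim < 0 || trim >= 0.5) stopf("trim must be in [0, 0.5)")
  if (!is.null(ids)) {
    if (length(ids) != length(x) || length(ids) != length(y)) {
      stopf("ids must match the length of x and y")
    }
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) {
    warnf("excluding %d unpaired/missing observation(s)", sum(!ok))
    x <- x[ok]; y <- y[ok]
  }
  d <- x - y
  n <- length(d)
  g <- floor(trim * n)
  h <- n - 2L * g
  if (h < 5L) stopf("need at least 5 pairs after trimming (have %d)", h)
  tm <- trimmed_mean(d, trim)
  wv <- .winsorized_var(d, trim)
  if (wv <= .Machine$double.eps) {
    if (all(d == 0)) {
      out <- list(statistic = 0, df = h - 1L, p.value = 1, effect_size = 0,
                  trimmed_mean_diff = 0, n = n, trim = trim)
      return(structure(out, class = "yuen_paired"))
    }
    stopf("degenerate winsorized variance of the paired differences")
  }
  se <- sqrt((n - 1) * wv / (h * (h - 1)))
  stat <- tm / se
  xi <- .winsor_consistency(trim) * tm / sqrt(wv)
  structure(list(statistic = stat, df = h - 1L,
                 p.value = 2 * pt(-abs(stat), h - 1L),
                 effect_size = xi, trimmed_mean_diff = tm, n = n, trim = trim),
            class = "yuen_paired")
}

#' @export
print.yuen_paired <- function(x, ...) {
  cat(sprintf("Yuen paired trimmed-means test (trim = %.2f, n = %d)\n",
              x$trim, x$n))
  cat(sprintf("  t = %.4f, df = %d, p = %.4g\n", x$statistic, x$df, x$p.value))
  cat(sprintf("  trimmed mean difference = %.4f, robust effect size = %.3f\n",
              x$trimmed_mean_diff, x$effect_size))
  invisible(x)
}

#' Greedy pairwise-correlation screen for predictors
#'
#' Walks the predictors in `ranking` order (most informative first) and keeps
#' a predictor only if its absolute Pearson correlation with every
#' already-kept predictor is below `r_max`, so the more informative member of
#' a correlated pair survives. Constant columns are dropped with a warning
#' (their correlation is undefined).
#'
#' @param predictors Numeric matrix or data.frame of candidate predictors.
#' @param r_max Exclusion threshold on |r| (default 0.6).
#' @param ranking Character vector ordering the columns by priority; default
#'   is the given column order.
#' @return List with `kept` (character), and `dropped` (`data.frame` of
#'   dropped predictor, blocking predictor and their correlation).
#' @export
collinearity_screen <- function(predictors, r_max = 0.6, ranking = NULL) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2L) stopf("need at least 2 predictors")
  const <- vapply(X, function(v) sd(v) == 0 || !is.finite(sd(v)), TRUE)
  if (any(const)) {
    warnf("dropping constant predictor(s): %s",
          paste(names(X)[const], collapse = ", "))
    X <- X[!const]
  }
  ranking <- ranking %||% names(X)
  ranking <- intersect(ranking, names(X))
  kept <- character(0)
  dropped <- data.frame(dropped = character(0), blocked_by = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (v in ranking) {
    r <- if (length(kept)) abs(cor(X[[v]], X[kept])) else numeric(0)
    if (all(r < r_max)) {
      kept <- c(kept, v)
    } else {
      j <- which.max(r)
      dropped <- rbind(dropped, data.frame(dropped = v, blocked_by = kept[j],
                                           r = r[j], stringsAsFactors = FALSE))
    }
  }
  list(kept = kept, dropped = dropped)
}

# VIF of every column: 1/(1 - R^2) from regressing each predictor on the rest.
# (Perfect fits are expected during screening, so lm's warning is silenced.)
vif_values <- function(X) {
  X <- as.data.frame(X)
  vapply(seq_along(X), function(j) {
    fit <- lm(X[[j]] ~ ., data = X[-j])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0.0)
}

#' Iterative variance-inflation-factor screen
#'
#' Repeatedly drops the predictor with the largest variance inflation factor
#' until all VIFs are below `vif_max`. Perfectly collinear predictors have
#' infinite VIF and are removed first.
#'
#' @param predictors Numeric matrix or data.frame (rows > columns).
#' @param vif_max Threshold (default 4).
#' @return List with `kept`, `vif` (named final VIFs) and `dropped`.
#' @export
vif_screen <- function(predictors, vif_max = 4) {
  X <- as.data.frame(predictors)
  if (nrow(X) <= ncol(X)) stopf("need more rows than predictors for VIF")
  dropped <- character(0)
  repeat {
    if (ncol(X) < 2L) break
    v <- vif_values(X)
    if (all(v < vif_max)) break
    j <- which.max(v)
    dropped <- c(dropped, names(X)[j])
    X <- X[-j]
  }
  v <- if (ncol(X) >= 2L) setNames(vif_values(X), names(X)) else setNames(1, names(X))
  list(kept = names(X), vif = v, dropped = dropped)
}

# Predict through either a fitted reefheat model or a plain function of a
# data.frame, so diagnostics work with any regression surface.
.pd_predict <- function(model, newdata) {
  if (is.function(model)) as.numeric(model(newdata)) else as.numeric(predict(model, newdata))
}

# Partial dependence of `model` on `vars` at the rows of `grid`: average
# prediction over the training data with the columns in `vars` clamped to
# each grid row.
.pd_eval <- function(model, data, vars, grid) {
  n <- nrow(data)
  m <- nrow(grid)
  big <- data[rep(seq_len(n), times = m), , drop = FALSE]
  for (v in vars) big[[v]] <- rep(grid[[v]], each = n)
  pred <- .pd_predict(model, big)
  colMeans(matrix(pred, nrow = n))
}

#' Partial dependence curve
#'
#' Average model prediction as a function of one predictor, evaluated on an
#' equally spaced grid spanning its observed range, with all other predictors
#' held at their observed values (Friedman's partial dependence).
#'
#' @param model Fitted model with a `predict(model, newdata)` method, or a
#'   function of a data.frame returning predictions.
#' @param data Training data (data.frame).
#' @param predictor Column name.
#' @param n_grid Number of grid points.
#' @return `data.frame` with columns `x` and `yhat`.
#' @export
partial_dependence <- function(model, data, predictor, n_grid = 50) {
  if (!predictor %in% names(data)) stopf("predictor '%s' not in data", predictor)
  grid <- data.frame(x = seq(min(data[[predictor]]), max(data[[predictor]]),
                             length.out = n_grid))
  names(grid) <- predictor
  data.frame(x = grid[[predictor]],
             yhat = .pd_eval(model, data, predictor, grid))
}

#' Bootstrap confidence band for a partial dependence curve
#'
#' Case-resampling bootstrap: the model is refitted on `n_boot` resamples of
#' the rows and the partial dependence re-evaluated on a common grid; the
#' band is the pointwise 2.5/97.5 percentile envelope. Replicates whose refit
#' fails are skipped (warned about when more than 5% fail).
#'
#' @param model_refitter Function `(data) -> model` returning a fitted model
#'   accepted by [partial_dependence].
#' @param data Training data.
#' @param predictor Column name.
#' @param n_boot Number of bootstrap refits (>= 100).
#' @param seed Seed for the resampling.
#' @param n_grid Grid resolution.
#' @return Object of class `pd_ci`: `data.frame` with columns `x`,
#'   `estimate`, `lower`, `upper`; attributes `rug` (observed predictor
#'   values) and `n_failed`.
#' @export
partial_dependence_ci <- function(model_refitter, data, predictor,
                                  n_boot = 1000, seed = NULL, n_grid = 50) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  full <- model_refitter(data)
  pd <- partial_dependence(full, data, predictor, n_grid)
  grid <- data.frame(x = pd$x); names(grid) <- predictor
  curves <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(data), replace = TRUE)
      db <- data[idx, , drop = FALSE]
      tryCatch(.pd_eval(model_refitter(db), db, predictor, grid),
               error = function(e) NULL)
    })
  })
  failed <- vapply(curves, is.null, TRUE)
  if (mean(failed) > 0.05) {
    warnf("%d of %d bootstrap refits failed", sum(failed), n_boot)
  }
  mat <- do.call(rbind, curves[!failed])
  out <- data.frame(x = pd$x, estimate = pd$yhat,
                    lower = apply(mat, 2, quantile, 0.025),
                    upper = apply(mat, 2, quantile, 0.975))
  attr(out, "rug") <- data[[predictor]]
  attr(out, "n_failed") <- sum(failed)
  class(out) <- c("pd_ci", "data.frame")
  out
}

#' Friedman-Popescu pairwise interaction statistic (H)
#'
#' Measures how far the model's joint partial dependence on two predictors
#' departs from additivity: H is the square root of the fraction of the
#' (centered) joint partial dependence variance not captured by the sum of
#' the two one-dimensional partial dependences, evaluated at observed
#' predictor combinations. H = 0 for a perfectly additive surface, 1 when
#' the joint effect is pure interaction.
#'
#' @param model Fitted model or prediction function (see
#'   [partial_dependence]).
#' @param data Training data.
#' @param pair Character vector of two predictor names.
#' @param grid_size Maximum number of observed points the statistic is
#'   evaluated at (evenly spaced through the data; keeps cost bounded).
#' @return H in `[0, 1]`.
#' @export
friedman_h <- function(model, data, pair, grid_size = 100) {
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% names(data))) stopf("pair must name columns of data")
  n <- nrow(data)
  idx <- if (n > grid_size) round(seq(1, n, length.out = grid_size)) else seq_len(n)
  pts <- data[idx, pair, drop = FALSE]
  pd_jk <- .pd_eval(model, data, pair, pts)
  pd_j <- .pd_eval(model, data, pair[1], pts[, 1, drop = FALSE])
  pd_k <- .pd_eval(model, data, pair[2], pts[, 2, drop = FALSE])
  pd_jk <- pd_jk - mean(pd_jk)
  pd_j <- pd_j - mean(pd_j)
  pd_k <- pd_k - mean(pd_k)
  denom <- sum(pd_jk^2)
  if (denom <= .Machine$double.eps) return(0)
  min(1, sqrt(max(0, sum((pd_jk - pd_j - pd_k)^2)) / denom))
}

#' Great-circle distance in kilometers
#'
#' Haversine distance between points given as decimal-degree longitude and
#' latitude.
#' @param lon1,lat1,lon2,lat2 Coordinates (vectors recycle).
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

#' Spline correlogram for spatial autocorrelation
#'
#' Nonparametric estimate of spatial correlation as a smooth function of
#' inter-site great-circle distance: Moran-type pairwise similarities of the
#' standardized variable are smoothed against distance with a cubic smoothing
#' spline whose equivalent degrees of freedom default to the square root of
#' the number of sites (the conventional choice for correlograms; automatic
#' smoothing selection is unstable on the tied pair distances a site
#' bootstrap produces), evaluated on a distance grid from 0 to the 75th
#' percentile of pairwise distances (the tail is data-sparse). A 95%
#' pointwise envelope is obtained by bootstrapping sites.
#'
#' @param lat,lon Site coordinates in decimal degrees.
#' @param z Residual (or data) value per site.
#' @param n_boot Bootstrap replicates for the envelope.
#' @param seed Seed for the bootstrap.
#' @param n_grid Number of distance grid points.
#' @param max_dist_q Quantile of pairwise distance bounding the grid.
#' @param df_spline Equivalent degrees of freedom of the smoothing spline
#'   (default `sqrt(number of sites)`, at least 4).
#' @return Object of class `spline_correlogram`: list with `distance` (km),
#'   `estimate`, `lower`, `upper`, `n_boot`, `n_sites`.
#' @export
spline_correlogram <- function(lat, lon, z, n_boot = 300, seed = NULL,
                               n_grid = 100, max_dist_q = 0.75,
                               df_spline = NULL) {
  n <- length(z)
  if (n < 10L) stopf("need at least 10 sites (have %d)", n)
  if (length(lat) != n || length(lon) != n) stopf("coordinate/value lengths differ")
  df_spline <- df_spline %||% max(4, sqrt(n))
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(2:n, function(k) k:n))
  dist_all <- haversine_km(lon[ii], lat[ii], lon[jj], lat[jj])
  if (all(dist_all < 1e-9)) stopf("all sites are colocated")
  zc <- (z - mean(z)) / sd(z)
  fit_curve <- function(idx) {
    # pairs among the (possibly resampled) site indices, self-pairs excluded
    i2 <- rep(idx[seq_len(length(idx) - 1)], times = (length(idx) - 1):1)
    j2 <- unlist(lapply(2:length(idx), function(k) idx[k:length(idx)]))
    keep <- i2 != j2
    i2 <- i2[keep]; j2 <- j2[keep]
    d <- haversine_km(lon[i2], lat[i2], lon[j2], lat[j2])
    w <- zc[i2] * zc[j2]
    if (length(unique(round(d, 6))) < 10L) return(NULL)
    sp <- tryCatch(smooth.spline(d, w, df = df_spline),
                   error = function(e) NULL)
    if (is.null(sp)) return(NULL)
    pmin(1, pmax(-1, predict(sp, grid)$y))
  }
  grid <- seq(0, quantile(dist_all, max_dist_q), length.out = n_grid)
  est <- fit_curve(seq_len(n))
  if (is.null(est)) stopf("could not fit the correlogram spline")
  boot <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) fit_curve(sample.int(n, replace = TRUE)))
  })
  boot <- do.call(rbind, boot[!vapply(boot, is.null, TRUE)])
  lower <- pmin(apply(boot, 2, quantile, 0.025), est)
  upper <- pmax(apply(boot, 2, quantile, 0.975), est)
  structure(list(distance = grid, estimate = est, lower = lower,
                 upper = upper, n_boot = n_boot, n_sites = n),
            class = "spline_correlogram")
}

#' @export
print.spline_correlogram <- function(x, ...) {
  cat(sprintf("<spline_correlogram> %d sites, %d bootstrap reps; correlation at distance 0: %.3f [%.3f, %.3f]\n",
              x$n_sites, x$n_boot, x$estimate[1], x$lower[1], x$upper[1]))
  invisible(x)
}
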