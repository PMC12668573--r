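#' Fit a regression random forest
#'
#' CART regression trees on bootstrap resamples with variance-reduction
#' splits; `mtry` candidate predictors per split (default `ceiling(p/3)`,
#' the usual regression default) and a minimum node size of 5.  The fit
#' uses an internal seeded RNG, so results are reproducible for a given
#' seed and independent of R's RNG state.
#'
#' @param X numeric matrix or data.frame of predictors (no missing
#'   values).
#' @param y numeric response.
#' @param trees number of trees (default 999).
#' @param mtry candidate predictors per split.
#' @param min_node minimum node size before splitting stops.
#' @param max_depth depth cap (safety bound).
#' @param seed integer seed.
#' @return Object of class `agro_rf` with out-of-bag predictions and OOB
#'   R-squared.
#' @export
fit_rf <- function(X, y, trees = 999, mtry = NULL, min_node = 5,
                   max_depth = 30, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 20) stop("need at least 20 observations to fit a forest")
  if (anyNA(X) || anyNA(y)) stop("missing values in predictors or response")
  if (stats::sd(y) == 0)
    warning("constant response: the forest will predict a constant")
  if (is.null(mtry)) mtry <- max(1L, ceiling(ncol(X) / 3))
  fit <- .rf_fit_cpp(X, y, as.integer(trees), as.integer(mtry),
                     as.integer(min_node), as.integer(max_depth),
                     as.integer(seed))
  oob <- fit$oob_pred
  oob_r2 <- if (stats::sd(y) > 0 && sum(is.finite(oob)) > 2) {
    ok <- is.finite(oob)
    1 - mean((y[ok] - oob[ok])^2) / stats::var(y[ok])
  } else NA_real_
  structure(list(trees = fit$trees, oob_pred = oob, oob_r2 = oob_r2,
                 predictors = colnames(X), mtry = mtry,
                 min_node = min_node, max_depth = max_depth,
                 n = n, seed = seed),
            class = "agro_rf")
}

#' @export
predict.agro_rf <- function(object, newdata, ...) {
  X <- prepare_rf_matrix(newdata, object$predictors)
  .rf_predict_cpp(object$trees, X)
}

prepare_rf_matrix <- function(newdata, predictors) {
  X <- as.matrix(as.data.frame(newdata)[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in prediction covariates")
  X
}

#' Fit an ensemble of independently seeded forests
#'
#' Fits `replicates` forests of `trees` trees with distinct seeds derived
#' from the master seed; the ensemble prediction is the mean over
#' replicate forests, and the spread across replicates is retained as an
#' uncertainty measure.
#'
#' @inheritParams fit_rf
#' @param replicates number of forest replicates (default 100).
#' @return Object of class `agro_rf_ensemble` with per-replicate OOB
#'   R-squared.
#' @export
fit_rf_ensemble <- function(X, y, trees = 999, replicates = 100,
                            mtry = NULL, min_node = 5, seed = 1L) {
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1)
  fits <- lapply(seq_len(replicates), function(r)
    fit_rf(X, y, trees = trees, mtry = mtry, min_node = min_node,
           seed = derive_seed(seed, r)))
  structure(list(fits = fits, trees = trees, replicates = replicates,
                 predictors = fits[[1]]$predictors,
                 oob_r2 = vapply(fits, `[[`, 0, "oob_r2"),
                 mtry = fits[[1]]$mtry, min_node = min_node, seed = seed),
            class = "agro_rf_ensemble")
}

#' @export
predict.agro_rf_ensemble <- function(object, newdata, se = FALSE, ...) {
  preds <- vapply(object$fits, function(f) predict(f, newdata),
                  numeric(nrow(as.data.frame(newdata))))
  preds <- matrix(preds, ncol = length(object$fits))
  m <- rowMeans(preds)
  if (!se) return(m)
  list(mean = m, sd = apply(preds, 1, stats::sd))
}

#' @export
print.agro_rf_ensemble <- function(x, ...) {
  cat(sprintf("Random-forest ensemble: %d replicate(s) x %d trees, ",
              x$replicates, x$trees),
      sprintf("mtry %d\n", x$mtry), sep = "")
  cat(sprintf("  mean OOB R2: %.3f\n", mean(x$oob_r2, na.rm = TRUE)))
  invisible(x)
}

#' Permutation importance with permutation-null significance
#'
#' Observed importance of predictor j is the mean increase in mean squared
#' prediction error when column j is shuffled (averaged over
#' `n_shuffle` shuffles).  Significance follows the response-permutation
#' scheme: the model is refit `n_perm` times on `y` permuted against `X`,
#' each refit yielding a null importance vector, and
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param model an `agro_rf` or `agro_rf_ensemble`.
#' @param X,y the data to measure importance on (typically the training
#'   set).
#' @param n_perm response permutations for the null (default 99; use at
#'   least 19 for p <= 0.05 to be attainable).
#' @param n_shuffle column shuffles averaged into each importance.
#' @param seed integer seed.
#' @return data.frame: `predictor`, `importance` (increase in MSE),
#'   `p_value`, sorted by decreasing importance.
#' @export
permutation_importance <- function(model, X, y, n_perm = 99, n_shuffle = 5,
                                   seed = 1L) {
  X <- as.data.frame(X)[, model$predictors, drop = FALSE]
  y <- as.numeric(y)
  obs <- importance_once(model, X, y, n_shuffle, derive_seed(seed, 0L))
  p <- ncol(X)
  exceed <- integer(p)
  refit <- function(yy, s) {
    if (inherits(model, "agro_rf_ensemble"))
      fit_rf_ensemble(X, yy, trees = model$trees,
                      replicates = model$replicates, mtry = model$mtry,
                      min_node = model$min_node, seed = s)
    else
      fit_rf(X, yy, trees = length(model$trees), mtry = model$mtry,
             min_node = model$min_node, max_depth = model$max_depth,
             seed = s)
  }
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, b))
    yp <- y[sample.int(length(y))]
    mnull <- refit(yp, derive_seed(seed, 1000L + b))
    null_imp <- importance_once(mnull, X, yp, n_shuffle,
                                derive_seed(seed, 2000L + b))
    exceed <- exceed + (null_imp >= obs)
  }
  out <- data.frame(predictor = names(X), importance = obs,
                    p_value = (1 + exceed) / (1 + n_perm))
  out[order(-out$importance), ]
}

importance_once <- function(model, X, y, n_shuffle, seed) {
  set.seed(seed)
  base_mse <- mean((y - predict(model, X))^2)
  n <- nrow(X)
  vapply(seq_len(ncol(X)), function(j) {
    if (length(unique(X[[j]])) == 1) return(0)  # constant: never split on
    d <- 0
    for (s in seq_len(n_shuffle)) {
      Xp <- X
      Xp[[j]] <- X[[j]][sample.int(n)]
      d <- d + mean((y - predict(model, Xp))^2) - base_mse
    }
    d / n_shuffle
  }, numeric(1))
}

#' Mahalanobis applicability mask
#'
#' Flags prediction locations whose covariate vector lies outside the
#' environmental envelope of the training data: the squared Mahalanobis
#' distance to the training mean (under the training covariance) is
#' compared with the `alpha` quantile of the chi-square distribution.
#' By default `df` equals the number of covariates, which is the
#' statistically consistent choice; a fixed override (e.g. `df = 6`) is
#' accepted for replication of published masks.
#'
#' @param newX matrix/data.frame of covariates at prediction locations.
#' @param trainX matrix/data.frame of training covariates (same columns).
#' @param alpha chi-square quantile (default 0.95).
#' @param df degrees of freedom; default `ncol(trainX)`.
#' @param shrink ridge shrinkage added to the covariance diagonal when it
#'   is singular (as a fraction of the mean diagonal), applied
#'   automatically with a warning.
#' @return Logical vector (`TRUE` = non-analog, masked); rows of `newX`
#'   with missing values are `NA`.
#' @export
mahalanobis_mask <- function(newX, trainX, alpha = 0.95, df = NULL,
                             shrink = 1e-8) {
  trainX <- as.matrix(trainX)
  newX <- as.matrix(as.data.frame(newX)[, colnames(trainX), drop = FALSE])
  if (nrow(trainX) <= ncol(trainX))
    stop("need more training rows than covariate dimensions")
  if (is.null(df)) df <- ncol(trainX)
  mu <- colMeans(trainX)
  S <- stats::cov(trainX)
  if (rcond_safe(S) < 1e-12) {
    warning(sprintf(
      "near-singular training covariance (rcond %.2e): ridge applied",
      rcond_safe(S)))
    S <- S + diag(shrink * mean(diag(S)), ncol(S))
  }
  ok <- stats::complete.cases(newX)
  d2 <- rep(NA_real_, nrow(newX))
  d2[ok] <- stats::mahalanobis(newX[ok, , drop = FALSE], mu, S)
  cut <- stats::qchisq(alpha, df = df)
  out <- d2 > cut
  out
}

rcond_safe <- function(S) tryCatch(1 / kappa(S, exact = FALSE),
                                   error = function(e) 0)

#' Validate predictions against observations
#'
#' Ordinary least squares of observed (y-axis) on predicted (x-axis):
#' perfect predictions give slope 1, intercept 0, R-squared 1.
#'
#' @param predicted,observed paired numeric vectors (n >= 3).
#' @return List: `slope`, `intercept`, `r2`, `n`.
#' @export
validate_pred_obs <- function(predicted, observed) {
  ok <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[ok]; observed <- observed[ok]
  n <- length(predicted)
  if (n < 3) stop("need at least 3 paired values")
  if (stats::sd(predicted) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                n = n, degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, predicted), observed)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), r2 = r2, n = n)
}

#' Predict a fitted model over a covariate lattice
#'
#' Takes a named list of aligned covariate grids (one [env_grid()] per
#' predictor), applies the model cell-wise, masks non-analog cells by
#' Mahalanobis distance, and standardizes the unmasked prediction to
#' `[0, 1]`.
#'
#' @param model `agro_rf` or `agro_rf_ensemble`.
#' @param covariate_grids named list of [env_grid()] layers covering the
#'   model's predictors.
#' @param trainX training covariates for the applicability mask.
#' @param mask_alpha,mask_df passed to [mahalanobis_mask()].
#' @return List of class `rf_map`: `prediction`, `standardized` (both
#'   [env_grid()]), `mask` (logical matrix), `masked_fraction`.
#' @export
predict_map <- function(model, covariate_grids, trainX, mask_alpha = 0.95,
                        mask_df = NULL) {
  preds <- model$predictors
  if (!all(preds %in% names(covariate_grids)))
    stop("covariate grids missing: ",
         paste(setdiff(preds, names(covariate_grids)), collapse = ", "))
  g1 <- covariate_grids[[preds[1]]]
  for (nm in preds)
    if (!same_geometry(covariate_grids[[nm]], g1))
      stop("covariate grids are not aligned")
  cells <- sapply(preds, function(nm) as.vector(covariate_grids[[nm]]$values))
  cells <- as.data.frame(cells)
  ok <- stats::complete.cases(cells)
  pred_vec <- rep(NA_real_, nrow(cells))
  if (any(ok)) pred_vec[ok] <- predict(model, cells[ok, , drop = FALSE])
  mask_vec <- mahalanobis_mask(cells, trainX[, preds, drop = FALSE],
                               alpha = mask_alpha, df = mask_df)
  dims <- dim(g1$values)
  prediction <- env_grid(matrix(pred_vec, dims[1], dims[2]),
                         cell_size = g1$cell_size, origin = g1$origin)
  mask <- matrix(isTRUE_vec(mask_vec), dims[1], dims[2])
  standardized <- standardize01(prediction, mask = mask)
  structure(list(prediction = prediction, standardized = standardized,
                 mask = mask,
                 masked_fraction = mean(mask_vec, na.rm = TRUE)),
            class = "rf_map")
}

isTRUE_vec <- function(x) !is.na(x) & x
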