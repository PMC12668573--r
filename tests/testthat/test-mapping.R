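test_that("aggregate_grid block means, edges and missing handling", {
  g <- env_grid(matrix(c(1, 3, 2, 4), 2, 2), cell_size = 1)
  a <- aggregate_grid(g, 2)
  expect_equal(a$values, matrix(2.5, 1, 1))
  expect_equal(a$cell_size, 2)
  expect_identical(aggregate_grid(g, 1), g)
  # NA ignored inside a block; all-NA block stays NA
  v <- matrix(c(1, NA, NA, NA, 5, 7, NA, NA), 2, 4)
  a2 <- aggregate_grid(env_grid(v, cell_size = 1), 2)
  expect_equal(a2$values, matrix(c(1, 6), 1, 2))
  # global mean preserved under exact-factor aggregation, no missing
  set.seed(4)
  m <- matrix(rnorm(36), 6, 6)
  expect_equal(mean(aggregate_grid(env_grid(m), 3)$values), mean(m),
               tolerance = 1e-12)
  expect_error(aggregate_grid(g, 0), "factor")
})

test_that("resample_grid is consistent with aggregation and identity", {
  set.seed(9)
  g <- env_grid(matrix(rnorm(64), 8, 8), cell_size = 5)
  expect_identical(resample_grid(g, 5), g)
  r <- resample_grid(g, 20)
  a <- aggregate_grid(g, 4)
  expect_equal(r$values, a$values, tolerance = 1e-12)
  expect_equal(r$cell_size, 20)
  cg <- env_grid(matrix(3, 6, 6), cell_size = 5)
  rc <- resample_grid(cg, 13)
  expect_true(all(rc$values == 3))
  expect_error(resample_grid(g, 2), "upsampling")
  expect_error(resample_grid(g, -1), "positive")
})

test_that("standardize01 maps to [0,1], is idempotent, flags constants", {
  g <- env_grid(matrix(c(2, 4, 6), 1, 3))
  s <- standardize01(g)
  expect_equal(as.numeric(s$values), c(0, 0.5, 1))
  expect_equal(standardize01(s)$values, s$values, tolerance = 1e-12)
  set.seed(2)
  g2 <- standardize01(env_grid(matrix(rnorm(30), 5, 6)))
  expect_equal(range(g2$values), c(0, 1), tolerance = 1e-12)
  expect_warning(sc <- standardize01(env_grid(matrix(7, 2, 2))),
                 "constant")
  expect_true(all(sc$values == 0))
  mask <- matrix(TRUE, 2, 2)
  expect_error(standardize01(env_grid(matrix(1:4, 2, 2)), mask = mask),
               "no unmasked")
})

test_that("compare_scenarios classification and antisymmetry", {
  lo <- env_grid(matrix(runif(20), 4, 5))
  expect_true(all(compare_scenarios(lo, lo)$values == 0))
  hi <- env_grid(pmin(lo$values + 0.5, 1.5))
  expect_true(all(compare_scenarios(lo, hi)$values == 1))
  set.seed(12)
  a <- env_grid(matrix(runif(40), 5, 8))
  b <- env_grid(matrix(runif(40), 5, 8))
  expect_equal(compare_scenarios(a, b)$values,
               -compare_scenarios(b, a)$values)
  bad <- env_grid(matrix(0, 2, 2))
  expect_error(compare_scenarios(a, bad), "misaligned")
})

test_that("grid CSV round-trips losslessly", {
  set.seed(3)
  v <- matrix(rnorm(24), 4, 6)
  v[2, 3] <- NA
  g <- env_grid(v, cell_size = 12.5, origin = c(-3, 7))
  path <- tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  g2 <- read_grid_csv(path)
  expect_equal(g2$values, unname(g$values), tolerance = 1e-15)
  expect_equal(g2$cell_size, 12.5)
  expect_equal(g2$origin, c(-3, 7))
})

test_that("forest fits are seed-deterministic and honor constant y", {
  set.seed(100)
  X <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(200, 0, 0.2)
  f1 <- fit_rf(X, y, trees = 50, seed = 7)
  set.seed(9999)  # fit must not depend on R's RNG state
  f2 <- fit_rf(X, y, trees = 50, seed = 7)
  expect_identical(predict(f1, X), predict(f2, X))
  e1 <- fit_rf_ensemble(X, y, trees = 30, replicates = 3, seed = 5)
  e2 <- fit_rf_ensemble(X, y, trees = 30, replicates = 3, seed = 5)
  expect_identical(predict(e1, X), predict(e2, X))
  expect_warning(fc <- fit_rf(X, rep(2.5, 200), trees = 20, seed = 1),
                 "constant response")
  expect_equal(unique(predict(fc, X)), 2.5)
})

test_that("ensemble prediction is invariant to replicate order", {
  set.seed(42)
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- X[, 2] + rnorm(100, 0, 0.3)
  e <- fit_rf_ensemble(X, y, trees = 25, replicates = 4, seed = 3)
  rev_e <- e
  rev_e$fits <- rev(e$fits)
  expect_equal(predict(e, X), predict(rev_e, X), tolerance = 1e-12)
})

test_that("forest recovers a strong linear signal", {
  set.seed(8)
  n <- 400
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 2 * X[, 1] + rnorm(n, 0, 0.05)
  e <- fit_rf_ensemble(X, y, trees = 200, replicates = 2, seed = 21)
  v <- validate_pred_obs(predict(e, X), y)
  expect_gt(v$r2, 0.9)
  expect_gt(mean(e$oob_r2), 0.7)
})

test_that("permutation importance: constant column scores exactly zero", {
  set.seed(15)
  X <- data.frame(signal = rnorm(150), junk = rnorm(150),
                  constant = rep(1, 150))
  y <- X$signal + rnorm(150, 0, 0.1)
  f <- fit_rf(X, y, trees = 60, seed = 2)
  imp <- permutation_importance(f, X, y, n_perm = 19, n_shuffle = 3,
                                seed = 6)
  expect_identical(imp$importance[imp$predictor == "constant"], 0)
  expect_identical(imp$predictor[1], "signal")
  expect_lte(imp$p_value[imp$predictor == "signal"], 0.05)
})

test_that("mahalanobis mask trivial geometry", {
  set.seed(23)
  train <- matrix(rnorm(500 * 3), 500, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  center <- matrix(colMeans(train), 1, dimnames = list(NULL, colnames(train)))
  expect_false(mahalanobis_mask(center, train))
  outlier <- center
  outlier[1, 1] <- outlier[1, 1] + 10 * sd(train[, 1])
  expect_true(mahalanobis_mask(outlier, train))
  # masking is monotone in alpha
  new <- matrix(rnorm(200 * 3), 200, 3, dimnames = dimnames(train))
  m90 <- mahalanobis_mask(new, train, alpha = 0.90)
  m99 <- mahalanobis_mask(new, train, alpha = 0.99)
  expect_true(all(m90[m99]))  # masked at 0.99 implies masked at 0.90
  expect_gte(sum(m90), sum(m99))
})

test_that("mahalanobis mask applies ridge to singular covariance", {
  set.seed(33)
  x <- rnorm(100)
  train <- cbind(a = x, b = 2 * x, c = rnorm(100))
  new <- train[1:5, ]
  expect_warning(m <- mahalanobis_mask(new, train), "singular")
  expect_length(m, 5)
})

test_that("validate_pred_obs matches the closed-form OLS oracle", {
  expect_equal(validate_pred_obs(1:10, 1:10),
               list(slope = 1, intercept = 0, r2 = 1, n = 10),
               tolerance = 1e-12)
  v <- validate_pred_obs(1:10, 1:10 + 3)
  expect_equal(v$slope, 1, tolerance = 1e-12)
  expect_equal(v$intercept, 3, tolerance = 1e-12)
  set.seed(71)
  p <- rnorm(50); o <- 0.8 * p + rnorm(50, 0, 0.5)
  v2 <- validate_pred_obs(p, o)
  slope_oracle <- sum((p - mean(p)) * (o - mean(o))) /
    sum((p - mean(p))^2)
  expect_equal(v2$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(v2$intercept, mean(o) - slope_oracle * mean(p),
               tolerance = 1e-10)
  expect_equal(v2$r2, cor(p, o)^2, tolerance = 1e-10)
  expect_true(validate_pred_obs(rep(1, 5), rnorm(5))$degenerate)
})

test_that("predict_map assembles prediction, mask and standardization", {
  set.seed(50)
  n <- 200
  train <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- train$a + rnorm(n, 0, 0.2)
  f <- fit_rf(train, y, trees = 50, seed = 3)
  grids <- list(a = env_grid(matrix(rnorm(48), 6, 8)),
                b = env_grid(matrix(rnorm(48), 6, 8)))
  m <- predict_map(f, grids, train)
  expect_s3_class(m$prediction, "env_grid")
  expect_equal(dim(m$prediction$values), c(6, 8))
  unmasked <- m$standardized$values[!m$mask]
  expect_true(all(unmasked >= 0 & unmasked <= 1, na.rm = TRUE))
  expect_true(all(is.na(m$standardized$values[m$mask])))
  grids$b <- env_grid(matrix(rnorm(48), 8, 6))
  expect_error(predict_map(f, grids, train), "not aligned")
})
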