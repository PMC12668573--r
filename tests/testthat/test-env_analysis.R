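test_that("vif matches the inverse-correlation oracle on correlated designs", {
  set.seed(14)
  for (i in 1:5) {
    n <- 300
    z <- rnorm(n)
    X <- cbind(x1 = z + rnorm(n, 0, 0.8),
               x2 = z + rnorm(n, 0, 0.5),
               x3 = rnorm(n),
               x4 = 0.5 * z + rnorm(n))
    v <- vif(X)
    # independent oracle: diagonal of the inverse correlation matrix
    oracle <- diag(solve(cor(X)))
    expect_equal(v$vif, unname(oracle), tolerance = 1e-8)
  }
})

test_that("vif trivial and degenerate cases", {
  set.seed(2)
  a <- rnorm(100)
  b <- residuals(lm(rnorm(100) ~ a))  # exactly uncorrelated with a
  expect_equal(vif(cbind(a = a, b = b))$vif, c(1, 1), tolerance = 1e-10)
  X <- cbind(x = rnorm(50), y = rnorm(50))
  X <- cbind(X, z = X[, "x"])  # exact duplicate
  v <- vif(X)
  expect_true(all(is.infinite(v$vif[c(1, 3)])))
  expect_true(all(v$flagged[c(1, 3)]))
})

test_that("vif is invariant under affine rescaling of predictors", {
  set.seed(31)
  X <- matrix(rnorm(600), 200, 3) %*% matrix(c(1, .4, 0, .4, 1, .2,
                                               0, .2, 1), 3)
  colnames(X) <- c("a", "b", "c")
  v1 <- vif(X)$vif
  X2 <- sweep(sweep(X, 2, c(3, -2, 100), "*"), 2, c(7, 0, -5), "+")
  expect_equal(vif(X2)$vif, v1, tolerance = 1e-8)
})

test_that("vif_screen drops the worst collinear predictor but honors keep", {
  set.seed(8)
  z <- rnorm(400)
  X <- data.frame(total_p = z + rnorm(400, 0, 0.05),
                  available_p = z + rnorm(400, 0, 0.05),
                  ph = rnorm(400))
  kept <- vif_screen(X, keep = "total_p")
  expect_true("total_p" %in% kept)
  expect_false("available_p" %in% kept)
})

test_that("spearman matches the rank-then-Pearson oracle, ties included", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 9)
  y <- c(2, 1, 4, 4, 6, 7, 7, 10)
  res <- spearman_assoc(data.frame(x = x), y)
  oracle_rho <- cor(rank(x), rank(y))
  expect_equal(res$rho, oracle_rho, tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("spearman endpoints, monotone invariance and degenerate input", {
  x <- sort(rnorm(30))
  expect_equal(spearman_assoc(data.frame(x = x), cumsum(abs(rnorm(30))))$rho,
               1, tolerance = 1e-12)
  expect_equal(spearman_assoc(data.frame(x = x),
                              rev(cumsum(abs(rnorm(30)))))$rho,
               -1, tolerance = 1e-12)
  set.seed(5)
  a <- rnorm(60); b <- rnorm(60)
  r0 <- spearman_assoc(data.frame(a = a), b)$rho
  r1 <- spearman_assoc(data.frame(a = exp(3 * a)), b^3 + 5 * b)$rho
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_true(is.na(spearman_assoc(data.frame(a = rep(1, 10)),
                                   rnorm(10))$rho))
})

test_that("adjusted_r2 formula and guards", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_equal(adjusted_r2(0.42, 50, 0), 0.42)
  expect_equal(adjusted_r2(0.5, 10, 2), 1 - 0.5 * 9 / 7,
               tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 4, 3), "undefined")
})

test_that("block_fit agrees with lm and yields valid permutation p", {
  set.seed(19)
  n <- 120
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- 0.5 * X[, 1] + rnorm(n)
  bf <- block_fit(y, X, n_perm = 199, seed = 3)
  expect_equal(bf$r2, summary(lm(y ~ X))$r.squared, tolerance = 1e-10)
  expect_equal(bf$adj_r2, summary(lm(y ~ X))$adj.r.squared,
               tolerance = 1e-10)
  expect_gte(bf$p_value, 1 / 200)
  expect_lte(bf$p_value, 1)
  # exact linear response: R2 = 1 and smallest attainable p
  y2 <- X %*% c(1, -2, 0.5)
  bf2 <- block_fit(as.numeric(y2), X, n_perm = 99, seed = 4)
  expect_equal(bf2$r2, 1, tolerance = 1e-10)
  expect_equal(bf2$p_value, 1 / 100, tolerance = 1e-12)
})

test_that("block_fit permutation test holds its size under the null", {
  set.seed(77)
  n <- 200
  rejections <- 0L
  n_sim <- 300
  for (i in seq_len(n_sim)) {
    X <- matrix(rnorm(n * 3), n)
    y <- rnorm(n)
    p <- block_fit(y, X, n_perm = 99, seed = i)$p_value
    if (p <= 0.05) rejections <- rejections + 1L
  }
  # binomial(300, 0.05): 3 sigma is about 0.038
  expect_lt(abs(rejections / n_sim - 0.05), 0.04)
})

test_that("varpart4 fractions sum to the full-model adjusted R2", {
  set.seed(41)
  n <- 150
  blocks <- list(sp = matrix(rnorm(n * 3), n), cl = matrix(rnorm(n * 5), n),
                 so = matrix(rnorm(n * 4), n), ve = matrix(rnorm(n * 3), n))
  y <- rnorm(n) + 0.3 * blocks$cl[, 1]
  vp <- varpart4(y, blocks)
  expect_equal(sum(vp$fractions), vp$total, tolerance = 1e-10)
  expect_equal(vp$residual, 1 - vp$total, tolerance = 1e-12)
  expect_equal(vp$shared, vp$total - sum(vp$unique), tolerance = 1e-12)
  expect_length(vp$fractions, 15)
})

test_that("varpart4 matches vegan::varpart on the same data", {
  set.seed(55)
  n <- 200
  b1 <- matrix(rnorm(n * 2), n); b2 <- matrix(rnorm(n * 3), n)
  b3 <- matrix(rnorm(n * 2), n); b4 <- matrix(rnorm(n * 2), n)
  y <- 0.6 * b2[, 1] - 0.4 * b3[, 2] + rnorm(n)
  vp <- varpart4(y, list(s = b1, c = b2, so = b3, v = b4))
  vv <- vegan::varpart(y, b1, b2, b3, b4)
  ind <- vv$part$indfract$Adj.R.square
  # vegan rows [a]-[d] are the unique fractions of X1..X4
  expect_equal(unname(vp$unique), ind[1:4], tolerance = 1e-8)
  expect_equal(vp$total, sum(ind[1:15]), tolerance = 1e-8)
  expect_equal(sort(unname(vp$fractions)), sort(ind[1:15]),
               tolerance = 1e-8)
})

test_that("duplicate blocks push all explained variance into shared", {
  set.seed(66)
  n <- 250
  B <- matrix(rnorm(n * 3), n)
  y <- B %*% c(1, 0.5, -0.3) + rnorm(n)
  other <- matrix(rnorm(n * 2), n)
  vp <- suppressWarnings(
    varpart4(as.numeric(y), list(a = B, b = B, c = other,
                                 d = matrix(rnorm(n * 2), n))))
  expect_lt(abs(vp$unique[["unique_a"]]), 0.02)
  expect_lt(abs(vp$unique[["unique_b"]]), 0.02)
  expect_gt(vp$fractions[["shared_a_b"]], 0.1)
})

test_that("null varpart fractions are centered at zero", {
  set.seed(71)
  n <- 500
  acc <- matrix(0, 40, 15)
  for (i in seq_len(nrow(acc))) {
    blocks <- list(a = matrix(rnorm(n * 3), n), b = matrix(rnorm(n * 5), n),
                   c = matrix(rnorm(n * 4), n), d = matrix(rnorm(n * 3), n))
    acc[i, ] <- varpart4(rnorm(n), blocks)$fractions
  }
  expect_lt(max(abs(colMeans(acc))), 0.02)
})

test_that("env_analysis runs the full chain on a synthetic database", {
  s <- local_sim()
  res <- env_analysis(s$database, "soil_fertility", "all", n_perm = 49,
                      seed = 12)
  expect_setequal(res$blocks$block,
                  c("spatial", "climate", "soil", "vegetation"))
  expect_true(all(res$blocks$p_value >= 1 / 50))
  expect_s3_class(res$varpart, "varpart4")
  expect_true(all(c("rho", "p_value") %in% names(res$spearman)))
  expect_true(all(res$retained %in% c("lat",
    unlist(env_blocks(), use.names = FALSE))))
})
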