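#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the least-squares
#' regression of predictor j on all other predictors (with intercept).
#' Exact linear dependence is reported as `Inf` rather than an error so
#' screening can name every involved predictor.
#'
#' @param X numeric matrix or data.frame of predictors (no constant
#'   column; more rows than predictors + 1).
#' @param threshold flag level, default 5.
#' @return data.frame: `predictor`, `vif`, `flagged` (`vif > threshold`
#'   or infinite).
#' @export
vif <- function(X, threshold = 5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need more rows than predictors + 1")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in predictors")
  v <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(X) %||% paste0("x", seq_len(p)),
             vif = v, flagged = !is.finite(v) | v > threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen predictors by VIF
#'
#' Iteratively drops the predictor with the largest VIF until all remain
#' below the threshold.  Mirrors the usual collinearity screen applied
#' before correlation and random-forest analyses.
#'
#' @inheritParams vif
#' @param keep predictors never dropped (e.g. a variable chosen a priori
#'   over its collinear partner, as total P is over available P).
#' @return Character vector of retained predictor names.
#' @export
vif_screen <- function(X, threshold = 5, keep = character(0)) {
  X <- as.data.frame(X)
  repeat {
    v <- vif(X, threshold = threshold)
    cand <- v[v$flagged & !(v$predictor %in% keep), , drop = FALSE]
    if (nrow(cand) == 0) return(v$predictor)
    drop <- cand$predictor[which.max(cand$vif)]
    X[[drop]] <- NULL
    if (ncol(X) < 2) return(names(X))
  }
}

#' Spearman rank correlations of covariates with a response
#'
#' Ranks with average ties, then the product-moment correlation of the
#' ranks; two-sided p from the large-sample t approximation.  Constant
#' inputs give `NA` (rho undefined).
#'
#' @param env numeric matrix or data.frame of covariates.
#' @param y numeric response vector (e.g. one service's LnRR).
#' @return data.frame: `predictor`, `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(env, y) {
  env <- as.data.frame(env)
  stopifnot(nrow(env) == length(y))
  res <- lapply(names(env), function(nm) {
    x <- env[[nm]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(predictor = nm, rho = NA_real_, p_value = NA_real_,
                        n = n))
    rho <- stats::cor(rank(x[ok]), rank(y[ok]))
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    data.frame(predictor = nm, rho = rho,
               p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
  })
  do.call(rbind, res)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`; unbiased enough to be additive
#' across subset models, which is what makes variance partitioning on it
#' meaningful.
#'
#' @param r2 raw coefficient of determination.
#' @param n number of observations.
#' @param p number of predictors (excluding the intercept).
#' @return Adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R2 undefined: need n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# R2 of y on X (with intercept); drops aliased columns.  Returns the fit
# pieces needed by block_fit/varpart4.
ols_r2 <- function(y, X) {
  X <- as.matrix(X)
  qx <- qr(cbind(`(Intercept)` = 1, X))
  if (qx$rank < ncol(X) + 1)
    warning("rank-deficient predictor block: ",
            ncol(X) + 1 - qx$rank, " column(s) aliased and dropped")
  res <- qr.resid(qx, y)
  tss <- sum((y - mean(y))^2)
  list(r2 = 1 - sum(res^2) / tss, rank = qx$rank - 1L, qr = qx, tss = tss)
}

#' Fit one predictor block to a service response
#'
#' With a univariate response, a redundancy analysis on one block of
#' predictors reduces to ordinary least squares; R-squared is reported
#' with its adjusted version and a permutation p-value obtained by
#' permuting the response rows.
#'
#' @param y numeric response (one service's observation-level LnRR).
#' @param X predictor block (matrix or data.frame).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return List: `r2`, `adj_r2`, `p_value`, `df` (predictors used), `n`.
#' @export
block_fit <- function(y, X, n_perm = 999, seed = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n <= ncol(X) + 1) stop("need more rows than block size + 1")
  fit <- ols_r2(y, X)
  p_used <- fit$rank
  set.seed(seed)
  # R2 under permutation via the fixed QR: R2 = 1 - ||Q resid||^2 / TSS
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    r2p <- 1 - sum(qr.resid(fit$qr, yp)^2) / sum((yp - mean(yp))^2)
    if (r2p >= fit$r2) exceed <- exceed + 1L
  }
  list(r2 = fit$r2, adj_r2 = adjusted_r2(fit$r2, n, p_used),
       p_value = (1 + exceed) / (1 + n_perm), df = p_used, n = n)
}

#' Four-block variance partitioning on adjusted R-squared
#'
#' Partitions the adjusted R-squared of `y` on the union of four predictor
#' blocks into 15 fractions (4 unique, 6 pairwise-shared, 4 triple-shared,
#' 1 shared by all) by fitting the 15 non-empty block unions and solving
#' the inclusion-exclusion system.  Shared fractions can be negative, and
#' are reported as such.  The fractions sum to the full-model adjusted
#' R-squared by construction.
#'
#' @param y numeric response.
#' @param blocks named list of exactly four predictor blocks (matrix or
#'   data.frame each), e.g. spatial/climate/soil/vegetation.
#' @return Object of class `varpart4`: `fractions` (named numeric, 15),
#'   `total` (full-model adjusted R2), `residual` (`1 - total`),
#'   `unique` (the 4 unique fractions), `shared` (`total - sum(unique)`),
#'   `subset_adj_r2` (adjusted R2 of every block union), `n`.
#' @export
varpart4 <- function(y, blocks) {
  stopifnot(is.list(blocks), length(blocks) == 4)
  if (is.null(names(blocks)) || anyDuplicated(names(blocks)))
    names(blocks) <- paste0("X", 1:4)
  blocks <- lapply(blocks, as.matrix)
  n <- length(y)
  p_tot <- sum(vapply(blocks, ncol, integer(1)))
  if (n <= p_tot + 1)
    stop("insufficient n for the full four-block model (need n > ",
         p_tot + 1, ")")

  subsets <- lapply(1:15, function(code) which(bitwAnd(code, 2^(0:3)) > 0))
  adj <- vapply(subsets, function(s) {
    Xs <- do.call(cbind, blocks[s])
    fit <- ols_r2(y, Xs)
    adjusted_r2(fit$r2, n, fit$rank)
  }, numeric(1))
  subset_names <- vapply(subsets, function(s)
    paste(names(blocks)[s], collapse = "+"), character(1))
  names(adj) <- subset_names

  # A(S) = sum of fractions of regions T with T intersecting S
  M <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15)
    M[i, j] <- as.numeric(bitwAnd(i, j) > 0)  # i = subset S, j = region T
  fractions <- solve(M, adj)
  region_names <- vapply(1:15, function(code) {
    members <- names(blocks)[which(bitwAnd(code, 2^(0:3)) > 0)]
    if (length(members) == 1) paste0("unique_", members)
    else paste0("shared_", paste(members, collapse = "_"))
  }, character(1))
  names(fractions) <- region_names

  total <- adj[[15]]  # all four blocks
  uni <- fractions[paste0("unique_", names(blocks))]
  structure(list(fractions = fractions, total = total,
                 residual = 1 - total, unique = uni,
                 shared = total - sum(uni), subset_adj_r2 = adj, n = n),
            class = "varpart4")
}

#' @export
print.varpart4 <- function(x, digits = 4, ...) {
  cat("Variance partitioning over four predictor blocks",
      sprintf("(n = %d)\n", x$n))
  cat(sprintf("Full-model adjusted R2: %.*f  (residual %.*f)\n",
              digits, x$total, digits, x$residual))
  cat("Unique fractions:\n")
  print(round(x$unique, digits))
  cat(sprintf("Pooled shared fraction: %.*f\n", digits, x$shared))
  invisible(x)
}

#' Environmental analysis of one service under one intensity class
#'
#' Convenience wrapper chaining the pieces the way the analysis is run in
#' practice: observation-level service effects are merged with site
#' covariates, predictors are VIF-screened, each of the four blocks is fit
#' separately (R2, adjusted R2, permutation p), the four-block variance
#' partition is computed, and Spearman associations are reported.
#'
#' @param db validated database data.frame.
#' @param service service id (one of the six).
#' @param class `"low"`, `"high"`, or `"all"`.
#' @param n_perm permutations for block significance.
#' @param seed integer seed.
#' @param vif_threshold collinearity flag level.
#' @return List: `blocks` (per-block fit table), `varpart`, `spearman`,
#'   `vif`, `retained`, `n`.
#' @export
env_analysis <- function(db, service, class = c("all", "low", "high"),
                         n_perm = 999, seed = 1L, vif_threshold = 5) {
  class <- match.arg(class)
  se <- observation_service_effects(db)
  se <- se[se$service_id == service, , drop = FALSE]
  if (class != "all")
    se <- se[intensity_class(se$n_practices) == class, , drop = FALSE]
  env_cols <- unlist(env_blocks(), use.names = FALSE)
  cov_cols <- c("lat", setdiff(env_cols, "lat"))
  site_cov <- db[!duplicated(db$site_id), c("site_id", cov_cols)]
  se <- se[, setdiff(names(se), cov_cols)]
  dat <- merge(se, site_cov, by = "site_id")
  dat <- dat[stats::complete.cases(dat[, c("effect", cov_cols)]), ]
  if (nrow(dat) <= length(cov_cols) + 1)
    stop("too few complete observations for service '", service, "'")

  X <- dat[, cov_cols]
  v <- vif(X, threshold = vif_threshold)
  retained <- vif_screen(X, threshold = vif_threshold)
  blocks <- lapply(env_blocks(), function(b)
    as.matrix(dat[, intersect(b, retained), drop = FALSE]))
  blocks <- blocks[vapply(blocks, ncol, integer(1)) > 0]
  fits <- lapply(seq_along(blocks), function(i)
    block_fit(dat$effect, blocks[[i]], n_perm = n_perm,
              seed = derive_seed(seed, i)))
  block_table <- data.frame(block = names(blocks),
                            r2 = vapply(fits, `[[`, 0, "r2"),
                            adj_r2 = vapply(fits, `[[`, 0, "adj_r2"),
                            p_value = vapply(fits, `[[`, 0, "p_value"),
                            df = vapply(fits, `[[`, 0L, "df"))
  vp <- if (length(blocks) == 4) varpart4(dat$effect, blocks) else NULL
  sp <- spearman_assoc(dat[, retained], dat$effect)
  list(blocks = block_table, varpart = vp, spearman = sp, vif = v,
       retained = retained, n = nrow(dat))
}
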