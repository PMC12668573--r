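# Shared fixtures, all generated in code.

# Minimal database with prescribed practice counts; effect sizes are zero
# (x_s = x_i) unless lnrr_values is given.
make_count_db <- function(counts, service = "crop_yield",
                          lnrr_values = NULL) {
  axes <- names(practice_taxonomy())
  n <- length(counts)
  pv <- t(vapply(counts, function(k) {
    v <- integer(length(axes))
    v[seq_len(k)] <- 1L
    v
  }, integer(length(axes))))
  colnames(pv) <- axes
  x_i <- rep(10, n)
  x_s <- if (is.null(lnrr_values)) x_i else x_i * exp(lnrr_values)
  covs <- setdiff(unlist(env_blocks(), use.names = FALSE), "lat")
  covdf <- as.data.frame(matrix(1, n, length(covs),
                                dimnames = list(NULL, covs)))
  cbind(data.frame(obs_id = sprintf("o%05d", seq_len(n)),
                   study_id = sprintf("s%04d", seq_len(n)),
                   site_id = sprintf("site%04d", seq_len(n)),
                   lat = 40, lon = 0, crop = "wheat",
                   attribute_id = "grain_yield", service_id = service,
                   x_s = x_s, x_i = x_i),
        as.data.frame(pv), covdf)
}

# Small simulated database, cached across tests in one run.
local_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_database(sim_config(n_sites = 40, n_obs = 300,
                                             seed = 424L))
    cache
  }
})

# Orthonormal predictor blocks from a QR decomposition: 4 named blocks of
# `each` columns, mutually orthogonal by construction.
orthogonal_blocks <- function(n, each = 2) {
  Q <- qr.Q(qr(matrix(stats::rnorm(n * 4 * each), n)))
  lapply(stats::setNames(1:4, c("b1", "b2", "b3", "b4")), function(i) {
    B <- Q[, ((i - 1) * each + 1):(i * each), drop = FALSE]
    colnames(B) <- paste0("b", i, "_", seq_len(each))
    B
  })
}
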