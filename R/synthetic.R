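#' Default attribute-to-service map
#'
#' Stand-in attribute lists for the six agroecosystem services (crop
#' yield, soil fertility, carbon sequestration, SOM decomposition, soil
#' habitat, biodiversity).  Real coding tables are study-specific; users
#' can supply their own named list.
#'
#' @return Named list: service id -> character vector of attribute ids.
#' @export
default_attribute_map <- function() {
  list(
    crop_yield = c("grain_yield", "aboveground_biomass", "harvest_index"),
    soil_fertility = c("total_n", "available_p", "available_k", "cec"),
    carbon_sequestration = c("soc_stock", "soc_concentration",
                             "microbial_biomass_c"),
    som_decomposition = c("beta_glucosidase", "soil_respiration",
                          "litter_mass_loss"),
    habitat = c("bacterial_abundance", "fungal_abundance",
                "microfauna_abundance"),
    biodiversity = c("bacterial_richness", "fungal_richness",
                     "fauna_richness")
  )
}

#' Configuration for the synthetic database generator
#'
#' Defines the stated world every downstream stage is tested against: a
#' linear dose-response of the true LnRR in the number of sustainable
#' practices, per service, modulated by standardized environmental
#' covariates, with a site random effect and residual noise.
#'
#' @param n_sites number of study sites (default 349).
#' @param n_obs number of paired attribute-level rows (default 1570).
#' @param practice_axes names of the binary practice axes (default: the 8
#'   axes of [practice_taxonomy()]).
#' @param attribute_map named list mapping each of the six services to its
#'   attribute ids.
#' @param effect_intercept named per-service intercept of the true LnRR
#'   (`alpha_s`, dimensionless).
#' @param effect_slope named per-service LnRR increment per additional
#'   sustainable practice (`beta_s`).
#' @param env_modulation named vector `gamma`: LnRR per standardized unit
#'   of a site covariate (names must be covariate columns); covariates not
#'   named contribute 0.
#' @param site_sd standard deviation of the site random effect (LnRR
#'   units).
#' @param residual_sd residual standard deviation per row (LnRR units).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   intensive-treatment means (positivity is required by the log ratio).
#' @param count_probs probabilities of practice counts 1..8; the default
#'   is right-skewed so that roughly 3% of rows stack 7+ practices, as in
#'   global compilations.
#' @param block_cor latent correlation between covariates in *different*
#'   blocks (0 = independent blocks); `within_cor` applies inside a block.
#' @param within_cor latent within-block covariate correlation.
#' @param use_log1p_dose if `TRUE` the dose term is
#'   `beta_s * log(1 + n)` instead of `beta_s * n` (saturating option).
#' @param seed integer seed.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_sites = 349L, n_obs = 1570L,
                       practice_axes = names(practice_taxonomy()),
                       attribute_map = default_attribute_map(),
                       effect_intercept = c(crop_yield = -0.08,
                                            soil_fertility = -0.05,
                                            carbon_sequestration = -0.02,
                                            som_decomposition = 0.00,
                                            habitat = 0.05,
                                            biodiversity = 0.02),
                       effect_slope = c(crop_yield = 0.020,
                                        soil_fertility = 0.025,
                                        carbon_sequestration = 0.030,
                                        som_decomposition = 0.020,
                                        habitat = 0.015,
                                        biodiversity = 0.020),
                       env_modulation = c(aridity_index = 0.05,
                                          sand = 0.03, mat = -0.02),
                       site_sd = 0.10, residual_sd = 0.30,
                       baseline_meanlog = 2, baseline_sdlog = 0.8,
                       count_probs = c(0.27, 0.24, 0.18, 0.12, 0.08,
                                       0.065, 0.025, 0.02),
                       block_cor = 0.15, within_cor = 0.35,
                       use_log1p_dose = FALSE, seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_obs = as.integer(n_obs),
              practice_axes = practice_axes, attribute_map = attribute_map,
              effect_intercept = effect_intercept,
              effect_slope = effect_slope, env_modulation = env_modulation,
              site_sd = site_sd, residual_sd = residual_sd,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, count_probs = count_probs,
              block_cor = block_cor, within_cor = within_cor,
              use_log1p_dose = isTRUE(use_log1p_dose),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  services <- c("crop_yield", "soil_fertility", "carbon_sequestration",
                "som_decomposition", "habitat", "biodiversity")
  if (cfg$n_sites < 1 || cfg$n_obs < cfg$n_sites)
    stop("need n_obs >= n_sites >= 1")
  if (cfg$site_sd < 0 || cfg$residual_sd < 0 || cfg$baseline_sdlog < 0)
    stop("standard deviations must be nonnegative")
  if (!setequal(names(cfg$attribute_map), services))
    stop("attribute_map must cover exactly the six services: ",
         paste(services, collapse = ", "))
  for (nm in c("effect_intercept", "effect_slope"))
    if (!all(services %in% names(cfg[[nm]])))
      stop(nm, " must name all six services")
  if (length(cfg$count_probs) != 8 || any(cfg$count_probs < 0))
    stop("count_probs must be 8 nonnegative probabilities (counts 1..8)")
  if (cfg$block_cor < 0 || cfg$block_cor >= 1 ||
      cfg$within_cor < 0 || cfg$within_cor >= 1)
    stop("latent correlations must lie in [0, 1)")
  invisible(cfg)
}

#' Names and block membership of the site-level environmental covariates
#'
#' Four blocks: spatial (latitude, elevation, slope), climate (aridity
#' index, MAT, MDR, TSEA, PSEA), soil (pH, sand, SOC, total P) and
#' vegetation (plant cover, NDVI, LAI).
#'
#' @return Named list of character vectors, one per block.
#' @export
env_blocks <- function() {
  list(spatial = c("lat", "elevation", "slope"),
       climate = c("aridity_index", "mat", "mdr", "tsea", "psea"),
       soil = c("ph", "sand", "soc", "total_p"),
       vegetation = c("plant_cover", "ndvi", "lai"))
}

#' Simulate site-level environmental covariates
#'
#' Sites are drawn from a Gaussian copula whose latent correlation is
#' `within_cor` inside a covariate block and `block_cor` across blocks;
#' marginals are transformed to field-plausible scales (uniform lat/lon,
#' lognormal elevation, bounded pH 3.5-9 and sand 0-100%, etc.).
#' Reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per site: `site_id`, `lon`, and the 15
#'   covariates of [env_blocks()].
#' @export
simulate_sites <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  simulate_covariates(config$n_sites, config$block_cor, config$within_cor,
                      site_ids = sprintf("site_%04d", seq_len(config$n_sites)))
}

# Shared covariate engine (used for both sites and prediction lattices).
simulate_covariates <- function(n, block_cor, within_cor, site_ids = NULL) {
  blocks <- env_blocks()
  vars <- unlist(blocks, use.names = FALSE)
  p <- length(vars)
  blk <- rep(names(blocks), lengths(blocks))
  # latent correlation: common factor across blocks + a block factor
  a <- sqrt(block_cor)                      # cross-block loading
  b <- sqrt(max(within_cor - block_cor, 0)) # extra within-block loading
  res <- sqrt(1 - a^2 - b^2)
  z_common <- stats::rnorm(n)
  z_block <- matrix(stats::rnorm(n * length(blocks)), n,
                    dimnames = list(NULL, names(blocks)))
  z <- sapply(seq_len(p), function(j)
    a * z_common + b * z_block[, blk[j]] + res * stats::rnorm(n))
  colnames(z) <- vars
  u <- stats::pnorm(z)

  df <- data.frame(
    lat = stats::qunif(u[, "lat"], -55, 65),
    elevation = stats::qlnorm(u[, "elevation"], log(300), 1),
    slope = pmin(stats::qgamma(u[, "slope"], shape = 1.5, scale = 3), 45),
    aridity_index = stats::qlnorm(u[, "aridity_index"], log(0.9), 0.6),
    mat = stats::qnorm(u[, "mat"], 12, 7),
    mdr = stats::qnorm(u[, "mdr"], 11, 3),
    tsea = pmax(stats::qnorm(u[, "tsea"], 7, 2.5), 0.1),
    psea = pmax(stats::qnorm(u[, "psea"], 60, 25), 1),
    ph = pmin(pmax(stats::qnorm(u[, "ph"], 6.5, 1.0), 3.5), 9),
    sand = 100 * stats::plogis(stats::qnorm(u[, "sand"], 0, 0.8)),
    soc = stats::qlnorm(u[, "soc"], log(15), 0.5),
    total_p = stats::qlnorm(u[, "total_p"], log(500), 0.4),
    plant_cover = 100 * stats::plogis(stats::qnorm(u[, "plant_cover"],
                                                   0.5, 0.9)),
    ndvi = 0.9 * stats::plogis(stats::qnorm(u[, "ndvi"], 0.3, 0.7)),
    lai = pmin(stats::qlnorm(u[, "lai"], log(2), 0.5), 8)
  )
  df <- cbind(lon = stats::runif(n, -180, 180), df)
  if (!is.null(site_ids)) df <- cbind(site_id = site_ids, df)
  df[, c(if (!is.null(site_ids)) "site_id", "lat", "lon",
         setdiff(unlist(blocks, use.names = FALSE), "lat"))]
}

#' Simulate a paired-observation database with known ground truth
#'
#' Inverts the effect-size model: intensive means `x_i` are lognormal and
#' sustainable means are `x_s = x_i * exp(true LnRR)`, where the true LnRR
#' of a row is `alpha_s + beta_s * dose(n) + gamma . env_std + site + eps`.
#' Observation units carry 1-3 attribute rows of one service so the
#' attribute-to-service aggregation is exercised.
#'
#' @param config a [sim_config()].
#' @return List with elements `database` (data.frame, `n_obs` rows, schema
#'   of [db_schema()]) and `truth` (a `truth_table`: per-service
#'   `alpha`/`beta`, `gamma`, and the expected group-mean LnRR per
#'   service x practice-count bin).
#' @export
simulate_database <- function(config = sim_config()) {
  validate_sim_config(config)
  sites <- simulate_sites(config)
  set.seed(derive_seed(config$seed, 2L))
  services <- names(config$attribute_map)
  axes <- config$practice_axes
  n_axes <- length(axes)

  # observation units sized 1-3 attribute rows until exactly n_obs rows
  unit_sizes <- integer(0)
  total <- 0L
  while (total < config$n_obs) {
    s <- sample(c(1L, 1L, 1L, 2L, 3L), 1L)
    s <- min(s, config$n_obs - total)
    unit_sizes <- c(unit_sizes, s)
    total <- total + s
  }
  n_units <- length(unit_sizes)

  # every site used at least once when possible
  site_idx <- if (n_units >= config$n_sites)
    c(seq_len(config$n_sites),
      sample.int(config$n_sites, n_units - config$n_sites, replace = TRUE))
  else sample.int(config$n_sites, n_units)
  site_idx <- sample(site_idx)

  probs <- config$count_probs / sum(config$count_probs)
  n_pr <- sample(seq_len(8), n_units, replace = TRUE, prob = probs)
  # guarantee the stated span 1..8 whenever there is room for it
  if (n_units >= 8) n_pr[sample.int(n_units, 8)] <- sample.int(8)
  n_pr <- pmin(n_pr, n_axes)
  pv <- matrix(0L, n_units, n_axes, dimnames = list(NULL, axes))
  for (i in seq_len(n_units))
    pv[i, sample.int(n_axes, n_pr[i])] <- 1L

  svc <- sample(services, n_units, replace = TRUE)
  site_eff <- stats::rnorm(config$n_sites, 0, config$site_sd)

  env_cols <- setdiff(unlist(env_blocks(), use.names = FALSE), character(0))
  env <- as.matrix(sites[, env_cols])
  env_std <- scale(env)
  gamma <- numeric(length(env_cols))
  names(gamma) <- env_cols
  known <- intersect(names(config$env_modulation), env_cols)
  gamma[known] <- config$env_modulation[known]
  env_term <- as.numeric(env_std %*% gamma)

  dose <- function(n) if (config$use_log1p_dose) log(1 + n) else n

  unit_id <- sprintf("obs_%05d", seq_len(n_units))
  study_id <- sprintf("study_%04d", site_idx)  # one study per site
  crop <- sample(c("wheat", "maize", "rice", "barley", "other"), n_units,
                 replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.1, 0.1))

  row_unit <- rep(seq_len(n_units), unit_sizes)
  attr_id <- unlist(lapply(seq_len(n_units), function(i) {
    pool <- config$attribute_map[[svc[i]]]
    sample(pool, unit_sizes[i], replace = unit_sizes[i] > length(pool))
  }))

  mu_true <- config$effect_intercept[svc] + config$effect_slope[svc] *
    dose(n_pr) + env_term[site_idx] + site_eff[site_idx]
  eps <- stats::rnorm(config$n_obs, 0, config$residual_sd)
  lnrr_row <- mu_true[row_unit] + eps

  x_i <- stats::rlnorm(config$n_obs, config$baseline_meanlog,
                       config$baseline_sdlog)
  x_s <- x_i * exp(lnrr_row)

  db <- data.frame(
    obs_id = unit_id[row_unit], study_id = study_id[row_unit],
    site_id = sites$site_id[site_idx][row_unit],
    lat = sites$lat[site_idx][row_unit], lon = sites$lon[site_idx][row_unit],
    crop = crop[row_unit], attribute_id = attr_id,
    service_id = svc[row_unit], x_s = x_s, x_i = x_i,
    pv[row_unit, , drop = FALSE],
    sites[site_idx[row_unit],
          setdiff(env_cols, "lat"), drop = FALSE],
    row.names = NULL
  )

  bins <- c(as.character(1:6), "7+")
  expected <- expand.grid(service_id = services, bin = bins,
                          stringsAsFactors = FALSE)
  bin_n <- function(b) if (b == "7+") {
    w <- probs[7:8] / sum(probs[7:8])
    sum(c(7, 8) * w)  # probability-weighted expected count within 7+
  } else as.numeric(b)
  expected$expected_lnrr <- mapply(function(s, b)
    config$effect_intercept[[s]] + config$effect_slope[[s]] * dose(bin_n(b)),
    expected$service_id, expected$bin)

  truth <- structure(list(alpha = config$effect_intercept,
                          beta = config$effect_slope, gamma = gamma,
                          dose = if (config$use_log1p_dose) "log1p" else
                            "linear",
                          expected_group_means = expected),
                     class = "truth_table")
  list(database = db, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Synthetic ground truth (true LnRR = alpha + beta * dose(n) + ",
      "gamma.env + site + eps)\n", sep = "")
  print(data.frame(alpha = x$alpha, beta = x$beta))
  cat("dose:", x$dose, "| nonzero gamma:",
      paste(sprintf("%s=%.3g", names(x$gamma)[x$gamma != 0],
                    x$gamma[x$gamma != 0]), collapse = ", "), "\n")
  invisible(x)
}
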