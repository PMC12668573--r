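#' Derive a stage seed from a master seed
#'
#' Single documented splitting rule used everywhere randomness is needed:
#' bootstraps, permutations and forests all draw their seeds from the
#' master seed through this function, so each stage is independently
#' reproducible.  The result stays inside the positive 32-bit integer
#' range.
#'
#' @param master integer master seed.
#' @param stage integer stage index (any non-negative integer).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) %% 2147483629 * 7919 +
              as.numeric(stage) * 104729 + 1) %% 2147483629)
}

#' Database schema
#'
#' Required columns of the paired-observation database: identifiers and
#' coordinates, the crop label, attribute and service ids, the two
#' treatment means, one 0/1 column per practice axis, and the 14
#' site-level covariates (latitude doubles as the spatial-block
#' predictor).  One row per (observation, attribute).
#'
#' @param axes practice-axis names.
#' @return Character vector of required column names.
#' @export
db_schema <- function(axes = names(practice_taxonomy())) {
  covs <- setdiff(unlist(env_blocks(), use.names = FALSE), "lat")
  c("study_id", "site_id", "lat", "lon", "crop", "attribute_id",
    "service_id", "x_s", "x_i", axes, covs)
}

#' Load and validate a database CSV
#'
#' Checks column presence (hard error naming any missing column), coerces
#' numeric columns (hard error on malformed numerics), and applies
#' row-level validation: rows with nonpositive or missing treatment means
#' and rows with non-binary practice codes are excluded, with
#' machine-readable reason codes collected in the report.
#'
#' @param path CSV file path.
#' @param axes practice-axis column names expected.
#' @return List: `data` (validated data.frame), `report` (list with
#'   `n_in`, `n_used`, `exclusions` data.frame of reason/count).
#' @export
load_database <- function(path, axes = names(practice_taxonomy())) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty database file: ", path)
  required <- db_schema(axes)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(required, c("study_id", "site_id", "crop",
                                  "attribute_id", "service_id"))
  for (cc in num_cols) {
    coerced <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- is.na(coerced) & !is.na(raw[[cc]]) &
      !(trimws(as.character(raw[[cc]])) %in% c("", "NA"))
    if (any(bad))
      stop(sprintf("malformed numeric value(s) in column '%s' (e.g. '%s')",
                   cc, raw[[cc]][which(bad)[1]]))
    raw[[cc]] <- coerced
  }
  n_in <- nrow(raw)
  reasons <- character(0)
  bad_mean <- !is.finite(raw$x_s) | !is.finite(raw$x_i) |
    raw$x_s <= 0 | raw$x_i <= 0
  pv <- as.matrix(raw[, axes, drop = FALSE])
  bad_pv <- apply(pv, 1, function(r) anyNA(r) || !all(r %in% c(0, 1)))
  zero_pv <- !bad_pv & rowSums(pv) == 0
  excl <- rbind(
    data.frame(reason = "nonpositive mean", count = sum(bad_mean)),
    data.frame(reason = "non-binary practice code",
               count = sum(bad_pv & !bad_mean)),
    data.frame(reason = "zero sustainable practices",
               count = sum(zero_pv & !bad_mean))
  )
  keep <- !bad_mean & !bad_pv & !zero_pv
  list(data = raw[keep, , drop = FALSE],
       report = list(n_in = n_in, n_used = sum(keep),
                     exclusions = excl[excl$count > 0, , drop = FALSE]))
}

#' Write a database CSV
#'
#' @param db database data.frame.
#' @param path output path.
#' @export
write_database <- function(db, path) {
  utils::write.csv(db, path, row.names = FALSE)
  invisible(path)
}

#' Expected true group mean from a truth table
#'
#' @param truth a `truth_table` from [simulate_database()].
#' @param service service id.
#' @param n practice count (may be fractional, e.g. the realized mean
#'   count inside the pooled 7+ bin).
#' @return Expected LnRR `alpha_s + beta_s * dose(n)` (environment and
#'   site effects average to zero by construction).
#' @export
truth_expected <- function(truth, service, n) {
  d <- if (truth$dose == "log1p") log(1 + n) else n
  unname(truth$alpha[[service]] + truth$beta[[service]] * d)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  Scale-sensitive
#' defaults (`trees`, `replicates`, bootstrap `B`, permutations) follow
#' the full-scale analysis; tests run with reduced values via overrides.
#'
#' @param sim a [sim_config()] (its seed is re-derived from `seed`).
#' @param seed master seed; every stage derives its own seed from it.
#' @param B bootstrap resamples for effect summaries.
#' @param alpha two-sided CI level.
#' @param n_perm permutations for block significance.
#' @param map_services services to map (default: the two services mapped
#'   at full scale, soil fertility and carbon sequestration).
#' @param trees,replicates forest size per replicate and replicate count.
#' @param grid_dim integer lattice dimensions (rows, cols) of the
#'   synthetic prediction grid.
#' @param mask_alpha,mask_df applicability-mask settings (`mask_df = NULL`
#'   uses the covariate dimension).
#' @param equivalence_band half-width for scenario comparison.
#' @param stages which stages to run, in order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), seed = 1L, B = 4999,
                            alpha = 0.05, n_perm = 999,
                            map_services = c("soil_fertility",
                                             "carbon_sequestration"),
                            trees = 999, replicates = 100,
                            grid_dim = c(20, 30), mask_alpha = 0.95,
                            mask_df = NULL, equivalence_band = 0.1,
                            stages = c("simulate", "effects", "envpart",
                                       "map")) {
  sim$seed <- derive_seed(seed, 101L)
  structure(list(sim = sim, seed = as.integer(seed), B = B, alpha = alpha,
                 n_perm = n_perm, map_services = map_services,
                 trees = trees, replicates = replicates,
                 grid_dim = as.integer(grid_dim), mask_alpha = mask_alpha,
                 mask_df = mask_df, equivalence_band = equivalence_band,
                 stages = stages),
            class = "pipeline_config")
}

#' Write a configuration as structured text (JSON)
#' @param config a [pipeline_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(path)
}

#' Run the full pipeline: simulate, effects, envpart, map
#'
#' Deterministic for a fixed master seed.  A stage failure is recorded in
#' the manifest with its cause and later stages are skipped.  When
#' `out_dir` is given, every stage writes its tables as CSV and the run
#' manifest as JSON.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @return List with the stage outputs (`database`, `truth`, `effects`,
#'   `envpart`, `maps`) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  services <- names(config$sim$attribute_map)
  bad <- setdiff(config$map_services, services)
  if (length(bad) > 0)
    stop("unknown service name(s) in map_services: ",
         paste(bad, collapse = ", "))
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("agrostack")),
                   stages = list())
  out <- list()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed || !(name %in% config$stages)) return(NULL)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       cause = conditionMessage(res))
      failed <<- TRUE
      return(NULL)
    }
    manifest$stages[[name]] <<- res$log
    res$value
  }

  sim_out <- run_stage("simulate", function() {
    s <- simulate_database(config$sim)
    list(value = s, log = list(status = "ok", rows_out = nrow(s$database),
                               seed = config$sim$seed))
  })
  out$database <- sim_out$database
  out$truth <- sim_out$truth

  out$effects <- run_stage("effects", function() {
    db <- out$database
    eff_seed <- derive_seed(config$seed, 2L)
    res <- list(
      by_count = summarize_effects(db, "count", B = config$B,
                                   alpha = config$alpha, seed = eff_seed),
      by_class = summarize_effects(db, "class", B = config$B,
                                   alpha = config$alpha,
                                   seed = derive_seed(eff_seed, 1L)),
      counts = tabulate_counts(db),
      by_practice = summarize_by_practice(
        db, which_axes = c("crop_rotation", "tillage",
                           "residue_management"),
        B = config$B, alpha = config$alpha,
        seed = derive_seed(eff_seed, 2L))
    )
    strata <- stratify_by_aridity(db)
    res$by_count_arid <- summarize_effects(strata$arid, "count",
                                           B = config$B,
                                           alpha = config$alpha,
                                           seed = derive_seed(eff_seed, 3L))
    res$by_count_non_arid <- summarize_effects(strata$non_arid, "count",
                                               B = config$B,
                                               alpha = config$alpha,
                                               seed = derive_seed(eff_seed,
                                                                  4L))
    list(value = res,
         log = list(status = "ok", rows_in = nrow(db),
                    rows_used = nrow(db),
                    groups = nrow(res$by_count),
                    n_arid = nrow(strata$arid),
                    n_non_arid = nrow(strata$non_arid)))
  })

  out$envpart <- run_stage("envpart", function() {
    db <- out$database
    combos <- expand.grid(service = services, class = c("low", "high"),
                          stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(combos)), function(i)
      tryCatch(env_analysis(db, combos$service[i],
                            class = combos$class[i],
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 300L + i)),
               error = function(e) conditionMessage(e)))
    names(res) <- paste(combos$service, combos$class, sep = ".")
    ok <- vapply(res, is.list, logical(1))
    list(value = res,
         log = list(status = "ok", analyses = sum(ok),
                    skipped = names(res)[!ok]))
  })

  out$maps <- run_stage("map", function() {
    db <- out$database
    map_seed <- derive_seed(config$seed, 4L)
    set.seed(derive_seed(map_seed, 0L))
    n_cells <- prod(config$grid_dim)
    lattice <- simulate_covariates(n_cells, config$sim$block_cor,
                                   config$sim$within_cor)
    rf_covs <- setdiff(unlist(env_blocks(), use.names = FALSE), "lat")
    grids <- lapply(rf_covs, function(nm)
      env_grid(matrix(lattice[[nm]], config$grid_dim[1],
                      config$grid_dim[2])))
    names(grids) <- rf_covs

    se_all <- observation_service_effects(db)
    se_all <- se_all[, setdiff(names(se_all), rf_covs)]
    site_cov <- db[!duplicated(db$site_id), c("site_id", rf_covs)]
    maps <- list()
    validation <- list()
    for (svc in config$map_services) {
      scen <- list()
      for (cls in c("low", "high")) {
        sub <- se_all[se_all$service_id == svc &
                        intensity_class(se_all$n_practices) == cls, ]
        dat <- merge(sub, site_cov, by = "site_id")
        dat <- dat[stats::complete.cases(dat[, c("effect", rf_covs)]), ]
        if (nrow(dat) < 20) {
          scen[[cls]] <- sprintf("skipped: only %d observations",
                                 nrow(dat))
          next
        }
        ens <- fit_rf_ensemble(dat[, rf_covs], dat$effect,
                               trees = config$trees,
                               replicates = config$replicates,
                               seed = derive_seed(map_seed,
                                                  match(svc, services) * 10 +
                                                    (cls == "high")))
        m <- predict_map(ens, grids, dat[, rf_covs],
                         mask_alpha = config$mask_alpha,
                         mask_df = config$mask_df)
        m$validation <- validate_pred_obs(predict(ens, dat[, rf_covs]),
                                          dat$effect)
        m$oob_r2 <- mean(ens$oob_r2, na.rm = TRUE)
        scen[[cls]] <- m
      }
      if (is.list(scen$low) && is.list(scen$high))
        scen$comparison <- compare_scenarios(scen$low$standardized,
                                             scen$high$standardized,
                                             band = config$equivalence_band)
      maps[[svc]] <- scen
    }
    list(value = maps,
         log = list(status = "ok", services = config$map_services,
                    grid_cells = n_cells))
  })

  manifest$determinism <- list(master_seed = config$seed,
                               splitting = "derive_seed(master, stage)")
  out$manifest <- manifest
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$database))
    write_database(out$database, file.path(out_dir, "database.csv"))
  if (!is.null(out$truth))
    utils::write.csv(out$truth$expected_group_means,
                     file.path(out_dir, "truth_group_means.csv"),
                     row.names = FALSE)
  for (nm in c("by_count", "by_class", "counts", "by_practice",
               "by_count_arid", "by_count_non_arid"))
    if (!is.null(out$effects[[nm]]))
      utils::write.csv(out$effects[[nm]],
                       file.path(out_dir, paste0("effects_", nm, ".csv")),
                       row.names = FALSE)
  if (!is.null(out$envpart)) {
    vp <- do.call(rbind, lapply(names(out$envpart), function(nm) {
      e <- out$envpart[[nm]]
      if (!is.list(e) || is.null(e$varpart)) return(NULL)
      data.frame(analysis = nm, fraction = names(e$varpart$fractions),
                 value = unname(e$varpart$fractions))
    }))
    if (!is.null(vp))
      utils::write.csv(vp, file.path(out_dir, "varpart_fractions.csv"),
                       row.names = FALSE)
  }
  if (!is.null(out$maps))
    for (svc in names(out$maps))
      for (cls in intersect(c("low", "high"), names(out$maps[[svc]])))
        if (is.list(out$maps[[svc]][[cls]]))
          write_grid_csv(out$maps[[svc]][[cls]]$standardized,
                         file.path(out_dir,
                                   sprintf("map_%s_%s.csv", svc, cls)))
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(out_dir)
}
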