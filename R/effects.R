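#' Default practice taxonomy
#'
#' The eight management axes along which a treatment is coded sustainable
#' (1) or intensive (0).  Each axis maps admissible raw labels to a binary
#' code; unknown labels are rejected rather than silently coded.  The axis
#' list and label sets are documented stand-ins for a study-specific
#' coding table and can be overridden wholesale.
#'
#' @return An object of class `practice_taxonomy`: a named list of axes,
#'   each a named integer vector mapping raw labels to 0 or 1.
#' @examples
#' tax <- practice_taxonomy()
#' names(tax)
#' @export
practice_taxonomy <- function() {
  tax <- list(
    tillage = c(no_till = 1L, reduced_till = 1L, conventional_till = 0L),
    crop_rotation = c(rotation = 1L, monoculture = 0L),
    residue_management = c(residue_retained = 1L, residue_removed = 0L,
                           residue_burned = 0L),
    organic_fertilization = c(organic = 1L, combined = 1L, mineral_only = 0L),
    cover_cropping = c(cover_crop = 1L, bare_fallow = 0L),
    pesticide_use = c(reduced_pesticide = 1L, biocontrol = 1L,
                      conventional_pesticide = 0L),
    irrigation_regime = c(deficit_irrigation = 1L, rainfed = 1L,
                          full_irrigation = 0L),
    intercropping = c(intercrop = 1L, sole_crop = 0L)
  )
  structure(tax, class = "practice_taxonomy")
}

#' Code raw practice labels to a binary sustainable/intensive vector
#'
#' @param labels named character vector, one raw label per axis (names must
#'   match the taxonomy axes).
#' @param taxonomy a [practice_taxonomy()] object.
#' @return Integer vector of 0/1 codes, one per axis, in taxonomy order.
#' @export
code_practices <- function(labels, taxonomy = practice_taxonomy()) {
  axes <- names(taxonomy)
  if (!all(axes %in% names(labels)))
    stop("missing labels for axes: ",
         paste(setdiff(axes, names(labels)), collapse = ", "))
  out <- vapply(axes, function(a) {
    lbl <- as.character(labels[[a]])
    map <- taxonomy[[a]]
    if (!lbl %in% names(map))
      stop(sprintf("unknown label '%s' for axis '%s'", lbl, a))
    map[[lbl]]
  }, integer(1))
  names(out) <- axes
  out
}

#' Log response ratio
#'
#' `lnrr(x_s, x_i) = ln(x_s) - ln(x_i)`: positive when the sustainable
#' treatment mean exceeds the intensive (control) mean.  Nonpositive or
#' missing means make the log-ratio undefined; those elements return `NA`
#' with a warning so callers can exclude and log them.
#'
#' @param x_s treatment (sustainable) means, must be positive.
#' @param x_i control (intensive) means, must be positive.
#' @return Numeric vector of effect sizes (dimensionless).
#' @examples
#' lnrr(2, 1)            # log(2)
#' lnrr(10, 10)          # 0
#' @export
lnrr <- function(x_s, x_i) {
  bad <- !is.finite(x_s) | !is.finite(x_i) | x_s <= 0 | x_i <= 0
  out <- rep(NA_real_, length(bad))
  out[!bad] <- log(x_s[!bad]) - log(x_i[!bad])
  if (any(bad))
    warning(sum(bad), " record(s) with nonpositive or missing treatment ",
            "means excluded (log-ratio undefined)")
  out
}

#' Count sustainable practices in a binary practice vector
#'
#' @param practice_vector a 0/1 vector (or a matrix with one row per
#'   observation and one column per axis).
#' @return Integer count(s) of practices coded sustainable.
#' @export
count_practices <- function(practice_vector) {
  v <- if (is.matrix(practice_vector) || is.data.frame(practice_vector))
    as.matrix(practice_vector) else matrix(practice_vector, nrow = 1)
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop("practice vector must contain only 0/1 entries")
  n <- as.integer(rowSums(v))
  if (length(n) == 1 && !is.matrix(practice_vector) &&
      !is.data.frame(practice_vector)) n <- n[[1]]
  n
}

#' Bin a practice count, merging 7 and 8
#'
#' Counts of 7 and 8 are pooled into a single `"7+"` bin because studies
#' stacking that many practices are rare.
#'
#' @param n_practices integer count(s) in 1..8.
#' @return Factor with levels `"1".."6","7+"`.
#' @export
bin_count <- function(n_practices) {
  if (any(n_practices < 1 | n_practices > 8))
    stop("practice counts must lie in 1..8")
  lab <- ifelse(n_practices >= 7, "7+", as.character(n_practices))
  factor(lab, levels = c(as.character(1:6), "7+"))
}

#' Classify a practice count as low (1-3) or high (4-8) intensity
#'
#' @param n_practices integer count(s) in 1..8.
#' @return Factor with levels `"low","high"`.
#' @export
intensity_class <- function(n_practices) {
  if (any(n_practices < 1 | n_practices > 8))
    stop("practice counts must lie in 1..8")
  factor(ifelse(n_practices <= 3, "low", "high"), levels = c("low", "high"))
}

#' Aggregate attribute-level effect sizes to one service-level effect
#'
#' Unweighted arithmetic mean of the attribute LnRRs measured for one
#' observation within one service group.
#'
#' @param attribute_lnrr numeric vector of attribute-level effect sizes.
#' @return Single numeric service-level effect.
#' @export
service_effect <- function(attribute_lnrr) {
  attribute_lnrr <- attribute_lnrr[is.finite(attribute_lnrr)]
  if (length(attribute_lnrr) == 0)
    stop("service_effect() needs at least one finite attribute effect size")
  mean(attribute_lnrr)
}

#' Summarize a group of effect sizes with a bootstrap confidence interval
#'
#' Computes the unweighted mean LnRR of a group and a nonparametric
#' percentile bootstrap CI; the group effect is flagged significant when
#' the interval excludes zero.  No multiple-testing correction is applied.
#' With fewer than two effects the CI is undefined (`NA`) and the group is
#' never significant.
#'
#' @param effects numeric vector of effect sizes.
#' @param B number of bootstrap resamples (default 4999).
#' @param alpha two-sided error level (default 0.05 for a 95% CI).
#' @param seed integer seed for the resampling.
#' @param method `"percentile"` (default) or `"t"` for a Student-t interval
#'   used as a parametric cross-check.
#' @return One-row data.frame: `n`, `mean_lnrr`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
summarize_group <- function(effects, B = 4999, alpha = 0.05, seed = 1L,
                            method = c("percentile", "t")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, B >= 1)
  effects <- effects[is.finite(effects)]
  n <- length(effects)
  if (n == 0)
    return(data.frame(n = 0L, mean_lnrr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, significant = FALSE))
  m <- mean(effects)
  if (n < 2)
    return(data.frame(n = n, mean_lnrr = m, ci_low = NA_real_,
                      ci_high = NA_real_, significant = FALSE))
  if (method == "t") {
    se <- stats::sd(effects) / sqrt(n)
    q <- stats::qt(1 - alpha / 2, df = n - 1)
    ci <- c(m - q * se, m + q * se)
  } else {
    ci <- local({
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
      bm <- boot_means(effects, B)
      stats::quantile(bm, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    })
  }
  data.frame(n = n, mean_lnrr = m, ci_low = ci[1], ci_high = ci[2],
             significant = ci[1] > 0 || ci[2] < 0)
}

# Bootstrap means in blocks so memory stays bounded for large B.
boot_means <- function(x, B) {
  n <- length(x)
  block <- max(1L, min(B, as.integer(2e6 / n)))
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(block, B - done)
    idx <- sample.int(n, n * b, replace = TRUE)
    out[(done + 1L):(done + b)] <- colMeans(matrix(x[idx], nrow = n))
    done <- done + b
  }
  out
}

#' Summarize service effects by practice-count bin or intensity class
#'
#' Runs the full aggregation chain on a validated database: attribute
#' LnRR, observation-level service mean, then a bootstrap group summary
#' per service and group.
#'
#' @param db a database data.frame (see [load_database()] for the schema).
#' @param group_by `"count"` for bins 1..6,7+ or `"class"` for low/high.
#' @param B,alpha,seed,method passed to [summarize_group()].
#' @param axes character vector of practice-axis column names; defaults to
#'   the taxonomy axes present in `db`.
#' @return data.frame with columns `service_id`, `group`, `n`, `n_studies`,
#'   `mean_lnrr`, `ci_low`, `ci_high`, `significant`.
#' @export
summarize_effects <- function(db, group_by = c("count", "class"), B = 4999,
                              alpha = 0.05, seed = 1L,
                              method = c("percentile", "t"), axes = NULL) {
  group_by <- match.arg(group_by)
  method <- match.arg(method)
  se <- observation_service_effects(db, axes = axes)
  se$group <- if (group_by == "count") bin_count(se$n_practices)
              else intensity_class(se$n_practices)
  groups <- split(se, list(se$service_id, se$group), drop = TRUE)
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    s <- summarize_group(g$effect, B = B, alpha = alpha,
                         seed = derive_seed(seed, i), method = method)
    cbind(data.frame(service_id = g$service_id[1],
                     group = as.character(g$group[1]),
                     n_studies = length(unique(g$study_id))), s)
  }))
  out <- out[order(out$service_id, out$group),
             c("service_id", "group", "n", "n_studies", "mean_lnrr",
               "ci_low", "ci_high", "significant")]
  rownames(out) <- NULL
  out
}

#' Collapse a database to observation-level service effects
#'
#' Attribute rows belonging to the same observation and service are
#' averaged into one effect, so observations reporting many attributes do
#' not dominate their service.
#'
#' @inheritParams summarize_effects
#' @return data.frame with one row per (observation, service): `obs_id`,
#'   `study_id`, `site_id`, `service_id`, `n_practices`, `aridity_index`,
#'   `effect`.
#' @export
observation_service_effects <- function(db, axes = NULL) {
  if (is.null(axes)) axes <- intersect(names(practice_taxonomy()), names(db))
  if (length(axes) == 0) stop("no practice-axis columns found in database")
  eff <- suppressWarnings(lnrr(db$x_s, db$x_i))
  keep <- is.finite(eff)
  db <- db[keep, , drop = FALSE]
  eff <- eff[keep]
  n_pr <- count_practices(db[, axes, drop = FALSE])
  obs_id <- if ("obs_id" %in% names(db)) db$obs_id
            else paste(db$study_id, db$site_id, sep = ":")
  key <- paste(obs_id, db$service_id, sep = "\r")
  agg <- tapply(eff, key, mean)
  first <- !duplicated(key)
  data.frame(obs_id = obs_id[first], study_id = db$study_id[first],
             site_id = db$site_id[first], service_id = db$service_id[first],
             n_practices = n_pr[first],
             aridity_index = db$aridity_index[first],
             effect = as.numeric(agg[key[first]]))
}

#' Split a database into arid and non-arid subsets
#'
#' Arid means aridity index (MAP/PET) strictly below 1; the boundary value
#' 1 is assigned to the non-arid subset.  Rows with missing aridity index
#' are dropped with a warning.
#'
#' @param db data.frame with an `aridity_index` column.
#' @return Named list with elements `arid` and `non_arid`.
#' @export
stratify_by_aridity <- function(db) {
  if (!"aridity_index" %in% names(db)) stop("aridity_index column missing")
  miss <- !is.finite(db$aridity_index)
  if (any(miss)) {
    warning(sum(miss), " row(s) with missing aridity index excluded")
    db <- db[!miss, , drop = FALSE]
  }
  list(arid = db[db$aridity_index < 1, , drop = FALSE],
       non_arid = db[db$aridity_index >= 1, , drop = FALSE])
}

#' Tabulate observations per practice-count bin
#'
#' @param db database data.frame (needs the practice-axis columns).
#' @param axes optional practice-axis column names.
#' @return data.frame with columns `bin`, `n`, `percent` (percent of all
#'   observations, rounded to 2 decimals).
#' @export
tabulate_counts <- function(db, axes = NULL) {
  if (nrow(db) == 0) stop("empty database")
  if (is.null(axes)) axes <- intersect(names(practice_taxonomy()), names(db))
  n_pr <- count_practices(db[, axes, drop = FALSE])
  bins <- bin_count(n_pr)
  tab <- table(bins)
  data.frame(bin = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(bins), 2))
}

#' Effects of individual practice types
#'
#' For each practice axis, summarizes the service-level effects of the
#' observations whose treatment codes that axis sustainable — the
#' per-practice analogue of the count-bin summary.
#'
#' @inheritParams summarize_effects
#' @param which_axes axes to report (default: all present).
#' @return data.frame like [summarize_effects()] with a `practice` column.
#' @export
summarize_by_practice <- function(db, which_axes = NULL, B = 4999,
                                  alpha = 0.05, seed = 1L) {
  axes <- intersect(names(practice_taxonomy()), names(db))
  if (is.null(which_axes)) which_axes <- axes
  out <- lapply(seq_along(which_axes), function(i) {
    a <- which_axes[[i]]
    sub <- db[db[[a]] == 1, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    se <- observation_service_effects(sub, axes = axes)
    groups <- split(se, se$service_id)
    do.call(rbind, lapply(seq_along(groups), function(j) {
      g <- groups[[j]]
      s <- summarize_group(g$effect, B = B, alpha = alpha,
                           seed = derive_seed(seed, i * 100 + j))
      cbind(data.frame(practice = a, service_id = g$service_id[1]), s)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
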