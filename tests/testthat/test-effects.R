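test_that("lnrr closed forms, antisymmetry and additivity", {
  expect_identical(lnrr(10, 10), 0)
  expect_equal(lnrr(2, 1), log(2), tolerance = 1e-12)
  for (xi in c(0.01, 1, 7, 1234))
    expect_equal(lnrr(xi * exp(1), xi), 1, tolerance = 1e-12)
  set.seed(11)
  a <- rlnorm(50); b <- rlnorm(50); k <- rlnorm(50)
  expect_equal(lnrr(a, b), -lnrr(b, a), tolerance = 1e-12)
  expect_equal(lnrr(k * a, b), log(k) + lnrr(a, b), tolerance = 1e-12)
})

test_that("lnrr flags nonpositive and missing means as NA with a warning", {
  expect_warning(out <- lnrr(c(1, 0, -2, NA), c(1, 1, 1, 1)),
                 "nonpositive or missing")
  expect_equal(out, c(0, NA, NA, NA))
})

test_that("practice counting, binning and intensity classes", {
  expect_identical(count_practices(rep(0L, 8)), 0L)
  expect_identical(count_practices(c(1, 1, 1, 0, 0, 0, 0, 0)), 3L)
  expect_error(count_practices(c(1, 2, 0)), "0/1")
  m <- rbind(rep(1, 8), c(1, rep(0, 7)))
  expect_identical(count_practices(m), c(8L, 1L))

  expect_identical(as.character(bin_count(c(7, 8))), c("7+", "7+"))
  expect_identical(as.character(bin_count(1:6)), as.character(1:6))
  expect_error(bin_count(0), "1\\.\\.8")

  expect_identical(as.character(intensity_class(c(1, 3, 4, 8))),
                   c("low", "low", "high", "high"))
  expect_error(intensity_class(9))
})

test_that("coding raw labels follows the taxonomy and rejects unknowns", {
  tax <- practice_taxonomy()
  labels <- c(tillage = "no_till", crop_rotation = "monoculture",
              residue_management = "residue_retained",
              organic_fertilization = "mineral_only",
              cover_cropping = "cover_crop",
              pesticide_use = "conventional_pesticide",
              irrigation_regime = "rainfed", intercropping = "sole_crop")
  v <- code_practices(labels, tax)
  expect_identical(unname(v), c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  labels[["tillage"]] <- "plowed_twice"
  expect_error(code_practices(labels, tax), "unknown label")
})

test_that("service_effect is the unweighted mean of attribute effects", {
  expect_equal(service_effect(c(0.2, 0.4)), 0.3)
  expect_equal(service_effect(0.5), 0.5)
  set.seed(7)
  x <- rnorm(7)
  acc <- 0
  for (v in x) acc <- acc + v  # independent accumulation oracle
  expect_equal(service_effect(x), acc / 7, tolerance = 1e-12)
  expect_error(service_effect(numeric(0)), "at least one")
})

test_that("summarize_group degenerate cases", {
  s <- summarize_group(rep(0.4, 10), B = 200, seed = 1)
  expect_equal(s$mean_lnrr, 0.4)
  expect_equal(c(s$ci_low, s$ci_high), c(0.4, 0.4))
  expect_true(s$significant)
  s0 <- summarize_group(rep(0, 10), B = 200, seed = 1)
  expect_false(s0$significant)
  s1 <- summarize_group(0.3, B = 200, seed = 1)
  expect_true(is.na(s1$ci_low) && is.na(s1$ci_high))
  expect_false(s1$significant)
})

test_that("bootstrap CI contains the sample mean and reproduces by seed", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(25, mean = runif(1, -1, 1), sd = runif(1, 0.1, 2))
    s <- summarize_group(x, B = 1000, seed = i)
    expect_lte(s$ci_low, mean(x))
    expect_gte(s$ci_high, mean(x))
  }
  s1 <- summarize_group(1:30 / 10, B = 999, seed = 9)
  s2 <- summarize_group(1:30 / 10, B = 999, seed = 9)
  expect_identical(s1, s2)
})

test_that("t-interval option matches the closed form", {
  set.seed(3)
  x <- rnorm(20, 0.5)
  s <- summarize_group(x, method = "t")
  half <- qt(0.975, 19) * sd(x) / sqrt(20)
  expect_equal(s$ci_low, mean(x) - half, tolerance = 1e-12)
  expect_equal(s$ci_high, mean(x) + half, tolerance = 1e-12)
})

test_that("aridity stratification uses a strict threshold at 1", {
  db <- make_count_db(c(1, 2, 3))
  db$aridity_index <- c(0.5, 1.5, 1.0)
  str <- stratify_by_aridity(db)
  expect_identical(str$arid$obs_id, "o00001")
  expect_setequal(str$non_arid$obs_id, c("o00002", "o00003"))
  db$aridity_index[2] <- NA
  expect_warning(str2 <- stratify_by_aridity(db), "missing aridity")
  expect_identical(nrow(str2$arid) + nrow(str2$non_arid), 2L)
})

test_that("tabulate_counts percentages", {
  db <- make_count_db(c(rep(1, 3), rep(7, 1)))
  tc <- tabulate_counts(db)
  expect_equal(tc$percent[tc$bin == "1"], 75)
  expect_equal(tc$percent[tc$bin == "7+"], 25)
  one <- tabulate_counts(make_count_db(rep(2, 5)))
  expect_equal(one$percent[one$bin == "2"], 100.00)
  expect_error(tabulate_counts(make_count_db(1)[0, ]), "empty")
})

test_that("observation-level aggregation averages attributes per service", {
  db <- make_count_db(c(2, 2, 5), lnrr_values = c(0.2, 0.4, 1.0))
  db$obs_id <- c("u1", "u1", "u2")  # two attribute rows in one unit
  db$attribute_id <- c("grain_yield", "harvest_index", "grain_yield")
  se <- observation_service_effects(db)
  expect_equal(nrow(se), 2L)
  expect_equal(se$effect[se$obs_id == "u1"], 0.3, tolerance = 1e-12)
  expect_equal(se$effect[se$obs_id == "u2"], 1.0, tolerance = 1e-12)
})

test_that("summarize_effects recovers group means on a synthetic database", {
  s <- local_sim()
  eff <- summarize_effects(s$database, "count", B = 300, seed = 99)
  expect_true(all(eff$ci_low <= eff$ci_high, na.rm = TRUE))
  expect_true(all(eff$n >= 1))
  # significant flag consistent with the interval
  has_ci <- !is.na(eff$ci_low)
  expect_identical(eff$significant[has_ci],
                   (eff$ci_low > 0 | eff$ci_high < 0)[has_ci])
})
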