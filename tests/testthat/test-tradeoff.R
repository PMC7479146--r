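test_that("relative normalization divides by species maxima", {
  d <- data.frame(tree_id = c("a", "b"), site_id = "S", species = "SP",
                  rw_early = c(1, 2), age = c(100, 50), stringsAsFactors = FALSE)
  r <- normalize_relative(d)
  expect_equal(r$rw_early, c(0.5, 1))
  expect_equal(r$age, c(1, 0.5))
  expect_true(attr(r, "relative"))
  expect_warning(normalize_relative(rbind(d, data.frame(
    tree_id = "c", site_id = "S", species = "LONE", rw_early = 1, age = 10))),
    "single tree")
})

test_that("weighted mean decay uses cube-root weights", {
  fits <- data.frame(b = c(-0.2, -0.6), n = c(8, 27))
  w <- weighted_mean_decay(fits)
  expect_equal(w$mean_b, (2 * -0.2 + 3 * -0.6) / 5)
  expect_equal(w$n_negative, 2L)
  # equal n reduces to the arithmetic mean; order never matters
  eq <- data.frame(b = c(-0.1, -0.5, -0.3), n = 100)
  expect_equal(weighted_mean_decay(eq)$mean_b, mean(eq$b))
  expect_equal(weighted_mean_decay(eq[3:1, ])$mean_b, weighted_mean_decay(eq)$mean_b)
  single <- data.frame(b = -0.42, n = 10)
  expect_equal(weighted_mean_decay(single)$mean_b, -0.42)
})

test_that("binned percentile ages track the fitted quantile curve", {
  s <- generate_known_tradeoff_sample(known_tradeoff_config(n = 10000, seed = 6))
  chk <- binned_quantile_check(s, n_bins = 5)
  expect_lt(attr(chk, "max_rel_deviation"), 0.1)
  one <- binned_quantile_check(s, n_bins = 1)
  expect_equal(one$empirical, unname(quantile(s$age, 0.95, type = 7)))
})

test_that("major axis fit matches its closed form and handles exact lines", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(fit_major_axis(x, 2 * x)$slope, 2)
  set.seed(3)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50, 0, 0.6)
  f <- fit_major_axis(x, y)
  # independent closed form for the major axis slope
  vx <- var(x); vy <- var(y); cxy <- cov(x, y)
  slope <- (vy - vx + sqrt((vy - vx)^2 + 4 * cxy^2)) / (2 * cxy)
  expect_equal(f$slope, slope, tolerance = 1e-10)
  expect_equal(f$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
  expect_error(fit_major_axis(rep(1, 5), 1:5), "zero variance")
})

test_that("stratification separates a direct trade-off from a climate proxy", {
  # construct data where temperature drives growth, and lifespan depends on
  # growth only: within temperature classes the trade-off must persist; within
  # growth bands the temperature-lifespan relation must collapse
  set.seed(21)
  n_sites <- 30
  sites <- data.frame(site_id = sprintf("S%02d", 1:n_sites),
                      mat_c = runif(n_sites, 0, 8), lat = 50, lon = -70)
  n <- 3000
  si <- sample(n_sites, n, replace = TRUE)
  rw <- exp(0.15 * sites$mat_c[si]) * exp(rnorm(n, -0.7, 0.25))
  age <- exp(log(400) - 0.5 * rw + log(runif(n)) - log(0.95))
  d <- data.frame(tree_id = sprintf("T%04d", 1:n), site_id = sites$site_id[si],
                  species = "SP", rw_early = rw, age = age, stringsAsFactors = FALSE)

  tc <- stratified_tradeoff(d, sites, "temperature", n_boot = 100, min_n = 100)
  expect_true(all(tc$b < 0))
  expect_true(mean(tc$significant) > 0.5)

  gb <- stratified_tradeoff(d, sites, "growth_band", n_boot = 100, min_n = 100)
  # temperature slopes within growth bands are an order of magnitude weaker
  # than the trade-off slopes within temperature classes
  expect_lt(median(abs(gb$b)), 0.05)
})

test_that("single and sparse strata degenerate gracefully", {
  s <- generate_known_tradeoff_sample(known_tradeoff_config(n = 200, seed = 2))
  sites <- data.frame(site_id = "KT01", mat_c = 1, lat = 50, lon = -70,
                      crown_cover_class = 2, soil_class = "till")
  s$site_id <- "KT01"
  one <- stratified_tradeoff(s, sites, "crown_cover_class", n_boot = 0)
  expect_equal(nrow(one), 1)
  plain <- fit_quantile_exponential(s, n_boot = 0)
  expect_equal(one$b, plain$b)
  none <- stratified_tradeoff(s[1:10, ], sites, "crown_cover_class", n_boot = 0)
  expect_equal(nrow(none), 0)
  expect_length(attr(none, "skipped"), 1)
})

test_that("nearby small sites pool until each pool reaches the minimum", {
  sm <- data.frame(tree_id = sprintf("t%02d", 1:70),
                   site_id = rep(c("A", "B", "C"), c(15, 15, 40)),
                   species = "SP", rw_early = 1, age = 100, stringsAsFactors = FALSE)
  sites <- data.frame(site_id = c("A", "B", "C"),
                      lat = c(50, 50.01, 58), lon = c(-70, -70.01, -60),
                      mat_c = c(1, 1.2, 4))
  pooled <- site_level_aggregate(sm, sites, min_per_site = 30)
  expect_equal(nrow(pooled), 2)
  expect_true(all(pooled$n >= 30))
  ab <- pooled[grepl("A", pooled$members), ]
  expect_true(grepl("B", ab$members))   # the two close sites merged
  # already-large sites stay unchanged
  big <- site_level_aggregate(sm[sm$site_id == "C", ], sites[3, ], min_per_site = 30)
  expect_equal(nrow(big), 1)
  expect_equal(big$n, 40)
})

test_that("maximum-age resampling matches rank-based expectations", {
  set.seed(4)
  ages <- runif(5000, 20, 500)            # tie-free
  r <- resample_max_age(ages, sizes = c(1, 100, 5000), reps = 400, seed = 5)
  f1 <- r$fraction[r$size == 1 & r$threshold == 0.95]
  expect_lt(abs(f1 - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  f100 <- r$fraction[r$size == 100 & r$threshold == 0.95]
  expect_lt(abs(f100 - (1 - 0.95^100)), 3 * sqrt(0.006 * 0.994 / 400) + 0.001)
  expect_equal(r$fraction[r$size == 5000 & r$threshold == 0.95], 1)
  expect_error(resample_max_age(ages, sizes = 6000), "exceeds")
})

test_that("decay-constant error shrinks with sample size", {
  s <- generate_known_tradeoff_sample(known_tradeoff_config(n = 2000, seed = 3))
  ec <- sample_size_error_curve(s, sizes = c(50, 300, 2000), reps = 40, seed = 2)
  expect_equal(ec$mean_abs_rel_err[ec$size == 2000], 0)   # whole population
  expect_lt(ec$mean_abs_rel_err[ec$size == 300], ec$mean_abs_rel_err[ec$size == 50])
})

test_that("big-tree sampling scenarios reproduce the bias directions", {
  pop <- generate_population(synth_config(n_trees = 2000, seed = 4))
  dist <- generate_stand_distribution(mortality_diameter(), synth_config(seed = 11),
                                      recruits_per_yr = 60, years = 400, tally_years = 80)
  ff <- data.frame(bin_low = dist$bin_low, count = round(dist$N) * 4)
  ff <- ff[ff$count > 0, ]
  # the size-threshold effect is a few percent, comparable to one resample's
  # noise, so the direction is asserted on the mean over resampling seeds
  ratios <- vapply(1:4, function(s) {
    bx <- big_tree_bias_experiment(pop$rings, ff, seed = s)
    expect_true(all(vapply(bx$fits, `[[`, numeric(1), "b") < 0))
    c(bx$b_ratio_vs_all[["threshold"]], bx$b_ratio_vs_all[["top10pct"]])
  }, numeric(2))
  # restricting to trees above the coring threshold (or to the largest 10%)
  # weakens the trade-off
  expect_lt(mean(ratios[1, ]), 1)
  expect_lt(mean(ratios[2, ]), 1)
  # self-consistency: sampling with the trajectory set's own size structure
  # cannot invert the sign
  own <- big_tree_bias_experiment(pop$rings, scenarios = "all", seed = 9)
  expect_lt(own$fits$all$b, 0)
})

test_that("published age-sensitivity constants evaluate as documented", {
  expect_equal(lambda_age(0), 0.229)
  expect_equal(lambda_age(100), 0.0000132 * 1e4 - 0.00291 * 100 + 0.229)
  expect_equal(lambda_age(100), 0.07, tolerance = 1e-6)
  expect_equal(lambda_age(135), 0.07)
  expect_equal(lambda_age(500), 0.07)
  expect_true(all(lambda_age(0:500) > 0))
})

test_that("age-band temperature sensitivities are recovered from ring data", {
  lp <- make_lambda_population(n_trees = 500, seed = 13)
  lf <- estimate_lambda(lp$rings, lp$sites)
  rel <- abs(lf$bands$lambda / lambda_age(lf$bands$centre) - 1)
  expect_lt(max(rel), 0.1)
  expect_equal(lf$coefs$plateau, 0.07, tolerance = 0.1)
  # quadratic reproduces the young-age sensitivities
  expect_equal(lambda_age(5, lf$coefs), lambda_age(5), tolerance = 0.1)
  # narrow temperature span is rejected
  warm <- lp$sites; warm$mat_c <- warm$mat_c * 0.2
  expect_error(estimate_lambda(lp$rings, warm), "temperature span")
})
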