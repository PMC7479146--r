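# Shared small trajectory set for the simulator tests.
pop_sim <- generate_population(synth_config(n_trees = 600, seed = 2))
traj_sim <- extend_trajectories(pop_sim$rings)

test_that("trajectories at or beyond the target age are kept unchanged", {
  long <- make_rings("LONG", rep(0.5, 60))
  tr <- extend_trajectories(long, target_age = 50)
  expect_equal(unname(tr$widths[1, ]), rep(0.5, 50))
})

test_that("extension appends the donor-pool mean growth", {
  # ten donors, all 1.0 mm for 10 rings then exactly 0.8 mm to age 80,
  # plus one short tree of the same early growth class
  donors <- do.call(rbind, lapply(1:10, function(i)
    make_rings(sprintf("D%02d", i), c(rep(1, 10), rep(0.8, 70)))))
  short <- make_rings("SHORT", rep(1, 30))
  tr <- extend_trajectories(rbind(donors, short), target_age = 80)
  i <- which(tr$meta$tree_id == "SHORT")
  expect_equal(unname(tr$widths[i, 31:80]), rep(0.8, 50))
  expect_equal(tr$meta$orig_age[i], 30L)
})

test_that("early growth classes are equal-width partitions of the range", {
  rw <- c(0.2, 0.8, 1.3, 1.9, 2.4, 3.2)   # range [0.2, 3.2], class width 0.5
  rings <- do.call(rbind, lapply(seq_along(rw), function(i)
    make_rings(sprintf("W%d", i), rep(rw[i], 15))))
  tr <- extend_trajectories(rings, n_early_classes = 6, target_age = 20)
  expect_equal(tr$meta$class[tr$meta$rw_early == 1.3], 3L)
  expect_equal(tr$meta$class[tr$meta$rw_early == 0.2], 1L)
  expect_equal(tr$meta$class[tr$meta$rw_early == 3.2], 6L)
})

test_that("with zero mortality every tree lives to the trajectory cap", {
  sim <- sim_config(horizon = 300, cohort_size = 10, max_age = 300,
                    mortality = mortality_diameter(b = 0, k = 0), seed = 3)
  out <- run_simulation(traj_sim, sim)
  expect_true(all(out$series$death_rate_pct[1:299] == 0))
  # the first cohort hits the age cap in the final year
  expect_equal(out$series$n_deaths[300], 10)
  expect_true(all(out$trees$age_at_death[!is.na(out$trees$age_at_death)] == 300))
})

test_that("stimulus anomaly and multipliers follow the ramp-and-hold form", {
  st <- stimulus_config()
  expect_equal(delta_t(st, 299), 0)
  expect_equal(delta_t(st, 325), 0.0221 * 25)
  expect_equal(delta_t(st, 350), 0.0221 * 50)
  expect_equal(delta_t(st, 500), 0.0221 * 50)   # constant after the ramp
  # published multipliers at the end of the ramp
  expect_equal(exp(lambda_age(150) * delta_t(st, 350)), 1.080, tolerance = 1e-3)
  expect_equal(exp(lambda_age(0) * delta_t(st, 350)), 1.288, tolerance = 1e-3)
})

test_that("runs are reproducible and paired baselines are exact", {
  sim <- sim_config(horizon = 500, cohort_size = 20, seed = 7)
  a <- run_simulation(traj_sim, sim)
  b <- run_simulation(traj_sim, sim)
  expect_identical(a$series, b$series)
  # a zero-warming stimulus changes nothing under paired seeds
  none <- run_simulation(traj_sim, sim, stimulus_config(warming_rate = 0))
  expect_equal(none$series, a$series)
  # a different seed gives a different realisation
  c <- run_simulation(traj_sim, sim_config(horizon = 500, cohort_size = 20, seed = 8))
  expect_false(identical(c$series$n_deaths, a$series$n_deaths))
})

test_that("yearly accounting conserves trees", {
  sim <- sim_config(horizon = 500, cohort_size = 15, seed = 4)
  out <- run_simulation(traj_sim, sim)
  s <- out$series
  expect_equal(s$n_living[-1], head(s$n_living - s$n_deaths, -1) + sim$cohort_size)
  expect_true(all(s$basal_area_mm2 >= 0))
  expect_true(all(s$death_rate_pct >= 0 & s$death_rate_pct <= 100))
})

test_that("constant hazard beyond the threshold gives geometric survival", {
  m <- mortality_age(a = 0.08, slope = 0, a0 = 0)
  sim <- sim_config(horizon = 400, cohort_size = 40, max_age = 400,
                    mortality = m, seed = 6)
  out <- run_simulation(traj_sim, sim)
  ages <- out$trees$age_at_death
  ages <- ages[!is.na(ages) & ages < 400]   # drop age-cap deaths
  expect_equal(mean(ages), 1 / 0.08, tolerance = 0.05)
  # chi-square goodness of fit against the geometric pmf
  obs <- tabulate(pmin(ages, 40), 40)
  p <- dgeom(0:38, 0.08)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("stimulation under size-dependent mortality shortens large trees' lives", {
  sim <- sim_config(horizon = 600, cohort_size = 40, seed = 9)
  base <- run_simulation(traj_sim, sim)
  stim <- run_simulation(traj_sim, sim, stimulus_config())
  post <- 400:600
  big_b <- mean(base$series$q75_age_death[post], na.rm = TRUE)
  big_s <- mean(stim$series$q75_age_death[post], na.rm = TRUE)
  expect_lt(big_s, big_b)
  # under age-dependent mortality the death-age distribution is untouched
  sima <- sim_config(horizon = 600, cohort_size = 40,
                     mortality = mortality_age(), seed = 9)
  basea <- run_simulation(traj_sim, sima)
  stima <- run_simulation(traj_sim, sima, stimulus_config())
  expect_equal(stima$trees$age_at_death, basea$trees$age_at_death)
})

test_that("scenario comparison is exactly zero for identical runs", {
  sim <- sim_config(horizon = 500, cohort_size = 15, seed = 4)
  out <- run_simulation(traj_sim, sim)
  cmp <- compare_scenarios(out, out, t0 = 300)
  expect_true(all(abs(cmp$series$growth_change_pct) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(cmp$series$basal_area_change_pct) < 1e-12, na.rm = TRUE))
  expect_equal(cmp$summary$peak_basal_area_gain_pct, 0)
  expect_true(is.na(cmp$summary$death_rate_lag_yr))
})

test_that("sampling the simulated stand needs enough living trees", {
  sim <- sim_config(horizon = 500, cohort_size = 5, seed = 4)
  out <- run_simulation(traj_sim, sim)
  expect_error(simulated_tradeoff(out, traj_sim, 500, min_n = 1e6), "alive")
  fit <- simulated_tradeoff(out, traj_sim, 500, min_n = 100, n_boot = 0)
  expect_s3_class(fit, "tradeoff_fit")
})
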