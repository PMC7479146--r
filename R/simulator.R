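#' Extend ring-width trajectories to a common maximum age
#'
#' The cohort simulator needs every trajectory to span the whole lifespan a
#' tree could reach. Short series are extended with the mean growth of the
#' \code{n_donors} oldest trees of similar early growth: all trees are
#' grouped into \code{n_early_classes} equal-width classes of mean early ring
#' width; beyond a tree's own record, its appended width at age A is the mean
#' width at A over its class's donors still that old (donors drop out
#' age-by-age; once all are exhausted the last available mean is held).
#'
#' @param rings long-form ring data frame (trees with fewer than 10 rings are
#'   dropped).
#' @param n_early_classes number of equal-width early growth classes,
#'   default 6.
#' @param n_donors donors (oldest trees) per class, default 10.
#' @param target_age age (years) to which every trajectory is extended,
#'   default 500.
#' @return list of class \code{trajectory_set}: \code{widths} (matrix, one
#'   row per tree, \code{target_age} columns, mm) and \code{meta} (tree_id,
#'   rw_early, orig_age, class).
#' @export
extend_trajectories <- function(rings, n_early_classes = 6L, n_donors = 10L,
                                target_age = 500L) {
  o <- rings[order(rings$tree_id, rings$age), ]
  sp <- split(o$rw_mm, o$tree_id)
  sp <- sp[vapply(sp, length, integer(1)) >= 10L]
  if (length(sp) == 0L) stop("no trees with at least 10 rings")
  rw_early <- vapply(sp, function(w) mean(w[1:10]), numeric(1))
  ages <- vapply(sp, length, integer(1))

  rng <- range(rw_early)
  if (diff(rng) == 0) {
    cls <- rep(1L, length(sp))
  } else {
    br <- seq(rng[1], rng[2], length.out = n_early_classes + 1L)
    cls <- as.integer(cut(rw_early, br, include.lowest = TRUE))
  }

  donor_mean <- function(members) {
    donors <- members[order(-ages[members])][seq_len(min(n_donors, length(members)))]
    max_age <- max(ages[donors])
    m <- numeric(max_age)
    for (a in seq_len(max_age)) {
      w <- vapply(donors[ages[donors] >= a], function(i) sp[[i]][a], numeric(1))
      m[a] <- mean(w)
    }
    m
  }
  class_means <- lapply(seq_len(max(cls)), function(k) {
    members <- which(cls == k)
    if (length(members) == 0L) return(NULL)
    donor_mean(members)
  })
  global_mean <- donor_mean(seq_along(sp))

  widths <- matrix(0, nrow = length(sp), ncol = target_age)
  for (i in seq_along(sp)) {
    own <- sp[[i]][seq_len(min(ages[i], target_age))]
    widths[i, seq_along(own)] <- own
    if (ages[i] < target_age) {
      m <- class_means[[cls[i]]]
      if (is.null(m)) {
        warning(sprintf("empty early growth class %d: falling back to global donor pool", cls[i]))
        m <- global_mean
      }
      need <- (ages[i] + 1L):target_age
      idx <- pmin(need, length(m))
      widths[i, need] <- m[idx]
    }
  }
  structure(list(widths = widths,
                 meta = data.frame(tree_id = names(sp), rw_early = unname(rw_early),
                                   orig_age = unname(ages), class = cls,
                                   stringsAsFactors = FALSE)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d trees extended to age %d\n",
              nrow(x$widths), ncol(x$widths)))
  invisible(x)
}

#' Growth stimulus configuration
#'
#' A warming-driven multiplicative ring-width boost
#' \eqn{RW_{stim}(t) = RW(t)\, e^{\lambda(A)\,\delta T(t)}} applied from
#' simulation year \code{t0}; the temperature anomaly ramps linearly at
#' \code{warming_rate} for \code{tau} years and is constant afterwards.
#'
#' @param t0 onset year of the stimulus, default 300.
#' @param tau ramp duration (years), default 50.
#' @param warming_rate warming rate (degrees C per year), default 0.0221.
#' @param lambda_coefs age-sensitivity coefficients, default
#'   [lambda_defaults()].
#' @return list of class \code{stimulus_config}.
#' @export
stimulus_config <- function(t0 = 300L, tau = 50L, warming_rate = 0.0221,
                            lambda_coefs = lambda_defaults()) {
  stop_field(tau <= 0, "tau", "must be > 0")
  stop_field(t0 < 0, "t0", "must be >= 0")
  if (warming_rate < 0) message("negative warming rate: simulating cooling")
  structure(list(t0 = as.integer(t0), tau = as.integer(tau),
                 warming_rate = warming_rate, lambda_coefs = lambda_coefs),
            class = "stimulus_config")
}

#' Temperature anomaly of a stimulus at a simulation year
#'
#' @param stim a [stimulus_config()].
#' @param t simulation year(s).
#' @return anomaly in degrees C: 0 before \code{t0}, a linear ramp for
#'   \code{tau} years, constant thereafter.
#' @export
delta_t <- function(stim, t) {
  el <- t - stim$t0
  ifelse(el < 0, 0, stim$warming_rate * pmin(el, stim$tau))
}

#' Cohort simulation configuration
#'
#' @param horizon simulated years, default 600.
#' @param cohort_size trees seeded per year; default 125 (desk scale; the
#'   full-scale run uses 1250).
#' @param max_age maximum trajectory age (years): trees reaching it die
#'   deterministically; default 500.
#' @param mortality a \code{mortality_model}, default [mortality_diameter()].
#' @param growth_multiplier multiplies the whole width series (2 emulates a
#'   species growing twice as fast); applied before any stimulus.
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(horizon = 600L, cohort_size = 125L, max_age = 500L,
                       mortality = mortality_diameter(), growth_multiplier = 1,
                       seed = 1L) {
  stop_field(cohort_size < 1, "cohort_size", "must be >= 1")
  stop_field(horizon < max_age, "horizon", "must be >= max_age")
  stopifnot(inherits(mortality, "mortality_model"))
  structure(list(horizon = as.integer(horizon), cohort_size = as.integer(cohort_size),
                 max_age = as.integer(max_age), mortality = mortality,
                 growth_multiplier = growth_multiplier, seed = as.integer(seed)),
            class = "sim_config")
}

#' Run the annually seeded stochastic cohort simulation
#'
#' Each year a cohort of \code{cohort_size} trees is seeded, each a
#' trajectory drawn with replacement from the trajectory set. Every living
#' tree then (i) grows its trajectory's next ring, multiplied - when a
#' stimulus is active - by \eqn{e^{\lambda(A)\,\delta T(t)}} with A the
#' tree's age entering the year, (ii) updates its diameter (twice the
#' cumulative realised ring widths, so stimulated growth feeds back into the
#' diameter the hazard sees), and (iii) faces an annual death lottery with
#' probability equal to the hazard evaluated after that year's growth.
#'
#' The lottery draws one uniform per tree at seeding and kills the tree in
#' the first year its cumulative survival probability falls below it; this is
#' distributionally identical to an independent Bernoulli per tree-year and
#' couples paired runs tightly: with the same seed, cohort compositions and
#' death quantiles are shared, so a run without stimulus is bit-identical to
#' its baseline and differences between scenarios are driven by the stimulus
#' alone. Trees reaching \code{max_age} die deterministically.
#'
#' @param traj a [extend_trajectories()] trajectory set.
#' @param sim a [sim_config()].
#' @param stim a [stimulus_config()], or \code{NULL} for a baseline run.
#' @return object of class \code{sim_output}: \code{series} (per-year data
#'   frame: year, n_living, mean_rw (mm), death_rate_pct, q75_age_death (yr),
#'   basal_area_mm2, n_deaths), \code{trees} (per-tree traj index, birth
#'   year, death year, age at death) and the configurations.
#' @export
run_simulation <- function(traj, sim = sim_config(), stim = NULL) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(sim, "sim_config"))
  W <- traj$widths * sim$growth_multiplier
  ntraj <- nrow(W)
  if (ncol(W) < sim$max_age) stop("trajectories shorter than max_age: extend them first")

  set.seed(sim$seed)
  total <- sim$horizon * sim$cohort_size
  traj_id <- sample.int(ntraj, total, replace = TRUE)
  u <- runif(total)
  birth <- rep(seq_len(sim$horizon), each = sim$cohort_size)

  death_year <- rep(NA_integer_, total)
  age_at_death <- rep(NA_integer_, total)
  cumd <- numeric(total)
  surv <- rep(1, total)

  years <- seq_len(sim$horizon)
  n_living <- integer(sim$horizon); n_deaths <- integer(sim$horizon)
  mean_rw <- numeric(sim$horizon); death_rate <- numeric(sim$horizon)
  q75_death <- rep(NA_real_, sim$horizon); basal <- numeric(sim$horizon)

  alive <- integer(0)
  for (t in years) {
    alive <- c(alive, which(birth == t))
    age <- t - birth[alive] + 1L
    ring <- W[cbind(traj_id[alive], age)]
    if (!is.null(stim)) {
      dt <- delta_t(stim, t)
      if (dt != 0) ring <- ring * exp(lambda_age(age - 1L, stim$lambda_coefs) * dt)
    }
    cumd[alive] <- cumd[alive] + 2 * ring
    h <- hazard(sim$mortality,
                if (sim$mortality$kind == "diameter") cumd[alive] else age)
    h[age >= sim$max_age] <- 1
    surv[alive] <- surv[alive] * (1 - h)
    die <- u[alive] > surv[alive]

    n_living[t] <- length(alive)
    n_deaths[t] <- sum(die)
    mean_rw[t] <- mean(ring)
    death_rate[t] <- 100 * n_deaths[t] / n_living[t]
    if (any(die)) q75_death[t] <- quantile(age[die], 0.75, type = 7)
    basal[t] <- sum(pi * (cumd[alive][!die] / 2)^2)

    if (any(die)) {
      dead <- alive[die]
      death_year[dead] <- t
      age_at_death[dead] <- age[die]
      alive <- alive[!die]
    }
  }

  structure(list(
    series = data.frame(year = years, n_living = n_living, mean_rw = mean_rw,
                        death_rate_pct = death_rate, q75_age_death = q75_death,
                        basal_area_mm2 = basal, n_deaths = n_deaths),
    trees = data.frame(traj = traj_id, birth_year = birth,
                       death_year = death_year, age_at_death = age_at_death),
    sim = sim, stim = stim),
    class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("Cohort simulation: %d years, %d trees/yr, %s mortality%s\n",
              x$sim$horizon, x$sim$cohort_size, x$sim$mortality$kind,
              if (is.null(x$stim)) "" else sprintf(", stimulus from year %d", x$stim$t0)))
  cat(sprintf("  final living trees: %d; final basal area: %.3g mm^2\n",
              tail(x$series$n_living, 1) - tail(x$series$n_deaths, 1),
              tail(x$series$basal_area_mm2, 1)))
  invisible(x)
}

#' Trade-off fit on the simulated population at a sampling year
#'
#' Emulates coring the simulated stand in a given year: trees alive at the
#' end of that year with at least 10 rings contribute their age and realised
#' mean early ring width (including any stimulus active during their first
#' ten years), and the exponential quantile trade-off is fitted to them.
#'
#' @param output a [run_simulation()] result.
#' @param traj the trajectory set the simulation used.
#' @param sampling_year year at which the stand is sampled.
#' @param min_n minimum trees required, default 150.
#' @param max_n cap on trees used (subsampled, seeded), to bound bootstrap
#'   cost; default 2000.
#' @param q,n_boot,seed passed to [fit_quantile_exponential()].
#' @return a \code{tradeoff_fit}.
#' @export
simulated_tradeoff <- function(output, traj, sampling_year, min_n = 150L,
                               max_n = 2000L, q = 0.95, n_boot = 1000L, seed = 1L) {
  tr <- output$trees
  alive <- which(tr$birth_year <= sampling_year &
                   (is.na(tr$death_year) | tr$death_year > sampling_year))
  age <- sampling_year - tr$birth_year[alive] + 1L
  keep <- age >= 10L
  alive <- alive[keep]; age <- age[keep]
  if (length(alive) < min_n) {
    stop(sprintf("only %d trees alive with >= 10 rings at year %d (need %d)",
                 length(alive), sampling_year, min_n))
  }
  set.seed(seed)
  if (length(alive) > max_n) {
    pick <- sample.int(length(alive), max_n)
    alive <- alive[pick]; age <- age[pick]
  }
  W <- traj$widths * output$sim$growth_multiplier
  early <- W[tr$traj[alive], 1:10, drop = FALSE]
  if (!is.null(output$stim)) {
    yrs <- outer(tr$birth_year[alive], 0:9, `+`)      # calendar year of each early ring
    mult <- exp(lambda_age(matrix(0:9, nrow = length(alive), ncol = 10, byrow = TRUE),
                           output$stim$lambda_coefs) * delta_t(output$stim, yrs))
    early <- early * mult
  }
  fit_quantile_exponential(data.frame(rw_early = rowMeans(early), age = age),
                           q = q, n_boot = n_boot, seed = seed)
}

#' Compare a stimulated run against its paired baseline
#'
#' Per-year percent change in stem death rate and standing basal area (and
#' raw growth change), computed on 10-year centred moving averages, plus
#' summary diagnostics of the transient-carbon-sink behaviour.
#'
#' @param baseline,treatment paired [run_simulation()] outputs (same horizon
#'   and seed).
#' @param t0 stimulus onset year, default taken from the treatment stimulus.
#' @param stim_end end of the growth ramp, default \code{t0 + tau}.
#' @param smooth_window moving-average window (years), default 10.
#' @param peak_window years over which the peak basal-area gain is sought,
#'   default \code{c(t0, t0 + 100)}.
#' @return list of class \code{scenario_comparison}: \code{series} (year,
#'   growth_change_pct, death_rate_change_pct, basal_area_change_pct,
#'   lifespan_reduction_yr - all smoothed except noted) and \code{summary}
#'   with elements \code{growth_change_at_ramp_end_pct} (raw, at
#'   \code{stim_end}), \code{peak_basal_area_gain_pct},
#'   \code{max_lifespan_reduction_yr} (largest post-ramp drop in the
#'   75th-percentile age at death), \code{death_rate_lag_yr} (years after
#'   \code{t0} until the smoothed death-rate change exceeds twice its
#'   pre-stimulus sd) and \code{final_basal_area_change_pct} (mean over the
#'   last decade).
#' @export
compare_scenarios <- function(baseline, treatment, t0 = NULL, stim_end = NULL,
                              smooth_window = 10L, peak_window = NULL) {
  sb <- baseline$series; st <- treatment$series
  if (nrow(sb) != nrow(st)) stop("runs have different horizons")
  t0 <- t0 %||% (if (!is.null(treatment$stim)) treatment$stim$t0 else 300L)
  stim_end <- stim_end %||% (if (!is.null(treatment$stim)) t0 + treatment$stim$tau else t0 + 50L)
  peak_window <- peak_window %||% c(t0, min(t0 + 100L, nrow(sb)))

  pct <- function(b, t) ifelse(b == 0, NA_real_, 100 * (t - b) / b)
  sm <- function(x) moving_average(x, smooth_window)

  growth_change <- pct(sm(sb$mean_rw), sm(st$mean_rw))
  dr_change <- pct(sm(sb$death_rate_pct), sm(st$death_rate_pct))
  ba_change <- pct(sm(sb$basal_area_mm2), sm(st$basal_area_mm2))
  life_red <- sm(sb$q75_age_death) - sm(st$q75_age_death)

  yrs <- sb$year
  in_peak <- yrs >= peak_window[1] & yrs <= peak_window[2]
  post <- yrs > stim_end

  # Detection threshold for the mortality response. Paired seeding makes the
  # pre-onset treatment-minus-baseline change identically zero, so the noise
  # floor is taken from the baseline's own pre-onset variability: the sd of
  # the smoothed baseline death rate, expressed in percent of its mean.
  pre <- yrs >= t0 - 100L & yrs < t0   # stationary century before onset
  base_dr <- sm(sb$death_rate_pct)
  pre_sd <- 100 * sd(base_dr[pre], na.rm = TRUE) / mean(base_dr[pre], na.rm = TRUE)
  over <- which(yrs > t0 & !is.na(dr_change) & dr_change > 2 * pre_sd)
  lag <- if (length(over)) yrs[over[1]] - t0 else NA_real_

  last_dec <- yrs > max(yrs) - 10
  summary <- list(
    growth_change_at_ramp_end_pct = 100 * (st$mean_rw[yrs == stim_end] /
                                             sb$mean_rw[yrs == stim_end] - 1),
    peak_basal_area_gain_pct = max(ba_change[in_peak], na.rm = TRUE),
    max_lifespan_reduction_yr = max(life_red[post], na.rm = TRUE),
    death_rate_lag_yr = lag,
    final_basal_area_change_pct = mean(ba_change[last_dec], na.rm = TRUE))

  structure(list(
    series = data.frame(year = yrs, growth_change_pct = growth_change,
                        death_rate_change_pct = dr_change,
                        basal_area_change_pct = ba_change,
                        lifespan_reduction_yr = life_red),
    summary = summary, t0 = t0, stim_end = stim_end),
    class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  s <- x$summary
  cat("Scenario comparison (treatment vs baseline)\n")
  cat(sprintf("  growth change at end of ramp (yr %d): %+.1f%%\n", x$stim_end,
              s$growth_change_at_ramp_end_pct))
  cat(sprintf("  peak basal-area gain: %+.1f%%\n", s$peak_basal_area_gain_pct))
  cat(sprintf("  max post-ramp lifespan reduction (q75 age at death): %.1f yr\n",
              s$max_lifespan_reduction_yr))
  cat(sprintf("  death-rate rise lag after onset: %s yr\n",
              ifelse(is.na(s$death_rate_lag_yr), "none detected", s$death_rate_lag_yr)))
  cat(sprintf("  final basal-area change (last decade): %+.1f%%\n",
              s$final_basal_area_change_pct))
  invisible(x)
}
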