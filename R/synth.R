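#' Configuration for the synthetic tree-ring population generator
#'
#' The generator emulates the statistical structure of boreal conifer
#' (black-spruce-like) ring-width data: each tree follows a saturating
#' diameter growth curve \eqn{D(A) = D_{max} (1 - e^{-rA})} whose asymptote
#' \code{Dmax} (a species/site trait, ~300 mm) is drawn independently of the
#' growth speed \code{r}, so fast and slow growers attain approximately the
#' same maximum size but at different ages. Ring widths are half the annual
#' diameter increments times multiplicative lognormal AR(1) noise (growth is
#' strongly autocorrelated in time and widths stay positive). Site mean
#' annual temperature modulates growth speed multiplicatively.
#'
#' Default rationale: \code{max_diameter_mean = 300} mm matches the observed
#' size plateau; \code{growth_rate_meanlog = log(0.0049)} puts the median
#' tree at the 91 mm sampling threshold near age 74; \code{max_diameter_sd}
#' and \code{growth_rate_sdlog} are set so that between-tree variation in
#' early growth is dominated by growth speed, not by the size trait.
#'
#' @param n_trees number of trees.
#' @param n_sites number of sites.
#' @param max_diameter_mean,max_diameter_sd mean and sd (mm) of the per-tree
#'   maximum-diameter trait (Normal, truncated > 0).
#' @param growth_rate_meanlog,growth_rate_sdlog lognormal parameters of the
#'   per-tree growth speed r (1/yr).
#' @param ar1_coef AR(1) coefficient of the log ring-width noise, in \[0, 1).
#' @param noise_sd stationary standard deviation of the log ring-width noise.
#' @param temp_range range (degrees C) of site mean annual temperature.
#' @param temp_growth_slope multiplicative effect on r per degree C above the
#'   mid-range temperature.
#' @param max_age cap (years) on the observation age of a tree.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(n_trees = 2000L, n_sites = 40L,
                         max_diameter_mean = 300, max_diameter_sd = 15,
                         growth_rate_meanlog = log(0.0049), growth_rate_sdlog = 0.5,
                         ar1_coef = 0.7, noise_sd = 0.3,
                         temp_range = c(-2, 4), temp_growth_slope = 0.1,
                         max_age = 500L, seed = 1L) {
  stop_field(n_trees < 1, "n_trees", "must be >= 1")
  stop_field(n_sites < 1, "n_sites", "must be >= 1")
  stop_field(max_diameter_mean <= 0, "max_diameter_mean", "must be > 0")
  stop_field(max_diameter_sd < 0, "max_diameter_sd", "must be >= 0")
  stop_field(growth_rate_sdlog < 0, "growth_rate_sdlog", "must be >= 0")
  stop_field(ar1_coef < 0 || ar1_coef >= 1, "ar1_coef", "must be in [0, 1)")
  stop_field(noise_sd < 0, "noise_sd", "must be >= 0")
  stop_field(length(temp_range) != 2 || diff(temp_range) < 0, "temp_range",
             "must be an increasing interval")
  stop_field(max_age < 10, "max_age", "must be >= 10")
  structure(list(n_trees = as.integer(n_trees), n_sites = as.integer(n_sites),
                 max_diameter_mean = max_diameter_mean, max_diameter_sd = max_diameter_sd,
                 growth_rate_meanlog = growth_rate_meanlog,
                 growth_rate_sdlog = growth_rate_sdlog,
                 ar1_coef = ar1_coef, noise_sd = noise_sd,
                 temp_range = temp_range, temp_growth_slope = temp_growth_slope,
                 max_age = as.integer(max_age), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic tree-ring population
#'
#' Draws sites and trees per [synth_config()], producing long-form ring-width
#' series plus site metadata. Each tree's deterministic diameter trajectory is
#' \eqn{D(A) = D_{max}(1 - e^{-rA})}; its ring width at cambial age A is
#' \eqn{(D(A) - D(A-1))/2} times \eqn{e^{\epsilon_A}} with
#' \eqn{\epsilon} a stationary AR(1) process. Growth speed is multiplied by
#' \code{exp(temp_growth_slope * (site MAT - mid-range MAT))}. Each tree is
#' observed up to an age drawn uniformly between 10 and the age at which it
#' reaches 99\% of its maximum diameter (capped at \code{max_age}), giving
#' uneven site age structures by construction.
#'
#' @param config a [synth_config()].
#' @return a list of class \code{ring_population} with elements
#'   \code{rings} (data frame: tree_id, site_id, species, age, rw_mm, status,
#'   last_year), \code{sites} (data frame: site_id, lat, lon, mat_c, map_mm,
#'   crown_cover_class, soil_class) and \code{truth} (per-tree generating
#'   parameters: r, dmax, mat, age_obs — for diagnostics only).
#' @export
generate_population <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cf <- config

  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(cf$n_sites)),
    lat = runif(cf$n_sites, 48, 54),
    lon = runif(cf$n_sites, -79, -62),
    mat_c = runif(cf$n_sites, cf$temp_range[1], cf$temp_range[2]),
    map_mm = runif(cf$n_sites, 600, 1100),
    crown_cover_class = sample(1:4, cf$n_sites, replace = TRUE),
    soil_class = sample(c("till", "organic", "sand", "clay"), cf$n_sites, replace = TRUE),
    stringsAsFactors = FALSE)

  n <- cf$n_trees
  site_idx <- sample.int(cf$n_sites, n, replace = TRUE)
  mat <- sites$mat_c[site_idx]
  mat_mid <- mean(cf$temp_range)

  dmax <- rnorm(n, cf$max_diameter_mean, cf$max_diameter_sd)
  while (any(dmax <= 0)) dmax[dmax <= 0] <- rnorm(sum(dmax <= 0), cf$max_diameter_mean, cf$max_diameter_sd)
  r <- exp(rnorm(n, cf$growth_rate_meanlog, cf$growth_rate_sdlog)) *
    exp(cf$temp_growth_slope * (mat - mat_mid))

  age99 <- pmin(cf$max_age, ceiling(log(100) / r))   # age at 0.99 * Dmax
  age_obs <- pmax(10L, floor(runif(n, 10, pmax(10, age99) + 1)))

  sd_inn <- cf$noise_sd * sqrt(1 - cf$ar1_coef^2)
  widths <- vector("list", n)
  for (i in seq_len(n)) {
    a <- seq_len(age_obs[i])
    base <- dmax[i] * (exp(-r[i] * (a - 1)) - exp(-r[i] * a)) / 2
    if (cf$noise_sd > 0) {
      z <- rnorm(age_obs[i], 0, sd_inn)
      e <- as.numeric(stats::filter(z, cf$ar1_coef, method = "recursive",
                                    init = rnorm(1, 0, cf$noise_sd)))
      widths[[i]] <- base * exp(e)
    } else {
      widths[[i]] <- base
    }
  }

  tree_id <- sprintf("T%05d", seq_len(n))
  rings <- data.frame(
    tree_id = rep(tree_id, age_obs),
    site_id = rep(sites$site_id[site_idx], age_obs),
    species = "PISY01",  # single synthetic black-spruce-like species
    age = unlist(lapply(age_obs, seq_len)),
    rw_mm = unlist(widths),
    status = "alive",
    last_year = NA_integer_,
    stringsAsFactors = FALSE)

  truth <- data.frame(tree_id = tree_id, site_id = sites$site_id[site_idx],
                      r = r, dmax = dmax, mat = mat, age_obs = age_obs,
                      stringsAsFactors = FALSE)

  structure(list(rings = rings, sites = sites, truth = truth),
            class = "ring_population")
}

#' @export
print.ring_population <- function(x, ...) {
  cat(sprintf("Synthetic ring population: %d trees, %d sites, %d rings\n",
              length(unique(x$rings$tree_id)), nrow(x$sites), nrow(x$rings)))
  invisible(x)
}

#' Configuration for a sample with a known growth-lifespan trade-off
#'
#' @param a_true intercept (log-years) of the generating quantile line.
#' @param b_true decay constant (per mm/yr of early growth).
#' @param quantile quantile at which the line is the exact conditional
#'   quantile of age (default 0.95).
#' @param n sample size.
#' @param rw_range interval (mm/yr) from which early growth is drawn uniformly.
#' @param seed integer seed.
#' @return a list of class \code{known_tradeoff_config}.
#' @export
known_tradeoff_config <- function(a_true = log(400), b_true = -0.5, quantile = 0.95,
                                  n = 1000L, rw_range = c(0.2, 3.2), seed = 1L) {
  stop_field(quantile <= 0 || quantile >= 1, "quantile", "must be in (0, 1)")
  stop_field(!is.finite(b_true), "b_true", "must be finite")
  stop_field(n < 1, "n", "must be >= 1")
  structure(list(a_true = a_true, b_true = b_true, quantile = quantile,
                 n = as.integer(n), rw_range = rw_range, seed = as.integer(seed)),
            class = "known_tradeoff_config")
}

#' Generate per-tree summaries with an exactly known trade-off quantile line
#'
#' Early growth RW is uniform on \code{rw_range}. Ages are constructed so
#' that the conditional q-quantile of log(age) given RW is exactly
#' \code{a_true + b_true * RW}: with U ~ Uniform(0,1),
#' \deqn{\log A = a + b\,RW + \log U - \log q.}
#' Proof: \eqn{\log U - \log q} has CDF \eqn{P(\log U \le z + \log q) = q e^z}
#' for \eqn{z \le -\log q}, so its q-quantile is exactly 0; adding the
#' constant (given RW) line term shifts the conditional quantile to the line.
#' Ages are continuous, hence tie-free.
#'
#' @param config a [known_tradeoff_config()].
#' @return data frame of tree summaries (tree_id, site_id, species, rw_early,
#'   age, max_diameter = NA, status) suitable for [fit_quantile_exponential()].
#' @export
generate_known_tradeoff_sample <- function(config = known_tradeoff_config()) {
  stopifnot(inherits(config, "known_tradeoff_config"))
  if (config$n < 20L) warning("n < 20: trade-off fits on this sample will be unstable")
  set.seed(config$seed)
  rw <- runif(config$n, config$rw_range[1], config$rw_range[2])
  u <- runif(config$n)
  age <- exp(config$a_true + config$b_true * rw + log(u) - log(config$quantile))
  data.frame(tree_id = sprintf("K%05d", seq_len(config$n)),
             site_id = "KT01", species = "SYNKT1",
             rw_early = rw, age = age, max_diameter = NA_real_,
             status = "alive", stringsAsFactors = FALSE)
}

#' Simulate a stand to stationarity and tally its size distribution
#'
#' Runs an annual recruitment / deterministic growth / stochastic death
#' population model to a stationary state and tallies, per diameter bin, the
#' average standing count N(D), the trees growing into the bin per year I(D)
#' and the trees growing out of it per year L(D). At stationarity
#' \code{I - L} equals deaths per bin per year, so
#' [estimate_mortality_from_distribution()] recovers the hazard.
#'
#' @param mortality a \code{mortality_model}.
#' @param config a [synth_config()] supplying the growth parameter
#'   distributions (temperature modulation is not used here).
#' @param recruits_per_yr new trees per year.
#' @param years total simulated years (burn-in plus tally window).
#' @param tally_years length of the final tally window.
#' @param bin_mm diameter bin width (default 20 mm = 2 cm).
#' @param check_stationary error if the total count drifts more than 1\% per
#'   decade at the end of the run (set \code{FALSE} e.g. for a zero-mortality
#'   population, which grows without bound).
#' @return a data frame of class \code{size_distribution} with columns
#'   \code{bin_low}, \code{bin_high}, \code{N}, \code{I}, \code{L}; attribute
#'   \code{deaths} holds a per-death record (age, diameter, age at crossing
#'   the model threshold) and attribute \code{tally_years} the window length.
#' @export
generate_stand_distribution <- function(mortality, config = synth_config(),
                                        recruits_per_yr = 100L, years = 500L,
                                        tally_years = 100L, bin_mm = 20,
                                        check_stationary = TRUE) {
  stopifnot(inherits(mortality, "mortality_model"), inherits(config, "synth_config"))
  stop_field(tally_years >= years, "tally_years", "must be shorter than 'years'")
  set.seed(config$seed)
  cf <- config

  draw_traits <- function(m) {
    dmax <- rnorm(m, cf$max_diameter_mean, cf$max_diameter_sd)
    while (any(dmax <= 0)) dmax[dmax <= 0] <- rnorm(sum(dmax <= 0), cf$max_diameter_mean, cf$max_diameter_sd)
    list(r = exp(rnorm(m, cf$growth_rate_meanlog, cf$growth_rate_sdlog)), dmax = dmax)
  }

  r <- numeric(0); dmax <- numeric(0); age <- integer(0); D <- numeric(0)
  max_bin <- ceiling((cf$max_diameter_mean + 6 * cf$max_diameter_sd) / bin_mm)
  I_tot <- numeric(max_bin + 1); L_tot <- numeric(max_bin + 1); N_tot <- numeric(max_bin + 1)
  deaths <- list()
  totals <- integer(years)
  tally_from <- years - tally_years + 1L

  for (t in seq_len(years)) {
    tr <- draw_traits(recruits_per_yr)
    r <- c(r, tr$r); dmax <- c(dmax, tr$dmax)
    age <- c(age, integer(recruits_per_yr)); D <- c(D, numeric(recruits_per_yr))

    age <- age + 1L
    D_new <- dmax * (1 - exp(-r * age))
    if (t >= tally_from) {
      b0 <- pmin(floor(D / bin_mm), max_bin)
      b1 <- pmin(floor(D_new / bin_mm), max_bin)
      cross <- which(b1 > b0)
      for (i in cross) {
        ent <- (b0[i] + 1L):b1[i]
        I_tot[ent + 1L] <- I_tot[ent + 1L] + 1
        lft <- b0[i]:(b1[i] - 1L)
        L_tot[lft + 1L] <- L_tot[lft + 1L] + 1
      }
      N_tot <- N_tot + tabulate(pmin(floor(D_new / bin_mm), max_bin) + 1L, max_bin + 1)
    }
    D <- D_new

    h <- hazard(mortality, if (mortality$kind == "diameter") D else age)
    die <- runif(length(D)) < h
    if (any(die)) {
      thr_age <- if (mortality$kind == "diameter") {
        ifelse(dmax[die] > mortality$d0,
               floor(-log(1 - mortality$d0 / dmax[die]) / r[die]) + 1, NA_real_)
      } else rep(mortality$a0, sum(die))
      deaths[[length(deaths) + 1L]] <-
        data.frame(age = age[die], diameter = D[die], age_at_threshold = thr_age)
      keep <- !die
      r <- r[keep]; dmax <- dmax[keep]; age <- age[keep]; D <- D[keep]
    }
    totals[t] <- length(D)
  }

  if (check_stationary) {
    m1 <- mean(totals[(years - 39):(years - 20)])
    m2 <- mean(totals[(years - 19):years])
    drift <- abs(m2 - m1) / m1 / 2 * 100  # % per decade
    if (drift > 1) stop(sprintf("stand not stationary: total count drifting %.2f%% per decade", drift))
  }

  out <- data.frame(bin_low = (seq_len(max_bin + 1) - 1) * bin_mm,
                    bin_high = seq_len(max_bin + 1) * bin_mm,
                    N = N_tot / tally_years,
                    I = I_tot / tally_years,
                    L = L_tot / tally_years)
  out <- out[out$N > 0 | out$I > 0 | out$L > 0, ]
  attr(out, "deaths") <- do.call(rbind, deaths)
  attr(out, "tally_years") <- tally_years
  class(out) <- c("size_distribution", "data.frame")
  out
}
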