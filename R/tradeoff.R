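#' Convert tree summaries to species-relative units
#'
#' Divides each tree's early growth and age by its species' maxima, putting
#' all species on a common (0, 1] scale so decay constants can be compared
#' and averaged across species.
#'
#' @param summaries per-tree summaries.
#' @return the summaries with \code{rw_early} and \code{age} rescaled and
#'   attribute \code{relative = TRUE}; species with a single tree are dropped
#'   with a warning (their maxima are degenerate).
#' @export
normalize_relative <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no trees to normalize")
  n_by_sp <- table(summaries$species)
  singletons <- names(n_by_sp)[n_by_sp < 2]
  if (length(singletons)) {
    warning(sprintf("dropping %d species with a single tree", length(singletons)))
    summaries <- summaries[!(summaries$species %in% singletons), , drop = FALSE]
    if (nrow(summaries) == 0L) stop("no species with at least two trees")
  }
  max_rw <- tapply(summaries$rw_early, summaries$species, max)
  max_a <- tapply(summaries$age, summaries$species, max)
  summaries$rw_early <- as.numeric(summaries$rw_early / max_rw[summaries$species])
  summaries$age <- as.numeric(summaries$age / max_a[summaries$species])
  attr(summaries, "relative") <- TRUE
  summaries
}

#' Mean decay constant across species, weighted by cube-root sample size
#'
#' Species differ enormously in sample size; weighting the per-species decay
#' constants by the cube root of n tempers the dominance of the largest
#' datasets while still crediting better-estimated fits.
#'
#' @param fits list of \code{tradeoff_fit} objects, or a data frame with
#'   columns \code{b} and \code{n}.
#' @return list: \code{mean_b} = sum(n^(1/3) b) / sum(n^(1/3)),
#'   \code{n_negative} = number of species with b < 0, \code{n_species}.
#' @export
weighted_mean_decay <- function(fits) {
  if (inherits(fits, "tradeoff_fit")) fits <- list(fits)
  if (is.data.frame(fits)) {
    b <- fits$b; n <- fits$n
  } else {
    b <- vapply(fits, `[[`, numeric(1), "b")
    n <- vapply(fits, `[[`, numeric(1), "n")
  }
  if (length(b) == 0L) stop("no fits supplied")
  w <- n^(1 / 3)
  list(mean_b = sum(w * b) / sum(w), n_negative = sum(b < 0), n_species = length(b))
}

#' Compare the fitted quantile curve with binned empirical percentiles
#'
#' Sanity check of the exponential quantile fit: within equal-width early
#' growth bins, the empirical q-th percentile age (type-7, linear
#' interpolation) should track \code{exp(a + b * bin centre)}.
#'
#' @param summaries per-tree summaries.
#' @param fit a \code{tradeoff_fit}; refitted from the data if missing.
#' @param n_bins number of equal-width early growth bins.
#' @param min_per_bin bins with fewer trees are flagged as sparse.
#' @return data frame per bin: centre, n, empirical q-percentile age,
#'   predicted age, relative deviation, sparse flag; attribute
#'   \code{max_rel_deviation} over non-sparse bins.
#' @export
binned_quantile_check <- function(summaries, fit = NULL, n_bins = 5L, min_per_bin = 20L) {
  if (is.null(fit)) fit <- fit_quantile_exponential(summaries, n_boot = 0L)
  br <- seq(min(summaries$rw_early), max(summaries$rw_early), length.out = n_bins + 1L)
  bin <- cut(summaries$rw_early, br, include.lowest = TRUE)
  centre <- (head(br, -1) + tail(br, -1)) / 2
  emp <- tapply(summaries$age, bin, quantile, probs = fit$q, type = 7, na.rm = TRUE)
  n <- tapply(summaries$age, bin, length)
  n[is.na(n)] <- 0L
  pred <- exp(fit$a + fit$b * centre)
  out <- data.frame(centre = centre, n = as.integer(n),
                    empirical = as.numeric(emp), predicted = pred,
                    rel_deviation = as.numeric(emp) / pred - 1,
                    sparse = as.integer(n) < min_per_bin)
  attr(out, "max_rel_deviation") <- max(abs(out$rel_deviation[!out$sparse]), na.rm = TRUE)
  out
}

#' Major axis regression
#'
#' Symmetric (errors-in-both-variables) line: the first principal axis of the
#' covariance matrix of (x, y), through the centroid. Used for cross-species
#' growth-lifespan and climate relationships where neither variable is a
#' controlled predictor.
#'
#' @param x,y numeric vectors.
#' @return list of class \code{major_axis_fit}: slope, intercept, n.
#' @export
fit_major_axis <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("major axis regression needs at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance in x or y")
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (v[1L] == 0) stop("major axis is vertical: slope undefined")
  slope <- v[2L] / v[1L]
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x), n = length(x)),
            class = "major_axis_fit")
}

#' @export
print.major_axis_fit <- function(x, ...) {
  cat(sprintf("Major axis fit (n = %d): y = %.4f %+.4f x\n", x$n, x$intercept, x$slope))
  invisible(x)
}

#' Trade-off and climate fits within environmental strata
#'
#' Disentangles a direct growth effect on lifespan from environmental
#' covariance. Within 2-degree-C temperature classes (half-open
#' \code{[T, T+2)}, anchored at the data minimum) the growth-lifespan
#' quantile fit is repeated: a direct trade-off stays negative. Within early
#' growth bands (equal-count quartiles by default) lifespan is instead
#' regressed (same quantile machinery) on site temperature: if temperature
#' acted only through growth, these slopes collapse towards zero. Strata can
#' also be crown cover or soil classes.
#'
#' @param summaries per-tree summaries.
#' @param sites site metadata (joined on \code{site_id}; needs \code{mat_c}
#'   for the temperature-based stratifications).
#' @param strat one of \code{"temperature"}, \code{"growth_band"},
#'   \code{"crown_cover_class"}, \code{"soil_class"}.
#' @param class_width_c temperature class width (degrees C), default 2.
#' @param n_bands number of growth bands, default 4.
#' @param min_n strata with fewer trees are skipped (reported), default 30.
#' @param q,n_boot,seed passed to [fit_quantile_exponential()].
#' @param alpha fits with bootstrap p above this are flagged non-significant.
#' @return data frame with one row per fitted stratum: stratum label, n,
#'   a, b, p_value, significant; attribute \code{skipped} lists strata below
#'   \code{min_n}.
#' @export
stratified_tradeoff <- function(summaries, sites, strat = c("temperature", "growth_band",
                                                            "crown_cover_class", "soil_class"),
                                class_width_c = 2, n_bands = 4L, min_n = 30L,
                                q = 0.95, n_boot = 200L, seed = 1L, alpha = 0.05) {
  strat <- match.arg(strat)
  d <- merge(summaries, sites, by = "site_id")

  if (strat == "temperature") {
    lo <- floor(min(d$mat_c))
    d$stratum <- paste0("[", lo + class_width_c * ((d$mat_c - lo) %/% class_width_c), ",",
                        lo + class_width_c * (1 + (d$mat_c - lo) %/% class_width_c), ")C")
    xvar <- "rw_early"
  } else if (strat == "growth_band") {
    qs <- quantile(d$rw_early, probs = seq(0, 1, length.out = n_bands + 1L), type = 7)
    d$stratum <- as.character(cut(d$rw_early, unique(qs), include.lowest = TRUE))
    xvar <- "mat_c"
  } else {
    d$stratum <- as.character(d[[strat]])
    xvar <- "rw_early"
  }

  sp <- split(d, d$stratum)
  fitted <- lapply(names(sp), function(s) {
    dd <- sp[[s]]
    if (nrow(dd) < min_n) return(NULL)
    fake <- data.frame(rw_early = dd[[xvar]], age = dd$age)
    f <- tryCatch(fit_quantile_exponential(fake, q = q, n_boot = n_boot, seed = seed),
                  error = function(e) NULL, warning = function(w) suppressWarnings(
                    fit_quantile_exponential(fake, q = q, n_boot = n_boot, seed = seed)))
    if (is.null(f)) return(NULL)
    data.frame(stratum = s, n = f$n, a = f$a, b = f$b, p_value = f$p_value,
               significant = !is.na(f$p_value) & f$p_value <= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fitted)
  skipped <- names(sp)[vapply(sp, nrow, integer(1)) < min_n]
  if (is.null(out)) out <- data.frame(stratum = character(0), n = integer(0), a = numeric(0),
                                      b = numeric(0), p_value = numeric(0), significant = logical(0))
  attr(out, "skipped") <- skipped
  attr(out, "x_variable") <- if (strat == "growth_band") "mat_c" else "rw_early"
  out
}

#' Pool nearby sites until each pool reaches a minimum sample size
#'
#' Site-level climate analyses need a minimum number of trees per site; small
#' neighbouring sites are pooled greedily: while any pool is below
#' \code{min_per_site} trees, the smallest pool is merged with its nearest
#' neighbour (great-circle distance between pool centroids).
#'
#' @param summaries per-tree summaries.
#' @param sites site metadata with \code{lat}, \code{lon}, \code{mat_c}.
#' @param min_per_site minimum trees per pooled site, default 30.
#' @return data frame per pooled site: pool_id, member site_ids, n, mean
#'   early growth, maximum age, tree-weighted mean temperature, centroid
#'   lat/lon. If the total falls short of the minimum, everything is pooled
#'   into one site.
#' @export
site_level_aggregate <- function(summaries, sites, min_per_site = 30L) {
  tab <- merge(summaries, sites[, c("site_id", "lat", "lon", "mat_c")], by = "site_id")
  pools <- lapply(unique(tab$site_id), function(s) s)
  pool_stats <- function(members) {
    d <- tab[tab$site_id %in% members, ]
    list(n = nrow(d), lat = mean(d$lat), lon = mean(d$lon),
         rw = mean(d$rw_early), max_age = max(d$age),
         mat = mean(d$mat_c))
  }
  stats <- lapply(pools, pool_stats)

  repeat {
    n <- vapply(stats, `[[`, numeric(1), "n")
    if (length(pools) <= 1L || all(n >= min_per_site)) break
    i <- which.min(n)
    p <- cbind(vapply(stats, `[[`, numeric(1), "lon"), vapply(stats, `[[`, numeric(1), "lat"))
    dist <- geosphere::distHaversine(p[i, , drop = FALSE], p)
    dist[i] <- Inf
    j <- which.min(dist)
    pools[[j]] <- c(pools[[j]], pools[[i]])
    stats[[j]] <- pool_stats(pools[[j]])
    pools[[i]] <- NULL
    stats[[i]] <- NULL
  }

  data.frame(pool_id = sprintf("P%03d", seq_along(pools)),
             members = vapply(pools, paste, character(1), collapse = "+"),
             n = vapply(stats, `[[`, numeric(1), "n"),
             mean_rw_early = vapply(stats, `[[`, numeric(1), "rw"),
             max_age = vapply(stats, `[[`, numeric(1), "max_age"),
             mat_c = vapply(stats, `[[`, numeric(1), "mat"),
             lat = vapply(stats, `[[`, numeric(1), "lat"),
             lon = vapply(stats, `[[`, numeric(1), "lon"),
             stringsAsFactors = FALSE)
}

#' How often does a subsample's maximum age exceed a population percentile?
#'
#' Repeatedly subsamples \code{size} trees without replacement and checks
#' whether the sample maximum exceeds the population's 95th/99th percentile
#' age (type-7, linear interpolation). For tie-free ages and sampling with
#' replacement the closed form is \eqn{1 - q^{size}}; sampling without
#' replacement from a large population is close to it. Quantifies whether a
#' species' sample size suffices to observe near-maximal lifespans.
#'
#' @param ages population ages.
#' @param sizes subsample sizes.
#' @param reps replicates per size, default 500.
#' @param thresholds percentile levels, default c(0.95, 0.99).
#' @param seed integer seed.
#' @return data frame: size, threshold, fraction of replicates whose sample
#'   maximum strictly exceeds the population percentile.
#' @export
resample_max_age <- function(ages, sizes = c(25, 50, 100, 150, 200, 300, 400, 500, 600),
                             reps = 500L, thresholds = c(0.95, 0.99), seed = 1L) {
  if (max(sizes) > length(ages)) stop("subsample size exceeds population size")
  set.seed(seed)
  pct <- quantile(ages, probs = thresholds, type = 7)
  rows <- list()
  for (s in sizes) {
    mx <- vapply(seq_len(reps), function(r) max(sample(ages, s, replace = FALSE)), numeric(1))
    for (k in seq_along(thresholds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        size = s, threshold = thresholds[k],
        fraction = mean(mx > pct[k]))
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity of the decay constant to sample size
#'
#' Refits the trade-off on subsamples of varying size (without replacement)
#' and reports, per size, the mean absolute and mean signed relative error of
#' the decay constant against the full-data fit.
#'
#' @param summaries per-tree summaries.
#' @param sizes subsample sizes.
#' @param reps replicates per size.
#' @param q quantile level.
#' @param seed integer seed.
#' @return data frame: size, mean_abs_rel_err, mean_signed_rel_err, n_failed.
#' @export
sample_size_error_curve <- function(summaries, sizes = c(25, 50, 100, 150, 300, 600),
                                    reps = 100L, q = 0.95, seed = 1L) {
  full <- fit_quantile_exponential(summaries, q = q, n_boot = 0L)
  set.seed(seed)
  n <- nrow(summaries)
  rows <- lapply(sizes, function(s) {
    if (s > n) return(NULL)
    errs <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, s, replace = FALSE)
      b <- tryCatch(suppressWarnings(
        fit_quantile_exponential(summaries[idx, ], q = q, n_boot = 0L)$b),
        error = function(e) NA_real_)
      (b - full$b) / full$b
    }, numeric(1))
    data.frame(size = s, mean_abs_rel_err = mean(abs(errs), na.rm = TRUE),
               mean_signed_rel_err = mean(errs, na.rm = TRUE),
               n_failed = sum(is.na(errs)))
  })
  do.call(rbind, rows)
}

#' Big-tree selection bias experiment
#'
#' Field protocols often core only trees above a minimum diameter (or only
#' the largest trees), under-representing slow-growing young trees and
#' potentially inflating the apparent trade-off. Given full diameter
#' trajectories, this reconstructs an artificial tree-ring sample whose size
#' structure matches a field size-frequency table: for each 2-cm size class
#' the observed number of trees is drawn (with replacement) from the trees
#' that transit the class, each observation being (early growth, age at
#' reaching the class). Fits are compared across scenarios:
#' \code{all} (all size classes), \code{threshold} (only classes at or above
#' \code{min_diameter}, mimicking a minimum coring diameter) and
#' \code{top10pct} (only the largest 10 percent of the artificial sample).
#'
#' @param trajectories long-form ring data frame with full trajectories.
#' @param field_size_frequency data frame with \code{bin_low} (mm) and
#'   \code{count}; defaults to the trajectory set's own final-size
#'   distribution.
#' @param min_diameter minimum coring diameter (mm), default 91.
#' @param scenarios subset of c("all", "threshold", "top10pct").
#' @param bin_mm size class width, default 20 mm (2 cm).
#' @param q,seed fitting quantile and seed.
#' @return list of class \code{bias_experiment}: per-scenario
#'   \code{tradeoff_fit}s, the ratio of each scenario's decay constant to the
#'   \code{all} scenario, and a report of empty size classes.
#' @export
big_tree_bias_experiment <- function(trajectories, field_size_frequency = NULL,
                                     min_diameter = 91, scenarios = c("all", "threshold", "top10pct"),
                                     bin_mm = 20, q = 0.95, seed = 1L) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  o <- trajectories[order(trajectories$tree_id, trajectories$age), ]
  sp <- split(o, o$tree_id)
  # per tree: early growth and age at first reaching each size-class lower edge
  per_tree <- lapply(sp, function(d) {
    if (nrow(d) < 10L) return(NULL)
    D <- 2 * cumsum(d$rw_mm)
    rw_early <- mean(d$rw_mm[1:10])
    max_bin <- floor(max(D) / bin_mm)
    if (max_bin < 1L) return(NULL)
    edges <- seq_len(max_bin) * bin_mm
    age_at <- vapply(edges, function(e) which(D >= e)[1L], numeric(1))
    data.frame(rw_early = rw_early, bin_low = edges, age_at = age_at,
               diameter = edges)
  })
  per_tree <- per_tree[!vapply(per_tree, is.null, logical(1))]
  obs <- do.call(rbind, per_tree)

  if (is.null(field_size_frequency)) {
    final_d <- vapply(sp, function(d) 2 * sum(d$rw_mm), numeric(1))
    tb <- table(floor(final_d / bin_mm) * bin_mm)
    field_size_frequency <- data.frame(bin_low = as.numeric(names(tb)),
                                       count = as.integer(tb))
  }

  set.seed(seed)
  sample_classes <- function(freq) {
    picked <- lapply(seq_len(nrow(freq)), function(i) {
      pool <- obs[obs$bin_low == freq$bin_low[i], , drop = FALSE]
      if (nrow(pool) == 0L || freq$count[i] == 0) return(NULL)
      pool[sample.int(nrow(pool), freq$count[i], replace = TRUE), , drop = FALSE]
    })
    do.call(rbind, picked)
  }

  empty <- field_size_frequency$bin_low[
    !(field_size_frequency$bin_low %in% obs$bin_low) & field_size_frequency$count > 0]

  art_all <- sample_classes(field_size_frequency)
  fits <- list()
  if ("all" %in% scenarios) {
    fits$all <- fit_quantile_exponential(
      data.frame(rw_early = art_all$rw_early, age = art_all$age_at), q = q, n_boot = 0L)
  }
  if ("threshold" %in% scenarios) {
    fr <- field_size_frequency[field_size_frequency$bin_low >= min_diameter - bin_mm / 2, ]
    art <- sample_classes(fr)
    fits$threshold <- fit_quantile_exponential(
      data.frame(rw_early = art$rw_early, age = art$age_at), q = q, n_boot = 0L)
  }
  if ("top10pct" %in% scenarios) {
    cutoff <- quantile(art_all$diameter, 0.9, type = 7)
    art <- art_all[art_all$diameter >= cutoff, ]
    fits$top10pct <- fit_quantile_exponential(
      data.frame(rw_early = art$rw_early, age = art$age_at), q = q, n_boot = 0L)
  }

  ratios <- if (!is.null(fits$all)) {
    vapply(fits, function(f) f$b / fits$all$b, numeric(1))
  } else NULL
  structure(list(fits = fits, b_ratio_vs_all = ratios, empty_classes = empty),
            class = "bias_experiment")
}

#' @export
print.bias_experiment <- function(x, ...) {
  cat("Big-tree sampling bias experiment\n")
  for (s in names(x$fits)) {
    cat(sprintf("  %-10s b = %8.4f (n = %d)\n", s, x$fits[[s]]$b, x$fits[[s]]$n))
  }
  invisible(x)
}
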