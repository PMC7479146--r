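# Small programmatic fixtures shared across test files.

# Long-form ring data frame for one tree.
make_rings <- function(tree_id, widths, site_id = "S001", species = "SP1",
                       status = "alive", last_year = NA_integer_) {
  data.frame(tree_id = tree_id, site_id = site_id, species = species,
             age = seq_along(widths), rw_mm = widths, status = status,
             last_year = last_year, stringsAsFactors = FALSE)
}

# Exhaustive pairwise-line pinball-loss oracle for small-n quantile
# regression: every line through two data points is scored; ties broken by
# the smaller |slope|. Independent of the package's solver.
oracle_qr <- function(x, y, q) {
  n <- length(x)
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    r <- y - a - b * x
    l <- sum(r * (q - (r < 0)))
    if (is.null(best) || l < best$loss ||
        (l == best$loss && abs(b) < abs(best$b))) {
      best <- list(a = a, b = b, loss = l)
    }
  }
  best
}

# Ring population whose widths respond to site temperature with a known
# age-dependent sensitivity (for recovery tests of estimate_lambda).
make_lambda_population <- function(n_trees = 600, n_sites = 20, max_age = 200,
                                   coefs = lambda_defaults(), noise_sd = 0.2,
                                   seed = 1) {
  set.seed(seed)
  sites <- data.frame(site_id = sprintf("L%02d", seq_len(n_sites)),
                      mat_c = seq(0, 8, length.out = n_sites),
                      lat = 50, lon = -70)
  rows <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    s <- sample.int(n_sites, 1)
    a <- seq_len(max_age)
    rw <- 0.5 * exp(lambda_age(a, coefs) * sites$mat_c[s]) *
      exp(rnorm(max_age, 0, noise_sd))
    rows[[i]] <- make_rings(sprintf("T%04d", i), rw, site_id = sites$site_id[s])
  }
  list(rings = do.call(rbind, rows), sites = sites)
}
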