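#' Age-modulated temperature sensitivity of ring width
#'
#' Young trees respond more strongly to warming than old trees. The
#' sensitivity \eqn{\lambda(A)} (per degree C) multiplying the temperature
#' anomaly in the growth stimulus \eqn{RW \cdot e^{\lambda(A)\,\delta T}} is
#' quadratic in age up to a knee and constant beyond it. `lambda_defaults()`
#' returns the published black-spruce calibration:
#' \deqn{\lambda(A) = 1.32\times 10^{-5} A^2 - 2.91\times 10^{-3} A + 0.229
#'   \ (A < 135), \quad 0.07 \ (A \ge 135).}
#'
#' @return list with elements \code{c2}, \code{c1}, \code{c0} (quadratic
#'   coefficients), \code{plateau} (per degree C) and \code{knee} (years).
#' @export
lambda_defaults <- function() {
  list(c2 = 0.0000132, c1 = -0.00291, c0 = 0.229, plateau = 0.07, knee = 135)
}

#' @rdname lambda_defaults
#' @param age tree ages (years).
#' @param coefs coefficient list as from [lambda_defaults()] or the
#'   \code{coefs} element of an [estimate_lambda()] fit.
#' @return for \code{lambda_age}, sensitivities (per degree C).
#' @export
lambda_age <- function(age, coefs = lambda_defaults()) {
  ifelse(age < coefs$knee,
         coefs$c2 * age^2 + coefs$c1 * age + coefs$c0,
         coefs$plateau)
}

#' Estimate the age-modulated temperature sensitivity from ring data
#'
#' Space-for-time substitution: within 10-year age bands, each tree's mean
#' ring width over the band is regressed (log scale) on its site's mean
#' annual temperature; the slope is the band's sensitivity
#' \eqn{\lambda(A_{band})}. A quadratic is then fitted to the band
#' sensitivities below the knee age, and the plateau is the mean sensitivity
#' of the bands at or beyond \code{plateau_from}.
#'
#' @param rings long-form ring data frame.
#' @param sites site metadata with \code{mat_c}; the temperature span across
#'   sites must be at least \code{min_mat_span_c}.
#' @param band_width age band width (years), default 10.
#' @param max_band_age bands run to this age, with one open-ended band above
#'   it; default 150.
#' @param plateau_from ages at or beyond this use the constant plateau,
#'   default 135 (also the quadratic knee).
#' @param min_mat_span_c minimum temperature span, default 3.
#' @return list of class \code{lambda_fit}: \code{bands} (data frame: band
#'   centre, lambda, n trees), \code{coefs} (c2, c1, c0, plateau, knee,
#'   usable with [lambda_age()]) and \code{scale_mm} (the fitted ring width
#'   at the reference temperature, mm/yr).
#' @export
estimate_lambda <- function(rings, sites, band_width = 10L, max_band_age = 150L,
                            plateau_from = 135, min_mat_span_c = 3) {
  d <- merge(rings, sites[, c("site_id", "mat_c")], by = "site_id")
  if (diff(range(d$mat_c)) < min_mat_span_c) {
    stop(sprintf("temperature span across sites below %g degrees C: cannot estimate sensitivities",
                 min_mat_span_c))
  }
  d$band <- pmin(d$age %/% band_width, max_band_age %/% band_width) # last band open-ended
  # per tree x band mean ring width
  key <- paste(d$tree_id, d$band)
  agg <- data.frame(band = tapply(d$band, key, `[`, 1L),
                    mat = tapply(d$mat_c, key, `[`, 1L),
                    rw = tapply(d$rw_mm, key, mean))
  agg <- agg[agg$rw > 0, ]

  bands <- sort(unique(agg$band))
  rows <- lapply(bands, function(bd) {
    a <- agg[agg$band == bd, ]
    if (nrow(a) < 10L || diff(range(a$mat)) < min_mat_span_c) return(NULL)
    fit <- stats::lm(log(rw) ~ mat, data = a)
    data.frame(centre = bd * band_width + band_width / 2,
               lambda = coef(fit)[[2L]], intercept = coef(fit)[[1L]], n = nrow(a))
  })
  bt <- do.call(rbind, rows)
  if (is.null(bt) || nrow(bt) < 4L) stop("too few informative age bands")

  low <- bt[bt$centre < plateau_from, ]
  qfit <- stats::lm(lambda ~ centre + I(centre^2), data = low, weights = low$n)
  plateau_bands <- bt[bt$centre >= plateau_from, ]
  plateau <- if (nrow(plateau_bands) > 0) {
    weighted.mean(plateau_bands$lambda, plateau_bands$n)
  } else {
    lambda_hat <- function(a) coef(qfit)[[1L]] + coef(qfit)[[2L]] * a + coef(qfit)[[3L]] * a^2
    lambda_hat(plateau_from)
  }
  coefs <- list(c2 = coef(qfit)[[3L]], c1 = coef(qfit)[[2L]], c0 = coef(qfit)[[1L]],
                plateau = plateau, knee = plateau_from)
  structure(list(bands = bt[, c("centre", "lambda", "n")], coefs = coefs,
                 scale_mm = exp(weighted.mean(bt$intercept, bt$n))),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Age-modulated temperature sensitivity (%d age bands)\n", nrow(x$bands)))
  cat(sprintf("  lambda(A) = %.3g A^2 %+.3g A %+.3g for A < %g; %.3g beyond\n",
              x$coefs$c2, x$coefs$c1, x$coefs$c0, x$coefs$knee, x$coefs$plateau))
  invisible(x)
}
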