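#' Parametric mortality (hazard) models
#'
#' Two annual hazard parameterisations for boreal conifers. The
#' diameter-dependent model is zero at or below the minimum sampling diameter
#' \code{d0} and rises as a quartic above it:
#' \deqn{\mu(D) = b + k (D - D_0)^4, \quad D > D_0,}
#' capped at 1. The age-dependent model is zero at or below \code{a0} and
#' linear above it: \eqn{\mu(A) = a + s A}. Hazards are interpreted as annual
#' death probabilities (Bernoulli per tree-year).
#'
#' @param b baseline annual hazard (1/yr) just above the diameter threshold.
#' @param k quartic curvature (1/yr per mm^4).
#' @param d0 diameter threshold (mm) below which mortality is zero
#'   (the minimum sampling diameter of the field protocol).
#' @return an object of class \code{mortality_model}.
#' @seealso [hazard()], [fit_hazard_model()]
#' @examples
#' m <- mortality_diameter()
#' hazard(m, c(50, 91, 92, 353))
#' @export
mortality_diameter <- function(b = 0.025, k = 3e-11, d0 = 91) {
  stop_field(b < 0, "b", "baseline hazard must be >= 0")
  stop_field(k < 0, "k", "curvature must be >= 0")
  stop_field(d0 < 0, "d0", "threshold diameter must be >= 0")
  structure(list(kind = "diameter", b = b, k = k, d0 = d0),
            class = "mortality_model")
}

#' @rdname mortality_diameter
#' @param a intercept annual hazard (1/yr) just above the age threshold.
#' @param slope hazard increase per year of age (1/yr^2).
#' @param a0 age threshold (years) below which mortality is zero (age at
#'   which the average tree reaches the diameter threshold).
#' @export
mortality_age <- function(a = 0.021, slope = 1.5e-6, a0 = 74) {
  stop_field(a < 0, "a", "intercept hazard must be >= 0")
  stop_field(slope < 0, "slope", "slope must be >= 0")
  stop_field(a0 < 0, "a0", "threshold age must be >= 0")
  structure(list(kind = "age", a = a, slope = slope, a0 = a0),
            class = "mortality_model")
}

#' Evaluate an annual hazard
#'
#' @param model a \code{mortality_model}.
#' @param x diameters (mm) for a diameter model, ages (years) for an age
#'   model; must be >= 0.
#' @return annual death probabilities in \[0, 1\]; exactly 0 at or below the
#'   model threshold.
#' @export
hazard <- function(model, x) {
  stopifnot(inherits(model, "mortality_model"), all(x >= 0))
  h <- if (model$kind == "diameter") {
    ifelse(x > model$d0, model$b + model$k * (x - model$d0)^4, 0)
  } else {
    ifelse(x > model$a0, model$a + model$slope * x, 0)
  }
  pmin(h, 1)
}

#' @export
print.mortality_model <- function(x, ...) {
  if (x$kind == "diameter") {
    cat(sprintf("Diameter-dependent mortality: mu(D) = %.4g + %.3g (D - %g)^4 for D > %g mm, else 0\n",
                x$b, x$k, x$d0, x$d0))
  } else {
    cat(sprintf("Age-dependent mortality: mu(A) = %.4g + %.3g A for A > %g yr, else 0\n",
                x$a, x$slope, x$a0))
  }
  invisible(x)
}

#' Mortality from a steady-state size distribution
#'
#' Under stand stationarity (dN/dt = 0 per diameter class) the annual
#' per-capita mortality in a class is the surplus of in-growers over leavers:
#' \deqn{\mu(D) = (I(D) - L(D)) / N(D).}
#'
#' @param dist a \code{size_distribution} (see [generate_stand_distribution()])
#'   or a data frame with columns \code{bin_low}, \code{bin_high} (mm),
#'   \code{N} (standing count), \code{I}, \code{L} (trees entering/leaving the
#'   class per year by growth).
#' @return the input with columns \code{mid} (bin midpoint, mm) and \code{mu}
#'   (1/yr) appended; \code{mu} is \code{NA} where \code{N = 0}. Negative
#'   estimates (leavers exceeding in-growers, sampling noise) are returned
#'   as-is with a warning.
#' @export
estimate_mortality_from_distribution <- function(dist) {
  d <- as.data.frame(dist)
  stopifnot(all(c("bin_low", "bin_high", "N", "I", "L") %in% names(d)))
  d$mid <- (d$bin_low + d$bin_high) / 2
  d$mu <- ifelse(d$N > 0, (d$I - d$L) / d$N, NA_real_)
  if (any(d$mu < 0, na.rm = TRUE)) {
    warning(sprintf("%d bins have negative mortality estimates (L > I): sampling noise",
                    sum(d$mu < 0, na.rm = TRUE)))
  }
  d
}

#' Mortality by yearly age class from death records
#'
#' Life-table analogue of [estimate_mortality_from_distribution()] with 1-year
#' age classes: \code{mu(A)} is the number of deaths at age A divided by the
#' number of tree-years at risk at age A.
#'
#' @param deaths data frame with one row per tree: column \code{age} (final
#'   observed age, years) and logical \code{dead} (died at that age, versus
#'   censored/still alive).
#' @return data frame with columns \code{age}, \code{n_risk}, \code{n_dead},
#'   \code{mu}; ages with no trees at risk are omitted.
#' @export
estimate_mortality_by_age <- function(deaths) {
  stopifnot(all(c("age", "dead") %in% names(deaths)))
  ages <- seq_len(max(deaths$age))
  n_risk <- vapply(ages, function(a) sum(deaths$age >= a), numeric(1))
  n_dead <- vapply(ages, function(a) sum(deaths$dead & deaths$age == a), numeric(1))
  out <- data.frame(age = ages, n_risk = n_risk, n_dead = n_dead,
                    mu = ifelse(n_risk > 0, n_dead / n_risk, NA_real_))
  out[out$n_risk > 0, ]
}

#' Fit a parametric hazard model to binned mortality estimates
#'
#' Weighted least squares of the parametric hazard form to per-bin mortality
#' estimates, weights proportional to the standing count per bin. The
#' threshold (\code{d0} or \code{a0}) is fixed by the sampling design, not
#' fitted; both model families are then linear in their remaining parameters.
#'
#' @param mu_table data frame with columns \code{mid} (bin midpoint: mm or
#'   years), \code{mu} (1/yr) and \code{N} (weight); e.g. the output of
#'   [estimate_mortality_from_distribution()].
#' @param kind \code{"diameter"} (quartic) or \code{"age"} (linear).
#' @param threshold fixed threshold \code{d0} (mm) or \code{a0} (years).
#' @return a \code{mortality_model} with attributes \code{residual_sd} and
#'   \code{n_bins}.
#' @export
fit_hazard_model <- function(mu_table, kind = c("diameter", "age"), threshold = 91) {
  kind <- match.arg(kind)
  d <- mu_table[is.finite(mu_table$mu) & mu_table$N > 0 & mu_table$mid > threshold, ]
  if (nrow(d) < 4L) stop("need at least 4 informative bins above the threshold")
  z <- if (kind == "diameter") (d$mid - threshold)^4 else d$mid
  fit <- stats::lm(mu ~ z, data = data.frame(mu = d$mu, z = z), weights = d$N)
  cf <- coef(fit)
  if (any(!is.finite(cf))) stop("hazard fit did not converge: singular design")
  model <- if (kind == "diameter") {
    mortality_diameter(b = max(0, cf[[1]]), k = max(0, cf[[2]]), d0 = threshold)
  } else {
    mortality_age(a = max(0, cf[[1]]), slope = max(0, cf[[2]]), a0 = threshold)
  }
  attr(model, "residual_sd") <- sqrt(sum(fit$weights * fit$residuals^2) / sum(fit$weights))
  attr(model, "n_bins") <- nrow(d)
  model
}
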