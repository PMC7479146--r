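#' Pinball (check) loss
#'
#' Loss minimised by quantile regression: residuals below the fitted line are
#' weighted \code{1 - q}, residuals above it \code{q}.
#'
#' @param r numeric vector of residuals.
#' @param q quantile level in (0, 1).
#' @return total loss (a scalar).
#' @export
pinball_loss <- function(r, q) {
  stopifnot(q > 0, q < 1)
  sum(r * (q - (r < 0)))
}

# Exact two-parameter quantile regression by vertex exchange.
#
# The minimiser of the (convex, piecewise-linear) pinball loss over lines
# y = a + b x is attained at a line through two data points (an LP vertex).
# Starting from a line through the x-extremes we repeatedly rotate the line
# about one of its two defining points: the 1-D rotation problem is a
# weighted-quantile problem whose breakpoints are the slopes to every other
# point, solved exactly in O(n log n). A step is accepted only if it strictly
# lowers the loss, so the loop terminates; at termination no rotation about
# either defining point improves, which for this LP is the global optimality
# condition. Ties are broken by the smaller |slope|.
qr_exact <- function(x, y, q) {
  n <- length(x)
  if (n < 2L) stop("need at least two points")
  if (diff(range(x)) == 0) stop("no growth variance: all predictor values identical")

  line_through <- function(i, j) {
    if (i > j) { k <- i; i <- j; j <- k }  # canonical order: same arithmetic as the pairwise oracle
    b <- (y[j] - y[i]) / (x[j] - x[i])
    c(a = y[i] - b * x[i], b = b)
  }

  # best partner for a line rotating about point p
  rotate <- function(p) {
    u <- x - x[p]
    v <- y - y[p]
    ok <- which(u != 0)
    if (length(ok) == 0L) return(NA_integer_)
    tt <- v[ok] / u[ok]
    w <- u[ok]
    o <- order(tt)
    tt <- tt[o]; w <- w[o]; id <- ok[o]
    # derivative of the loss in the slope, just below the smallest breakpoint
    d <- -q * sum(w) + sum(w[w < 0])
    dcum <- d + cumsum(abs(w))
    k <- which(dcum >= 0)[1L]
    if (is.na(k)) k <- length(tt)
    # flat optimum: both neighbouring breakpoints minimise; pick smaller |slope|
    if (k < length(tt) && dcum[k] == 0 && abs(tt[k + 1L]) < abs(tt[k])) k <- k + 1L
    id[k]
  }

  i <- which.min(x); j <- which.max(x)
  ab <- line_through(i, j)
  loss <- pinball_loss(y - ab[1L] - ab[2L] * x, q)

  for (iter in seq_len(500L)) {
    improved <- FALSE
    for (p in c(i, j)) {
      cand <- rotate(p)
      if (is.na(cand) || cand == p) next
      ab2 <- line_through(p, cand)
      l2 <- pinball_loss(y - ab2[1L] - ab2[2L] * x, q)
      if (l2 < loss) {
        if (p == i) j <- cand else i <- cand
        ab <- ab2
        loss <- l2
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(a = unname(ab[1L]), b = unname(ab[2L]), loss = loss, points = sort(c(i, j)))
}

#' Fit the exponential growth-lifespan trade-off by quantile regression
#'
#' Fits \code{log(A) = a + b * RW} at quantile \code{q} (default the 95th),
#' where \code{A} is tree age and \code{RW} the mean ring width over the first
#' ten years, by exact minimisation of the pinball loss. Lifespan conditional
#' on early growth is then \code{exp(a + b * RW)} and \code{b} is the
#' exponential decay constant of lifespan with increasing early growth.
#'
#' The significance of \code{b} is assessed by a seeded case bootstrap:
#' trees are resampled with replacement, the fit repeated, and a two-sided
#' p-value computed as \code{2 * min(Pr(b* >= 0), Pr(b* <= 0))} with the
#' add-one correction \code{(1 + count) / (1 + n_boot)}.
#'
#' @param summaries data frame of per-tree summaries with columns
#'   \code{rw_early} (mm/yr, > 0) and \code{age} (years), as produced by
#'   [summarize_trees()] or [generate_known_tradeoff_sample()].
#' @param q quantile level, default 0.95.
#' @param n_boot bootstrap replicates for the p-value of the slope
#'   (0 skips the bootstrap and leaves the p-value \code{NA}).
#' @param seed integer seed for the bootstrap.
#' @return an object of class \code{tradeoff_fit}: list with elements
#'   \code{a} (intercept, log-years), \code{b} (decay constant per mm/yr of
#'   early growth, or per relative unit), \code{q}, \code{n}, \code{p_value},
#'   \code{relative}, \code{loss}.
#' @examples
#' s <- generate_known_tradeoff_sample(known_tradeoff_config(
#'   a_true = log(400), b_true = -0.5, n = 500, seed = 1))
#' fit <- fit_quantile_exponential(s, n_boot = 50)
#' fit$b
#' @export
fit_quantile_exponential <- function(summaries, q = 0.95, n_boot = 1000L, seed = 1L) {
  x <- summaries$rw_early
  y <- log(summaries$age)
  keep <- is.finite(x) & is.finite(y) & x > 0
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least two trees with positive early growth and age")
  if (n < 20L) warning("fewer than 20 trees: quantile fit may be unstable")
  fit <- qr_exact(x, y, q)

  p_value <- NA_real_
  if (n_boot > 0L) {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      out <- tryCatch(qr_exact(x[idx], y[idx], q)$b, error = function(e) NA_real_)
      out
    }, numeric(1))
    bs <- bs[is.finite(bs)]
    if (length(bs) > 0) {
      p_lo <- (1 + sum(bs <= 0)) / (1 + length(bs))
      p_hi <- (1 + sum(bs >= 0)) / (1 + length(bs))
      p_value <- min(1, 2 * min(p_lo, p_hi))
    }
  }

  structure(
    list(a = fit$a, b = fit$b, q = q, n = n, p_value = p_value,
         relative = isTRUE(attr(summaries, "relative")), loss = fit$loss),
    class = "tradeoff_fit")
}

#' @export
print.tradeoff_fit <- function(x, ...) {
  cat(sprintf("Exponential quantile trade-off fit (q = %.2f, n = %d%s)\n",
              x$q, x$n, if (isTRUE(x$relative)) ", relative units" else ""))
  cat(sprintf("  log(lifespan) = %.4f %+.4f * early growth\n", x$a, x$b))
  cat(sprintf("  lifespan at RW = 1: %.1f years\n", exp(x$a + x$b)))
  if (!is.na(x$p_value)) cat(sprintf("  bootstrap p-value (b != 0): %.4g\n", x$p_value))
  invisible(x)
}

#' Predicted lifespan from a trade-off fit
#'
#' @param object a \code{tradeoff_fit}.
#' @param rw_early vector of mean early ring widths (same units as the fit).
#' @param ... unused.
#' @return predicted lifespans (years): \code{exp(a + b * rw_early)}.
#' @export
predict.tradeoff_fit <- function(object, rw_early, ...) {
  exp(object$a + object$b * rw_early)
}
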