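# Two-sided stretched-exponential null density.
#
# Empirical score histograms from randomization nulls are summarized by
#   f(x) = h * exp(-(b_side * |x - x0|)^c_side),
# with independent (b, c) on each side of the mode x0.  The fitted density
# can be extrapolated far beyond the histogram range, which is how p-values
# are obtained for submissions that score much better (or worse) than any
# of the simulated random predictions.

#' Fit a two-sided stretched exponential to a score sample
#'
#' The sample is histogrammed (Freedman-Diaconis bin count by default), the
#' mode bin provides `x0` (bin midpoint) and `h` (modal density), and each
#' side is fitted by least squares on the log-density of its non-empty bins.
#' Empty bins are ignored rather than pseudo-counted.
#'
#' @param sample numeric vector of metric values, length >= 1000.
#' @param n_bins number of histogram bins; `NULL` (default) chooses the
#'   Freedman-Diaconis count.
#' @return Object of class `stretched_exp_fit` with elements `h`, `x0`,
#'   `b_left`, `c_left`, `b_right`, `c_right`, `normalization` (integral of
#'   the unnormalized density) and the histogram used.
#' @export
fit_stretched_exponential <- function(sample, n_bins = NULL) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 1000) db_stop("need >= 1000 sample values to fit tails")
  if (stats::sd(sample) == 0) db_stop("constant sample: null distribution is degenerate")
  if (is.null(n_bins)) {
    n_bins <- max(10L, grDevices::nclass.FD(sample))
  }
  breaks <- seq(min(sample), max(sample), length.out = n_bins + 1L)
  hst <- graphics::hist(sample, breaks = breaks, plot = FALSE)
  dens <- hst$density
  mids <- hst$mids
  imode <- which.max(dens)
  x0 <- mids[imode]
  h <- dens[imode]

  fit_side <- function(side) {
    if (side == "left") {
      keep <- mids < x0 & dens > 0
    } else {
      keep <- mids > x0 & dens > 0
    }
    d <- abs(mids[keep] - x0)
    y <- dens[keep]
    usable <- y < h  # log(h/y) must be positive for the log-log start
    if (sum(keep) < 3 || sum(usable) < 2) {
      db_stop("fewer than 3 usable non-empty bins on the %s side; use a larger sample",
              side)
    }
    # start values from the linearization log(log(h/y)) = c*log(b) + c*log(d)
    ll <- stats::lm(log(log(h / y[usable])) ~ log(d[usable]))
    c0 <- max(0.2, min(5, unname(stats::coef(ll)[2])))
    b0 <- exp(unname(stats::coef(ll)[1]) / c0)
    # refine by least squares on log-density (all non-empty bins on the side)
    fit <- tryCatch(
      stats::nls(log(y) ~ log(h) - (b * d)^cc,
                 start = list(b = b0, cc = c0),
                 lower = c(b = 1e-10, cc = 0.05),
                 upper = c(b = Inf, cc = 10),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      c(b = b0, c = c0)
    } else {
      cf <- stats::coef(fit)
      c(b = unname(cf["b"]), c = unname(cf["cc"]))
    }
  }
  left <- fit_side("left")
  right <- fit_side("right")
  # side integral of h*exp(-(b t)^c) over t in (0, Inf) is h*Gamma(1+1/c)/b
  z_left <- h * gamma(1 + 1 / left["c"]) / left["b"]
  z_right <- h * gamma(1 + 1 / right["c"]) / right["b"]
  structure(list(
    h = h, x0 = x0,
    b_left = unname(left["b"]), c_left = unname(left["c"]),
    b_right = unname(right["b"]), c_right = unname(right["c"]),
    normalization = unname(z_left + z_right),
    z_left = unname(z_left), z_right = unname(z_right),
    histogram = list(mids = mids, density = dens)
  ), class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<stretched_exp_fit> x0=%.4g h=%.4g | left b=%.4g c=%.3g | right b=%.4g c=%.3g\n",
    x$x0, x$h, x$b_left, x$c_left, x$b_right, x$c_right))
  invisible(x)
}

#' Evaluate the normalized fitted density
#' @param fit a `stretched_exp_fit`.
#' @param x numeric vector of points.
#' @return density values.
#' @export
stretched_exp_density <- function(fit, x) {
  d <- abs(x - fit$x0)
  left <- x < fit$x0
  b <- ifelse(left, fit$b_left, fit$b_right)
  cc <- ifelse(left, fit$c_left, fit$c_right)
  fit$h * exp(-(b * d)^cc) / fit$normalization
}

# Unnormalized mass of one side beyond distance d from the mode:
# integral_d^Inf h*exp(-(b t)^c) dt = h * Gamma(1/c)/(b c) * Q(1/c, (b d)^c)
side_tail_mass <- function(h, b, cc, d) {
  h * gamma(1 / cc) / (b * cc) *
    stats::pgamma((b * d)^cc, shape = 1 / cc, lower.tail = FALSE)
}

#' Tail p-value from a fitted stretched-exponential null
#'
#' Integrates the normalized fitted density from `observed` outward.  Uses
#' the incomplete-gamma closed form; p-values are floored at the smallest
#' positive double and flagged when the true value underflows ("below the
#' precision of the calculation").
#'
#' @param fit a `stretched_exp_fit`.
#' @param observed observed metric value (finite).
#' @param side `"upper"` for `P(X >= observed)`, `"lower"` for
#'   `P(X <= observed)`.
#' @return Numeric p-value in (0, 1) with attribute `below_precision`
#'   (logical).
#' @export
tail_pvalue <- function(fit, observed, side = c("upper", "lower")) {
  side <- match.arg(side)
  stopifnot(inherits(fit, "stretched_exp_fit"))
  if (!is.finite(observed)) db_stop("observed value must be finite")
  d <- abs(observed - fit$x0)
  mass <- if (side == "upper") {
    if (observed >= fit$x0) {
      side_tail_mass(fit$h, fit$b_right, fit$c_right, d)
    } else {
      fit$z_right + (fit$z_left - side_tail_mass(fit$h, fit$b_left, fit$c_left, d))
    }
  } else {
    if (observed <= fit$x0) {
      side_tail_mass(fit$h, fit$b_left, fit$c_left, d)
    } else {
      fit$z_left + (fit$z_right - side_tail_mass(fit$h, fit$b_right, fit$c_right, d))
    }
  }
  p <- mass / fit$normalization
  below <- p <= 0 || !is.finite(p) || p < .Machine$double.xmin
  p <- min(max(p, .Machine$double.xmin), 1 - .Machine$double.eps)
  structure(p, below_precision = below)
}
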