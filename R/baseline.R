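# Parametric baseline-hazard families: exponential, Weibull, cubic B-spline
# on the log hazard. Time is measured in days throughout.

#' Baseline hazard specifications
#'
#' Three families for the baseline hazard h0(t):
#' \itemize{
#'   \item exponential: h0(t) = lambda, H0(t) = lambda t
#'   \item weibull: h0(t) = alpha lambda t^(alpha-1), H0(t) = lambda t^alpha
#'   \item bspline: log h0(t) is a cubic B-spline with interior knots over
#'     [0, t_max]; positivity of h0 holds by construction and H0 is obtained
#'     by quadrature of exp(spline). Beyond t_max the hazard is extended as
#'     the constant h0(t_max).
#' }
#'
#' @param rate exponential rate lambda > 0
#' @return an object of class `baseline_hazard`
#' @export
baseline_exponential <- function(rate) {
  stopifnot(rate > 0)
  structure(list(family = "exponential", rate = rate),
            class = "baseline_hazard")
}

#' @rdname baseline_exponential
#' @param shape Weibull shape alpha > 0
#' @param scale Weibull rate-like scale lambda > 0 in h0(t) =
#'   alpha lambda t^(alpha-1)
#' @export
baseline_weibull <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(family = "weibull", shape = shape, scale = scale),
            class = "baseline_hazard")
}

#' @rdname baseline_exponential
#' @param coef spline coefficients for log h0
#' @param knots interior knot locations in (0, t_max)
#' @param t_max upper boundary knot (days)
#' @export
baseline_bspline <- function(coef, knots, t_max) {
  stopifnot(t_max > 0, all(knots > 0), all(knots < t_max))
  k <- length(knots) + 4L
  if (length(coef) != k)
    stop("bspline needs ", k, " coefficients for ", length(knots),
         " interior knots (cubic)")
  structure(list(family = "bspline", coef = coef, knots = sort(knots),
                 t_max = t_max),
            class = "baseline_hazard")
}

#' Default interior knots at follow-up-time quantiles
#' @param t follow-up times
#' @param probs quantile positions of the interior knots
#' @keywords internal
default_bspline_knots <- function(t, probs = c(0.25, 0.5, 0.75)) {
  k <- unname(quantile(t[t > 0], probs))
  k[k <= 0] <- min(t[t > 0])
  unique(k)
}

#' Cubic B-spline basis over [0, t_max], constant-extended beyond t_max
#' @keywords internal
bspline_basis <- function(t, knots, t_max) {
  kn <- c(rep(0, 4), sort(knots), rep(t_max, 4))
  splines::splineDesign(kn, pmin(pmax(t, 0), t_max), ord = 4, outer.ok = TRUE)
}

#' Baseline hazard h0(t)
#' @param t nonnegative times (days)
#' @param baseline a `baseline_hazard`
#' @return h0 evaluated at t
#' @export
baseline_hazard <- function(t, baseline) {
  if (any(t < 0)) stop("negative time in baseline_hazard")
  switch(baseline$family,
    exponential = rep(baseline$rate, length(t)),
    weibull = baseline$shape * baseline$scale * t^(baseline$shape - 1),
    bspline = {
      lh <- drop(bspline_basis(t, baseline$knots, baseline$t_max) %*%
                   baseline$coef)
      exp(lh)
    },
    stop("unknown baseline family"))
}

#' Cumulative baseline hazard H0(t)
#'
#' Closed form for exponential/Weibull; adaptive quadrature of exp(spline)
#' for the B-spline family (relative tolerance 1e-10), with linear
#' extension beyond `t_max`.
#'
#' @inheritParams baseline_hazard
#' @return H0 evaluated at t; H0(0) = 0 and H0 nondecreasing
#' @export
cumulative_baseline <- function(t, baseline) {
  if (any(t < 0)) stop("negative time in cumulative_baseline")
  switch(baseline$family,
    exponential = baseline$rate * t,
    weibull = baseline$scale * t^baseline$shape,
    bspline = {
      h <- function(u) baseline_hazard(u, baseline)
      H_at <- function(ti) {
        tin <- min(ti, baseline$t_max)
        v <- if (tin == 0) 0 else
          integrate(h, 0, tin, rel.tol = 1e-10, subdivisions = 500L)$value
        if (ti > baseline$t_max)
          v <- v + (ti - baseline$t_max) *
            baseline_hazard(baseline$t_max, baseline)
        v
      }
      vapply(t, H_at, numeric(1))
    },
    stop("unknown baseline family"))
}

# Internal: pack a baseline into the parameter vector used by the sampler
# (log scale for positive parameters, raw coefficients for the spline).
baseline_to_logomega <- function(baseline) {
  switch(baseline$family,
    exponential = log(baseline$rate),
    weibull = c(log(baseline$shape), log(baseline$scale)),
    bspline = baseline$coef)
}

logomega_to_baseline <- function(logomega, family, knots = NULL,
                                 t_max = NULL) {
  switch(family,
    exponential = baseline_exponential(exp(logomega[1])),
    weibull = baseline_weibull(exp(logomega[1]), exp(logomega[2])),
    bspline = baseline_bspline(logomega, knots, t_max))
}
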