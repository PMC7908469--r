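# Area-level covariate construction: ordinary kriging of a partially
# observed socioeconomic index, and a Gaussian-kernel hospital density
# surface evaluated at district centroids.

#' Variogram model
#'
#' @param model one of `"exponential"`, `"spherical"`, `"gaussian"`
#' @param nugget nonnegative nugget variance
#' @param psill positive partial sill
#' @param range positive range parameter in metres. For the exponential
#'   model this is the e-folding scale (effective range about 3x); for the
#'   spherical model the exact sill-reaching range; for the gaussian model
#'   the e-folding scale of the squared-distance exponent.
#' @return object of class `variogram_model`
#' @export
variogram_model <- function(model = c("exponential", "spherical", "gaussian"),
                            nugget, psill, range) {
  model <- match.arg(model)
  if (nugget < 0) stop("nugget must be >= 0")
  if (psill <= 0) stop("partial sill must be > 0")
  if (range <= 0) stop("range must be > 0")
  structure(list(model = model, nugget = nugget, psill = psill, range = range),
            class = "variogram_model")
}

#' Semivariance of a variogram model
#'
#' gamma(0) = 0 exactly; gamma(0+) -> nugget; gamma(Inf) = nugget + psill.
#' @param v a [variogram_model]
#' @param h nonnegative distances (metres)
#' @export
semivariance <- function(v, h) {
  s <- switch(v$model,
    exponential = 1 - exp(-h / v$range),
    gaussian    = 1 - exp(-(h / v$range)^2),
    spherical   = ifelse(h >= v$range, 1,
                         1.5 * h / v$range - 0.5 * (h / v$range)^3))
  ifelse(h == 0, 0, v$nugget + v$psill * s)
}

#' Empirical (binned) semivariogram
#'
#' @param locations two-column coordinate matrix (metres)
#' @param values numeric vector
#' @param n_bins number of distance bins
#' @param cutoff maximum pair distance used; default a third of the maximum
#'   pairwise distance (standard practice: long-lag bins are noisy)
#' @return data.frame with columns `dist` (bin mean distance), `gamma`, `n`
#' @export
empirical_variogram <- function(locations, values, n_bins = 13, cutoff = NULL) {
  locations <- as.matrix(locations)
  d <- as.matrix(dist(locations))
  iu <- which(upper.tri(d))
  h <- d[iu]
  g <- 0.5 * (outer(values, values, "-")^2)[iu]
  if (is.null(cutoff)) cutoff <- max(h) / 3
  keep <- h <= cutoff & h > 0
  h <- h[keep]; g <- g[keep]
  if (!length(h)) stop("no point pairs within cutoff")
  bins <- cut(h, breaks = seq(0, cutoff, length.out = n_bins + 1),
              include.lowest = TRUE)
  data.frame(
    dist  = as.numeric(tapply(h, bins, mean)),
    gamma = as.numeric(tapply(g, bins, mean)),
    n     = as.integer(table(bins))
  )[!is.na(tapply(h, bins, mean)), ]
}

#' Fit a variogram by weighted least squares
#'
#' Fits each candidate model to the empirical semivariogram with
#' Cressie-style weights n_j / gamma_model(h_j)^2 and keeps the model with
#' the smallest weighted residual sum of squares — an automatic-fitting
#' convention in the spirit of `automap::autoKrige`.
#'
#' @param locations two-column coordinate matrix of observed points (metres)
#' @param values observed values (needs nonzero spread)
#' @param models candidate model set
#' @param n_bins number of distance bins
#' @param cutoff maximum pair distance used; default half the maximum
#'   pairwise distance (long enough to anchor the sill, which stabilises
#'   the range estimate)
#' @return a [variogram_model] with attributes `sse` and `empirical`
#' @export
fit_variogram <- function(locations, values,
                          models = c("exponential", "spherical", "gaussian"),
                          n_bins = 15, cutoff = NULL) {
  locations <- as.matrix(locations)
  if (nrow(locations) < 10)
    stop("fit_variogram needs at least 10 observed locations")
  if (sd(values) == 0)
    stop("degenerate field: values are constant, no variogram to fit")
  if (is.null(cutoff)) cutoff <- max(dist(locations)) / 2
  emp <- empirical_variogram(locations, values, n_bins, cutoff)

  fit_one <- function(model) {
    # log-scale parameters enforce positivity; several starts guard against
    # the flat nugget/short-range and long-range/sill ridges
    gmax <- max(emp$gamma); hmax <- max(emp$dist)
    starts <- list(c(log(1e-4 * gmax), log(gmax), log(hmax / 3)),
                   c(log(0.5 * gmax), log(0.5 * gmax), log(hmax / 10)),
                   c(log(1e-4 * gmax), log(gmax), log(hmax / 20)))
    obj <- function(p) {
      if (p[3] > log(20 * hmax)) return(1e12)  # off the identifiable window
      v <- variogram_model(model, exp(p[1]), exp(p[2]), exp(p[3]))
      gm <- semivariance(v, emp$dist)
      sum(emp$n / pmax(gm, 1e-12)^2 * (emp$gamma - gm)^2)
    }
    fit <- NULL
    for (s in starts) {
      f <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(fit) || f$value < fit$value) fit <- f
    }
    list(v = variogram_model(model, exp(fit$par[1]), exp(fit$par[2]),
                             exp(fit$par[3])),
         sse = fit$value)
  }
  fits <- lapply(models, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "sse"))]]
  out <- best$v
  attr(out, "sse") <- best$sse
  attr(out, "empirical") <- emp
  out
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary-kriging system (unit-sum weights enforced through a
#' Lagrange multiplier) for each target location. With a zero nugget the
#' predictor interpolates exactly at observed locations with zero variance.
#'
#' @param observed_locations (n x 2) matrix of observed coordinates
#' @param observed_values length-n vector
#' @param targets (m x 2) matrix of prediction locations
#' @param v a [variogram_model]
#' @return list with `prediction` (m), `variance` (m, >= 0), and `weights`
#'   (n x m matrix; columns sum to 1)
#' @export
ordinary_krige <- function(observed_locations, observed_values, targets, v) {
  observed_locations <- as.matrix(observed_locations)
  targets <- rbind(targets)
  n <- nrow(observed_locations)
  if (n < 2) stop("ordinary kriging needs at least 2 observed points")
  stopifnot(inherits(v, "variogram_model"), length(observed_values) == n)

  D <- as.matrix(dist(observed_locations))
  dup <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup))
    stop("duplicate observed locations make the kriging matrix singular: ",
         paste(sprintf("(%d,%d)", dup[, 1], dup[, 2]), collapse = ", "))

  A <- rbind(cbind(semivariance(v, D), 1), c(rep(1, n), 0))
  m <- nrow(targets)
  d0 <- sqrt(outer(observed_locations[, 1], targets[, 1], "-")^2 +
             outer(observed_locations[, 2], targets[, 2], "-")^2)
  B <- rbind(semivariance(v, d0), rep(1, m))
  sol <- solve(A, B)
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- unname(drop(crossprod(w, observed_values)))
  kvar <- unname(colSums(w * semivariance(v, d0)) + mu)
  kvar <- pmax(kvar, 0)  # clamp tiny negative round-off
  list(prediction = pred, variance = kvar, weights = unname(w))
}

#' Gaussian-kernel density of facility points
#'
#' Isotropic Gaussian kernel intensity estimate
#' \eqn{\lambda(s) = \sum_k \exp(-\|s-s_k\|^2/(2h^2)) / (2\pi h^2)},
#' evaluated at each location and reported in points per km^2. No edge
#' correction by default. Integrating the surface over a window padded by
#' several bandwidths recovers approximately the point count.
#'
#' @param points (k x 2) matrix of facility coordinates (metres)
#' @param eval_at (m x 2) matrix of evaluation locations (metres)
#' @param bandwidth kernel standard deviation in metres; default is the
#'   normal rule of thumb `sigma * k^(-1/6)` with `sigma` the root mean
#'   marginal spatial variance of the points
#' @param per_km2 report per km^2 (default) rather than per m^2
#' @return numeric vector of densities, with attribute `bandwidth`
#' @export
hospital_density <- function(points, eval_at, bandwidth = NULL,
                             per_km2 = TRUE) {
  points <- rbind(points); eval_at <- rbind(eval_at)
  if (nrow(points) < 1) stop("need at least 1 point")
  if (is.null(bandwidth)) {
    sig <- sqrt(mean(c(var(points[, 1]), var(points[, 2]))))
    if (!is.finite(sig) || sig == 0) sig <- 1000
    bandwidth <- sig * nrow(points)^(-1 / 6)
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  d2 <- outer(eval_at[, 1], points[, 1], "-")^2 +
        outer(eval_at[, 2], points[, 2], "-")^2
  dens <- rowSums(exp(-d2 / (2 * bandwidth^2))) / (2 * pi * bandwidth^2)
  if (per_km2) dens <- dens * 1e6
  structure(dens, bandwidth = bandwidth)
}

#' Build the district-level covariate table
#'
#' Districts with an observed socioeconomic index keep their value; missing
#' districts receive an ordinary-kriging prediction at their centroid from a
#' variogram fitted to the observed districts. Hospital density is evaluated
#' at every centroid. Both covariates are also returned z-scored
#' (`*_z` columns) so coefficient scales are comparable in the survival
#' model; raw values are retained.
#'
#' @param map a [district_map]
#' @param se_observed data.frame with columns `district_id`, `value`;
#'   missing districts may be absent or have `NA` value
#' @param hospitals (k x 2) matrix or data.frame of hospital coordinates
#'   (metres; columns x, y)
#' @param bandwidth optional kernel bandwidth (metres), see
#'   [hospital_density]
#' @param variogram optional pre-fitted [variogram_model]; fitted
#'   automatically when NULL
#' @return data.frame: `district_id`, `se_index`, `se_index_source`
#'   (`"observed"`/`"kriged"`), `se_kriging_se`, `hospital_density`,
#'   `se_index_z`, `hospital_density_z`
#' @export
build_area_covariates <- function(map, se_observed, hospitals,
                                  bandwidth = NULL, variogram = NULL) {
  stopifnot(inherits(map, "district_map"))
  se <- se_observed[!is.na(se_observed$value), , drop = FALSE]
  se <- se[se$district_id %in% map$district_id, , drop = FALSE]
  obs_ids <- se$district_id
  mis_ids <- setdiff(map$district_id, obs_ids)
  if (!length(obs_ids))
    stop("all socioeconomic-index values missing: nothing to krige from")

  idx <- match(obs_ids, map$district_id)
  out <- data.frame(district_id = map$district_id,
                    se_index = NA_real_,
                    se_index_source = "observed",
                    se_kriging_se = 0,
                    stringsAsFactors = FALSE)
  out$se_index[idx] <- se$value

  if (length(mis_ids)) {
    loc_obs <- cbind(map$cx[idx], map$cy[idx])
    if (is.null(variogram))
      variogram <- fit_variogram(loc_obs, se$value)
    tgt <- match(mis_ids, map$district_id)
    kr <- ordinary_krige(loc_obs, se$value,
                         cbind(map$cx[tgt], map$cy[tgt]), variogram)
    out$se_index[tgt] <- kr$prediction
    out$se_index_source[tgt] <- "kriged"
    out$se_kriging_se[tgt] <- sqrt(kr$variance)
  }

  hosp <- as.matrix(hospitals[, 1:2])
  out$hospital_density <- as.numeric(
    hospital_density(hosp, cbind(map$cx, map$cy), bandwidth))
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  out$se_index_z <- zs(out$se_index)
  out$hospital_density_z <- zs(out$hospital_density)
  out
}

#' Write area covariates as tab-delimited text (with provenance column)
#' @param covariates output of [build_area_covariates]
#' @param path output file
#' @export
write_area_covariates <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
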