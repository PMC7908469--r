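# Posterior post-processing: hazard-ratio tables, spatial correlation decay
# curves, baseline/cumulative hazard curves, and covariate-adjusted
# exceedance-probability risk maps.

chain_cols <- function(chain, prefix) {
  j <- grep(paste0("^", prefix), colnames(chain$draws))
  chain$draws[, j, drop = FALSE]
}

#' Posterior hazard-ratio table
#'
#' Each covariate effect is exponentiated draw-wise; the table reports the
#' posterior median, equal-tailed 95 percent credible interval, and a
#' significance flag set when the interval excludes 1. Reference levels have
#' no row by construction (they carry no coefficient).
#'
#' @param chain a `spfrail_chain`
#' @param n optional named vector of level counts to include as a column
#' @param covariates optional subset of coefficient names (error if absent)
#' @return data.frame: covariate, n, hr_median, hr_lower, hr_upper,
#'   significant
#' @export
hazard_ratio_table <- function(chain, n = NULL, covariates = NULL) {
  stopifnot(inherits(chain, "spfrail_chain"))
  if (nrow(chain$draws) < 100)
    stop("hazard_ratio_table needs >= 100 retained draws")
  B <- chain_cols(chain, "beta:")
  nms <- sub("^beta:", "", colnames(B))
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, nms)
    if (length(miss)) stop("covariate(s) absent from chain: ",
                           paste(miss, collapse = ", "))
    B <- B[, match(covariates, nms), drop = FALSE]
    nms <- covariates
  }
  HR <- exp(B)
  q <- t(apply(HR, 2, quantile, probs = c(0.5, 0.025, 0.975)))
  out <- data.frame(covariate = nms,
                    n = if (is.null(n)) NA_integer_ else
                      as.integer(n[nms]),
                    hr_median = q[, 1], hr_lower = q[, 2], hr_upper = q[, 3],
                    row.names = NULL)
  out$significant <- out$hr_lower > 1 | out$hr_upper < 1
  out
}

#' Posterior spatial correlation decay curve
#'
#' For each distance d in the grid, summarises exp(-d/phi) over the
#' posterior draws of phi: median and equal-tailed 95 percent band. The
#' median curve is nonincreasing in d.
#'
#' @param chain a `spfrail_chain`
#' @param d_grid distances in metres
#' @return data.frame: d, median, lower, upper
#' @export
correlation_curve <- function(chain, d_grid) {
  stopifnot(inherits(chain, "spfrail_chain"))
  phi <- exp(chain$draws[, "log_phi"])
  rows <- lapply(d_grid, function(d) {
    r <- exp(-d / phi)
    q <- quantile(r, c(0.5, 0.025, 0.975))
    data.frame(d = d, median = q[1], lower = q[2], upper = q[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exceedance probabilities of the district relative risk
#'
#' Per district and threshold c, the fraction of retained draws with
#' exp(Y_j) > c -- the posterior probability that the covariate-adjusted
#' relative risk of district j exceeds c -- plus a binomial Monte-Carlo
#' standard error.
#'
#' @param chain a `spfrail_chain`
#' @param thresholds positive thresholds; defaults 1.1, 1.25 and 1.5 (the
#'   reporting thresholds for the two regions)
#' @return object of class `exceedance_surface`: data.frame `district_id`
#'   plus `p_exc_<c>` and `mcse_<c>` columns; thresholds in the
#'   `thresholds` attribute
#' @export
exceedance_probability <- function(chain, thresholds = c(1.1, 1.25, 1.5)) {
  stopifnot(inherits(chain, "spfrail_chain"))
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  Y <- chain_cols(chain, "Y:")
  S <- nrow(Y)
  out <- data.frame(district_id = sub("^Y:", "", colnames(Y)))
  for (c0 in thresholds) {
    p <- colMeans(exp(Y) > c0)
    out[[sprintf("p_exc_%g", c0)]] <- p
    out[[sprintf("mcse_%g", c0)]] <- sqrt(p * (1 - p) / S)
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("exceedance_surface", "data.frame")
  out
}

#' Bin probabilities into reporting classes
#' @param p probabilities in [0, 1]
#' @param breaks bin edges; defaults follow the 0.5 / 0.75 reporting breaks
#' @return integer bin index with labels attribute
#' @export
probability_bins <- function(p, breaks = c(0, 0.25, 0.5, 0.75, 1)) {
  cut(p, breaks = breaks, include.lowest = TRUE, right = FALSE,
      labels = FALSE) -> b
  # right-closed top bin
  b[p >= breaks[length(breaks) - 1]] <- length(breaks) - 1L
  attr(b, "labels") <- paste0("[", breaks[-length(breaks)], ",",
                              breaks[-1], ")")
  b
}

#' Export an exceedance surface as choropleth artifacts
#'
#' Writes one GeoJSON with per-district probability and bin properties, and
#' (optionally) one static PNG per threshold with the probability bin
#' colours. Bins default to [0,0.25), [0.25,0.5), [0.5,0.75), [0.75,1].
#'
#' @param surface an `exceedance_surface`
#' @param map a [district_map] covering every surface district
#' @param out_dir output directory (created if needed)
#' @param breaks probability bin edges
#' @param image write PNG images as well as GeoJSON
#' @return invisible character vector of files written
#' @export
export_risk_map <- function(surface, map, out_dir,
                            breaks = c(0, 0.25, 0.5, 0.75, 1),
                            image = TRUE) {
  stopifnot(inherits(surface, "exceedance_surface"),
            inherits(map, "district_map"))
  missing_d <- setdiff(surface$district_id, map$district_id)
  if (length(missing_d))
    stop("district(s) in surface but not in map: ",
         paste(missing_d, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- attr(surface, "thresholds")
  props <- surface[, c("district_id",
                       sprintf("p_exc_%g", thresholds)), drop = FALSE]
  for (c0 in thresholds)
    props[[sprintf("bin_%g", c0)]] <-
      as.integer(probability_bins(props[[sprintf("p_exc_%g", c0)]], breaks))
  files <- character()
  gj <- file.path(out_dir, "exceedance.geojson")
  write_district_geojson(map[map$district_id %in% surface$district_id, ],
                         gj, properties = props)
  files <- gj

  if (image) {
    geom <- attr(map, "geometry")
    cols <- c("#ffffcc", "#fdbb84", "#fc4e2a", "#b10026")[
      seq_len(length(breaks) - 1)]
    for (c0 in thresholds) {
      f <- file.path(out_dir, sprintf("exceedance_%g.png", c0))
      grDevices::png(f, width = 800, height = 800)
      plot(NA, xlim = range(map$cx) + c(-1, 1) * 2 * sqrt(max(map$area_km2)) * 1000,
           ylim = range(map$cy) + c(-1, 1) * 2 * sqrt(max(map$area_km2)) * 1000,
           asp = 1, xlab = "x (m)", ylab = "y (m)",
           main = sprintf("P[exp(Y) > %g]", c0))
      for (i in seq_len(nrow(map))) {
        di <- map$district_id[i]
        j <- match(di, props$district_id)
        fill <- if (is.na(j)) "grey90" else
          cols[props[[sprintf("bin_%g", c0)]][j]]
        for (part in geom[[i]])
          graphics::polygon(part[[1]][, 1], part[[1]][, 2], col = fill,
                            border = "grey30")
      }
      graphics::legend("topright", fill = cols,
                       legend = attr(probability_bins(0.5, breaks), "labels"),
                       title = "probability", bty = "n")
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

# Rebuild a baseline_hazard from one retained draw.
baseline_from_draw <- function(chain, draw_row) {
  fam <- chain$baseline_family
  lw <- switch(fam,
    exponential = draw_row["log_rate"],
    weibull = draw_row[c("log_shape", "log_scale")],
    bspline = draw_row[grep("^bs_coef_", names(draw_row))])
  logomega_to_baseline(unname(lw), fam, chain$knots, chain$t_max)
}

#' Posterior baseline and cumulative hazard curves
#'
#' Evaluates h0(t) and H0(t) per retained draw over a time grid and returns
#' draw-wise quantile summaries (median and equal-tailed 95 percent band).
#'
#' @param chain a `spfrail_chain`
#' @param t_grid times (days)
#' @param max_draws cap on draws evaluated (evenly subsampled)
#' @return list of two data.frames `h0` and `H0` (t, median, lower, upper)
#' @export
baseline_curves <- function(chain, t_grid, max_draws = 500) {
  stopifnot(inherits(chain, "spfrail_chain"))
  S <- nrow(chain$draws)
  rows <- unique(round(seq(1, S, length.out = min(S, max_draws))))
  h <- H <- matrix(NA_real_, length(rows), length(t_grid))
  for (k in seq_along(rows)) {
    b <- baseline_from_draw(chain, chain$draws[rows[k], ])
    h[k, ] <- baseline_hazard(t_grid, b)
    H[k, ] <- cumulative_baseline(t_grid, b)
  }
  qs <- function(M) {
    q <- apply(M, 2, quantile, probs = c(0.5, 0.025, 0.975))
    data.frame(t = t_grid, median = q[1, ], lower = q[2, ], upper = q[3, ])
  }
  list(h0 = qs(h), H0 = qs(H))
}
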