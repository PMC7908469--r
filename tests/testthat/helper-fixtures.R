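# Shared fixtures, built in code at test time.

# n x n grid of 1 km square districts
grid9 <- function(region = "west") make_grid_map(3, 3, 1000, region = region)

# small registry-style cohort for fast fits
small_cohort <- function(n = 400, m = 16, seed = 11, sigma2 = 0.25,
                         phi = 60000,
                         baseline = baseline_exponential(6e-4),
                         beta = c("age" = 0.2)) {
  spec <- cohort_spec(n_patients = n, n_west = m, n_east = 1, cell = 30000,
                      covariates = list(
                        age = list(type = "numeric", mean = 60, sd = 12)),
                      beta = beta, baseline = baseline,
                      sigma2 = sigma2, phi = phi, censor_time = 2192,
                      n_hospitals = 10, seed = seed)
  generate_cohort(spec)
}

# GeoJSON fixture written to a temp file: 3x3 grid of ~1km cells in
# geographic degrees near (102E, 3N), one cell labelled per `regions`
write_geo_grid <- function(path, regions = rep("west", 9)) {
  lon0 <- 102; lat0 <- 3
  dlat <- 1000 / 111194.9
  feats <- list()
  k <- 0
  for (iy in 1:3) for (ix in 1:3) {
    k <- k + 1
    dlon <- dlat / cos((lat0 + (iy - 0.5) * dlat) * pi / 180)
    x0 <- lon0 + (ix - 1) * dlon; y0 <- lat0 + (iy - 1) * dlat
    ring <- list(c(x0, y0), c(x0 + dlon, y0), c(x0 + dlon, y0 + dlat),
                 c(x0, y0 + dlat), c(x0, y0))
    feats[[k]] <- list(type = "Feature",
                       properties = list(district_id = sprintf("G%02d", k),
                                         name = sprintf("cell %d", k),
                                         region = regions[k]),
                       geometry = list(type = "Polygon",
                                       coordinates = list(ring)))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 12)
  path
}

# exponential-covariance Gaussian field draw at given locations
sim_gp_exp <- function(loc, sill, range_m, nugget = 0) {
  d <- as.matrix(dist(loc))
  S <- sill * exp(-d / range_m) + diag(nugget, nrow(loc))
  L <- t(chol(S + diag(1e-10, nrow(loc))))
  drop(L %*% rnorm(nrow(loc)))
}
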