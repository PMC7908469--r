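# Synthetic registry cohorts with the exact statistical structure the
# analysis assumes: grid district maps, a spatially correlated frailty
# field, categorical covariates with explicit "Missing" levels, survival
# times drawn from the proportional-hazards model by inverse-transform
# sampling, and administrative right-censoring at end of study.

#' Default registry-style covariate scheme
#'
#' Age is continuous; the categorical covariates carry explicit missing
#' levels with the first level as reference, mirroring registry recoding
#' practice (prevalences loosely follow a national colorectal-cancer
#' registry's level counts).
#'
#' @keywords internal
default_covariate_scheme <- function() {
  list(
    age = list(type = "numeric", mean = 62, sd = 13),
    sex = list(type = "factor",
               levels = c("Female", "Male", "Missing"),
               prob = c(0.43, 0.56, 0.01)),
    ethnicity = list(type = "factor",
                     levels = c("NonMalay", "Malay", "Missing"),
                     prob = c(0.56, 0.43, 0.01)),
    stage = list(type = "factor",
                 levels = c("StageI", "StageII", "StageIII", "StageIV",
                            "NotStaged", "Missing"),
                 prob = c(0.05, 0.14, 0.18, 0.15, 0.14, 0.34))
  )
}

#' Cohort specification for the synthetic-data generator
#'
#' Defaults emulate the registry analysis's stated world: 4412 patients
#' over 144 square-grid districts split 87 (west) + 57 (east), explicit
#' missing-category covariates, administrative censoring at the end of a
#' six-year study window (2192 days), and survival times generated from the
#' spatial proportional-hazards model.
#'
#' @param n_patients cohort size
#' @param n_west,n_east districts per region (square grids, trimmed
#'   row-major to these counts)
#' @param cell district cell side in metres (30 km: districts are tens of
#'   kilometres across)
#' @param covariates covariate scheme (see
#'   `spfrail:::default_covariate_scheme`)
#' @param beta named true log-hazard-ratio vector; names must match design
#'   matrix columns built from the scheme
#' @param baseline a `baseline_hazard` (the truth)
#' @param sigma2,phi frailty variance and correlation range (metres)
#' @param censor_time administrative censoring time (days > 0)
#' @param se_missing_frac fraction of districts whose socioeconomic index
#'   is masked (exercises kriging imputation)
#' @param n_hospitals hospitals scattered per region
#' @param towns_per_district range of pseudo-towns per district (exercises
#'   the town-to-district join)
#' @param seed integer seed
#' @export
cohort_spec <- function(n_patients = 4412, n_west = 87, n_east = 57,
                        cell = 30000,
                        covariates = default_covariate_scheme(),
                        beta = c("age" = 0.15, "sex:Male" = 0.05,
                                 "stage:StageIV" = 0.9),
                        baseline = baseline_exponential(rate = 4e-4),
                        sigma2 = 0.25, phi = 50000,
                        censor_time = 2192, se_missing_frac = 0.06,
                        n_hospitals = 60,
                        towns_per_district = c(3L, 6L), seed = 1) {
  stopifnot(censor_time > 0, n_patients >= 1, sigma2 > 0, phi > 0,
            inherits(baseline, "baseline_hazard"))
  for (cv in covariates)
    if (cv$type == "factor" && abs(sum(cv$prob) - 1) > 1e-8)
      stop("factor level probabilities must sum to 1")
  structure(list(n_patients = n_patients, n_west = n_west, n_east = n_east,
                 cell = cell, covariates = covariates, beta = beta,
                 baseline = baseline, sigma2 = sigma2, phi = phi,
                 censor_time = censor_time,
                 se_missing_frac = se_missing_frac,
                 n_hospitals = n_hospitals,
                 towns_per_district = as.integer(towns_per_district),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a log-Gaussian frailty field over districts
#'
#' One draw from N(-sigma2/2, sigma2 exp(-d/phi)) via Cholesky, so the
#' multiplicative frailty exp(Y) has unit prior mean.
#'
#' @param map a [district_map]
#' @param sigma2 frailty variance > 0
#' @param phi correlation range (metres) > 0
#' @param seed optional seed (uses the current RNG stream when NULL)
#' @return named vector of per-district log frailties
#' @export
sample_frailty_field <- function(map, sigma2, phi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- centroid_distances(map)
  S <- covariance_matrix(D, spatial_correlation(sigma2, phi))
  L <- t(chol(S))
  y <- drop(-sigma2 / 2 + L %*% rnorm(nrow(D)))
  names(y) <- map$district_id
  y
}

#' Simulate right-censored survival times from the spatial PH model
#'
#' Inverse-transform sampling of T with cumulative hazard
#' H0(T) exp(lp) = -log U: closed-form inversion for the exponential and
#' Weibull families, numeric root-finding for the B-spline family. Events
#' after `censor_time` are administratively censored at `censor_time`.
#'
#' @param lp per-patient linear predictor x beta + Y_d
#' @param baseline the true `baseline_hazard`
#' @param censor_time administrative censoring time (days); `Inf` disables
#' @param seed optional seed
#' @return data.frame with columns `time` (> 0) and `status` (1 event,
#'   0 censored)
#' @export
simulate_survival <- function(lp, baseline, censor_time = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(lp)
  u <- runif(n)
  target <- -log(u) / exp(lp)   # H0(T) = target
  T <- switch(baseline$family,
    exponential = target / baseline$rate,
    weibull = (target / baseline$scale)^(1 / baseline$shape),
    bspline = {
      Hmax_t <- baseline$t_max
      vapply(target, function(tg) {
        f <- function(s) cumulative_baseline(s, baseline) - tg
        hi <- Hmax_t
        while (f(hi) < 0) hi <- hi * 2
        uniroot(f, c(0, hi), tol = 1e-8)$root
      }, numeric(1))
    })
  status <- as.integer(T <= censor_time)
  time <- pmin(T, censor_time)
  time <- pmax(time, .Machine$double.eps)
  data.frame(time = time, status = status)
}

sample_covariates <- function(n, scheme) {
  out <- list()
  for (nm in names(scheme)) {
    cv <- scheme[[nm]]
    out[[nm]] <- if (cv$type == "numeric")
      rnorm(n, cv$mean, cv$sd)
    else
      factor(sample(cv$levels, n, replace = TRUE, prob = cv$prob),
             levels = cv$levels)
  }
  as.data.frame(out)
}

# Smooth synthetic socioeconomic index: a broad spatial trend plus noise,
# z-scored so it is dimensionless and signed like the real index.
synthesise_se_index <- function(map) {
  x <- (map$cx - mean(map$cx)) / max(sd(map$cx), 1)
  y <- (map$cy - mean(map$cy)) / max(sd(map$cy), 1)
  v <- 0.8 * sin(x) + 0.6 * cos(1.3 * y) + 0.4 * x * y + rnorm(nrow(map), 0, 0.3)
  as.numeric(scale(v))
}

#' Generate a full synthetic registry cohort
#'
#' Builds grid district maps per region, pseudo-towns (3-6 per district),
#' a synthetic socioeconomic index with a masked fraction (to exercise
#' kriging), hospital point locations, a spatially correlated frailty
#' field, covariates with explicit missing levels, and right-censored
#' survival outcomes. The simulation truth (beta, baseline, sigma2, phi,
#' per-district Y) is returned separately from the patient table, which
#' shares no columns with the truth beyond `district_id`.
#'
#' @param spec a [cohort_spec]
#' @return object of class `synthetic_cohort`: list with `patients`
#'   (registry-style table: town, covariates, time, status), `maps` (list
#'   west/east of [district_map]), `lookup` ([town_lookup]), `se_index`
#'   (district_id, value with NA for masked), `hospitals` (x, y, region),
#'   `truth` (list incl. per-district frailty data.frame) and `spec`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  grid_dims <- function(n) {
    nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx); c(nx, ny)
  }
  gw <- grid_dims(spec$n_west); ge <- grid_dims(spec$n_east)
  west <- make_grid_map(gw[1], gw[2], spec$cell, region = "west",
                        id_prefix = "W", n_keep = spec$n_west)
  # east region offset well away from west (physically separated regions)
  east <- make_grid_map(ge[1], ge[2], spec$cell, region = "east",
                        origin = c((gw[1] + 10) * spec$cell, 0),
                        id_prefix = "E", n_keep = spec$n_east)
  maps <- list(west = west, east = east)
  all_ids <- c(west$district_id, east$district_id)
  m <- length(all_ids)

  # pseudo-towns
  n_towns <- sample(seq(spec$towns_per_district[1],
                        spec$towns_per_district[2]),
                    m, replace = TRUE)
  town_names <- unlist(mapply(function(id, k)
    sprintf("Town %s %02d", id, seq_len(k)), all_ids, n_towns,
    SIMPLIFY = FALSE))
  town_district <- rep(all_ids, n_towns)
  lookup <- town_lookup(town_names, town_district, map = all_ids)

  # frailty field per region (regions are modelled separately; independent)
  Yw <- sample_frailty_field(west, spec$sigma2, spec$phi)
  Ye <- sample_frailty_field(east, spec$sigma2, spec$phi)
  Y <- c(Yw, Ye)

  # patients: district proportional to a mild population gradient
  wpop <- exp(rnorm(m, 0, 0.5))
  district <- sample(all_ids, spec$n_patients, replace = TRUE,
                     prob = wpop / sum(wpop))
  town <- vapply(district, function(d) {
    cand <- town_names[town_district == d]
    cand[sample.int(length(cand), 1)]
  }, character(1))

  covs <- sample_covariates(spec$n_patients, spec$covariates)
  X <- build_design_matrix(covs, names(spec$covariates))
  beta_full <- setNames(numeric(ncol(X)), colnames(X))
  unknown <- setdiff(names(spec$beta), colnames(X))
  if (length(unknown))
    stop("true beta name(s) not in design matrix: ",
         paste(unknown, collapse = ", "))
  beta_full[names(spec$beta)] <- spec$beta

  lp <- drop(X %*% beta_full) + Y[district]
  surv <- simulate_survival(lp, spec$baseline, spec$censor_time)

  patients <- cbind(data.frame(patient_id = sprintf("P%05d",
                                                    seq_len(spec$n_patients)),
                               town = town, district_id = district,
                               stringsAsFactors = FALSE),
                    covs, surv)

  # socioeconomic index (per district) with a masked fraction
  se_val <- synthesise_se_index(rbind_maps_df(maps))
  n_mask <- max(1L, round(spec$se_missing_frac * m))
  masked <- sample(m, n_mask)
  se_index <- data.frame(district_id = all_ids, value = se_val)
  se_index$value[masked] <- NA

  # hospitals: uniform over each region's bounding box
  hosp <- do.call(rbind, lapply(maps, function(mp) {
    k <- spec$n_hospitals
    data.frame(x = runif(k, min(mp$cx) - spec$cell / 2,
                         max(mp$cx) + spec$cell / 2),
               y = runif(k, min(mp$cy) - spec$cell / 2,
                         max(mp$cy) + spec$cell / 2),
               region = mp$region[1])
  }))
  rownames(hosp) <- NULL

  truth <- list(beta = beta_full, baseline = spec$baseline,
                sigma2 = spec$sigma2, phi = spec$phi,
                frailty = data.frame(district_id = all_ids, Y = unname(Y)),
                se_index_true = data.frame(district_id = all_ids,
                                           value = se_val))
  structure(list(patients = patients, maps = maps, lookup = lookup,
                 se_index = se_index, hospitals = hosp, truth = truth,
                 spec = spec),
            class = "synthetic_cohort")
}

# stack the map data.frames (no geometry needed) for field synthesis
rbind_maps_df <- function(maps) {
  do.call(rbind, lapply(maps, as.data.frame))
}

#' Build a [survival_dataset] for one region of a cohort
#'
#' @param cohort a `synthetic_cohort`
#' @param region `"west"` or `"east"`
#' @param covariates covariate columns to include (default: all in the
#'   spec's scheme)
#' @return list with `data` (a [survival_dataset]), `D` (distance matrix),
#'   `X_names`, and the region `map`
#' @export
cohort_region_dataset <- function(cohort, region = "west",
                                  covariates = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  map <- cohort$maps[[region]]
  if (is.null(covariates)) covariates <- names(cohort$spec$covariates)
  pat <- cohort$patients[cohort$patients$district_id %in% map$district_id, ]
  X <- build_design_matrix(pat, covariates)
  ds <- survival_dataset(pat$time, pat$status, X, pat$district_id,
                         map$district_id)
  list(data = ds, D = centroid_distances(map), X_names = colnames(X),
       map = map)
}

#' Write a synthetic cohort to a seeded output directory
#'
#' Patient table, per-region GeoJSON maps, socioeconomic-index table (with
#' masked entries as NA), hospital table, town lookup and the truth file,
#' all as plain text. Truth and data share no columns beyond district ids.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory
#' @return invisible vector of files written
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    patients = file.path(dir, "patients.tsv"),
    se = file.path(dir, "se_index.tsv"),
    hosp = file.path(dir, "hospitals.tsv"),
    lookup = file.path(dir, "town_lookup.tsv"),
    truth_frailty = file.path(dir, "truth_frailty.tsv"),
    truth_params = file.path(dir, "truth_params.tsv"))
  wt <- function(x, f) write.table(x, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(cohort$patients, files["patients"])
  wt(cohort$se_index, files["se"])
  wt(cohort$hospitals, files["hosp"])
  wt(data.frame(town = names(cohort$lookup),
                district_id = unname(cohort$lookup)), files["lookup"])
  wt(cohort$truth$frailty, files["truth_frailty"])
  bl <- unlist(cohort$truth$baseline[setdiff(names(cohort$truth$baseline),
                                             "family")])
  wt(data.frame(parameter = c(names(cohort$truth$beta), "sigma2", "phi",
                              paste0("baseline_", names(bl))),
                value = c(unname(cohort$truth$beta), cohort$truth$sigma2,
                          cohort$truth$phi, unname(bl))),
     files["truth_params"])
  for (rg in names(cohort$maps)) {
    f <- file.path(dir, sprintf("districts_%s.geojson", rg))
    write_district_geojson(cohort$maps[[rg]], f)
    files[paste0("map_", rg)] <- f
  }
  invisible(files)
}
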