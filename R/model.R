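# Spatial proportional-hazards model with district-level log-Gaussian
# frailties: h(t_i) = h0(t_i; omega) exp(x_i beta + Y_{d(i)}), where the
# frailty vector Y over districts is multivariate normal with covariance
# sigma2 * exp(-d/phi) on centroid distances d, and prior mean -sigma2/2 so
# that the multiplicative frailty exp(Y) has unit prior mean (this separates
# the frailty level from the baseline scale, which are otherwise confounded).

#' Exponential spatial correlation
#'
#' rho(d) = exp(-d / range): correlation e^-1 at distance `range`, little
#' dependence well beyond it.
#'
#' @param d nonnegative distances (metres)
#' @param range correlation range parameter (metres), > 0
#' @export
correlation <- function(d, range) {
  if (any(d < 0)) stop("negative distance")
  if (range <= 0) stop("range must be > 0")
  exp(-d / range)
}

#' Spatial correlation (frailty covariance) parameters
#' @param sigma2 frailty variance > 0
#' @param range correlation range (metres) > 0
#' @export
spatial_correlation <- function(sigma2, range) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (range <= 0) stop("range must be > 0")
  structure(list(sigma2 = sigma2, range = range),
            class = "spatial_correlation")
}

#' Frailty covariance matrix sigma2 * exp(-d/range)
#'
#' If the Cholesky factorisation fails numerically, a diagonal jitter is
#' escalated (1e-10, 1e-8, ... times sigma2) until it succeeds; the jitter
#' used is recorded in the `jitter` attribute and reported via a message.
#'
#' @param D symmetric distance matrix (metres)
#' @param corr a [spatial_correlation]
#' @return covariance matrix with attribute `jitter`
#' @export
covariance_matrix <- function(D, corr) {
  stopifnot(inherits(corr, "spatial_correlation"))
  S <- corr$sigma2 * correlation(D, corr$range)
  jit <- 0
  for (j in c(0, 10^seq(-10, -4, by = 2))) {
    ok <- tryCatch({ chol(S + diag(j * corr$sigma2, nrow(S))); TRUE },
                   error = function(e) FALSE)
    if (ok) { jit <- j * corr$sigma2; break }
    if (j == 1e-4) stop("covariance matrix not positive definite after jitter")
  }
  if (jit > 0) {
    message("covariance_matrix: added diagonal jitter ", jit)
    S <- S + diag(jit, nrow(S))
  }
  attr(S, "jitter") <- jit
  S
}

#' Construct a spatial proportional-hazards model
#'
#' @param beta covariate effects on the log hazard-ratio scale
#' @param baseline a `baseline_hazard` (see [baseline_exponential])
#' @param corr a [spatial_correlation]
#' @param Y per-district log-frailty values
#' @export
spatial_ph_model <- function(beta, baseline, corr, Y) {
  stopifnot(inherits(baseline, "baseline_hazard"),
            inherits(corr, "spatial_correlation"))
  structure(list(beta = as.numeric(beta), baseline = baseline, corr = corr,
                 Y = as.numeric(Y)),
            class = "spatial_ph_model")
}

#' Construct a survival dataset
#'
#' @param time follow-up times in days, > 0
#' @param status event indicator: 1 = dead, 0 = censored
#' @param X numeric design matrix (n x p); p may be 0
#' @param district per-patient district index (1-based) or district id
#'   matching `district_ids`
#' @param district_ids ordered district id vector defining the frailty index
#' @return object of class `survival_dataset`
#' @export
survival_dataset <- function(time, status, X, district, district_ids) {
  n <- length(time)
  X <- as.matrix(X)
  if (!all(time > 0)) stop("all follow-up times must be > 0")
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  if (nrow(X) != n) stop("X rows != number of patients")
  if (is.character(district) || is.factor(district)) {
    di <- match(as.character(district), district_ids)
    if (anyNA(di)) stop("unknown district id(s): ",
                        paste(unique(district[is.na(di)]), collapse = ", "))
  } else {
    di <- as.integer(district)
    if (any(di < 1 | di > length(district_ids)))
      stop("district index out of range")
  }
  structure(list(time = as.numeric(time), status = as.integer(status),
                 X = X, district = di,
                 district_ids = as.character(district_ids)),
            class = "survival_dataset")
}

#' Dummy-coded design matrix with explicit missing levels
#'
#' Categorical covariates are dummy coded against their first listed level
#' (the reference); `NA` values are folded into an explicit `"Missing"`
#' level, mirroring registry recoding practice. Numeric covariates are
#' z-scored by default.
#'
#' @param df patient data.frame
#' @param covariates character vector of column names to include
#' @param standardise z-score numeric columns (centre/scale stored in
#'   attributes `centre` and `scale`)
#' @return numeric design matrix with descriptive column names
#' @export
build_design_matrix <- function(df, covariates, standardise = TRUE) {
  cols <- list(); centres <- c(); scales <- c()
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.null(x)) stop("covariate '", cv, "' not found")
    if (is.numeric(x)) {
      ctr <- if (standardise) mean(x) else 0
      scl <- if (standardise && sd(x) > 0) sd(x) else 1
      cols[[cv]] <- matrix((x - ctr) / scl, ncol = 1,
                           dimnames = list(NULL, cv))
      centres[cv] <- ctr; scales[cv] <- scl
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "Missing"
      levs <- if (is.factor(df[[cv]]))
        union(levels(df[[cv]]), unique(x)) else unique(x)
      f <- factor(x, levels = levs)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, ":", levs[-1])
      cols[[cv]] <- mm
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "centre") <- centres
  attr(out, "scale") <- scales
  out
}

#' Log-likelihood of the spatial proportional-hazards model
#'
#' sum_i [ delta_i (log h0(t_i) + x_i beta + Y_d(i))
#'         - H0(t_i) exp(x_i beta + Y_d(i)) ]
#'
#' @param data a [survival_dataset]
#' @param model a [spatial_ph_model]
#' @return scalar log-likelihood (finite for valid parameters)
#' @export
log_likelihood <- function(data, model) {
  stopifnot(inherits(data, "survival_dataset"),
            inherits(model, "spatial_ph_model"))
  if (length(data$time) == 0) stop("empty dataset")
  if (length(model$beta) != ncol(data$X))
    stop("dimension mismatch: length(beta) != ncol(X)")
  if (length(model$Y) != length(data$district_ids))
    stop("dimension mismatch: length(Y) != number of districts")
  lp <- drop(data$X %*% model$beta) + model$Y[data$district]
  h0 <- baseline_hazard(data$time, model$baseline)
  H0 <- cumulative_baseline(data$time, model$baseline)
  ll_i <- data$status * (log(h0) + lp) - H0 * exp(lp)
  if (any(!is.finite(ll_i)))
    stop("nonfinite log-likelihood contribution at patient index ",
         which(!is.finite(ll_i))[1])
  sum(ll_i)
}

#' Prior specification for the spatial survival model
#'
#' Defaults: independent zero-mean normals with standard deviation 10 on
#' beta; normals with standard deviation 2 on log omega, log sigma2 and
#' log phi. The log-phi prior mean is typically set to the log median
#' inter-centroid distance at fit time (weakly informative on the map's own
#' scale). Alternatively, `lambda_gamma = c(shape, rate)` replaces the
#' log-normal prior on the exponential baseline rate with a Gamma prior
#' (used by conjugate validation checks).
#'
#' @param beta_sd sd of the normal prior on each beta component
#' @param omega_mean,omega_sd mean/sd of normals on the log baseline
#'   parameters (recycled); `omega_mean = NA` (default) means "centre at the
#'   non-spatial maximum-likelihood prefit at fit time". Baseline scales in
#'   day units sit many prior sds from zero, so a zero-centred prior would
#'   push the baseline level into the frailty field through the known
#'   baseline/frailty confounding
#' @param sigma2_mean,sigma2_sd mean/sd of the normal on log sigma2
#' @param phi_mean,phi_sd mean/sd of the normal on log phi (metres);
#'   `phi_mean = NA` means "set to log median distance at fit time"
#' @param lambda_gamma optional c(shape, rate) Gamma prior on the
#'   exponential baseline rate
#' @export
ph_priors <- function(beta_sd = 10, omega_mean = NA_real_, omega_sd = 2,
                      sigma2_mean = log(0.1), sigma2_sd = 2,
                      phi_mean = NA_real_, phi_sd = 2,
                      lambda_gamma = NULL) {
  pr <- list(beta_sd = beta_sd, omega_mean = omega_mean, omega_sd = omega_sd,
             sigma2_mean = sigma2_mean, sigma2_sd = sigma2_sd,
             phi_mean = phi_mean, phi_sd = phi_sd,
             lambda_gamma = lambda_gamma)
  for (nm in setdiff(names(pr), c("lambda_gamma", "phi_mean", "omega_mean")))
    if (is.null(pr[[nm]]) || anyNA(pr[[nm]]))
      stop("unspecified prior component: ", nm)
  structure(pr, class = "ph_priors")
}

#' Multivariate normal log-density of the frailty vector
#'
#' The frailty prior mean is -sigma2/2 (so E[exp(Y)] = 1), with sigma2 read
#' off the diagonal of `Sigma`.
#'
#' @param Y frailty vector
#' @param Sigma frailty covariance matrix
#' @export
frailty_log_density <- function(Y, Sigma) {
  m <- length(Y)
  stopifnot(nrow(Sigma) == m, ncol(Sigma) == m)
  sigma2 <- Sigma[1, 1]
  ctr <- Y + sigma2 / 2
  L <- chol(Sigma)
  z <- backsolve(L, ctr, transpose = TRUE)
  -0.5 * m * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Joint log-prior of a spatial PH model
#'
#' Sum of the independent prior log-densities for beta, log omega,
#' log sigma2 and log phi, plus the multivariate-normal log-density of the
#' frailty vector under the model's own covariance (prior mean -sigma2/2).
#'
#' @param model a [spatial_ph_model]
#' @param priors a [ph_priors]
#' @param D distance matrix for the frailty covariance
#' @export
log_prior <- function(model, priors, D) {
  stopifnot(inherits(priors, "ph_priors"))
  lw <- baseline_to_logomega(model$baseline)
  if (anyNA(priors$phi_mean))
    stop("unspecified prior component: phi_mean (set it, e.g. to the log ",
         "median inter-centroid distance)")
  lp <- sum(dnorm(model$beta, 0, priors$beta_sd, log = TRUE))
  if (!is.null(priors$lambda_gamma)) {
    if (model$baseline$family != "exponential")
      stop("lambda_gamma prior applies to the exponential family only")
    a <- priors$lambda_gamma[1]; b <- priors$lambda_gamma[2]
    # Gamma(a, b) density in lambda, with Jacobian d lambda / d log lambda
    lp <- lp + a * lw[1] - b * exp(lw[1]) + a * log(b) - lgamma(a)
  } else {
    if (anyNA(priors$omega_mean))
      stop("unspecified prior component: omega_mean (NA is resolved to the ",
           "non-spatial prefit only inside run_mcmc)")
    lp <- lp + sum(dnorm(lw, priors$omega_mean, priors$omega_sd, log = TRUE))
  }
  lp <- lp + dnorm(log(model$corr$sigma2), priors$sigma2_mean,
                   priors$sigma2_sd, log = TRUE)
  lp <- lp + dnorm(log(model$corr$range), priors$phi_mean, priors$phi_sd,
                   log = TRUE)
  S <- covariance_matrix(D, model$corr)
  lp + frailty_log_density(model$Y, S)
}

#' Survival function S(t) = exp(-H0(t) exp(x beta + Y))
#' @param t times
#' @param baseline a `baseline_hazard`
#' @param lp linear predictor x beta + Y (scalar)
#' @export
survival_function <- function(t, baseline, lp = 0) {
  exp(-cumulative_baseline(t, baseline) * exp(lp))
}
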