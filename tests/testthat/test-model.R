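test_that("baseline hazards: closed forms and limits", {
  # weibull alpha=1 reduces to exponential
  w1 <- baseline_weibull(1, 0.2)
  expect_equal(baseline_hazard(3, w1), 0.2)
  expect_equal(cumulative_baseline(3, w1), 0.6)
  # closed form alpha=2, lambda=0.5, t=2: h0 = 2*0.5*2 = 2, H0 = 0.5*4 = 2
  w2 <- baseline_weibull(2, 0.5)
  expect_equal(baseline_hazard(2, w2), 2)
  expect_equal(cumulative_baseline(2, w2), 2)
  expect_error(baseline_hazard(-1, w2), "negative")
})

test_that("weibull/exponential H0 agree with quadrature of h0", {
  for (b in list(baseline_exponential(0.3), baseline_weibull(1.7, 0.04),
                 baseline_weibull(0.8, 0.5))) {
    for (tt in c(0.5, 2, 7)) {
      q <- integrate(function(u) baseline_hazard(u, b), 0, tt,
                     rel.tol = 1e-10)$value
      expect_equal(cumulative_baseline(tt, b), q, tolerance = 1e-8)
    }
  }
})

test_that("bspline baseline: H0 matches quadrature, monotone, positive", {
  set.seed(4)
  for (r in 1:5) {
    b <- baseline_bspline(coef = rnorm(7, -1, 0.8),
                          knots = c(2, 5, 8), t_max = 10)
    tt <- sort(runif(6, 0.1, 12))  # includes beyond t_max
    H <- cumulative_baseline(tt, b)
    expect_true(all(diff(H) > 0))
    expect_equal(cumulative_baseline(0, b), 0)
    for (t1 in tt[tt <= 10]) {
      q <- integrate(function(u) baseline_hazard(u, b), 0, t1,
                     rel.tol = 1e-9, subdivisions = 400)$value
      expect_equal(cumulative_baseline(t1, b), q, tolerance = 1e-6)
    }
    expect_true(all(baseline_hazard(tt, b) > 0))
  }
})

test_that("exponential correlation and covariance matrix", {
  expect_equal(correlation(0, 123), 1)
  # at d = range the correlation is e^-1 (the range interpretation)
  expect_equal(correlation(16384, 16384), exp(-1), tolerance = 1e-12)
  expect_error(correlation(1, -5), "range")
  expect_error(spatial_correlation(-0.1, 5), "sigma2")
  set.seed(12)
  xy <- matrix(runif(20, 0, 1e5), ncol = 2)
  D <- as.matrix(dist(xy))
  corr <- spatial_correlation(0.7, 3e4)
  S <- covariance_matrix(D, corr)
  # elementwise oracle
  expect_equal(unname(S), 0.7 * exp(-unname(D) / 3e4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_no_error(chol(S))
})

test_that("log-likelihood: closed forms and invariances", {
  # one patient, delta=1, exponential lambda=1, x=0, Y=0, t=1 -> logL = -1
  d1 <- survival_dataset(1, 1, matrix(0, 1, 0), 1, "A")
  m1 <- spatial_ph_model(numeric(0), baseline_exponential(1),
                         spatial_correlation(0.1, 1), 0)
  expect_equal(log_likelihood(d1, m1), -1)

  # beta=0, Y=0 exponential: censored-exponential closed form
  set.seed(8)
  tt <- rexp(60, 0.3); dd <- rbinom(60, 1, 0.7)
  ds <- survival_dataset(tt, dd, matrix(rnorm(120), 60, 2),
                         sample(1:4, 60, TRUE), c("A", "B", "C", "D"))
  lam <- 0.42
  m <- spatial_ph_model(c(0, 0), baseline_exponential(lam),
                        spatial_correlation(0.1, 1), rep(0, 4))
  expect_equal(log_likelihood(ds, m),
               sum(dd) * log(lam) - lam * sum(tt), tolerance = 1e-12)

  # lambda/Y confounding: Y + log 2 with lambda/2 leaves logL unchanged
  m_a <- spatial_ph_model(c(0.3, -0.2), baseline_exponential(lam),
                          spatial_correlation(0.1, 1), rnorm(4))
  m_b <- spatial_ph_model(m_a$beta, baseline_exponential(lam / 2),
                          m_a$corr, m_a$Y + log(2))
  expect_equal(log_likelihood(ds, m_a), log_likelihood(ds, m_b),
               tolerance = 1e-10)

  # proportional hazards: scaling exp(x beta) by k scales h by k at all t
  h_at <- function(mult, t0) baseline_hazard(t0, m_a$baseline) * mult
  expect_equal(h_at(3 * exp(0.5), 2) / h_at(exp(0.5), 2), 3)

  # dimension mismatch errors
  expect_error(log_likelihood(ds, m1), "dimension mismatch")
})

test_that("likelihood reduces to the non-spatial PH likelihood as sigma2->0", {
  set.seed(10)
  n <- 80
  X <- matrix(rnorm(2 * n), n, 2)
  beta <- c(0.4, -0.3)
  tt <- rexp(n, 0.2 * exp(drop(X %*% beta)))
  dd <- rep(1L, n)
  ds <- survival_dataset(tt, dd, X, sample(1:5, n, TRUE), letters[1:5])
  b <- baseline_weibull(1.3, 0.1)
  # independently coded non-spatial parametric PH log-likelihood
  nonspatial <- function(beta) {
    lp <- drop(X %*% beta)
    sum(dd * (log(1.3 * 0.1 * tt^0.3) + lp) - 0.1 * tt^1.3 * exp(lp))
  }
  s2 <- 1e-10
  m <- spatial_ph_model(beta, b, spatial_correlation(s2, 1e4),
                        rep(-s2 / 2, 5))
  expect_equal(log_likelihood(ds, m), nonspatial(beta), tolerance = 1e-6)
})

test_that("survival function S(t): S(0)=1, monotone nonincreasing", {
  for (b in list(baseline_exponential(0.2), baseline_weibull(2, 0.05),
                 baseline_bspline(rep(-1.5, 7), c(2, 4, 6), 10))) {
    tg <- seq(0, 9, by = 0.5)
    S <- survival_function(tg, b, lp = 0.3)
    expect_equal(S[1], 1)
    expect_true(all(diff(S) <= 1e-12))
  }
})

test_that("frailty log-density: iid case and dense MVN oracle", {
  # Sigma = I sigma2 at the prior mean: product of univariate densities
  s2 <- 0.4; m <- 6
  Y <- rep(-s2 / 2, m)
  expect_equal(frailty_log_density(Y, diag(s2, m)),
               sum(dnorm(Y, -s2 / 2, sqrt(s2), log = TRUE)))
  # dense oracle with explicit inverse and determinant, random 8-district
  set.seed(14)
  for (r in 1:5) {
    xy <- matrix(runif(16, 0, 1e5), ncol = 2)
    S <- covariance_matrix(as.matrix(dist(xy)), spatial_correlation(0.6, 4e4))
    Y <- rnorm(8)
    mu <- rep(-0.6 / 2, 8)
    oracle <- -0.5 * (8 * log(2 * pi) + log(det(S)) +
                      drop(t(Y - mu) %*% solve(S) %*% (Y - mu)))
    expect_equal(frailty_log_density(Y, S), oracle, tolerance = 1e-8)
  }
})

test_that("priors: validation and log_prior composition", {
  expect_error(ph_priors(beta_sd = NA), "unspecified prior")
  pr <- ph_priors(phi_mean = log(5e4), omega_mean = 0)
  g <- grid9()
  D <- centroid_distances(g)
  m <- spatial_ph_model(c(0.1), baseline_exponential(0.2),
                        spatial_correlation(0.3, 5e4), rnorm(9, -0.15, 0.5))
  lp <- log_prior(m, pr, D)
  expect_true(is.finite(lp))
  # missing phi_mean errors when not resolvable
  expect_error(log_prior(m, ph_priors(omega_mean = 0), D), "phi_mean")
  # an unresolved (NA) omega_mean also errors outside run_mcmc
  expect_error(log_prior(m, ph_priors(phi_mean = 0), D), "omega_mean")
  # gamma prior on lambda restricted to the exponential family
  prg <- ph_priors(phi_mean = 0, lambda_gamma = c(2, 5))
  mw <- spatial_ph_model(c(0.1), baseline_weibull(1.5, 0.2), m$corr, m$Y)
  expect_error(log_prior(mw, prg, D), "exponential family")
})

test_that("design matrix: reference levels, explicit Missing, z-scoring", {
  df <- data.frame(age = c(50, 60, 70, 80),
                   stage = factor(c("I", "II", NA, "I"),
                                  levels = c("I", "II")))
  X <- build_design_matrix(df, c("age", "stage"))
  expect_equal(colnames(X), c("age", "stage:II", "stage:Missing"))
  expect_equal(mean(X[, "age"]), 0)
  expect_equal(sd(X[, "age"]), 1)
  # one dummy set per row sums to <= 1
  expect_true(all(rowSums(X[, -1, drop = FALSE]) <= 1))
  expect_equal(X[3, "stage:Missing"], 1, ignore_attr = TRUE)
})
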