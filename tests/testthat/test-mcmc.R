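# Sampler-level unit tests; the heavier distributional checks live in
# test-acceptance.R.

make_expo_data <- function(n = 120, lambda = 0.02, censor = 80, seed = 3) {
  set.seed(seed)
  T <- rexp(n, lambda)
  data.frame(time = pmin(T, censor), status = as.integer(T <= censor))
}

test_that("identical seeds give bitwise-identical chains", {
  co <- small_cohort(n = 200, m = 9)
  rd <- cohort_region_dataset(co, "west", covariates = "age")
  run <- function() run_mcmc(rd$data, ph_model_spec("exponential", rd$D),
                             settings = mcmc_settings(1500, 500, 2, seed = 99))
  c1 <- run(); c2 <- run()
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$ll, c2$ll)
})

test_that("invalid settings and initial states error clearly", {
  expect_error(mcmc_settings(1000, 1000), "n_burn")
  co <- small_cohort(n = 100, m = 4)
  rd <- cohort_region_dataset(co, "west", covariates = "age")
  expect_error(run_mcmc(rd$data,
                        ph_model_spec("exponential", rd$D[1:3, 1:3])),
               "distance matrix")
})

test_that("conjugate check: gamma-exponential posterior mean (single seed)", {
  d <- make_expo_data()
  ds <- survival_dataset(d$time, d$status, matrix(0, nrow(d), 0),
                         rep(1L, nrow(d)), "only")
  a <- 2; b <- 50
  post_mean <- (a + sum(d$status)) / (b + sum(d$time))  # closed form
  ch <- run_mcmc(ds,
                 ph_model_spec("exponential", matrix(0, 1, 1),
                               use_frailty = FALSE),
                 priors = ph_priors(phi_mean = 0, lambda_gamma = c(a, b)),
                 settings = mcmc_settings(12000, 2000, 5, seed = 17))
  lam <- exp(ch$draws[, "log_rate"])
  mcse <- sd(lam) / sqrt(ess(lam))
  expect_lt(abs(mean(lam) - post_mean), 3 * mcse + 1e-12)
})

test_that("prior-only run recovers prior quantiles (likelihood off)", {
  co <- small_cohort(n = 150, m = 9)
  rd <- cohort_region_dataset(co, "west", covariates = "age")
  pr <- ph_priors(beta_sd = 1.5, omega_mean = -6, omega_sd = 0.7,
                  sigma2_mean = -2, sigma2_sd = 0.8,
                  phi_mean = 11, phi_sd = 0.6)
  ch <- run_mcmc(rd$data,
                 ph_model_spec("exponential", rd$D, prior_only = TRUE),
                 priors = pr,
                 settings = mcmc_settings(30000, 5000, 5, seed = 4))
  qcheck <- function(x, mu, sdv) {
    e <- max(20, ess(x))
    tol <- 4 * sdv / sqrt(e)
    expect_lt(abs(mean(x) - mu), max(tol, 0.15 * sdv))
    expect_lt(abs(sd(x) - sdv), 0.25 * sdv)
  }
  qcheck(ch$draws[, "beta:age"], 0, 1.5)
  qcheck(ch$draws[, "log_rate"], -6, 0.7)
  qcheck(ch$draws[, "log_sigma2"], -2, 0.8)
  qcheck(ch$draws[, "log_phi"], 11, 0.6)
})

test_that("ESS: white noise, constant, AR(1) oracles", {
  set.seed(6)
  x <- rnorm(1000)
  expect_gt(ess(x), 800)
  expect_lt(ess(x), 1200)
  expect_equal(ess(rep(2, 500)), 1)
  # AR(1) rho = 0.9: ESS ~ n (1-rho)/(1+rho)
  n <- 20000; rho <- 0.9
  ar <- numeric(n); ar[1] <- rnorm(1)
  innov <- rnorm(n, 0, sqrt(1 - rho^2))
  for (i in 2:n) ar[i] <- rho * ar[i - 1] + innov[i]
  target <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(ess(ar) - target) / target, 0.3)
})

test_that("diagnostics flag bad chains and summarise good ones", {
  set.seed(13)
  draws <- cbind(good = rnorm(500), stuck = rep(1, 500))
  dg <- diagnostics(draws, ess_floor = 100)
  expect_false(dg$low_ess[dg$parameter == "good"])
  expect_true(dg$low_ess[dg$parameter == "stuck"])
  expect_error(diagnostics(draws[1:50, ]), "at least 100")
})

test_that("density overlap: identity, separation, symmetry", {
  set.seed(15)
  x <- rnorm(4000); y <- rnorm(4000)
  expect_gt(density_overlap(x, y), 0.9)             # same distribution
  z <- rnorm(4000, 8, 0.3)                          # far-apart posterior
  expect_lt(density_overlap(x, z), 0.2)
  # oracle: overlap of N(0,1) and N(2,1) = 2*pnorm(-1) ~ 0.3173
  a <- rnorm(20000); b <- rnorm(20000, 2, 1)
  expect_equal(density_overlap(a, b), 2 * pnorm(-1), tolerance = 0.05)
  expect_equal(density_overlap(a, b), density_overlap(b, a),
               tolerance = 1e-12)
})

test_that("prior_posterior_compare: no-data run overlaps ~1, flags", {
  co <- small_cohort(n = 150, m = 9)
  rd <- cohort_region_dataset(co, "west", covariates = "age")
  pr <- ph_priors(beta_sd = 1, omega_mean = -6, omega_sd = 0.7,
                  sigma2_mean = -2, sigma2_sd = 0.8,
                  phi_mean = 11, phi_sd = 0.6)
  ch <- run_mcmc(rd$data,
                 ph_model_spec("exponential", rd$D, prior_only = TRUE),
                 priors = pr,
                 settings = mcmc_settings(30000, 5000, 5, seed = 5))
  pp <- prior_posterior_compare(ch, pr)
  expect_true(all(pp$overlap > 0.85))
  expect_true(all(pp$weakly_identified))
  # informative data: the baseline rate must be identified (low overlap is
  # not required, but well below 1)
  ch2 <- run_mcmc(rd$data, ph_model_spec("exponential", rd$D),
                  priors = pr,
                  settings = mcmc_settings(4000, 1000, 3, seed = 5))
  pp2 <- prior_posterior_compare(ch2, pr)
  expect_lt(pp2$overlap[pp2$parameter == "log_rate"], 0.5)
})

test_that("WAIC: hand-computed oracle and degenerate draws", {
  # 3 patients x 4 draws, hand-computed lppd / p_waic
  ll <- matrix(c(-1.0, -1.2, -0.8, -1.1,
                 -2.0, -2.1, -1.9, -2.2,
                 -0.5, -0.4, -0.6, -0.5), nrow = 3, byrow = TRUE)
  lppd <- sum(log(rowMeans(exp(ll))))
  p_waic <- sum(apply(ll, 1, var))
  w <- compute_waic(ll)
  expect_equal(w$lppd, lppd, tolerance = 1e-10)
  expect_equal(w$p_waic, p_waic, tolerance = 1e-10)
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-10)
  # identical draws: p_waic = 0, waic = -2 sum ll
  ll0 <- matrix(rep(c(-1, -3, -0.2), 5), nrow = 3)
  w0 <- compute_waic(ll0)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * sum(c(-1, -3, -0.2)))
  expect_error(compute_waic(ll[, 1, drop = FALSE]), "at least 2")
})

test_that("WAIC is invariant to thinning beyond Monte-Carlo error", {
  co <- small_cohort(n = 250, m = 9)
  rd <- cohort_region_dataset(co, "west", covariates = "age")
  ch <- run_mcmc(rd$data, ph_model_spec("exponential", rd$D),
                 settings = mcmc_settings(12000, 2000, 2, seed = 8))
  w_all <- compute_waic(ch)
  w_thin <- compute_waic(ch$ll[, seq(1, ncol(ch$ll), by = 5)])
  expect_lt(abs(w_all$waic - w_thin$waic) / abs(w_all$waic), 0.02)
})

test_that("posterior contraction: doubling n shrinks beta CRI width", {
  widths <- sapply(c(200, 800), function(n) {
    co <- small_cohort(n = n, m = 9, seed = 31)
    rd <- cohort_region_dataset(co, "west", covariates = "age")
    ch <- run_mcmc(rd$data, ph_model_spec("exponential", rd$D),
                   settings = mcmc_settings(6000, 2000, 4, seed = 2))
    diff(quantile(ch$draws[, "beta:age"], c(0.025, 0.975)))
  })
  expect_lt(widths[2], widths[1])
})

test_that("chain serialisation is deterministic text", {
  co <- small_cohort(n = 100, m = 4)
  rd <- cohort_region_dataset(co, "west", covariates = "age")
  ch <- run_mcmc(rd$data, ph_model_spec("exponential", rd$D),
                 settings = mcmc_settings(800, 300, 1, seed = 1))
  f1 <- tempfile(); f2 <- tempfile()
  write_chain(ch, f1); write_chain(ch, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[1], "seed=1")
})
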