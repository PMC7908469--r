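# Posterior post-processing: HR tables, correlation curves, exceedance
# surfaces, choropleth export, baseline curves. A fabricated chain object
# with controlled draws drives most tests.

fake_chain <- function(S = 500, districts = c("A", "B", "C"), seed = 2,
                       beta_draws = NULL, phi_draws = NULL, Y_draws = NULL,
                       family = "exponential") {
  set.seed(seed)
  m <- length(districts)
  if (is.null(beta_draws))
    beta_draws <- matrix(rnorm(S, 0, 0.1), S, 1,
                         dimnames = list(NULL, "beta:x"))
  if (is.null(phi_draws)) phi_draws <- exp(rnorm(S, 10, 0.2))
  if (is.null(Y_draws))
    Y_draws <- matrix(rnorm(S * m, 0, 0.3), S, m)
  colnames(Y_draws) <- paste0("Y:", districts)
  draws <- cbind(beta_draws,
                 log_rate = rnorm(S, -6, 0.05),
                 log_sigma2 = rnorm(S, -2, 0.1),
                 log_phi = log(phi_draws), Y_draws)
  structure(list(draws = draws, ll = NULL,
                 accept = list(), settings = mcmc_settings(10, 1, 1, 1),
                 baseline_family = family, knots = NULL, t_max = 100,
                 district_ids = districts,
                 beta_names = sub("^beta:", "", colnames(beta_draws)),
                 priors = ph_priors(phi_mean = 10), phi_mean_used = 10,
                 jitter_max = 0, use_frailty = TRUE),
            class = "spfrail_chain")
}

test_that("hazard_ratio_table: degenerate, constructed and sort oracle", {
  # all-zero draws -> HR 1 (1,1), not significant
  ch0 <- fake_chain(beta_draws = matrix(0, 500, 1,
                                        dimnames = list(NULL, "beta:x")))
  hr0 <- hazard_ratio_table(ch0)
  expect_equal(hr0$hr_median, 1)
  expect_equal(hr0$hr_lower, 1)
  expect_false(hr0$significant)
  # draws ~ N(log 2, tiny) -> HR ~ 2, significant
  ch2 <- fake_chain(beta_draws = matrix(rnorm(500, log(2), 0.01), 500, 1,
                                        dimnames = list(NULL, "beta:x")))
  hr2 <- hazard_ratio_table(ch2)
  expect_equal(hr2$hr_median, 2, tolerance = 0.02)
  expect_true(hr2$significant)
  # quantiles match a brute-force sort of exponentiated draws
  b <- matrix(rnorm(501, 0.3, 0.5), 501, 1,
              dimnames = list(NULL, "beta:x"))
  ch <- fake_chain(S = 501, beta_draws = b)
  hr <- hazard_ratio_table(ch)
  srt <- sort(exp(b[, 1]))
  expect_equal(hr$hr_median, quantile(srt, 0.5, names = FALSE))
  expect_equal(hr$hr_lower, quantile(srt, 0.025, names = FALSE))
  expect_equal(hr$hr_upper, quantile(srt, 0.975, names = FALSE))
  expect_true(all(hr$hr_lower <= hr$hr_median & hr$hr_median <= hr$hr_upper))
  # absent covariate errors
  expect_error(hazard_ratio_table(ch, covariates = "nope"), "absent")
})

test_that("correlation_curve: d=0 is 1, fixed-phi value, sort oracle", {
  ch <- fake_chain(phi_draws = rep(16384, 500))
  cc <- correlation_curve(ch, c(0, 16384, 17000))
  expect_equal(cc$median[cc$d == 0], 1)
  expect_equal(cc$median[cc$d == 16384], exp(-1), tolerance = 1e-12)
  # the "high correlation within ~17 km" regime boundary
  expect_equal(cc$median[cc$d == 17000], exp(-17000 / 16384),
               tolerance = 1e-12)
  # random phi draws: band matches per-draw evaluation + sort
  ch2 <- fake_chain(seed = 3)
  phi <- exp(ch2$draws[, "log_phi"])
  cc2 <- correlation_curve(ch2, c(5000, 20000))
  for (i in 1:2) {
    r <- exp(-cc2$d[i] / phi)
    expect_equal(cc2$median[i], quantile(r, 0.5, names = FALSE))
    expect_equal(cc2$lower[i], quantile(r, 0.025, names = FALSE))
    expect_equal(cc2$upper[i], quantile(r, 0.975, names = FALSE))
  }
  # median curve nonincreasing over a fine grid
  cc3 <- correlation_curve(ch2, seq(0, 1e5, length.out = 40))
  expect_true(all(diff(cc3$median) <= 1e-12))
})

test_that("exceedance probabilities: degenerate draws, counting oracle,
           monotonicity", {
  # district A pinned at exp(Y) = 1.2
  Y <- cbind(rep(log(1.2), 400), rnorm(400, 0, 0.2), rnorm(400, 0.1, 0.3))
  ch <- fake_chain(S = 400, Y_draws = Y)
  es <- exceedance_probability(ch, thresholds = c(1.1, 1.25))
  expect_equal(es$p_exc_1.1[es$district_id == "A"], 1)
  expect_equal(es$p_exc_1.25[es$district_id == "A"], 0)
  # tiny threshold: probability 1 everywhere
  es0 <- exceedance_probability(ch, thresholds = 1e-4)
  expect_true(all(es0[["p_exc_0.0001"]] == 1))
  # counting oracle + monotone in threshold
  es2 <- exceedance_probability(ch, thresholds = c(1.05, 1.1, 1.5))
  for (j in 1:3) {
    cnt <- mean(exp(Y[, j]) > 1.05)
    expect_equal(es2$p_exc_1.05[j], cnt)
  }
  expect_true(all(es2$p_exc_1.05 >= es2$p_exc_1.1))
  expect_true(all(es2$p_exc_1.1 >= es2$p_exc_1.5))
  expect_error(exceedance_probability(ch, thresholds = c(1.1, -2)), "> 0")
})

test_that("export_risk_map: GeoJSON round-trip, binning oracle, mismatch", {
  g <- grid9()
  ch <- fake_chain(S = 200, districts = g$district_id, seed = 9,
                   Y_draws = matrix(rnorm(200 * 9, 0, 0.4), 200, 9))
  es <- exceedance_probability(ch, thresholds = c(1.1, 1.25))
  out <- tempfile()
  files <- export_risk_map(es, g, out)
  gj <- jsonlite::read_json(file.path(out, "exceedance.geojson"))
  expect_length(gj$features, 9)
  got <- vapply(gj$features, function(f) f$properties[["p_exc_1.1"]], 0)
  ids <- vapply(gj$features, function(f) f$properties$district_id, "")
  expect_equal(got[match(es$district_id, ids)], es$p_exc_1.1,
               tolerance = 1e-9)
  # binning oracle against the break list
  breaks <- c(0, 0.25, 0.5, 0.75, 1)
  bins <- vapply(gj$features, function(f) f$properties[["bin_1.1"]], 0L)
  oracle <- vapply(got, function(p) {
    b <- max(which(p >= breaks[-length(breaks)])); b }, 0L)
  expect_equal(bins, oracle)
  # PNG written per threshold
  expect_true(file.exists(file.path(out, "exceedance_1.1.png")))
  expect_true(file.exists(file.path(out, "exceedance_1.25.png")))
  # district in surface but not in map errors
  es_bad <- es; es_bad$district_id[1] <- "GHOST"
  attr(es_bad, "thresholds") <- attr(es, "thresholds")
  class(es_bad) <- class(es)
  expect_error(export_risk_map(es_bad, g, tempfile()), "GHOST")
})

test_that("baseline_curves: linearity for exponential, H0(0)=0, sort oracle", {
  ch <- fake_chain(S = 300)
  tg <- c(0, 10, 20, 40)
  bc <- baseline_curves(ch, tg)
  expect_equal(bc$H0$median[1], 0)
  expect_true(all(diff(bc$H0$median) >= 0))
  # exponential: H0 median is lambda_median * t (straight line thru origin)
  lam <- exp(ch$draws[, "log_rate"])
  expect_equal(bc$H0$median, quantile(lam, 0.5, names = FALSE) * tg,
               tolerance = 1e-10)
  # band matches per-draw evaluation + sort
  expect_equal(bc$h0$lower, quantile(lam, 0.025, names = FALSE) * rep(1, 4),
               tolerance = 1e-10)
})
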