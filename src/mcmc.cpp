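// Blockwise adaptive random-walk Metropolis sampler for the spatial
// proportional-hazards model with district-level log-Gaussian frailties.
//
// Parameter blocks:
//   beta            covariate effects (adaptive MVN random walk)
//   log omega       baseline-hazard parameters (adaptive MVN random walk)
//   v               whitened frailties, Y = -sigma2/2 + L v with
//                   L L' = sigma2 exp(-D/phi)  (non-centred parameterisation:
//                   proposing in the Cholesky-decorrelated space)
//   (log s2, log phi) spatial covariance parameters; updating them moves Y
//                   through the non-centred map while v keeps a standard
//                   normal prior
//
// The likelihood factorises so that frailty/covariance updates only touch
// district-level aggregates E_j = sum delta_i and
// S_j = sum H0(t_i) exp(x_i beta): full log-likelihood =
//   C1 + sum_j E_j Y_j - sum_j S_j exp(Y_j),
//   C1 = sum_i delta_i (log h0(t_i) + x_i beta).
//
// All randomness comes from R's RNG, so chains are reproducible (bitwise)
// given set.seed(). Proposal scales adapt by Robbins-Monro toward 0.234
// (multivariate blocks) / 0.44 (scalar blocks) and freeze after burn-in so
// the retained chain is Markovian.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// Cholesky with escalating diagonal jitter; returns false if it never works.
static bool chol_jitter(const arma::mat &S, arma::mat &L, double &jit_used) {
  jit_used = 0.0;
  if (arma::chol(L, S, "lower")) return true;
  double s2 = S(0, 0);
  for (double j = 1e-10; j <= 1e-4; j *= 100) {
    arma::mat Sj = S + arma::eye(S.n_rows, S.n_rows) * (j * s2);
    if (arma::chol(L, Sj, "lower")) { jit_used = j * s2; return true; }
  }
  return false;
}

struct AdaptiveBlock {
  int d;
  double ls;            // log proposal scale
  double target;
  arma::vec mean;       // running mean (for covariance adaptation, d >= 2)
  arma::mat cov;
  arma::mat R;          // lower-triangular proposal shape
  long n_seen;
  long acc_post, att_post;

  void init(int dim, double ls0, double tgt) {
    d = dim; ls = ls0; target = tgt;
    mean = arma::zeros(d);
    cov = arma::eye(d, d);
    R = arma::eye(d, d);
    n_seen = 0; acc_post = 0; att_post = 0;
  }
  arma::vec propose(const arma::vec &x) {
    return x + std::exp(ls) * (R * rnorm_vec(d));
  }
  void learn(const arma::vec &x, double alpha, long it, bool burn) {
    if (!burn) { att_post++; return; }
    double g = std::pow((double)it + 1.0, -0.6);
    ls += g * (alpha - target);
    if (d >= 2) {
      n_seen++;
      arma::vec dx = x - mean;
      mean += dx / (double)n_seen;
      if (n_seen > 1)
        cov = cov * ((double)(n_seen - 2) / (n_seen - 1)) +
              dx * dx.t() / (double)n_seen;
      if (n_seen >= 50 && n_seen % 100 == 0) {
        arma::mat Rt;
        arma::mat C = cov * (5.76 / d) + arma::eye(d, d) * 1e-8;
        if (arma::chol(Rt, C, "lower")) R = Rt;
      }
    }
  }
};

// [[Rcpp::export]]
List mcmc_spatial_ph_cpp(const arma::vec &t, const arma::vec &delta,
                         const arma::mat &X, const arma::uvec &dist_idx,
                         const arma::mat &D, int family,
                         const arma::mat &Bt, const arma::mat &Bq,
                         const arma::vec &tq,
                         List priors, List init, List settings) {
  const int n = t.n_elem;
  const int p = X.n_cols;
  const int m = D.n_rows;

  const int n_iter = as<int>(settings["n_iter"]);
  const int n_burn = as<int>(settings["n_burn"]);
  const int n_thin = as<int>(settings["n_thin"]);
  const bool use_frailty = as<bool>(settings["use_frailty"]);
  const bool update_eta = as<bool>(settings["update_eta"]);
  const bool update_omega = as<bool>(settings["update_omega"]);
  const bool prior_only = as<bool>(settings["prior_only"]);
  const bool store_ll = as<bool>(settings["store_ll"]);
  // frailty/covariance blocks cost O(m) / O(m^3) with m << n, so they are
  // refreshed several times per sweep to match the O(n) blocks' mixing
  const int rep_v = as<int>(settings["n_frailty_updates"]);
  const int rep_eta = as<int>(settings["n_eta_updates"]);
  if (n_burn >= n_iter) stop("n_burn must be < n_iter");

  const double beta_sd = as<double>(priors["beta_sd"]);
  const arma::vec omega_mean = as<arma::vec>(priors["omega_mean"]);
  const arma::vec omega_sd = as<arma::vec>(priors["omega_sd"]);
  const double s2_mean = as<double>(priors["sigma2_mean"]);
  const double s2_sd = as<double>(priors["sigma2_sd"]);
  const double phi_mean = as<double>(priors["phi_mean"]);
  const double phi_sd = as<double>(priors["phi_sd"]);
  bool gamma_prior = false;
  double gam_a = 0, gam_b = 0;
  if (priors.containsElementNamed("lambda_gamma") &&
      !Rf_isNull(priors["lambda_gamma"])) {
    arma::vec lg = as<arma::vec>(priors["lambda_gamma"]);
    gamma_prior = true; gam_a = lg[0]; gam_b = lg[1];
    if (family != 0) stop("gamma prior on lambda: exponential family only");
  }

  arma::vec beta = as<arma::vec>(init["beta"]);
  arma::vec lom = as<arma::vec>(init["logomega"]);
  double ls2 = as<double>(init["logsigma2"]);
  double lphi = as<double>(init["logphi"]);
  arma::vec v = as<arma::vec>(init["v"]);
  const int kom = lom.n_elem;

  const arma::vec logt = arma::log(t);

  // ---- baseline evaluation ------------------------------------------------
  int nq = tq.n_elem;
  double dtq = nq > 1 ? tq[1] - tq[0] : 1.0;
  arma::uvec gidx(n); arma::vec gfrac(n);
  if (family == 2) {
    for (int i = 0; i < n; ++i) {
      int gi = std::min((int)std::floor(t[i] / dtq), nq - 2);
      gi = std::max(gi, 0);
      gidx[i] = gi;
      gfrac[i] = (t[i] - tq[gi]) / dtq;
    }
  }
  arma::vec H0grid(std::max(nq, 1));
  auto baseline_eval = [&](const arma::vec &lw, arma::vec &logh0,
                           arma::vec &H0) {
    if (family == 0) {
      logh0.fill(lw[0]);
      H0 = std::exp(lw[0]) * t;
    } else if (family == 1) {
      double alpha = std::exp(lw[0]);
      logh0 = lw[0] + lw[1] + (alpha - 1.0) * logt;
      H0 = arma::exp(lw[1] + alpha * logt);
    } else {
      arma::vec hq = arma::exp(Bq * lw);
      H0grid[0] = 0.0;
      for (int j = 1; j < nq; ++j)
        H0grid[j] = H0grid[j - 1] + 0.5 * (hq[j - 1] + hq[j]) * dtq;
      logh0 = Bt * lw;
      for (int i = 0; i < n; ++i) {
        int gi = gidx[i];
        H0[i] = H0grid[gi] + gfrac[i] * (H0grid[gi + 1] - H0grid[gi]);
      }
    }
  };

  // district aggregates
  arma::vec E = arma::zeros(m);
  for (int i = 0; i < n; ++i) E[dist_idx[i]] += delta[i];
  auto aggregate = [&](const arma::vec &logh0, const arma::vec &H0,
                       const arma::vec &xb, double &C1, arma::vec &S) {
    C1 = 0.0; S.zeros();
    for (int i = 0; i < n; ++i) {
      C1 += delta[i] * (logh0[i] + xb[i]);
      S[dist_idx[i]] += H0[i] * std::exp(xb[i]);
    }
  };
  auto loglik = [&](double C1, const arma::vec &S, const arma::vec &Y,
                    const arma::vec &expY) {
    if (prior_only) return 0.0;
    return C1 + arma::dot(E, Y) - arma::dot(S, expY);
  };

  // ---- priors -------------------------------------------------------------
  auto lp_beta = [&](const arma::vec &b) {
    return -0.5 * arma::dot(b, b) / (beta_sd * beta_sd);
  };
  auto lp_omega = [&](const arma::vec &lw) {
    if (gamma_prior) return gam_a * lw[0] - gam_b * std::exp(lw[0]);
    double s = 0;
    for (int j = 0; j < kom; ++j) {
      double z = (lw[j] - omega_mean[j % omega_mean.n_elem]) /
                 omega_sd[j % omega_sd.n_elem];
      s += -0.5 * z * z;
    }
    return s;
  };
  auto lp_eta = [&](double l2, double lp_) {
    double z1 = (l2 - s2_mean) / s2_sd, z2 = (lp_ - phi_mean) / phi_sd;
    return -0.5 * (z1 * z1 + z2 * z2);
  };

  // ---- state --------------------------------------------------------------
  arma::mat L(m, m, arma::fill::zeros);
  arma::vec Linv1(m, arma::fill::zeros);
  double jit_used = 0, jit_max = 0;
  arma::vec Y = arma::zeros(m);
  const arma::vec ones_m = arma::ones(m);
  if (use_frailty) {
    double s2 = std::exp(ls2), phi = std::exp(lphi);
    arma::mat S0 = s2 * arma::exp(-D / phi);
    if (!chol_jitter(S0, L, jit_used))
      stop("initial frailty covariance not positive definite");
    jit_max = jit_used;
    Y = -s2 / 2.0 + L * v;
    Linv1 = arma::solve(arma::trimatl(L), ones_m);
  }
  arma::vec expY = arma::exp(Y);

  arma::vec xb = p > 0 ? arma::vec(X * beta) : arma::zeros(n);
  arma::vec logh0(n), H0(n), Svec(m);
  double C1;
  baseline_eval(lom, logh0, H0);
  aggregate(logh0, H0, xb, C1, Svec);
  double ll_cur = loglik(C1, Svec, Y, expY);

  if (!std::isfinite(ll_cur)) stop("nonfinite posterior at init: likelihood");
  if (!std::isfinite(lp_beta(beta))) stop("nonfinite posterior at init: beta prior");
  if (!std::isfinite(lp_omega(lom))) stop("nonfinite posterior at init: omega prior");
  if (use_frailty && !std::isfinite(lp_eta(ls2, lphi)))
    stop("nonfinite posterior at init: eta prior");

  AdaptiveBlock ab_beta, ab_om, ab_eta;
  double ls_v = std::log(2.38 / std::sqrt((double)std::max(m, 1)));
  double ls_lvl = std::log(0.5);
  long acc_v = 0, att_v = 0, acc_lvl = 0;
  const double sum_delta = arma::accu(delta);
  if (p > 0) ab_beta.init(p, std::log(0.1 / std::sqrt((double)p)),
                          p >= 2 ? 0.234 : 0.44);
  ab_om.init(kom, std::log(0.1 / std::sqrt((double)kom)),
             kom >= 2 ? 0.234 : 0.44);
  ab_eta.init(2, std::log(0.5), 0.234);

  const int n_keep = (n_iter - n_burn) / n_thin;
  arma::mat draws(n_keep, p + kom + 2 + m);
  arma::mat llmat;
  if (store_ll) llmat.set_size(n, n_keep);
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool burn = it < n_burn;

    // --- beta block ---
    if (p > 0) {
      arma::vec bp = ab_beta.propose(beta);
      arma::vec xbp = X * bp;
      double C1p; arma::vec Sp(m);
      aggregate(logh0, H0, xbp, C1p, Sp);
      double llp = loglik(C1p, Sp, Y, expY);
      double lr = llp - ll_cur + lp_beta(bp) - lp_beta(beta);
      double alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
      if (R::unif_rand() < alpha) {
        beta = bp; xb = xbp; C1 = C1p; Svec = Sp; ll_cur = llp;
        if (!burn) ab_beta.acc_post++;
      }
      ab_beta.learn(beta, alpha, it, burn);
    }

    // --- omega block ---
    if (update_omega) {
      arma::vec lwp = ab_om.propose(lom);
      arma::vec logh0p(n), H0p(n);
      baseline_eval(lwp, logh0p, H0p);
      double C1p; arma::vec Sp(m);
      aggregate(logh0p, H0p, xb, C1p, Sp);
      double llp = loglik(C1p, Sp, Y, expY);
      double lr = llp - ll_cur + lp_omega(lwp) - lp_omega(lom);
      double alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
      if (R::unif_rand() < alpha) {
        lom = lwp; logh0 = logh0p; H0 = H0p; C1 = C1p; Svec = Sp;
        ll_cur = llp;
        if (!burn) ab_om.acc_post++;
      }
      ab_om.learn(lom, alpha, it, burn);
    }

    if (use_frailty) {
      // --- whitened frailty block ---
      for (int r = 0; r < rep_v; ++r) {
        arma::vec vp = v + std::exp(ls_v) * rnorm_vec(m);
        arma::vec Yp = -std::exp(ls2) / 2.0 + L * vp;
        arma::vec expYp = arma::exp(Yp);
        double llp = loglik(C1, Svec, Yp, expYp);
        double lr = llp - ll_cur - 0.5 * (arma::dot(vp, vp) - arma::dot(v, v));
        double alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
        if (R::unif_rand() < alpha) {
          v = vp; Y = Yp; expY = expYp; ll_cur = llp;
          if (!burn) acc_v++;
        }
        if (burn)
          ls_v += std::pow((double)it + 1.0, -0.6) * (alpha - 0.234);
        else att_v++;
      }
      // --- covariance (eta) block: centred update. Y is held fixed and
      // (log s2, log phi) are accepted on the multivariate-normal density
      // ratio of Y (determinant included) times the eta prior; the
      // likelihood is untouched. Combined with the whitened v update this
      // interweaves the two parameterisations, which keeps both the field
      // and its covariance parameters identified and mixing.
      if (update_eta) for (int r = 0; r < rep_eta; ++r) {
        arma::vec cur = {ls2, lphi};
        arma::vec prop = ab_eta.propose(cur);
        double s2p = std::exp(prop[0]), phip = std::exp(prop[1]);
        arma::mat Lp; double jit;
        arma::mat Sg = s2p * arma::exp(-D / phip);
        double alpha = 0.0;
        if (chol_jitter(Sg, Lp, jit)) {
          if (jit > jit_max) jit_max = jit;
          arma::vec vp = arma::solve(arma::trimatl(Lp), Y + s2p / 2.0);
          double logdet_p = arma::accu(arma::log(Lp.diag()));
          double logdet_c = arma::accu(arma::log(L.diag()));
          double lr = -logdet_p - 0.5 * arma::dot(vp, vp) + logdet_c +
                      0.5 * arma::dot(v, v) +
                      lp_eta(prop[0], prop[1]) - lp_eta(ls2, lphi);
          alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
          if (R::unif_rand() < alpha) {
            ls2 = prop[0]; lphi = prop[1]; L = Lp; v = vp;
            Linv1 = arma::solve(arma::trimatl(L), ones_m);
            if (!burn) ab_eta.acc_post++;
          }
        }
        arma::vec now = {ls2, lphi};
        ab_eta.learn(now, alpha, it, burn);
      }
      // --- level-transfer move along the baseline/frailty ridge ---
      // Shifting every Y by c while scaling the baseline hazard by e^{-c}
      // leaves the likelihood exactly unchanged (the lambda/Y confounding),
      // so the move is accepted on the prior ratio alone. It lets the
      // sampler traverse the ridge and the priors allocate the level.
      if (update_omega) {
        double c = std::exp(ls_lvl) * R::norm_rand();
        arma::vec lwp = lom;
        if (family == 0) lwp[0] -= c;          // log rate
        else if (family == 1) lwp[1] -= c;     // log scale
        else lwp -= c;                         // spline partition of unity
        arma::vec vp = v + c * Linv1;
        double lr = lp_omega(lwp) - lp_omega(lom) -
                    0.5 * (arma::dot(vp, vp) - arma::dot(v, v));
        double alpha = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
        if (R::unif_rand() < alpha) {
          lom = lwp; v = vp;
          Y += c; expY = arma::exp(Y);
          logh0 -= c; H0 *= std::exp(-c);
          C1 -= c * sum_delta;
          Svec *= std::exp(-c);
          if (!burn) acc_lvl++;
        }
        if (burn)
          ls_lvl += std::pow((double)it + 1.0, -0.6) * (alpha - 0.44);
      }
    }

    // --- record ---
    if (!burn && ((it - n_burn + 1) % n_thin == 0) && keep < n_keep) {
      int c = 0;
      for (int j = 0; j < p; ++j) draws(keep, c++) = beta[j];
      for (int j = 0; j < kom; ++j) draws(keep, c++) = lom[j];
      draws(keep, c++) = ls2;
      draws(keep, c++) = lphi;
      for (int j = 0; j < m; ++j) draws(keep, c++) = Y[j];
      if (store_ll) {
        for (int i = 0; i < n; ++i) {
          double lp_i = xb[i] + Y[dist_idx[i]];
          llmat(i, keep) = delta[i] * (logh0[i] + lp_i) -
                           H0[i] * std::exp(lp_i);
        }
      }
      keep++;
    }
    if (it % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  double post = (double)(n_iter - n_burn);
  List accept = List::create(
    _["beta"] = p > 0 ? (double)ab_beta.acc_post / post : NA_REAL,
    _["omega"] = update_omega ? (double)ab_om.acc_post / post : NA_REAL,
    _["frailty"] = use_frailty ? (double)acc_v / (post * rep_v) : NA_REAL,
    _["eta"] = (use_frailty && update_eta)
                 ? (double)ab_eta.acc_post / (post * rep_eta) : NA_REAL,
    _["level"] = (use_frailty && update_omega)
                 ? (double)acc_lvl / post : NA_REAL);

  return List::create(_["draws"] = draws,
                      _["ll"] = store_ll ? wrap(llmat) : R_NilValue,
                      _["accept"] = accept,
                      _["jitter_max"] = jit_max,
                      _["n_keep"] = keep);
}
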