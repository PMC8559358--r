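#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the dynamic-persistence
// correlated random walk. State: beta (7), log sigma_x, log sigma_nu and
// the latent eta_i = logit(gamma_i) for each modeled step i = 3..n.
//
// beta | eta is conjugate (weighted normal regression of eta on Z with a
// N(0, prior_beta_sd^2) prior) and is drawn exactly. Each eta_i and the
// two log-scales use random-walk Metropolis with Robbins-Monro scale
// adaptation toward 0.44 acceptance, frozen at the end of burn-in so the
// post-burn-in kernel is a fixed valid MH kernel.
//
// Units contract: dt in hours, coordinates in km; sigma_x in km/sqrt(h),
// latent sd = dt * sigma_nu.

static const int P = 7;

// lower Cholesky of a PxP SPD matrix (in/out: a)
static void chol_lower(double a[P][P]) {
  for (int j = 0; j < P; ++j) {
    for (int k = 0; k < j; ++k) a[j][j] -= a[j][k] * a[j][k];
    a[j][j] = std::sqrt(a[j][j]);
    for (int i = j + 1; i < P; ++i) {
      for (int k = 0; k < j; ++k) a[i][j] -= a[i][k] * a[j][k];
      a[i][j] /= a[j][j];
    }
  }
}

// [[Rcpp::export]]
List dcrw_mcmc_chain(NumericMatrix xy, NumericVector dt_h, NumericMatrix Z,
                     double prior_beta_sd, double prior_sx_scale,
                     double prior_snu_scale, NumericVector beta_init,
                     double sigma_x_init, double sigma_nu_init,
                     int n_iter, int n_burnin, int thin,
                     bool include_likelihood) {
  const int n = xy.nrow();
  const int m = n - 2;
  if (Z.nrow() != n || Z.ncol() != P) stop("bad design dimensions");
  if (dt_h.size() != n - 1) stop("bad dt length");

  // per-step quantities, s = 0..m-1 maps to fix i = s+2 (0-based)
  std::vector<double> dts(m), dtp(m), dx(m), dy(m), w_step(m);
  for (int s = 0; s < m; ++s) {
    dtp[s] = dt_h[s];
    dts[s] = dt_h[s + 1];
    dx[s] = xy(s + 1, 0) - xy(s, 0);
    dy[s] = xy(s + 1, 1) - xy(s, 1);
  }

  std::vector<double> beta(P), eta(m, 0.0);
  for (int k = 0; k < P; ++k) beta[k] = beta_init[k];
  double lsx = std::log(sigma_x_init), lsnu = std::log(sigma_nu_init);

  // adaptation state
  std::vector<double> ls_eta(m, std::log(0.5));
  std::vector<double> ls_ridge(P, std::log(0.2));
  std::vector<double> eta_tmp(m);
  double ls_sx = std::log(0.1), ls_snu = std::log(0.1);
  std::vector<int> acc_eta(m, 0);
  std::vector<int> acc_ridge(P, 0);
  int acc_sx = 0, acc_snu = 0, batch = 0, batch_n = 0;
  const int batch_size = 50;

  // squared residual of the movement step s given gamma
  auto step_sse = [&](int s, double gamma) {
    double r = dts[s] / dtp[s];
    double mx = xy(s + 1, 0) + gamma * r * dx[s];
    double my = xy(s + 1, 1) + gamma * r * dy[s];
    double ex = xy(s + 2, 0) - mx, ey = xy(s + 2, 1) - my;
    return ex * ex + ey * ey;
  };

  const int n_keep = (n_iter - n_burnin + thin - 1) / thin;
  NumericMatrix out_beta(n_keep, P), out_eta(n_keep, m);
  NumericVector out_sx(n_keep), out_snu(n_keep);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    double sx = std::exp(lsx), snu = std::exp(lsnu);
    double sx2 = sx * sx, snu2 = snu * snu;

    // --- eta_i updates (random-walk MH on each site) ---
    for (int s = 0; s < m; ++s) {
      double mu = 0.0;
      for (int k = 0; k < P; ++k) mu += Z(s + 2, k) * beta[k];
      double vlat = dts[s] * dts[s] * snu2;
      double cur = eta[s];
      double prop = cur + std::exp(ls_eta[s]) * R::norm_rand();
      double gc = 1.0 / (1.0 + std::exp(-cur));
      double gp = 1.0 / (1.0 + std::exp(-prop));
      double lp_cur = -(cur - mu) * (cur - mu) / (2.0 * vlat);
      double lp_prop = -(prop - mu) * (prop - mu) / (2.0 * vlat);
      if (include_likelihood) {
        lp_cur += -step_sse(s, gc) / (2.0 * dts[s] * sx2);
        lp_prop += -step_sse(s, gp) / (2.0 * dts[s] * sx2);
      }
      if (std::log(R::unif_rand()) < lp_prop - lp_cur) {
        eta[s] = prop;
        ++acc_eta[s];
      }
      // independence proposal from the latent prior: acceptance reduces
      // to the movement-likelihood ratio; decorrelates the site quickly
      if (include_likelihood) {
        double cur2 = eta[s];
        double prop2 = mu + std::sqrt(vlat) * R::norm_rand();
        double g2c = 1.0 / (1.0 + std::exp(-cur2));
        double g2p = 1.0 / (1.0 + std::exp(-prop2));
        double d = (step_sse(s, g2c) - step_sse(s, g2p)) /
          (2.0 * dts[s] * sx2);
        if (std::log(R::unif_rand()) < d) eta[s] = prop2;
      } else {
        // prior target: the conditional is the latent prior itself
        eta[s] = mu + std::sqrt(vlat) * R::norm_rand();
      }
    }

    // --- beta | eta: exact conjugate draw ---
    // (prior target: the (beta, eta) block is drawn jointly from the
    // prior, which is its exact conditional given the scales)
    if (!include_likelihood) {
      for (int k = 0; k < P; ++k) beta[k] = prior_beta_sd * R::norm_rand();
      for (int s = 0; s < m; ++s) {
        double mu = 0.0;
        for (int k = 0; k < P; ++k) mu += Z(s + 2, k) * beta[k];
        eta[s] = mu + dts[s] * snu * R::norm_rand();
      }
    } else {
      double prec[P][P] = {{0.0}};
      double b[P] = {0.0};
      for (int s = 0; s < m; ++s) {
        double w = 1.0 / (dts[s] * dts[s] * snu2);
        for (int k = 0; k < P; ++k) {
          double zw = Z(s + 2, k) * w;
          b[k] += zw * eta[s];
          for (int l = 0; l <= k; ++l) prec[k][l] += zw * Z(s + 2, l);
        }
      }
      for (int k = 0; k < P; ++k) {
        for (int l = k + 1; l < P; ++l) prec[k][l] = prec[l][k];
        prec[k][k] += 1.0 / (prior_beta_sd * prior_beta_sd);
      }
      chol_lower(prec);  // prec now holds L (lower)
      // solve L y = b
      double yv[P];
      for (int k = 0; k < P; ++k) {
        yv[k] = b[k];
        for (int l = 0; l < k; ++l) yv[k] -= prec[k][l] * yv[l];
        yv[k] /= prec[k][k];
      }
      // solve L' mu = y (posterior mean) and L' u = z (noise)
      double zv[P];
      for (int k = 0; k < P; ++k) zv[k] = R::norm_rand();
      double muv[P], uv[P];
      for (int k = P - 1; k >= 0; --k) {
        muv[k] = yv[k];
        uv[k] = zv[k];
        for (int l = k + 1; l < P; ++l) {
          muv[k] -= prec[l][k] * muv[l];
          uv[k] -= prec[l][k] * uv[l];
        }
        muv[k] /= prec[k][k];
        uv[k] /= prec[k][k];
      }
      for (int k = 0; k < P; ++k) beta[k] = muv[k] + uv[k];
    }

    // --- sigma_nu (log-scale RW-MH; half-Normal prior) ---
    {
      double ssr = 0.0;
      for (int s = 0; s < m; ++s) {
        double mu = 0.0;
        for (int k = 0; k < P; ++k) mu += Z(s + 2, k) * beta[k];
        double r = (eta[s] - mu) / dts[s];
        ssr += r * r;
      }
      double prop = lsnu + std::exp(ls_snu) * R::norm_rand();
      double s_cur = std::exp(lsnu), s_prop = std::exp(prop);
      double lp_cur = -m * lsnu - ssr / (2.0 * s_cur * s_cur)
        - s_cur * s_cur / (2.0 * prior_snu_scale * prior_snu_scale) + lsnu;
      double lp_prop = -m * prop - ssr / (2.0 * s_prop * s_prop)
        - s_prop * s_prop / (2.0 * prior_snu_scale * prior_snu_scale) + prop;
      if (std::log(R::unif_rand()) < lp_prop - lp_cur) {
        lsnu = prop;
        ++acc_snu;
      }
    }

    // --- ridge translation moves: (beta_k, eta) shifted together ---
    // proposes beta_k* = beta_k + delta, eta_s* = eta_s + Z_sk delta,
    // leaving every latent residual eta - Z'beta unchanged; the latent
    // layer cancels exactly and only the movement likelihood and the
    // beta prior decide. This is the slow direction of the posterior
    // when per-step information about gamma is weak.
    if (include_likelihood) {
      double sx2b = std::exp(2.0 * lsx);
      for (int rep = 0; rep < 8; ++rep)
      for (int k = 0; k < P; ++k) {
        double delta = std::exp(ls_ridge[k]) * R::norm_rand();
        double bstar = beta[k] + delta;
        double logr =
          (beta[k] * beta[k] - bstar * bstar) /
            (2.0 * prior_beta_sd * prior_beta_sd);
        for (int s = 0; s < m; ++s) {
          double ep = eta[s] + Z(s + 2, k) * delta;
          double gc = 1.0 / (1.0 + std::exp(-eta[s]));
          double gp = 1.0 / (1.0 + std::exp(-ep));
          logr += (step_sse(s, gc) - step_sse(s, gp)) /
            (2.0 * dts[s] * sx2b);
          eta_tmp[s] = ep;
        }
        if (std::log(R::unif_rand()) < logr) {
          beta[k] = bstar;
          for (int s = 0; s < m; ++s) eta[s] = eta_tmp[s];
          ++acc_ridge[k];
        }
      }
    }

    // --- joint (sigma_nu, eta) rescaling move ---
    // proposes sigma_nu* = c sigma_nu, eta* = mu + c (eta - mu): the
    // latent density is invariant up to -m log c, which cancels against
    // the Jacobian c^(m+1) and the log-scale proposal asymmetry to a
    // net +log c; only the movement likelihood and the half-Normal
    // prior on sigma_nu decide. Breaks the slow coupling between the
    // latent spread and its scale.
    if (include_likelihood) {
      double snu_cur = std::exp(lsnu);
      double eps = 0.3 * R::norm_rand();
      double c = std::exp(eps);
      double snu_prop = c * snu_cur;
      double logr = eps +
        (snu_cur * snu_cur - snu_prop * snu_prop) /
          (2.0 * prior_snu_scale * prior_snu_scale);
      double sx2b = std::exp(2.0 * lsx);
      std::vector<double> mu_s(m), eta_prop(m);
      for (int s = 0; s < m; ++s) {
        double mu = 0.0;
        for (int k = 0; k < P; ++k) mu += Z(s + 2, k) * beta[k];
        mu_s[s] = mu;
        eta_prop[s] = mu + c * (eta[s] - mu);
        double gc = 1.0 / (1.0 + std::exp(-eta[s]));
        double gp = 1.0 / (1.0 + std::exp(-eta_prop[s]));
        logr += (step_sse(s, gc) - step_sse(s, gp)) /
          (2.0 * dts[s] * sx2b);
      }
      if (std::log(R::unif_rand()) < logr) {
        lsnu = std::log(snu_prop);
        eta = eta_prop;
      }
    }

    // --- sigma_x (log-scale RW-MH; half-Normal prior) ---
    {
      double prop = lsx + std::exp(ls_sx) * R::norm_rand();
      double s_cur = std::exp(lsx), s_prop = std::exp(prop);
      double lp_cur = -s_cur * s_cur /
        (2.0 * prior_sx_scale * prior_sx_scale) + lsx;
      double lp_prop = -s_prop * s_prop /
        (2.0 * prior_sx_scale * prior_sx_scale) + prop;
      if (include_likelihood) {
        double sse = 0.0;
        for (int s = 0; s < m; ++s) {
          double g = 1.0 / (1.0 + std::exp(-eta[s]));
          sse += step_sse(s, g) / dts[s];
        }
        lp_cur += -2.0 * m * lsx - sse / (2.0 * s_cur * s_cur);
        lp_prop += -2.0 * m * prop - sse / (2.0 * s_prop * s_prop);
      }
      if (std::log(R::unif_rand()) < lp_prop - lp_cur) {
        lsx = prop;
        ++acc_sx;
      }
    }

    // --- scale adaptation during burn-in only ---
    if (++batch_n == batch_size) {
      if (it < n_burnin) {
        ++batch;
        double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
        for (int s = 0; s < m; ++s) {
          ls_eta[s] += (acc_eta[s] > 0.44 * batch_size) ? delta : -delta;
        }
        for (int k = 0; k < P; ++k) {
          ls_ridge[k] += (acc_ridge[k] > 0.44 * 8 * batch_size) ? delta : -delta;
        }
        ls_sx += (acc_sx > 0.44 * batch_size) ? delta : -delta;
        ls_snu += (acc_snu > 0.44 * batch_size) ? delta : -delta;
      }
      std::fill(acc_eta.begin(), acc_eta.end(), 0);
      std::fill(acc_ridge.begin(), acc_ridge.end(), 0);
      acc_sx = acc_snu = 0;
      batch_n = 0;
    }

    // --- record ---
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      for (int k = 0; k < P; ++k) out_beta(kept, k) = beta[k];
      out_sx[kept] = std::exp(lsx);
      out_snu[kept] = std::exp(lsnu);
      for (int s = 0; s < m; ++s) out_eta(kept, s) = eta[s];
      ++kept;
    }
  }

  return List::create(_["beta"] = out_beta, _["sigma_x"] = out_sx,
                      _["sigma_nu"] = out_snu, _["eta"] = out_eta);
}
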