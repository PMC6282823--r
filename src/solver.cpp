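// Marginalized Gauss-Seidel solver for whole-genome regression under a
// spike-plus-Laplace prior.  Each coordinate visit computes the one-locus
// sufficient statistics from the current residual and replaces the effect
// by its closed-form posterior expectation; epistatic product columns are
// materialized on the fly and never stored.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Mean of N(mu, sd^2) truncated to (0, Inf).
static inline double trunc_upper_mean(double mu, double sd) {
  const double z = mu / sd;
  if (z < -30.0) {
    const double a = -z;
    return (sd / a) * (1.0 - 2.0 / (a * a) + 10.0 / std::pow(a, 4) -
                       74.0 / std::pow(a, 6));
  }
  return mu + sd * std::exp(R::dnorm(z, 0.0, 1.0, 1) -
                            R::pnorm(z, 0.0, 1.0, 1, 1));
}

// Posterior expectation of a single effect under the mixture prior
// gamma * Laplace(lambda) + (1 - gamma) * delta_0, given sufficient
// statistics Y = (x'x)^-1 x'y and s2 = (x'x)^-1 sigma_e^2.  All mixture
// weights are handled in log space; lgam = log(2 (1-gamma) / (gamma lambda)).
static inline double post_mean_scalar(double Y, double s2, double lambda,
                                      double lgam) {
  const double sd = std::sqrt(s2);
  const double muU = Y - lambda * s2;  // location of the g>0 Gaussian piece
  const double muL = Y + lambda * s2;  // location of the g<0 Gaussian piece
  const double lT1 = -lambda * Y + R::pnorm(muU / sd, 0.0, 1.0, 1, 1);
  const double lT2 = lambda * Y + R::pnorm(-muL / sd, 0.0, 1.0, 1, 1);
  const double lT3 = lgam - 0.5 * lambda * lambda * s2 +
                     R::dnorm(Y / sd, 0.0, 1.0, 1) - std::log(sd);
  double m = lT1 > lT2 ? lT1 : lT2;
  if (lT3 > m) m = lT3;
  const double lZ =
      m + std::log(std::exp(lT1 - m) + std::exp(lT2 - m) + std::exp(lT3 - m));
  // Means of the zero-truncated Gaussian pieces: log-scale Mills ratio,
  // switching to the asymptotic series for deep truncation where the
  // direct form cancels catastrophically.
  const double thU = trunc_upper_mean(muU, sd);
  const double thL = -trunc_upper_mean(-muL, sd);
  return std::exp(lT1 - lZ) * thU + std::exp(lT2 - lZ) * thL;
}

// [[Rcpp::export]]
NumericVector post_mean_cpp(NumericVector Y, NumericVector s2, double gamma,
                            double lambda) {
  const double lgam = std::log(2.0 * (1.0 - gamma) / (gamma * lambda));
  const R_xlen_t n = Y.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = post_mean_scalar(Y[i], s2[i], lambda, lgam);
  return out;
}

// Visit every main-effect coordinate of one kind once.
static void sweep_main(const arma::mat& X, const arma::vec& xtx, arma::vec& g,
                       arma::vec& r, double sigma_e2, double lambda,
                       double lgam) {
  const arma::uword p = X.n_cols;
  for (arma::uword j = 0; j < p; ++j) {
    if (xtx[j] <= 0.0) continue;
    const double gold = g[j];
    const double xty = arma::dot(X.col(j), r) + xtx[j] * gold;
    const double gnew =
        post_mean_scalar(xty / xtx[j], sigma_e2 / xtx[j], lambda, lgam);
    const double d = gnew - gold;
    if (d != 0.0) r -= X.col(j) * d;
    g[j] = gnew;
  }
}

// Visit all 2 p (p-1) epistatic coordinates once, building each product
// column transiently.  Kind order: aa, ad, da, dd; pairs i < j lexicographic.
static void sweep_epi(const arma::mat& Xa, const arma::mat& Xd, arma::vec& ge,
                      arma::vec& r, double sigma_e2, double lambda,
                      double lgam) {
  const arma::uword n = Xa.n_rows, p = Xa.n_cols;
  double* rp = r.memptr();
  arma::uword idx = 0;
  for (int kind = 0; kind < 4; ++kind) {
    const double* F1 = (kind < 2) ? Xa.memptr() : Xd.memptr();
    const double* F2 = (kind % 2 == 0) ? Xa.memptr() : Xd.memptr();
    for (arma::uword i = 0; i + 1 < p; ++i) {
      Rcpp::checkUserInterrupt();
      const double* u = F1 + (size_t)i * n;
      for (arma::uword j = i + 1; j < p; ++j, ++idx) {
        const double* v = F2 + (size_t)j * n;
        double s = 0.0, t = 0.0;
        for (arma::uword m = 0; m < n; ++m) {
          const double c = u[m] * v[m];
          s += c * c;
          t += c * rp[m];
        }
        if (s <= 0.0) continue;
        const double gold = ge[idx];
        const double xty = t + s * gold;
        const double gnew =
            post_mean_scalar(xty / s, sigma_e2 / s, lambda, lgam);
        const double d = gnew - gold;
        if (d != 0.0)
          for (arma::uword m = 0; m < n; ++m) rp[m] -= u[m] * v[m] * d;
        ge[idx] = gnew;
      }
    }
  }
}

// Final pass: realized x'x and x'y_j (trait residualized for all other
// effects) for every coordinate, used by the significance module.
static void epi_stats(const arma::mat& Xa, const arma::mat& Xd,
                      const arma::vec& ge, const arma::vec& r,
                      arma::vec& xtx_e, arma::vec& xty_e) {
  const arma::uword n = Xa.n_rows, p = Xa.n_cols;
  const double* rp = r.memptr();
  arma::uword idx = 0;
  for (int kind = 0; kind < 4; ++kind) {
    const double* F1 = (kind < 2) ? Xa.memptr() : Xd.memptr();
    const double* F2 = (kind % 2 == 0) ? Xa.memptr() : Xd.memptr();
    for (arma::uword i = 0; i + 1 < p; ++i) {
      Rcpp::checkUserInterrupt();
      const double* u = F1 + (size_t)i * n;
      for (arma::uword j = i + 1; j < p; ++j, ++idx) {
        const double* v = F2 + (size_t)j * n;
        double s = 0.0, t = 0.0;
        for (arma::uword m = 0; m < n; ++m) {
          const double c = u[m] * v[m];
          s += c * c;
          t += c * rp[m];
        }
        xtx_e[idx] = s;
        xty_e[idx] = t + s * ge[idx];
      }
    }
  }
}

// [[Rcpp::export]]
List gs_fit_cpp(const arma::vec& y, const arma::mat& Xa, const arma::mat& Xd,
                bool use_dom, bool use_epi, const arma::mat& W,
                double gamma_main, double lambda_main, double gamma_epi,
                double lambda_epi, double tol, int max_sweeps, double sigma_e2,
                bool update_sigma, bool verbose) {
  const arma::uword n = y.n_elem, p = Xa.n_cols, q = W.n_cols;
  const arma::uword n_epi = use_epi ? 2 * p * (p - 1) : 0;
  const double lgam_m =
      std::log(2.0 * (1.0 - gamma_main) / (gamma_main * lambda_main));
  const double lgam_e =
      use_epi ? std::log(2.0 * (1.0 - gamma_epi) / (gamma_epi * lambda_epi))
              : 0.0;

  arma::vec ga(p, arma::fill::zeros);
  arma::vec gd(use_dom ? p : 0, arma::fill::zeros);
  arma::vec ge(n_epi, arma::fill::zeros);
  arma::vec b(q, arma::fill::zeros);
  arma::vec r = y;

  const arma::vec xtx_a = arma::sum(arma::square(Xa), 0).t();
  arma::vec xtx_d;
  if (use_dom) xtx_d = arma::sum(arma::square(Xd), 0).t();
  arma::mat WtW;
  if (q > 0) WtW = W.t() * W;

  int sweeps = 0;
  bool converged = false;
  double rel = NA_REAL;
  std::vector<double> rel_hist;

  for (int k = 1; k <= max_sweeps; ++k) {
    sweeps = k;
    const arma::vec ga0 = ga, gd0 = gd, ge0 = ge;

    sweep_main(Xa, xtx_a, ga, r, sigma_e2, lambda_main, lgam_m);
    if (use_dom) sweep_main(Xd, xtx_d, gd, r, sigma_e2, lambda_main, lgam_m);
    if (use_epi) sweep_epi(Xa, Xd, ge, r, sigma_e2, lambda_epi, lgam_e);

    if (q > 0) {
      // Empirical-Bayes update of fixed effects and residual variance.
      const arma::vec ystar = r + W * b;  // y - X ghat
      b = arma::solve(WtW, W.t() * ystar, arma::solve_opts::likely_sympd);
      r = ystar - W * b;
      sigma_e2 = arma::dot(r, r) / (double)(n - q);
    } else if (update_sigma) {
      sigma_e2 = arma::dot(r, r) / (double)n;
    }

    double num = arma::accu(arma::square(ga - ga0));
    double den = arma::accu(arma::square(ga));
    if (use_dom) {
      num += arma::accu(arma::square(gd - gd0));
      den += arma::accu(arma::square(gd));
    }
    if (use_epi) {
      num += arma::accu(arma::square(ge - ge0));
      den += arma::accu(arma::square(ge));
    }
    rel = (den > 0.0) ? std::sqrt(num) / std::sqrt(den)
                      : (num > 0.0 ? R_PosInf : 0.0);
    rel_hist.push_back(rel);
    if (verbose) {
      arma::uword nz = arma::accu(ga != 0.0);
      if (use_dom) nz += arma::accu(gd != 0.0);
      if (use_epi) nz += arma::accu(ge != 0.0);
      Rcout << "sweep " << k << "  rel.change " << rel << "  sigma_e2 "
            << sigma_e2 << "  nonzero " << nz << "\n";
    }
    if (rel < tol) {
      converged = true;
      break;
    }
  }

  // Per-coordinate sufficient statistics at convergence.
  arma::vec xty_a(p);
  for (arma::uword j = 0; j < p; ++j)
    xty_a[j] = arma::dot(Xa.col(j), r) + xtx_a[j] * ga[j];
  arma::vec xty_d(use_dom ? p : 0);
  if (use_dom)
    for (arma::uword j = 0; j < p; ++j)
      xty_d[j] = arma::dot(Xd.col(j), r) + xtx_d[j] * gd[j];
  arma::vec xtx_e(n_epi), xty_e(n_epi);
  if (use_epi) epi_stats(Xa, Xd, ge, r, xtx_e, xty_e);

  return List::create(
      _["ga"] = ga, _["gd"] = gd, _["ge"] = ge, _["b"] = b,
      _["sigma_e2"] = sigma_e2, _["sweeps"] = sweeps,
      _["converged"] = converged, _["rel_change"] = rel,
      _["rel_history"] = rel_hist, _["residual"] = r, _["xtx_a"] = xtx_a,
      _["xty_a"] = xty_a, _["xtx_d"] = xtx_d, _["xty_d"] = xty_d,
      _["xtx_e"] = xtx_e, _["xty_e"] = xty_e);
}
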