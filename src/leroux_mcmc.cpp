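#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Leroux CAR Poisson model
//   O_i ~ Poisson(E_i * exp(alpha + X_i beta + psi_i))
//   psi ~ N(0, tau2 * Q(rho)^{-1}),  Q(rho) = rho (D_w - W) + (1 - rho) I
//   tau2 ~ Inverse-Gamma(shape, scale),  rho ~ Uniform(0, 1)
// alpha and beta get diffuse N(0, prior_var_beta) priors and random-walk MH
// updates; psi is updated site by site against its full conditional; tau2 is
// a conjugate Gibbs draw; rho moves on the logit scale with a Jacobian
// correction, using the precomputed eigenvalues of the graph Laplacian for
// the determinant term. Step sizes adapt only during burn-in.
//
// RNG comes from R's stream (RNGScope), so set.seed() in R makes a chain
// bit-reproducible.

// neighbour structure in compressed sparse row form (built once per fit)
static void quad_parts(const NumericVector &psi,
                       const std::vector<int> &nb_start,
                       const std::vector<int> &nb_flat,
                       const NumericVector &wplus,
                       double &qL, double &qI) {
  // qL = psi' (D_w - W) psi, qI = psi' psi
  int n = psi.size();
  qL = 0.0; qI = 0.0;
  for (int i = 0; i < n; i++) {
    double s = 0.0;
    for (int k = nb_start[i]; k < nb_start[i + 1]; k++) s += psi[nb_flat[k]];
    qL += psi[i] * (wplus[i] * psi[i] - s);
    qI += psi[i] * psi[i];
  }
}

static inline double draw_invgamma(double shape, double scale) {
  // density proportional to x^(-shape-1) exp(-scale/x)
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// [[Rcpp::export]]
NumericVector rinvgamma_cpp(int n, double shape, double scale) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = draw_invgamma(shape, scale);
  return out;
}

static inline double adapt_step(double step, int acc, int window) {
  double rate = (double)acc / window;
  if (rate > 0.5) step *= 1.5;
  else if (rate < 0.3) step /= 1.5;
  if (step < 1e-5) step = 1e-5;
  if (step > 20.0) step = 20.0;
  return step;
}

// [[Rcpp::export]]
List leroux_mcmc_cpp(IntegerVector O, NumericVector E, NumericMatrix X,
                     List nb, NumericVector wplus, NumericVector lambda,
                     int n_iter, int burn_in, int thin,
                     double prior_shape, double prior_scale,
                     double prior_var_beta,
                     double alpha_init, NumericVector beta_init,
                     double tau2_init, double rho_init,
                     bool fix_rho) {
  int n = O.size(), p = X.ncol();
  int n_keep = (n_iter - burn_in) / thin;

  // flatten the neighbour lists once (CSR layout)
  std::vector<int> nb_start(n + 1, 0), nb_flat;
  for (int i = 0; i < n; i++) {
    IntegerVector nbi = nb[i];
    nb_start[i + 1] = nb_start[i] + nbi.size();
    for (int k = 0; k < nbi.size(); k++) nb_flat.push_back(nbi[k]);
  }

  double alpha = alpha_init, tau2 = tau2_init, rho = rho_init;
  NumericVector beta = clone(beta_init);
  NumericVector psi(n, 0.0);
  NumericVector eta(n), mu(n);
  double sumO = 0.0;
  for (int i = 0; i < n; i++) sumO += O[i];
  for (int i = 0; i < n; i++) {
    double xb = 0.0;
    for (int k = 0; k < p; k++) xb += X(i, k) * beta[k];
    eta[i] = alpha + xb + psi[i];
    mu[i] = E[i] * std::exp(eta[i]);
  }

  // step sizes and acceptance counters
  double s_alpha = 0.05, s_psi = 0.5, s_rho = 0.5;
  NumericVector s_beta(p, 0.05);
  int acc_alpha = 0, acc_rho = 0, acc_psi = 0;
  IntegerVector acc_beta(p, 0);
  long tot_alpha = 0, tot_rho = 0, tot_psi = 0;
  long kept_alpha = 0, kept_rho = 0, kept_psi = 0;
  IntegerVector kept_beta(p, 0);
  const int window = 100;

  NumericMatrix draws(n_keep, p + 3);      // alpha, beta..., tau2, rho
  NumericMatrix psi_draws(n_keep, n);
  NumericMatrix loglik(n_keep, n);
  int keep_row = 0;

  RNGScope scope;

  for (int iter = 1; iter <= n_iter; iter++) {
    bool adapting = iter <= burn_in;

    // --- alpha: random-walk MH (shifts every eta) -----------------------
    {
      double delta = R::rnorm(0.0, s_alpha);
      double summu = 0.0;
      for (int i = 0; i < n; i++) summu += mu[i];
      double lr = delta * sumO - (std::exp(delta) - 1.0) * summu;
      double an = alpha + delta;
      lr += (alpha * alpha - an * an) / (2.0 * prior_var_beta);
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        alpha = an;
        double ed = std::exp(delta);
        for (int i = 0; i < n; i++) { eta[i] += delta; mu[i] *= ed; }
        acc_alpha++; if (!adapting) kept_alpha++;
      }
      if (!adapting) tot_alpha++;
      if (adapting && iter % window == 0) {
        s_alpha = adapt_step(s_alpha, acc_alpha, window);
        acc_alpha = 0;
      }
    }

    // --- beta_k: random-walk MH ----------------------------------------
    for (int k = 0; k < p; k++) {
      double delta = R::rnorm(0.0, s_beta[k]);
      double lr = 0.0;
      for (int i = 0; i < n; i++) {
        double d = delta * X(i, k);
        lr += O[i] * d - mu[i] * (std::exp(d) - 1.0);
      }
      double bn = beta[k] + delta;
      lr += (beta[k] * beta[k] - bn * bn) / (2.0 * prior_var_beta);
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        beta[k] = bn;
        for (int i = 0; i < n; i++) {
          double d = delta * X(i, k);
          eta[i] += d; mu[i] *= std::exp(d);
        }
        acc_beta[k]++; if (!adapting) kept_beta[k]++;
      }
      if (adapting && iter % window == 0) {
        s_beta[k] = adapt_step(s_beta[k], acc_beta[k], window);
        acc_beta[k] = 0;
      }
    }

    // --- psi: single-site MH against the Leroux full conditional -------
    for (int i = 0; i < n; i++) {
      double s = 0.0;
      for (int k = nb_start[i]; k < nb_start[i + 1]; k++) s += psi[nb_flat[k]];
      double denom = rho * wplus[i] + 1.0 - rho;
      double m = rho * s / denom;
      double prec = denom / tau2;
      double prop = psi[i] + R::rnorm(0.0, s_psi);
      double d = prop - psi[i];
      double lr = O[i] * d - mu[i] * (std::exp(d) - 1.0)
        - 0.5 * prec * ((prop - m) * (prop - m)
                        - (psi[i] - m) * (psi[i] - m));
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        psi[i] = prop;
        eta[i] += d; mu[i] *= std::exp(d);
        acc_psi++; if (!adapting) kept_psi++;
      }
      if (!adapting) tot_psi++;
    }
    if (adapting && iter % window == 0) {
      s_psi = adapt_step(s_psi, acc_psi, window * n);
      acc_psi = 0;
    }

    // --- recenter psi; alpha absorbs the mean (identifiability) --------
    {
      double mbar = 0.0;
      for (int i = 0; i < n; i++) mbar += psi[i];
      mbar /= n;
      for (int i = 0; i < n; i++) psi[i] -= mbar;
      alpha += mbar;   // eta and mu unchanged
    }

    // --- tau2: conjugate inverse-gamma Gibbs draw -----------------------
    {
      double qL, qI;
      quad_parts(psi, nb_start, nb_flat, wplus, qL, qI);
      double quad = rho * qL + (1.0 - rho) * qI;
      tau2 = draw_invgamma(prior_shape + 0.5 * n, prior_scale + 0.5 * quad);
    }

    // --- rho: MH on the logit scale with Jacobian ------------------------
    if (!fix_rho) {
      double z = std::log(rho / (1.0 - rho));
      double zn = z + R::rnorm(0.0, s_rho);
      double rn = 1.0 / (1.0 + std::exp(-zn));
      double qL, qI;
      quad_parts(psi, nb_start, nb_flat, wplus, qL, qI);
      bool ok = true;
      double ld_new = 0.0, ld_old = 0.0;
      for (int m2 = 0; m2 < n; m2++) {
        double tn = rn * lambda[m2] + 1.0 - rn;
        double to = rho * lambda[m2] + 1.0 - rho;
        if (tn <= 0.0 || to <= 0.0) { ok = false; break; }
        ld_new += std::log(tn); ld_old += std::log(to);
      }
      if (ok) {
        double qn = rn * qL + (1.0 - rn) * qI;
        double qo = rho * qL + (1.0 - rho) * qI;
        double lr = 0.5 * (ld_new - ld_old) - (qn - qo) / (2.0 * tau2)
          + std::log(rn * (1.0 - rn)) - std::log(rho * (1.0 - rho));
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          rho = rn;
          acc_rho++; if (!adapting) kept_rho++;
        }
      }
      if (!adapting) tot_rho++;
      if (adapting && iter % window == 0) {
        s_rho = adapt_step(s_rho, acc_rho, window);
        acc_rho = 0;
      }
    }

    // --- retention -------------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      draws(keep_row, 0) = alpha;
      for (int k = 0; k < p; k++) draws(keep_row, 1 + k) = beta[k];
      draws(keep_row, p + 1) = tau2;
      draws(keep_row, p + 2) = rho;
      for (int i = 0; i < n; i++) {
        psi_draws(keep_row, i) = psi[i];
        loglik(keep_row, i) = R::dpois(O[i], mu[i], 1);
      }
      keep_row++;
    }
  }

  NumericVector acc(3 + p);
  acc[0] = tot_alpha > 0 ? (double)kept_alpha / tot_alpha : NA_REAL;
  for (int k = 0; k < p; k++)
    acc[1 + k] = (double)kept_beta[k] / (n_iter - burn_in);
  acc[p + 1] = tot_psi > 0 ? (double)kept_psi / tot_psi : NA_REAL;
  acc[p + 2] = tot_rho > 0 ? (double)kept_rho / tot_rho : NA_REAL;

  return List::create(_["draws"] = draws,
                      _["psi"] = psi_draws,
                      _["loglik"] = loglik,
                      _["acceptance"] = acc,
                      _["n_retained"] = keep_row,
                      _["steps"] = NumericVector::create(
                        _["alpha"] = s_alpha, _["psi"] = s_psi,
                        _["rho"] = s_rho));
}
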