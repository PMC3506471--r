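#include <Rcpp.h>
using namespace Rcpp;

// One BayesR chain: four-component normal-mixture marker model on adjusted
// phenotypes, y* = 1 mu + W m (+ a) + e, with
//   m_j | c_j = k  ~  N(0, gamma_k * sigma_g2),  gamma = (0, 1e-4, 1e-3, 1e-2)
//   pi ~ Dirichlet(prior + class counts)
//   sigma_e2 ~ scaled inverse chi-square
//   sigma_g2 optionally resampled from the current marker effects
//   a (optional) polygenic, single-site Gibbs given dense A-inverse.
// Uses R's RNG, so set.seed() in R makes a chain reproducible.

// [[Rcpp::export]]
List bayesr_chain(const NumericMatrix& W, const NumericVector& y,
                  const NumericVector& gamma, const NumericVector& dir_prior,
                  int n_iter, int burn_in,
                  double sigma_g2_init, double sigma_e2_init,
                  bool update_sigma_g2, bool update_sigma_e2, bool update_pi,
                  Nullable<NumericMatrix> Ainv_ = R_NilValue,
                  bool residual_check = false,
                  Nullable<List> init_ = R_NilValue) {
  const int n = W.nrow(), m = W.ncol(), K = gamma.size();
  if (n_iter < 1 || burn_in < 0 || burn_in >= n_iter)
    stop("need 0 <= burn_in < n_iter");

  NumericVector xx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    xx[j] = s;
  }

  // state
  NumericVector beta(m, 0.0);
  IntegerVector cls(m, 0);           // 0-based class index
  NumericVector pi(K);
  for (int k = 0; k < K; ++k) pi[k] = dir_prior[k];
  double ps = sum(pi);
  for (int k = 0; k < K; ++k) pi[k] /= ps;
  double mu = 0.0, se2 = sigma_e2_init, sg2 = sigma_g2_init;
  bool poly = Ainv_.isNotNull();
  NumericMatrix Ainv;
  NumericVector a(n, 0.0);
  double sa2 = 0.1 * sigma_e2_init;
  if (poly) Ainv = as<NumericMatrix>(Ainv_);

  if (init_.isNotNull()) {
    List init(init_);
    beta = clone(as<NumericVector>(init["beta"]));
    cls = clone(as<IntegerVector>(init["class"]));
    pi = clone(as<NumericVector>(init["pi"]));
    mu = as<double>(init["mu"]);
    se2 = as<double>(init["sigma_e2"]);
    sg2 = as<double>(init["sigma_g2"]);
    if (poly && init.containsElementNamed("a")) {
      a = clone(as<NumericVector>(init["a"]));
      sa2 = as<double>(init["sigma_a2"]);
    }
  }

  // running residual
  NumericVector e(n);
  for (int i = 0; i < n; ++i) {
    double fit = mu + (poly ? a[i] : 0.0);
    e[i] = y[i] - fit;
  }
  for (int j = 0; j < m; ++j) {
    if (beta[j] != 0.0)
      for (int i = 0; i < n; ++i) e[i] -= W(i, j) * beta[j];
  }

  const double nu_g = 4.0, nu_e = 4.0, nu_a = 4.0;
  const double Sg = sigma_g2_init * (nu_g - 2.0) / nu_g;
  const double Se = sigma_e2_init * (nu_e - 2.0) / nu_e;
  const double Sa = 0.1 * sigma_e2_init * (nu_a - 2.0) / nu_a;

  // accumulators (post burn-in)
  NumericVector sum_b(m, 0.0), sum_b2(m, 0.0);
  NumericMatrix cls_count(m, K);
  NumericVector pi_sum(K, 0.0);
  double mu_sum = 0.0, se2_sum = 0.0, sg2_sum = 0.0, sa2_sum = 0.0;
  NumericVector a_sum(n, 0.0);
  int kept = 0;
  NumericVector genvar_trace(n_iter - burn_in);
  NumericVector logl(K);
  double max_resid_drift = 0.0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept (flat prior)
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += e[i] + mu;
      double mu_new = s / n + R::norm_rand() * std::sqrt(se2 / n);
      double d = mu - mu_new;
      for (int i = 0; i < n; ++i) e[i] += d;
      mu = mu_new;
    }

    IntegerVector counts(K);
    const double* Wp = &W(0, 0);
    double* ep = &e[0];
    for (int j = 0; j < m; ++j) {
      const double* wj = Wp + (size_t)j * n;
      double bj = beta[j];
      double rhs = bj * xx[j];
      for (int i = 0; i < n; ++i) rhs += wj[i] * ep[i];
      // class membership
      double lmax = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double v = gamma[k] * sg2;
        double l = std::log(pi[k] > 0 ? pi[k] : 1e-300);
        if (v > 0.0) {
          double denom = v * xx[j] + se2;
          l += 0.5 * (std::log(se2 / denom) + rhs * rhs * v / (se2 * denom));
        }
        logl[k] = l;
        if (l > lmax) lmax = l;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { logl[k] = std::exp(logl[k] - lmax); tot += logl[k]; }
      double u = R::unif_rand() * tot, acc = 0.0;
      int k_new = K - 1;
      for (int k = 0; k < K; ++k) { acc += logl[k]; if (u <= acc) { k_new = k; break; } }
      cls[j] = k_new;
      counts[k_new]++;
      double b_new = 0.0;
      double v = gamma[k_new] * sg2;
      if (v > 0.0) {
        double cvar = 1.0 / (xx[j] / se2 + 1.0 / v);
        b_new = cvar * rhs / se2 + R::norm_rand() * std::sqrt(cvar);
      }
      if (b_new != bj) {
        double d = bj - b_new;
        for (int i = 0; i < n; ++i) ep[i] += wj[i] * d;
        beta[j] = b_new;
      }
    }

    // mixture proportions
    if (update_pi) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double shape = dir_prior[k] + counts[k];
        pi[k] = (shape > 0.0) ? R::rgamma(shape, 1.0) : 0.0;
        tot += pi[k];
      }
      for (int k = 0; k < K; ++k) pi[k] /= tot;
    }

    // marker-variance anchor from current effects
    if (update_sigma_g2) {
      double ss = 0.0; int nz = 0;
      for (int j = 0; j < m; ++j) {
        if (cls[j] > 0) { ss += beta[j] * beta[j] / gamma[cls[j]]; nz++; }
      }
      sg2 = (ss + nu_g * Sg) / R::rchisq(nu_g + nz);
    }

    // polygenic effects, single-site
    if (poly) {
      for (int i = 0; i < n; ++i) {
        double ri = e[i] + a[i];
        double cross = 0.0;
        for (int j2 = 0; j2 < n; ++j2) if (j2 != i) cross += Ainv(i, j2) * a[j2];
        double prec = Ainv(i, i) / sa2 + 1.0 / se2;
        double mean = (ri / se2 - cross / sa2) / prec;
        double ai_new = mean + R::norm_rand() / std::sqrt(prec);
        e[i] = ri - ai_new;
        a[i] = ai_new;
      }
      double qf = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j2 = 0; j2 < n; ++j2) qf += a[i] * Ainv(i, j2) * a[j2];
      sa2 = (qf + nu_a * Sa) / R::rchisq(nu_a + n);
    }

    // residual variance
    if (update_sigma_e2) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      se2 = (sse + nu_e * Se) / R::rchisq(nu_e + n);
    }
    if (!R_finite(se2) || !R_finite(sg2))
      stop("non-finite variance at iteration %d; chain aborted", it + 1);

    if (residual_check && (it + 1) % 1000 == 0) {
      double drift = 0.0;
      for (int i = 0; i < n; ++i) {
        double fit = mu + (poly ? a[i] : 0.0);
        for (int j = 0; j < m; ++j) fit += W(i, j) * beta[j];
        drift = std::max(drift, std::fabs(y[i] - fit - e[i]));
      }
      max_resid_drift = std::max(max_resid_drift, drift);
      if (drift > 1e-6) stop("running-residual identity violated: %g", drift);
    }

    if (it >= burn_in) {
      kept++;
      double gv = 0.0;
      for (int j = 0; j < m; ++j) {
        sum_b[j] += beta[j];
        sum_b2[j] += beta[j] * beta[j];
        cls_count(j, cls[j]) += 1.0;
        gv += beta[j] * beta[j] * xx[j];
      }
      genvar_trace[it - burn_in] = gv / n;
      for (int k = 0; k < K; ++k) pi_sum[k] += pi[k];
      mu_sum += mu; se2_sum += se2; sg2_sum += sg2;
      if (poly) { sa2_sum += sa2; for (int i = 0; i < n; ++i) a_sum[i] += a[i]; }
    }
  }

  NumericVector mean_b(m), sd_b(m);
  NumericMatrix cls_prob(m, K);
  for (int j = 0; j < m; ++j) {
    mean_b[j] = sum_b[j] / kept;
    double v2 = sum_b2[j] / kept - mean_b[j] * mean_b[j];
    sd_b[j] = std::sqrt(v2 > 0 ? v2 : 0);
    for (int k = 0; k < K; ++k) cls_prob(j, k) = cls_count(j, k) / kept;
  }
  for (int k = 0; k < K; ++k) pi_sum[k] /= kept;
  NumericVector a_mean(n);
  if (poly) for (int i = 0; i < n; ++i) a_mean[i] = a_sum[i] / kept;

  List state = List::create(_["beta"] = beta, _["class"] = cls, _["pi"] = pi,
                            _["mu"] = mu, _["sigma_e2"] = se2,
                            _["sigma_g2"] = sg2);
  if (poly) { state["a"] = a; state["sigma_a2"] = sa2; }

  return List::create(
    _["mean_effect"] = mean_b, _["sd_effect"] = sd_b,
    _["class_probs"] = cls_prob, _["pi_mean"] = pi_sum,
    _["mu_mean"] = mu_sum / kept, _["sigma_e2_mean"] = se2_sum / kept,
    _["sigma_g2_mean"] = sg2_sum / kept,
    _["sigma_a2_mean"] = poly ? sa2_sum / kept : NA_REAL,
    _["a_mean"] = a_mean,
    _["genvar_trace"] = genvar_trace,
    _["max_resid_drift"] = max_resid_drift,
    _["state"] = state, _["n_kept"] = kept);
}
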