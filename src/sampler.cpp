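// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// Bernoulli-logit breeding-probability models.
//
// Model (H3; H1/H2 drop terms):
//   y_r ~ Bernoulli(inv_logit(lp_r))
//   lp_r = mu + delta[state_r] + g1*A_r + g2*A_r^2
//          + eta[yr_r] + alpha[ind_r] + ice_r * beta[ind_r]
//   delta parameterized sum-to-zero: (dF, dE, -dF-dE)
//   eta_t ~ N(0, sd_eta), alpha_i ~ N(0, sd_alpha), beta_i ~ N(0, sd_beta)
// Priors: mean rate inv_logit(mu) ~ U(0,1)  => mu ~ Logistic(0,1);
//   dF, dE, g1, g2 ~ N(0, 1000) (variance);
//   sd ~ U(0,10), or variance ~ InvGamma(4, 0.05) when prior_type == 1.
//
// Scalar parameters and each latent effect get random-walk Metropolis
// updates with proposal scales adapted (toward 0.44 acceptance) during
// burn-in only; variances get conjugate Gibbs updates; two likelihood-
// invariant translation moves (mu vs eta, mu vs alpha) decorrelate the
// intercept from the latent-effect means. R's RNG is used throughout, so
// draws are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double LP_CLIP = 35.0;

static inline double clip(double x) {
  if (x > LP_CLIP) return LP_CLIP;
  if (x < -LP_CLIP) return -LP_CLIP;
  return x;
}

// log Bernoulli(y | inv_logit(lp))
static inline double ll_term(double lp, int y) {
  double z = y ? -clip(lp) : clip(lp);
  if (z > LP_CLIP) return -z;
  return -log1p(std::exp(z));
}

// log density of Logistic(0, 1) (the prior on mu implied by a uniform
// prior on the mean rate)
static inline double log_dlogis(double x) {
  double ax = std::fabs(x);
  return -ax - 2.0 * log1p(std::exp(-ax));
}

struct Adapt {
  double scale;
  int acc, tries;
  Adapt() : scale(0.3), acc(0), tries(0) {}
  void tally(bool a) { tries++; if (a) acc++; }
  void maybe_adapt() {
    if (tries >= 50) {
      double rate = (double)acc / tries;
      scale *= std::exp(rate > 0.44 ? 0.1 : -0.1);
      if (scale < 1e-4) scale = 1e-4;
      if (scale > 20.0) scale = 20.0;
      acc = 0; tries = 0;
    }
  }
};

// inverse-gamma draw for a variance: v ~ IG(shape, rate)
static inline double rinvgamma(double shape, double rate) {
  return rate / R::rgamma(shape, 1.0);
}

// [[Rcpp::export]]
List mh_sampler(IntegerVector y, NumericVector A, IntegerVector state,
                IntegerVector yr, IntegerVector ind, IntegerVector ice,
                int n_year, int n_ind, int hypothesis, int prior_type,
                int n_burn, int n_keep, int thin, List inits) {
  const int N = y.size();
  const bool has_alpha = hypothesis >= 2;
  const bool has_beta = hypothesis >= 3;
  const double prior_sd2 = 1000.0;  // variance of the diffuse normal prior
  const double sd_upper = 10.0;     // uniform prior upper bound on SDs

  // --- index structures -------------------------------------------------
  std::vector<int> idxF, idxE, idxS;
  std::vector<std::vector<int>> by_year(n_year), by_ind(n_ind),
      by_ind_ice(n_ind);
  for (int r = 0; r < N; r++) {
    if (state[r] == 0) idxF.push_back(r);
    else if (state[r] == 1) idxE.push_back(r);
    else idxS.push_back(r);
    by_year[yr[r]].push_back(r);
    by_ind[ind[r]].push_back(r);
    if (ice[r]) by_ind_ice[ind[r]].push_back(r);
  }

  // --- state ------------------------------------------------------------
  double mu = as<double>(inits["mu"]);
  double dF = as<double>(inits["dF"]), dE = as<double>(inits["dE"]);
  double g1 = as<double>(inits["g1"]), g2 = as<double>(inits["g2"]);
  double sd_eta = as<double>(inits["sd_eta"]);
  double sd_alpha = has_alpha ? as<double>(inits["sd_alpha"]) : 0.0;
  double sd_beta = has_beta ? as<double>(inits["sd_beta"]) : 0.0;
  std::vector<double> eta(n_year, 0.0), alpha(n_ind, 0.0), beta(n_ind, 0.0);

  std::vector<double> lp(N);
  auto rebuild_lp = [&]() {
    for (int r = 0; r < N; r++) {
      double d = state[r] == 0 ? dF : (state[r] == 1 ? dE : -dF - dE);
      lp[r] = mu + d + g1 * A[r] + g2 * A[r] * A[r] + eta[yr[r]] +
              (has_alpha ? alpha[ind[r]] : 0.0) +
              (has_beta && ice[r] ? beta[ind[r]] : 0.0);
    }
  };
  rebuild_lp();

  // --- adaptation bookkeeping -------------------------------------------
  Adapt ad_mu, ad_dF, ad_dE, ad_g1, ad_g2, ad_shift_eta, ad_shift_alpha;
  std::vector<Adapt> ad_eta(n_year), ad_alpha(n_ind), ad_beta(n_ind);
  ad_g1.scale = ad_g2.scale = 0.1;
  ad_mu.scale = ad_dF.scale = ad_dE.scale = 0.1;

  // shift in lp over a record subset (coef * d), returning delta loglik
  auto dll_subset = [&](const std::vector<int> &idx, double coef, double d) {
    double out = 0.0;
    for (size_t k = 0; k < idx.size(); k++) {
      int r = idx[k];
      out += ll_term(lp[r] + coef * d, y[r]) - ll_term(lp[r], y[r]);
    }
    return out;
  };
  auto apply_subset = [&](const std::vector<int> &idx, double coef,
                          double d) {
    for (size_t k = 0; k < idx.size(); k++) lp[idx[k]] += coef * d;
  };

  // --- storage ----------------------------------------------------------
  NumericMatrix fixed(n_keep, 8);
  colnames(fixed) = CharacterVector::create(
      "mu", "delta_F", "delta_E", "g1", "g2", "sd_eta", "sd_alpha",
      "sd_beta");
  NumericMatrix eta_draws(n_keep, n_year);
  NumericMatrix alpha_draws(has_alpha ? n_keep : 0,
                            has_alpha ? n_ind : 0);
  NumericMatrix beta_draws(has_beta ? n_keep : 0, has_beta ? n_ind : 0);

  RNGScope scope;
  const int n_iter = n_burn + n_keep * thin;
  int stored = 0;

  for (int it = 0; it < n_iter; it++) {
    const bool adapting = it < n_burn;

    // mu: affects every record with coefficient 1
    {
      double d = R::norm_rand() * ad_mu.scale;
      double dl = log_dlogis(mu + d) - log_dlogis(mu);
      for (int r = 0; r < N; r++)
        dl += ll_term(lp[r] + d, y[r]) - ll_term(lp[r], y[r]);
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) { mu += d; for (int r = 0; r < N; r++) lp[r] += d; }
      if (adapting) { ad_mu.tally(acc); ad_mu.maybe_adapt(); }
    }
    // dF: +1 on F records, -1 on S records (through delta_S = -dF - dE)
    {
      double d = R::norm_rand() * ad_dF.scale;
      double dl = -((dF + d) * (dF + d) - dF * dF) / (2.0 * prior_sd2);
      dl += dll_subset(idxF, 1.0, d) + dll_subset(idxS, -1.0, d);
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) {
        dF += d; apply_subset(idxF, 1.0, d); apply_subset(idxS, -1.0, d);
      }
      if (adapting) { ad_dF.tally(acc); ad_dF.maybe_adapt(); }
    }
    // dE: +1 on E records, -1 on S records
    {
      double d = R::norm_rand() * ad_dE.scale;
      double dl = -((dE + d) * (dE + d) - dE * dE) / (2.0 * prior_sd2);
      dl += dll_subset(idxE, 1.0, d) + dll_subset(idxS, -1.0, d);
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) {
        dE += d; apply_subset(idxE, 1.0, d); apply_subset(idxS, -1.0, d);
      }
      if (adapting) { ad_dE.tally(acc); ad_dE.maybe_adapt(); }
    }
    // g1 (coef A) and g2 (coef A^2)
    {
      double d = R::norm_rand() * ad_g1.scale;
      double dl = -((g1 + d) * (g1 + d) - g1 * g1) / (2.0 * prior_sd2);
      for (int r = 0; r < N; r++)
        dl += ll_term(lp[r] + d * A[r], y[r]) - ll_term(lp[r], y[r]);
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) { g1 += d; for (int r = 0; r < N; r++) lp[r] += d * A[r]; }
      if (adapting) { ad_g1.tally(acc); ad_g1.maybe_adapt(); }
    }
    {
      double d = R::norm_rand() * ad_g2.scale;
      double dl = -((g2 + d) * (g2 + d) - g2 * g2) / (2.0 * prior_sd2);
      for (int r = 0; r < N; r++) {
        double a2 = A[r] * A[r];
        dl += ll_term(lp[r] + d * a2, y[r]) - ll_term(lp[r], y[r]);
      }
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) {
        g2 += d;
        for (int r = 0; r < N; r++) lp[r] += d * A[r] * A[r];
      }
      if (adapting) { ad_g2.tally(acc); ad_g2.maybe_adapt(); }
    }
    // year effects
    for (int t = 0; t < n_year; t++) {
      if (by_year[t].empty()) {  // no data: conditional = prior
        eta[t] = R::norm_rand() * sd_eta;
        continue;
      }
      double d = R::norm_rand() * ad_eta[t].scale;
      double e2 = eta[t] + d;
      double dl = -(e2 * e2 - eta[t] * eta[t]) / (2.0 * sd_eta * sd_eta);
      dl += dll_subset(by_year[t], 1.0, d);
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) { eta[t] = e2; apply_subset(by_year[t], 1.0, d); }
      if (adapting) { ad_eta[t].tally(acc); ad_eta[t].maybe_adapt(); }
    }
    // sd_eta (Gibbs on the variance)
    {
      double S = 0.0;
      for (int t = 0; t < n_year; t++) S += eta[t] * eta[t];
      double v;
      if (prior_type == 1) {
        v = rinvgamma(4.0 + n_year / 2.0, 0.05 + S / 2.0);
      } else {
        int tries = 0;
        do {
          v = rinvgamma((n_year - 1) / 2.0, S / 2.0);
        } while (v > sd_upper * sd_upper && ++tries < 1000);
        if (v > sd_upper * sd_upper) v = sd_upper * sd_upper;
      }
      sd_eta = std::sqrt(v);
    }
    // individual effects
    if (has_alpha) {
      for (int i = 0; i < n_ind; i++) {
        if (by_ind[i].empty()) {  // no transitions: conditional = prior
          alpha[i] = R::norm_rand() * sd_alpha;
          continue;
        }
        double d = R::norm_rand() * ad_alpha[i].scale;
        double a2 = alpha[i] + d;
        double dl =
            -(a2 * a2 - alpha[i] * alpha[i]) / (2.0 * sd_alpha * sd_alpha);
        dl += dll_subset(by_ind[i], 1.0, d);
        bool acc = std::log(R::unif_rand()) < dl;
        if (acc) { alpha[i] = a2; apply_subset(by_ind[i], 1.0, d); }
        if (adapting) { ad_alpha[i].tally(acc); ad_alpha[i].maybe_adapt(); }
      }
      double S = 0.0;
      for (int i = 0; i < n_ind; i++) S += alpha[i] * alpha[i];
      double v;
      if (prior_type == 1) {
        v = rinvgamma(4.0 + n_ind / 2.0, 0.05 + S / 2.0);
      } else {
        int tries = 0;
        do {
          v = rinvgamma((n_ind - 1) / 2.0, S / 2.0);
        } while (v > sd_upper * sd_upper && ++tries < 1000);
        if (v > sd_upper * sd_upper) v = sd_upper * sd_upper;
      }
      sd_alpha = std::sqrt(v);
    }
    if (has_beta) {
      for (int i = 0; i < n_ind; i++) {
        if (by_ind_ice[i].empty()) {  // never exposed: conditional = prior
          beta[i] = R::norm_rand() * sd_beta;
          continue;
        }
        double d = R::norm_rand() * ad_beta[i].scale;
        double b2 = beta[i] + d;
        double dl =
            -(b2 * b2 - beta[i] * beta[i]) / (2.0 * sd_beta * sd_beta);
        dl += dll_subset(by_ind_ice[i], 1.0, d);
        bool acc = std::log(R::unif_rand()) < dl;
        if (acc) { beta[i] = b2; apply_subset(by_ind_ice[i], 1.0, d); }
        if (adapting) { ad_beta[i].tally(acc); ad_beta[i].maybe_adapt(); }
      }
      double S = 0.0;
      for (int i = 0; i < n_ind; i++) S += beta[i] * beta[i];
      double v;
      if (prior_type == 1) {
        v = rinvgamma(4.0 + n_ind / 2.0, 0.05 + S / 2.0);
      } else {
        int tries = 0;
        do {
          v = rinvgamma((n_ind - 1) / 2.0, S / 2.0);
        } while (v > sd_upper * sd_upper && ++tries < 1000);
        if (v > sd_upper * sd_upper) v = sd_upper * sd_upper;
      }
      sd_beta = std::sqrt(v);
    }

    // translation moves: mu + d with eta (resp. alpha) shifted by -d keeps
    // every linear predictor unchanged, so only priors enter the ratio
    {
      double d = R::norm_rand() * ad_shift_eta.scale;
      double dl = log_dlogis(mu + d) - log_dlogis(mu);
      for (int t = 0; t < n_year; t++) {
        double e2 = eta[t] - d;
        dl -= (e2 * e2 - eta[t] * eta[t]) / (2.0 * sd_eta * sd_eta);
      }
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) {
        mu += d;
        for (int t = 0; t < n_year; t++) eta[t] -= d;
      }
      if (adapting) { ad_shift_eta.tally(acc); ad_shift_eta.maybe_adapt(); }
    }
    if (has_alpha) {
      double d = R::norm_rand() * ad_shift_alpha.scale;
      double dl = log_dlogis(mu + d) - log_dlogis(mu);
      for (int i = 0; i < n_ind; i++) {
        double a2 = alpha[i] - d;
        dl -= (a2 * a2 - alpha[i] * alpha[i]) /
              (2.0 * sd_alpha * sd_alpha);
      }
      bool acc = std::log(R::unif_rand()) < dl;
      if (acc) {
        mu += d;
        for (int i = 0; i < n_ind; i++) alpha[i] -= d;
      }
      if (adapting) {
        ad_shift_alpha.tally(acc);
        ad_shift_alpha.maybe_adapt();
      }
    }

    // periodic exact rebuild to stop float drift in the cached predictors
    if ((it + 1) % 1000 == 0) rebuild_lp();

    if (it >= n_burn && (it - n_burn) % thin == thin - 1) {
      fixed(stored, 0) = mu;
      fixed(stored, 1) = dF;
      fixed(stored, 2) = dE;
      fixed(stored, 3) = g1;
      fixed(stored, 4) = g2;
      fixed(stored, 5) = sd_eta;
      fixed(stored, 6) = sd_alpha;
      fixed(stored, 7) = sd_beta;
      for (int t = 0; t < n_year; t++) eta_draws(stored, t) = eta[t];
      if (has_alpha)
        for (int i = 0; i < n_ind; i++) alpha_draws(stored, i) = alpha[i];
      if (has_beta)
        for (int i = 0; i < n_ind; i++) beta_draws(stored, i) = beta[i];
      stored++;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      Named("fixed") = fixed, Named("eta") = eta_draws,
      Named("alpha") = alpha_draws, Named("beta") = beta_draws);
}

// Per-draw, individual-averaged, covariate-averaged state rates.
// For each posterior draw: mean over records of from-state k of
// E_z[inv_logit(base_r + s_r z)], z ~ N(0,1) integrated by Gauss-Hermite,
// with s_r = sd_alpha (sqrt(sd_alpha^2 + sd_beta^2) in iceberg years).
// [[Rcpp::export]]
NumericMatrix derived_rates_cpp(NumericMatrix fixed, NumericMatrix eta_draws,
                                NumericVector A, IntegerVector state,
                                IntegerVector yr, IntegerVector ice,
                                NumericVector gh_x, NumericVector gh_w) {
  const int n_draw = fixed.nrow(), N = A.size(), Q = gh_x.size();
  NumericMatrix out(n_draw, 3);  // F, E, S
  for (int d = 0; d < n_draw; d++) {
    double mu = fixed(d, 0), dF = fixed(d, 1), dE = fixed(d, 2);
    double g1 = fixed(d, 3), g2 = fixed(d, 4);
    double sa = fixed(d, 6), sb = fixed(d, 7);
    double sums[3] = {0, 0, 0};
    int counts[3] = {0, 0, 0};
    for (int r = 0; r < N; r++) {
      double del = state[r] == 0 ? dF : (state[r] == 1 ? dE : -dF - dE);
      double base = mu + del + g1 * A[r] + g2 * A[r] * A[r] +
                    eta_draws(d, yr[r]);
      double s = ice[r] ? std::sqrt(sa * sa + sb * sb) : sa;
      double pbar = 0.0;
      for (int q = 0; q < Q; q++) {
        double x = clip(base + s * gh_x[q]);
        pbar += gh_w[q] / (1.0 + std::exp(-x));
      }
      sums[state[r]] += pbar;
      counts[state[r]]++;
    }
    for (int k = 0; k < 3; k++)
      out(d, k) = counts[k] ? sums[k] / counts[k] : NA_REAL;
  }
  colnames(out) = CharacterVector::create("F", "E", "S");
  return out;
}
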