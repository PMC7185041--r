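#include <Rcpp.h>
#include <vector>
#include <numeric>
#include <cmath>
using namespace Rcpp;

// Bernoulli log-likelihood for one species' observations under (a, b);
// Rf_log1pexp is R's numerically stable log(1 + exp(x))
static double sp_loglik(const std::vector<int>& rows,
                        const IntegerVector& y, const NumericVector& evi,
                        double a, double b) {
  double s = 0.0;
  for (size_t q = 0; q < rows.size(); ++q) {
    int i = rows[q];
    double eta = a + b * evi[i];
    s += y[i] * eta - Rf_log1pexp(eta);
  }
  return s;
}

// full-data Bernoulli log-likelihood under per-species effects, with the
// linear predictor optionally shifted by (da + db * evi) or scaled about mu
static double full_loglik(const IntegerVector& y, const IntegerVector& sp,
                          const NumericVector& evi, const NumericVector& a,
                          const NumericVector& b) {
  double s = 0.0;
  const int N = y.size();
  for (int i = 0; i < N; ++i) {
    double eta = a[sp[i]] + b[sp[i]] * evi[i];
    s += y[i] * eta - Rf_log1pexp(eta);
  }
  return s;
}

// Adaptive Metropolis-within-Gibbs for the multispecies Bernoulli/logit
// model: y_i ~ Bern(logit^-1(alpha_j + beta_j * evi_i)),
// alpha_j ~ N(mu_a, sg_a^2), beta_j ~ N(mu_b, sg_b^2),
// mu_* ~ N(0, mu_prior_sd^2), sg_* ~ Uniform(0, sigma_upper).
// Species effects: random-walk Metropolis with Robbins-Monro scale
// adaptation during warmup. mu_*: conjugate Gibbs. sg_* (J >= 2):
// inverse-gamma Gibbs on the variance truncated at sigma_upper^2; for
// J == 1 a random-walk Metropolis step on sigma is used instead.
// Two extra block moves per iteration decouple the species effects from
// their hyperparameters (translation of a whole effect block together with
// its mean, and rescaling of the deviations together with their SD), which
// is what makes mu_* and sg_* mix well in the centered parameterization.
// fix / fix_val (length 4: mu_a, mu_b, sg_a, sg_b) pin hyperparameters.
// [[Rcpp::export]]
List ymg_sample_chain(IntegerVector y, IntegerVector sp, NumericVector evi,
                      int J, int warmup, int keep, List init,
                      double mu_prior_sd, double sigma_upper,
                      LogicalVector fix, NumericVector fix_val,
                      double target_accept) {
  const int N = y.size();
  std::vector< std::vector<int> > rows(J);
  for (int i = 0; i < N; ++i) rows[sp[i]].push_back(i);

  NumericVector a = clone(as<NumericVector>(init["alpha"]));
  NumericVector b = clone(as<NumericVector>(init["beta"]));
  double mu_a = as<double>(init["mu_alpha"]);
  double mu_b = as<double>(init["mu_beta"]);
  double sg_a = as<double>(init["sigma_alpha"]);
  double sg_b = as<double>(init["sigma_beta"]);
  if (fix[0]) mu_a = fix_val[0];
  if (fix[1]) mu_b = fix_val[1];
  if (fix[2]) sg_a = fix_val[2];
  if (fix[3]) sg_b = fix_val[3];

  std::vector<double> ls_a(J, std::log(0.5)), ls_b(J, std::log(0.5));
  double ls_sg_a = std::log(0.5), ls_sg_b = std::log(0.5);
  double ls_tr[2] = {std::log(0.2), std::log(0.2)};   // translation moves
  double ls_sc[2] = {std::log(0.2), std::log(0.2)};   // scale moves
  std::vector<double> acc_a(J, 0.0), acc_b(J, 0.0);

  const int P = 2 * J + 4;
  NumericMatrix draws(keep, P);
  const double mu_prec0 = 1.0 / (mu_prior_sd * mu_prior_sd);
  const int total = warmup + keep;

  for (int t = 1; t <= total; ++t) {
    const double gam = std::min(0.25, 1.0 / std::sqrt((double)t));

    // species intercepts and slopes: random-walk Metropolis
    for (int j = 0; j < J; ++j) {
      // alpha_j
      double prop = a[j] + std::exp(ls_a[j]) * norm_rand();
      double d = sp_loglik(rows[j], y, evi, prop, b[j]) -
                 sp_loglik(rows[j], y, evi, a[j], b[j]);
      d += -0.5 * ((prop - mu_a) * (prop - mu_a) -
                   (a[j] - mu_a) * (a[j] - mu_a)) / (sg_a * sg_a);
      double acc = d >= 0 ? 1.0 : std::exp(d);
      if (unif_rand() < acc) a[j] = prop;
      if (t <= warmup) ls_a[j] += gam * (acc - target_accept);
      else acc_a[j] += acc;

      // beta_j
      prop = b[j] + std::exp(ls_b[j]) * norm_rand();
      d = sp_loglik(rows[j], y, evi, a[j], prop) -
          sp_loglik(rows[j], y, evi, a[j], b[j]);
      d += -0.5 * ((prop - mu_b) * (prop - mu_b) -
                   (b[j] - mu_b) * (b[j] - mu_b)) / (sg_b * sg_b);
      acc = d >= 0 ? 1.0 : std::exp(d);
      if (unif_rand() < acc) b[j] = prop;
      if (t <= warmup) ls_b[j] += gam * (acc - target_accept);
      else acc_b[j] += acc;
    }

    // hyper-means: conjugate normal Gibbs
    if (!fix[0]) {
      double prec = J / (sg_a * sg_a) + mu_prec0;
      double mean = (std::accumulate(a.begin(), a.end(), 0.0) / (sg_a * sg_a)) / prec;
      mu_a = mean + norm_rand() / std::sqrt(prec);
    }
    if (!fix[1]) {
      double prec = J / (sg_b * sg_b) + mu_prec0;
      double mean = (std::accumulate(b.begin(), b.end(), 0.0) / (sg_b * sg_b)) / prec;
      mu_b = mean + norm_rand() / std::sqrt(prec);
    }

    // hyper-SDs
    for (int which = 0; which < 2; ++which) {
      if (fix[2 + which]) continue;
      NumericVector& eff = which == 0 ? a : b;
      double mu = which == 0 ? mu_a : mu_b;
      double& sg = which == 0 ? sg_a : sg_b;
      double& ls = which == 0 ? ls_sg_a : ls_sg_b;
      double S = 0.0;
      for (int j = 0; j < J; ++j) S += (eff[j] - mu) * (eff[j] - mu);
      if (J >= 2) {
        // variance ~ Inv-Gamma((J-1)/2, S/2) truncated below sigma_upper^2
        double v = sigma_upper * sigma_upper;
        for (int tries = 0; tries < 100; ++tries) {
          double g = R::rgamma((J - 1) / 2.0, 2.0 / S);
          if (g > 0 && 1.0 / g < sigma_upper * sigma_upper) { v = 1.0 / g; break; }
        }
        sg = std::sqrt(v);
      } else {
        // J == 1: random-walk Metropolis on sigma within (0, sigma_upper)
        double prop = sg + std::exp(ls) * norm_rand();
        if (prop > 0 && prop < sigma_upper) {
          double d = (-std::log(prop) - 0.5 * S / (prop * prop)) -
                     (-std::log(sg) - 0.5 * S / (sg * sg));
          double acc = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < acc) sg = prop;
          if (t <= warmup) ls += gam * (acc - target_accept);
        } else if (t <= warmup) {
          ls += gam * (0.0 - target_accept);
        }
      }
    }

    // block moves: translate (effects + mean) and rescale (deviations + SD)
    for (int which = 0; which < 2; ++which) {
      NumericVector& eff = which == 0 ? a : b;
      double& mu = which == 0 ? mu_a : mu_b;
      double& sg = which == 0 ? sg_a : sg_b;
      const bool mu_fixed = fix[which], sg_fixed = fix[2 + which];

      // translation
      {
        double delta = std::exp(ls_tr[which]) * norm_rand();
        NumericVector prop = clone(eff);
        for (int j = 0; j < J; ++j) prop[j] += delta;
        double d = (which == 0 ? full_loglik(y, sp, evi, prop, b)
                               : full_loglik(y, sp, evi, a, prop)) -
                   full_loglik(y, sp, evi, a, b);
        if (mu_fixed) {
          for (int j = 0; j < J; ++j)
            d += -0.5 * ((prop[j] - mu) * (prop[j] - mu) -
                         (eff[j] - mu) * (eff[j] - mu)) / (sg * sg);
        } else {
          double mu_new = mu + delta;
          d += -0.5 * (mu_new * mu_new - mu * mu) /
               (mu_prior_sd * mu_prior_sd);
        }
        double acc = d >= 0 ? 1.0 : std::exp(d);
        if (unif_rand() < acc) {
          for (int j = 0; j < J; ++j) eff[j] = prop[j];
          if (!mu_fixed) mu += delta;
        }
        if (t <= warmup) ls_tr[which] += gam * (acc - target_accept);
      }

      // rescale (only when the SD is free to move with the deviations)
      if (!sg_fixed) {
        double c = std::exp(std::exp(ls_sc[which]) * norm_rand());
        double sg_new = c * sg;
        if (sg_new < sigma_upper) {
          NumericVector prop = clone(eff);
          for (int j = 0; j < J; ++j) prop[j] = mu + c * (eff[j] - mu);
          double d = (which == 0 ? full_loglik(y, sp, evi, prop, b)
                                 : full_loglik(y, sp, evi, a, prop)) -
                     full_loglik(y, sp, evi, a, b) + std::log(c);
          double acc = d >= 0 ? 1.0 : std::exp(d);
          if (unif_rand() < acc) {
            for (int j = 0; j < J; ++j) eff[j] = prop[j];
            sg = sg_new;
          }
          if (t <= warmup) ls_sc[which] += gam * (acc - target_accept);
        } else if (t <= warmup) {
          ls_sc[which] += gam * (0.0 - target_accept);
        }
      }
    }

    if (t > warmup) {
      int r = t - warmup - 1;
      for (int j = 0; j < J; ++j) draws(r, j) = a[j];
      for (int j = 0; j < J; ++j) draws(r, J + j) = b[j];
      draws(r, 2 * J) = mu_a;
      draws(r, 2 * J + 1) = mu_b;
      draws(r, 2 * J + 2) = sg_a;
      draws(r, 2 * J + 3) = sg_b;
    }
  }

  for (int j = 0; j < J; ++j) { acc_a[j] /= keep; acc_b[j] /= keep; }
  return List::create(_["draws"] = draws,
                      _["accept_alpha"] = wrap(acc_a),
                      _["accept_beta"] = wrap(acc_b));
}
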