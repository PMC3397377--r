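#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form first-passage statistics of the pure DDM in scaled units
// (z = scaled threshold, x = scaled initial condition, m = scaled drift
// squared signal-to-noise). All exponents are kept non-positive so the
// expressions stay finite for z*m well past the overflow range of the
// naive sinh/cosh forms.

static inline double er_closed(double z, double x, double m) {
  // P(hit -z first) = 1 - expm1(-2(z+x)m)/expm1(-4zm)
  double num = std::expm1(-2.0 * (z + x) * m);
  double den = std::expm1(-4.0 * z * m);
  double er = 1.0 - num / den;
  if (er < 0.0) er = 0.0;
  if (er > 1.0) er = 1.0;
  return er;
}

// s * coth(s*m), with the s -> 0 limit 1/m handled by series expansion.
static inline double s_coth(double s, double m) {
  double u = s * m;
  if (u < 1e-4) return 1.0 / m + s * s * m / 3.0;
  return s / std::tanh(u);
}

static inline double dt_correct_closed(double z, double x, double m) {
  return s_coth(2.0 * z, m) - s_coth(z + x, m);
}

static inline double dt_error_closed(double z, double x, double m) {
  return s_coth(2.0 * z, m) - s_coth(z - x, m);
}

static inline double dt_mean_closed(double z, double x, double m) {
  // mean decision time with stable rearrangement of the x-dependent term
  double den = -std::expm1(-4.0 * z * m);
  double num = std::exp(-2.0 * z * m) - std::exp(-2.0 * (z + x) * m);
  return z * std::tanh(z * m) + 2.0 * z * num / den - x;
}

// [[Rcpp::export(name = ".er_closed_cpp")]]
NumericVector er_closed_cpp(NumericVector z, NumericVector x, NumericVector m) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = er_closed(z[i], x[i], m[i]);
  return out;
}

// [[Rcpp::export(name = ".dt_mean_closed_cpp")]]
NumericVector dt_mean_closed_cpp(NumericVector z, NumericVector x, NumericVector m) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dt_mean_closed(z[i], x[i], m[i]);
  return out;
}

// [[Rcpp::export(name = ".dt_cond_closed_cpp")]]
List dt_cond_closed_cpp(NumericVector z, NumericVector x, NumericVector m) {
  int n = z.size();
  NumericVector dc(n), de(n);
  for (int i = 0; i < n; ++i) {
    dc[i] = dt_correct_closed(z[i], x[i], m[i]);
    de[i] = dt_error_closed(z[i], x[i], m[i]);
  }
  return List::create(_["dt_correct"] = dc, _["dt_error"] = de);
}

// One pass of the adapted DDM through a single block of stimuli.
//
// State rules: memory M(1) = M(2) = 1/2, then M(n) = delta*M(n-1) +
// (1-delta)*1[repetition at n]; threshold starts at z_max, moves down by
// z_down after a correct trial and up by z_up after an error, clamped to
// [k/2 + x_offset, z_max]. Trial n's starting point uses M(n-1) and the
// sign of trial n's transition; trial 1 has no transition so x0 = 0.
// Exactly one uniform deviate is consumed per trial (the correctness coin
// flip), so results are reproducible from R's RNG state.
// [[Rcpp::export(name = ".simulate_block_cpp")]]
DataFrame simulate_block_cpp(IntegerVector stimuli,
                             double mu_tilde, double t_nd, double k,
                             double x_offset, double delta,
                             double z_down, double z_up, double z_max) {
  int n = stimuli.size();
  double z_lo = k / 2.0 + x_offset;
  if (z_lo > z_max) stop("threshold lower bound k/2 + x_offset exceeds z_max");

  IntegerVector response(n);
  LogicalVector correct(n);
  NumericVector rt(n), x0_out(n), z_out(n), er_out(n), mem_out(n);
  CharacterVector transition(n);

  double memory = 0.5;   // M(n-1) while processing trial n
  double z_cur = z_max;

  for (int i = 0; i < n; ++i) {
    bool has_trans = (i > 0);
    bool is_rep = has_trans && (stimuli[i] == stimuli[i - 1]);

    double x0 = 0.0;
    if (has_trans) {
      double s = is_rep ? 1.0 : -1.0;
      x0 = s * (k * (memory - 0.5) + x_offset);
    }
    // keep strictly inside the boundaries (clamping margin)
    double lim = z_cur * (1.0 - 1e-9);
    if (x0 > lim) x0 = lim;
    if (x0 < -lim) x0 = -lim;

    double er = er_closed(z_cur, x0, mu_tilde);
    double u = R::unif_rand();
    bool ok;
    if (er <= 0.0) ok = true;
    else if (er >= 1.0) ok = false;
    else ok = (u >= er);

    double dt = ok ? dt_correct_closed(z_cur, x0, mu_tilde)
                   : dt_error_closed(z_cur, x0, mu_tilde);

    response[i] = ok ? stimuli[i] : 3 - stimuli[i];
    correct[i] = ok;
    rt[i] = t_nd + dt;
    x0_out[i] = x0;
    z_out[i] = z_cur;
    er_out[i] = er;
    if (has_trans) transition[i] = is_rep ? "R" : "A";
    else transition[i] = NA_STRING;

    // memory update: held at 1/2 through trial 2 (i = 1), then filtered
    if (i >= 1) {
      if (i >= 2) memory = delta * memory + (is_rep ? (1.0 - delta) : 0.0);
      else memory = 0.5;
    }
    mem_out[i] = memory;

    // post-trial threshold update with clamping
    z_cur += ok ? -z_down : z_up;
    if (z_cur < z_lo) z_cur = z_lo;
    if (z_cur > z_max) z_cur = z_max;
  }

  return DataFrame::create(
    _["trial"] = seq_len(n),
    _["stimulus"] = stimuli,
    _["transition"] = transition,
    _["response"] = response,
    _["correct"] = correct,
    _["rt"] = rt,
    _["x0_tilde"] = x0_out,
    _["z_tilde"] = z_out,
    _["er_trial"] = er_out,
    _["memory"] = mem_out,
    _["stringsAsFactors"] = false);
}

// Euler-Maruyama simulation of dx = mu dt + sigma dW with absorbing
// boundaries at +/- z, including the Brownian-bridge crossing probability
// within each step (removes the O(sqrt(step)) threshold-overshoot bias).
// [[Rcpp::export(name = ".em_first_passage_cpp")]]
List em_first_passage_cpp(double mu, double sigma, double z, double x0,
                          double step, int n_paths, double horizon) {
  double sstep = sigma * std::sqrt(step);
  double var2 = sigma * sigma * step;

  long n_correct = 0, n_error = 0, n_unabsorbed = 0;
  double sum_c = 0.0, sumsq_c = 0.0, sum_e = 0.0, sumsq_e = 0.0;

  for (int p = 0; p < n_paths; ++p) {
    double x = x0, t = 0.0;
    int outcome = -1; // 1 correct, 0 error, -1 unabsorbed
    if (x >= z) outcome = 1;        // started on (or past) a boundary
    else if (x <= -z) outcome = 0;
    while (outcome == -1 && t < horizon) {
      double xn = x + mu * step + sstep * norm_rand();
      t += step;
      if (xn >= z) { outcome = 1; break; }
      if (xn <= -z) { outcome = 0; break; }
      // bridge crossing probabilities for each boundary within the step
      double pu = std::exp(-2.0 * (z - x) * (z - xn) / var2);
      if (unif_rand() < pu) { outcome = 1; break; }
      double pl = std::exp(-2.0 * (z + x) * (z + xn) / var2);
      if (unif_rand() < pl) { outcome = 0; break; }
      x = xn;
    }
    if (outcome == 1) { n_correct++; sum_c += t; sumsq_c += t * t; }
    else if (outcome == 0) { n_error++; sum_e += t; sumsq_e += t * t; }
    else n_unabsorbed++;
  }

  long n_abs = n_correct + n_error;
  double er = n_abs > 0 ? (double)n_error / n_abs : NA_REAL;
  double mean_c = n_correct > 0 ? sum_c / n_correct : NA_REAL;
  double mean_e = n_error > 0 ? sum_e / n_error : NA_REAL;
  double mean_all = n_abs > 0 ? (sum_c + sum_e) / n_abs : NA_REAL;

  double var_c = n_correct > 1 ? (sumsq_c - sum_c * sum_c / n_correct) / (n_correct - 1.0) : NA_REAL;
  double var_e = n_error > 1 ? (sumsq_e - sum_e * sum_e / n_error) / (n_error - 1.0) : NA_REAL;
  double var_all = n_abs > 1
    ? ((sumsq_c + sumsq_e) - (sum_c + sum_e) * (sum_c + sum_e) / n_abs) / (n_abs - 1.0)
    : NA_REAL;

  double se_er = n_abs > 0 ? std::sqrt(er * (1.0 - er) / n_abs) : NA_REAL;
  double se_c = (n_correct > 1 && var_c >= 0) ? std::sqrt(var_c / n_correct) : NA_REAL;
  double se_e = (n_error > 1 && var_e >= 0) ? std::sqrt(var_e / n_error) : NA_REAL;
  double se_all = (n_abs > 1 && var_all >= 0) ? std::sqrt(var_all / n_abs) : NA_REAL;

  return List::create(
    _["er"] = er, _["dt_mean"] = mean_all,
    _["dt_correct"] = mean_c, _["dt_error"] = mean_e,
    _["se_er"] = se_er, _["se_dt_mean"] = se_all,
    _["se_dt_correct"] = se_c, _["se_dt_error"] = se_e,
    _["n_correct"] = (double)n_correct, _["n_error"] = (double)n_error,
    _["n_unabsorbed"] = (double)n_unabsorbed);
}
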