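#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state zi
// (state vector length max(length(a), length(b)) - 1). Coefficients must be
// normalised so a[0] == 1.
// [[Rcpp::export(name = ".filter_df2t")]]
NumericVector filter_df2t(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int ns = std::max(nb, na) - 1;
  int n = x.size();
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0), z(ns, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < ns && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + (ns > 0 ? z[0] : 0.0);
    for (int k = 0; k < ns - 1; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    if (ns > 0) z[ns - 1] = bb[ns] * xt - aa[ns] * yt;
    y[t] = yt;
  }
  return y;
}

static const double LOG2PI = 1.8378770664093454836;

// log N(x; mu, v)
static inline double lnorm(double x, double mu, double v) {
  double d = x - mu;
  return -0.5 * (LOG2PI + std::log(v)) - d * d / (2.0 * v);
}

// Decision threshold where the two weighted component densities are equal.
// Prefers the root between the means; flag reports whether it lies there.
static double solve_theta(double wr, double mur, double vr, double wm,
                          double mum, double vm, bool &in_interval,
                          bool &degenerate) {
  in_interval = true;
  degenerate = false;
  double lo = std::min(mur, mum), hi = std::max(mur, mum);
  if (mur == mum) {
    degenerate = true;
    return mur;
  }
  double vmax = std::max(vr, vm);
  if (std::fabs(vr - vm) <= 1e-12 * vmax) {
    double v = 0.5 * (vr + vm);
    double th = 0.5 * (mur + mum) + v * std::log(wr / wm) / (mum - mur);
    in_interval = (th >= lo && th <= hi);
    return th;
  }
  double a2 = 1.0 / vm - 1.0 / vr;
  double a1 = -2.0 * (mum / vm - mur / vr);
  double a0 = mum * mum / vm - mur * mur / vr + 2.0 * std::log(wr / wm) +
              std::log(vm / vr);
  double disc = a1 * a1 - 4.0 * a2 * a0;
  if (disc < 0.0) {  // densities never equal: closest-approach point
    in_interval = false;
    return -a1 / (2.0 * a2);
  }
  double sq = std::sqrt(disc);
  // numerically stable pair
  double q = -0.5 * (a1 + (a1 >= 0 ? sq : -sq));
  double r1 = q / a2;
  double r2 = (q != 0.0) ? a0 / q : -a1 / (2.0 * a2);
  bool in1 = (r1 >= lo && r1 <= hi), in2 = (r2 >= lo && r2 <= hi);
  double mid = 0.5 * (lo + hi);
  if (in1 && in2) return (std::fabs(r1 - mid) <= std::fabs(r2 - mid)) ? r1 : r2;
  if (in1) return r1;
  if (in2) return r2;
  in_interval = false;
  double d1 = std::min(std::fabs(r1 - lo), std::fabs(r1 - hi));
  double d2 = std::min(std::fabs(r2 - lo), std::fabs(r2 - hi));
  return (d1 <= d2) ? r1 : r2;
}

// [[Rcpp::export(name = ".solve_theta_cpp")]]
NumericVector solve_theta_cpp(double wr, double mur, double vr, double wm,
                              double mum, double vm) {
  bool ii, dg;
  double th = solve_theta(wr, mur, vr, wm, mum, vm, ii, dg);
  return NumericVector::create(th, ii ? 1.0 : 0.0, dg ? 1.0 : 0.0);
}

// Streaming rest/movement classification with sequential parameter update
// (exponential forgetting). Classification of x[l] uses the threshold derived
// from the parameters *before* seeing x[l]; the update then folds x[l] in.
// [[Rcpp::export(name = ".classify_stream_cpp")]]
List classify_stream_cpp(NumericVector x, NumericVector par, double alpha,
                         bool adapt, double var_floor) {
  double wr = par[0], wm = par[1], mur = par[2], mum = par[3], vr = par[4],
         vm = par[5];
  int n = x.size();
  IntegerVector lab(n);
  NumericVector theta(n), wsum(n), wrtrace(n);
  int n_floored = 0, n_out = 0;
  bool ii, dg;
  for (int l = 0; l < n; ++l) {
    double th = solve_theta(wr, mur, vr, wm, mum, vm, ii, dg);
    if (!ii) ++n_out;
    theta[l] = th;
    double xl = x[l];
    lab[l] = (xl >= th) ? 1 : 0;  // at/above threshold -> movement
    if (adapt && alpha < 1.0) {
      double lr = std::log(wr) + lnorm(xl, mur, vr);
      double lm = std::log(wm) + lnorm(xl, mum, vm);
      double pr, pm;
      if (!std::isfinite(lr) && !std::isfinite(lm)) {
        pr = (std::fabs(xl - mur) <= std::fabs(xl - mum)) ? 1.0 : 0.0;
        pm = 1.0 - pr;
      } else {
        double mx = std::max(lr, lm);
        double er = std::exp(lr - mx), em = std::exp(lm - mx);
        pr = er / (er + em);
        pm = em / (er + em);
      }
      double wr1 = alpha * wr + (1.0 - alpha) * pr;
      double wm1 = alpha * wm + (1.0 - alpha) * pm;
      double s = wr1 + wm1;
      wr1 /= s;
      wm1 = 1.0 - wr1;  // weight sum exactly 1 in floating point
      double mur1 = (alpha * wr * mur + (1.0 - alpha) * pr * xl) / wr1;
      double mum1 = (alpha * wm * mum + (1.0 - alpha) * pm * xl) / wm1;
      double dr = xl - mur1, dm = xl - mum1;
      double vr1 = (alpha * wr * vr + (1.0 - alpha) * pr * dr * dr) / wr1;
      double vm1 = (alpha * wm * vm + (1.0 - alpha) * pm * dm * dm) / wm1;
      if (vr1 < var_floor) { vr1 = var_floor; ++n_floored; }
      if (vm1 < var_floor) { vm1 = var_floor; ++n_floored; }
      wr = wr1; wm = wm1; mur = mur1; mum = mum1; vr = vr1; vm = vm1;
    }
    wsum[l] = wr + wm;
    wrtrace[l] = wr;
  }
  return List::create(
      _["labels"] = lab, _["theta"] = theta, _["w_sum"] = wsum,
      _["w_rest"] = wrtrace,
      _["params"] = NumericVector::create(wr, wm, mur, mum, vr, vm),
      _["n_floored"] = n_floored, _["n_theta_outside"] = n_out);
}
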