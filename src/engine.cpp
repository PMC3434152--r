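#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Second-order difference equation with optional bilinear motor-state
// cross term:
//   r[t] = -a1*r[t-1] - a2*r[t-2] + b1*u[t-1] + b2*u[t-2] + k*u[t-1]*r[t-1]
// Zero initial conditions. `guard` aborts on |r| blow-up (bilinear runs
// near the stability edge can diverge); guard <= 0 disables the check.
// [[Rcpp::export]]
NumericVector simulate_bilinear_cpp(NumericVector u, double a1, double a2,
                                    double b1, double b2, double k,
                                    double guard) {
  int n = u.size();
  NumericVector r(n);
  double r1 = 0.0, r2 = 0.0;
  for (int t = 0; t < n; ++t) {
    double u1 = (t >= 1) ? u[t - 1] : 0.0;
    double u2 = (t >= 2) ? u[t - 2] : 0.0;
    double rt = -a1 * r1 - a2 * r2 + b1 * u1 + b2 * u2;
    if (k != 0.0) rt += k * u1 * r1;
    if (guard > 0.0 && (!std::isfinite(rt) || std::fabs(rt) > guard)) {
      stop("simulation diverged at sample %d (|r| = %g exceeds guard %g)",
           t + 1, rt, guard);
    }
    r[t] = rt;
    r2 = r1;
    r1 = rt;
  }
  return r;
}

// Online LMS novelty scheme over a tap-delay line.
//
// mode: 0 = motor-only, 1 = sensory-only, 2 = sensorimotor.
// Motor tap i (0-based) reads  u[t - delay_m - i*stride];
// sensory tap j reads          z[t - delay_s - j*stride];
// indices before the record start read 0 (zero-padded start-up).
// Per sample: yhat = w.p ; e = z - yhat ; w += beta * e * p.
// Weight snapshots are stored every `snapshot_every` samples (0 = none).
// [[Rcpp::export]]
List lms_novelty_cpp(NumericVector u, NumericVector z, int n_taps,
                     int stride, int delay_m, int delay_s, int mode,
                     double beta, NumericVector w0, int snapshot_every) {
  int n = z.size();
  bool use_motor = (mode == 0 || mode == 2);
  bool use_sense = (mode == 1 || mode == 2);
  int n_total = n_taps * ((mode == 2) ? 2 : 1);
  if (w0.size() != n_total)
    stop("initial weight vector has length %d, expected %d",
         (int)w0.size(), n_total);
  if (use_motor && u.size() != n)
    stop("motor and sensory series must have equal length");

  NumericVector w = clone(w0);
  NumericVector e(n), yhat(n);
  int n_snaps = (snapshot_every > 0) ? (n / snapshot_every) : 0;
  NumericMatrix snaps(n_snaps, n_total);
  IntegerVector snap_at(n_snaps);
  int snap_i = 0;

  for (int t = 0; t < n; ++t) {
    double y = 0.0;
    if (use_motor) {
      int base = t - delay_m;  // motor block occupies weights [0, n_taps)
      for (int i = 0; i < n_taps; ++i) {
        int idx = base - i * stride;
        if (idx < 0) break;  // earlier taps are all zero too
        y += w[i] * u[idx];
      }
    }
    if (use_sense) {
      int base = t - delay_s;
      int off = use_motor ? n_taps : 0;
      for (int i = 0; i < n_taps; ++i) {
        int idx = base - i * stride;
        if (idx < 0) break;
        y += w[off + i] * z[idx];
      }
    }
    double et = z[t] - y;
    yhat[t] = y;
    e[t] = et;
    if (!std::isfinite(et))
      stop("weight update diverged at sample %d (non-finite error)", t + 1);
    if (beta != 0.0) {
      double g = beta * et;
      if (use_motor) {
        int base = t - delay_m;
        for (int i = 0; i < n_taps; ++i) {
          int idx = base - i * stride;
          if (idx < 0) break;
          w[i] += g * u[idx];
        }
      }
      if (use_sense) {
        int base = t - delay_s;
        int off = use_motor ? n_taps : 0;
        for (int i = 0; i < n_taps; ++i) {
          int idx = base - i * stride;
          if (idx < 0) break;
          w[off + i] += g * z[idx];
        }
      }
    }
    if (snapshot_every > 0 && (t + 1) % snapshot_every == 0 &&
        snap_i < n_snaps) {
      for (int j = 0; j < n_total; ++j) snaps(snap_i, j) = w[j];
      snap_at[snap_i] = t + 1;
      ++snap_i;
    }
  }
  return List::create(_["e"] = e, _["yhat"] = yhat, _["weights"] = w,
                      _["snapshots"] = snaps, _["snapshot_sample"] = snap_at);
}
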