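// Fast dataset log-likelihood for the coverage models.
//
// Mirrors the closed forms in R/models.R exactly (same branch and limit
// conventions); the R implementation is the reference, this is the MCMC
// inner loop.  Reads are passed flattened: positions x, a 0-based
// transcript index per read, and per-transcript lengths/read counts.
// Model E is evaluated with the modified rates passed as theta1/theta2 and
// a unit alpha1*alpha2 prefactor (the prefactor cancels between density and
// area, so the total is unchanged).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double e1m(double a) {
  return a == 0.0 ? 1.0 : -std::expm1(-a) / a;
}

// Area under the coverage function for one transcript (models 0=A..4=E).
static double area_one(int m, double t1, double t2, double d, double h,
                       double l) {
  double th = t1 + t2;
  double A0 = 0.0, Ah = 0.0;
  switch (m) {
  case 0:
    A0 = l * std::exp(-l * th);
    Ah = (l - 2.0 * h) * std::exp(-l * th);
    break;
  case 1:
    if (th == 0.0) { A0 = l; Ah = l - 2.0 * h; }
    else {
      A0 = (t1 * l * e1m(l * th) + t2 * l * std::exp(-l * th)) / th;
      Ah = (t1 * (std::exp(-2.0 * h * th) - std::exp(-l * th)) / th +
            t2 * (l - 2.0 * h) * std::exp(-l * th)) / th;
    }
    break;
  case 2:
    A0 = std::exp(-t1 * l) * l * e1m(l * t2);
    Ah = std::exp(-t1 * l) *
      (t2 == 0.0 ? (l - 2.0 * h)
                 : (std::exp(-2.0 * h * t2) - std::exp(-l * t2)) / t2);
    break;
  case 3:
    if (th == 0.0) { A0 = l; Ah = l - 2.0 * h; }
    else {
      A0 = l * e1m(l * th);
      Ah = (std::exp(-2.0 * h * th) - std::exp(-l * th)) / th;
    }
    break;
  case 4: {
    double tp = th;  // t1, t2 are already the modified rates
    double cE = 1.0 / (t1 * tp);
    // note tp here is t1' + t2'
    A0 = cE * (l - l * e1m(l * tp) - l * e1m(l * t1) +
               std::exp(-l * t1) * l * e1m(l * t2));
    Ah = cE * ((l - 2.0 * h) * std::exp(-2.0 * h * tp) -
               (std::exp(-2.0 * h * tp) - std::exp(-l * tp)) / tp -
               std::exp(-2.0 * h * t2) *
                 (std::exp(-2.0 * h * t1) - std::exp(-l * t1)) / t1 +
               std::exp(-l * t1) *
                 (std::exp(-2.0 * h * t2) - std::exp(-l * t2)) / t2);
    break;
  }
  }
  return A0 / d + (h < l / 2.0 ? Ah : 0.0);
}

// [[Rcpp::export]]
double cov_loglik_cpp(int model, double theta1, double theta2, double d,
                      double h, double alpha,
                      NumericVector x, IntegerVector tidx,
                      NumericVector ulen, NumericVector ucount) {
  const int nt = ulen.size();
  const int nr = x.size();
  const double t1 = theta1, t2 = theta2, th = t1 + t2;
  const double neginf = -std::numeric_limits<double>::infinity();

  // per-transcript area term (and constants reused by the read loop)
  std::vector<double> areaT(nt);
  double areasum = 0.0;
  for (int t = 0; t < nt; ++t) {
    double a;
    if (model == 5) {
      a = alpha * area_one(1, t1, t2, d, h, ulen[t]) +
          (1.0 - alpha) * area_one(3, t1, t2, d, h, ulen[t]);
    } else {
      a = area_one(model, t1, t2, d, h, ulen[t]);
    }
    if (!std::isfinite(a) || a <= 0.0) return neginf;
    areaT[t] = a;
    areasum += ucount[t] * std::log(a);
  }

  std::vector<double> El(nt), kB(nt), cC(nt), K2(nt), K3(nt);
  switch (model) {
  case 0:
    break;
  case 1:
    for (int t = 0; t < nt; ++t) El[t] = std::exp(-th * ulen[t]);
    break;
  case 2: case 3:
    for (int t = 0; t < nt; ++t) El[t] = std::exp(-t1 * ulen[t]);
    break;
  case 4: {
    double tp = th;
    for (int t = 0; t < nt; ++t) {
      El[t] = std::exp(-ulen[t] * t1);                       // e^{-l t1'}
      K2[t] = std::exp(-2.0 * h * t2 - (ulen[t] + h) * t1);
      K3[t] = std::exp(-ulen[t] * t1 - h * t2);
      cC[t] = std::exp(-h * tp);
    }
    break;
  }
  case 5:
    for (int t = 0; t < nt; ++t) {
      El[t] = std::exp(-t1 * ulen[t]);                       // e^{-l t1}
      kB[t] = std::exp(-th * ulen[t]);                       // e^{-l th}
    }
    break;
  }

  const double ehB = (th > 0.0) ? std::exp(-th * h) : 1.0;
  const double ehC = std::exp(-t2 * h);
  const double kd1 = std::exp(-t1 * h - 2.0 * t2 * h);
  const double kd2 = std::exp(-t2 * h);
  const double K0E = std::exp(-2.0 * h * th);
  const double invd = 1.0 / d;

  double ll = 0.0;
  for (int i = 0; i < nr; ++i) {
    const int t = tidx[i];
    const double l = ulen[t];
    const double xi = x[i];
    const bool interior = (xi > h && xi < l - h);
    double f;
    switch (model) {
    case 0: {
      double g = std::exp(-l * th);
      f = g * invd + (interior ? g : 0.0);
      break;
    }
    case 1: {
      if (th == 0.0) { f = invd + (interior ? 1.0 : 0.0); break; }
      double w = std::exp(th * xi) * El[t] * t1;
      double k = t2 * El[t];
      double g0 = (w + k) / th;
      f = g0 * invd + (interior ? (w * ehB + k) / th : 0.0);
      break;
    }
    case 2: {
      double v = std::exp(-t2 * xi) * El[t];
      f = v * invd + (interior ? v * ehC : 0.0);
      break;
    }
    case 3: {
      if (th == 0.0) { f = invd + (interior ? 1.0 : 0.0); break; }
      double u = t1 * El[t] * std::exp(t1 * xi);
      double v = t2 * El[t] * std::exp(-t2 * xi);
      f = (u + v) / th * invd + (interior ? (u * kd1 + v * kd2) / th : 0.0);
      break;
    }
    case 4: {
      double tp = th, cE = 1.0 / (t1 * tp);
      double u = std::exp(t1 * xi);
      double v = std::exp(-t2 * xi);
      double exn = v / u;                                    // e^{-x tp}
      double g0 = cE * (1.0 - exn - El[t] * u + El[t] * v);
      double gh = cE * (K0E - cC[t] * exn - K2[t] * u + K3[t] * v);
      f = g0 * invd + (interior ? gh : 0.0);
      break;
    }
    default: {  // BD mixture
      double fB, fD;
      if (th == 0.0) {
        fB = fD = invd + (interior ? 1.0 : 0.0);
      } else {
        double u = std::exp(t1 * xi);
        double v = std::exp(-t2 * xi);
        double w = u / v;                                    // e^{x th}
        double wB = t1 * kB[t] * w;
        double kBc = t2 * kB[t];
        fB = (wB + kBc) / th * invd +
             (interior ? (wB * ehB + kBc) / th : 0.0);
        double uD = t1 * El[t] * u;
        double vD = t2 * El[t] * v;
        fD = (uD + vD) / th * invd +
             (interior ? (uD * kd1 + vD * kd2) / th : 0.0);
      }
      f = alpha * fB + (1.0 - alpha) * fD;
    }
    }
    if (!(f > 0.0) || !std::isfinite(f)) return neginf;
    ll += std::log(f);
  }
  return ll - areasum;
}
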