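#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// State order everywhere: (xL, xA, xO, cA, cL).
// Parameter vector order: r1, r2, K, beta1, beta2, gamma1, gamma2,
// kcA, kcL, ro, influxA, influxL.

static inline double monod(double c, double k) {
  // Saturating uptake fraction; defined as 0 at c = 0 (k > 0 enforced in R).
  if (c <= 0.0) return 0.0;
  return c / (c + k);
}

static void rhs(double t, const double y[5], const double p[12], double dy[5]) {
  (void)t; // autonomous
  const double xL = y[0], xA = y[1], xO = y[2], cA = y[3], cL = y[4];
  const double crowd = 1.0 - (xL + xA + xO) / p[2];
  const double mA = monod(cA, p[7]);
  const double mL = monod(cL, p[8]);
  dy[0] = xL * p[0] * mA * crowd;
  dy[1] = xA * p[1] * mL * crowd;
  dy[2] = xO * p[9] * crowd;
  dy[3] = p[3] * (xA + xO) - p[5] * mA * xL + p[10];
  dy[4] = p[4] * (xL + xO) - p[6] * mL * xA + p[11];
}

// Dormand-Prince 5(4) coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
// 4th-order embedded weights
static const double E1 = 5179.0 / 57600, E3 = 7571.0 / 16695, E4 = 393.0 / 640,
                    E5 = -92097.0 / 339200, E6 = 187.0 / 2100, E7 = 1.0 / 40;

// Integrate the cross-feeding system from times[0] to times[last], writing the
// state at every requested time. `times` must be strictly increasing. Returns
// a length(times) x 5 matrix. Throws on step-size underflow.
// [[Rcpp::export(name = ".cf_integrate_cpp")]]
NumericMatrix cf_integrate_cpp(NumericVector y0, NumericVector times,
                               NumericVector pars, double rtol, double atol,
                               double hmax) {
  if (y0.size() != 5) stop("state vector must have length 5");
  if (pars.size() != 12) stop("parameter vector must have length 12");
  const int nt = times.size();
  if (nt < 1) stop("need at least one output time");

  NumericMatrix out(nt, 5);
  double y[5], k1[5], k2[5], k3[5], k4[5], k5[5], k6[5], k7[5], ytmp[5], y5[5];
  double p[12];
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  for (int i = 0; i < 12; ++i) p[i] = pars[i];

  double t = times[0];
  for (int i = 0; i < 5; ++i) out(0, i) = y[i];

  double h = std::min(hmax, 1e-2);
  const double hmin = 1e-14;
  bool have_k1 = false;

  for (int idx = 1; idx < nt; ++idx) {
    const double tend = times[idx];
    while (t < tend) {
      if (h > hmax) h = hmax;
      if (t + h > tend) h = tend - t;
      if (h < hmin) stop("step size underflow at t = %f", t);
      if (!have_k1) rhs(t, y, p, k1);

      for (int i = 0; i < 5; ++i) ytmp[i] = y[i] + h * A21 * k1[i];
      rhs(t + C2 * h, ytmp, p, k2);
      for (int i = 0; i < 5; ++i)
        ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
      rhs(t + C3 * h, ytmp, p, k3);
      for (int i = 0; i < 5; ++i)
        ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
      rhs(t + C4 * h, ytmp, p, k4);
      for (int i = 0; i < 5; ++i)
        ytmp[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                              A54 * k4[i]);
      rhs(t + C5 * h, ytmp, p, k5);
      for (int i = 0; i < 5; ++i)
        ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                              A64 * k4[i] + A65 * k5[i]);
      rhs(t + h, ytmp, p, k6);
      for (int i = 0; i < 5; ++i)
        y5[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                            B5 * k5[i] + B6 * k6[i]);
      rhs(t + h, y5, p, k7);

      // embedded error estimate
      double errnorm = 0.0;
      for (int i = 0; i < 5; ++i) {
        const double y4 = y[i] + h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] +
                                      E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(y5[i]));
        const double e = (y5[i] - y4) / sc;
        errnorm += e * e;
      }
      errnorm = std::sqrt(errnorm / 5.0);

      if (errnorm <= 1.0) {
        t += h;
        for (int i = 0; i < 5; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
        have_k1 = true; // FSAL
        double fac = 0.9 * std::pow(errnorm > 1e-30 ? errnorm : 1e-30, -0.2);
        if (fac > 5.0) fac = 5.0;
        h *= fac;
      } else {
        double fac = 0.9 * std::pow(errnorm, -0.2);
        if (fac < 0.1) fac = 0.1;
        h *= fac;
        // k1 still valid at unchanged (t, y)
      }
    }
    for (int i = 0; i < 5; ++i) out(idx, i) = y[i];
  }
  return out;
}
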