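#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dormand-Prince 5(4) embedded Runge-Kutta pair, the same family as MATLAB's
// ode45. Hand-rolled because no ODE solver package ships with the target
// environment; the systems here are 2- and 3-dimensional so a dedicated
// integrator is both faster and lighter than a generic one with R callbacks.

namespace {

const double C2 = 1.0 / 5.0, C3 = 3.0 / 10.0, C4 = 4.0 / 5.0, C5 = 8.0 / 9.0;
const double A21 = 1.0 / 5.0;
const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
             A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
             A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
             A65 = -5103.0 / 18656.0;
// 5th-order solution weights (also the A7j row: FSAL)
const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0, B4 = 125.0 / 192.0,
             B5 = -2187.0 / 6784.0, B6 = 11.0 / 84.0;
// embedded 4th-order weights
const double E1 = 5179.0 / 57600.0, E3 = 7571.0 / 16695.0, E4 = 393.0 / 640.0,
             E5 = -92097.0 / 339200.0, E6 = 187.0 / 2100.0, E7 = 1.0 / 40.0;

template <int N, class RHS>
void dp45(const RHS& f, const double* y0, const NumericVector& tgrid,
          double rtol, double atol, NumericMatrix& out) {
  const int nt = tgrid.size();
  double y[N], k1[N], k2[N], k3[N], k4[N], k5[N], k6[N], k7[N], ytmp[N],
      ynew[N];
  for (int j = 0; j < N; ++j) y[j] = y0[j];
  for (int j = 0; j < N; ++j) out(0, j) = y[j];

  double t = tgrid[0];
  const double tend = tgrid[nt - 1];
  const double hmin = 1e-12 * std::max(1.0, std::fabs(tend - tgrid[0]));
  double h = (tend - tgrid[0]) / 100.0;
  f(t, y, k1);
  bool fsal_valid = true;
  int iout = 1;

  while (iout < nt) {
    double tnext = tgrid[iout];
    if (h > tnext - t) h = tnext - t;
    if (h < hmin)
      stop("integrator step size underflow at t = %g", t);

    if (!fsal_valid) {
      f(t, y, k1);
      fsal_valid = true;
    }
    for (int j = 0; j < N; ++j) ytmp[j] = y[j] + h * A21 * k1[j];
    f(t + C2 * h, ytmp, k2);
    for (int j = 0; j < N; ++j)
      ytmp[j] = y[j] + h * (A31 * k1[j] + A32 * k2[j]);
    f(t + C3 * h, ytmp, k3);
    for (int j = 0; j < N; ++j)
      ytmp[j] = y[j] + h * (A41 * k1[j] + A42 * k2[j] + A43 * k3[j]);
    f(t + C4 * h, ytmp, k4);
    for (int j = 0; j < N; ++j)
      ytmp[j] =
          y[j] + h * (A51 * k1[j] + A52 * k2[j] + A53 * k3[j] + A54 * k4[j]);
    f(t + C5 * h, ytmp, k5);
    for (int j = 0; j < N; ++j)
      ytmp[j] = y[j] + h * (A61 * k1[j] + A62 * k2[j] + A63 * k3[j] +
                            A64 * k4[j] + A65 * k5[j]);
    f(t + h, ytmp, k6);
    for (int j = 0; j < N; ++j)
      ynew[j] = y[j] + h * (B1 * k1[j] + B3 * k3[j] + B4 * k4[j] + B5 * k5[j] +
                            B6 * k6[j]);
    f(t + h, ynew, k7);

    double errnorm = 0.0;
    for (int j = 0; j < N; ++j) {
      double e = h * ((B1 - E1) * k1[j] + (B3 - E3) * k3[j] +
                      (B4 - E4) * k4[j] + (B5 - E5) * k5[j] +
                      (B6 - E6) * k6[j] - E7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / N);

    if (!R_finite(errnorm))
      stop("integrator produced non-finite values at t = %g", t);

    if (errnorm <= 1.0) {
      t += h;
      for (int j = 0; j < N; ++j) {
        y[j] = ynew[j];
        k1[j] = k7[j];  // FSAL
      }
      if (t >= tnext - 1e-14 * std::max(1.0, std::fabs(tnext))) {
        for (int j = 0; j < N; ++j) out(iout, j) = y[j];
        ++iout;
      }
    } else {
      fsal_valid = true;  // k1 still valid at unchanged (t, y)
    }
    double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
  }
}

struct ReducedRHS {
  double p, q, r, d, g;
  void operator()(double, const double* y, double* dy) const {
    // y[0] = [Ca2+]cyt (nM), y[1] = [Ca2+]ret (nM)
    dy[0] = p - q * y[0] + r * y[1] - d * y[0] * y[0];
    dy[1] = g * (y[0] - y[1]);
  }
};

struct FullRHS {
  // closed three-compartment model: cytosol, ER, acidic vesicles
  double pleak1, pleak2, a_ret, a_ves;
  double k_serca, k_av;     // pump composite rates (flux = k * ca_cyt^2 * sat)
  double atp_sat;           // [ATP]/(Km + [ATP]), held constant
  double fc_vc, fr_vr, fv_vv;  // f_X / Vol_X for each compartment
  bool thapsigargin;
  void operator()(double, const double* y, double* dy) const {
    double cyt = y[0], ret = y[1], ves = y[2];
    double j1 = thapsigargin ? 0.0 : k_serca * cyt * cyt * atp_sat;
    double j2 = k_av * cyt * cyt * atp_sat;
    double j3 = pleak1 * a_ret * (ret - cyt);
    double j4 = pleak2 * a_ves * (ves - cyt);
    dy[0] = fc_vc * (-j1 - j2 + j3 + j4);
    dy[1] = fr_vr * (j1 - j3);
    dy[2] = fv_vv * (j2 - j4);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_simulate_reduced(double p, double q, double r, double d,
                                   double g, NumericVector ic,
                                   NumericVector tgrid, double rtol,
                                   double atol) {
  ReducedRHS f{p, q, r, d, g};
  NumericMatrix out(tgrid.size(), 2);
  dp45<2>(f, &ic[0], tgrid, rtol, atol, out);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_full(List pars, NumericVector ic,
                                NumericVector tgrid, double rtol, double atol,
                                bool thapsigargin) {
  FullRHS f{as<double>(pars["p_leak1"]), as<double>(pars["p_leak2"]),
            as<double>(pars["a_ret"]),   as<double>(pars["a_ves"]),
            as<double>(pars["k_serca"]), as<double>(pars["k_av"]),
            as<double>(pars["atp_sat"]), as<double>(pars["fc_vc"]),
            as<double>(pars["fr_vr"]),   as<double>(pars["fv_vv"]),
            thapsigargin};
  NumericMatrix out(tgrid.size(), 3);
  dp45<3>(f, &ic[0], tgrid, rtol, atol, out);
  return out;
}
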