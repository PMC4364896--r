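#include <Rcpp.h>
using namespace Rcpp;

// Functional response g(F). kind: 0 piecewise (Holling I), 1 ivlev,
// 2 holling2 (standard type II), 3 uncapped. F is clamped at 0 so that
// RK4 stage states that overshoot below zero cannot produce negative
// consumption.
static inline double g_of_F(int kind, double c, double shape, double F) {
  if (F < 0.0) F = 0.0;
  switch (kind) {
  case 0: return c * (F < shape ? F : shape);        // c1 * min(F, K)
  case 1: return c * (1.0 - std::exp(-shape * F));   // c2 * (1 - exp(-e F))
  case 2: return c * F / (F + shape);                // c2 * F / (F + K)
  default: return c * F;                             // c1 * F
  }
}

struct Deriv {
  int kind; double c, shape, alpha, mu1, mu2, h; bool feedback;
  inline void operator()(double M, double F, double S,
                         double &dM, double &dF) const {
    if (M < 0.0) M = 0.0;
    if (F < 0.0) F = 0.0;
    const double g = g_of_F(kind, c, shape, F);
    dM = (alpha * g - mu1 - mu2 * M) * M;
    dF = S - h * F - (feedback ? g * M : 0.0);
  }
};

// Quarter-segmented classical RK4 simulation of the consumer-resource
// system. Food F is reset to 0 at each year start; seed input S is
// F_year/0.25 during the first quarter and 0 otherwise, so forcing
// discontinuities and the reset fall exactly on segment boundaries.
// M is recorded at the start of every quarter (before integrating it).
// States are floored at 0 after each full step; floored steps are counted.
// [[Rcpp::export]]
List simulate_rk4_cpp(double m0, NumericVector seedfall, int fr_kind,
                      double c, double shape, double alpha,
                      double mu1, double mu2, double h,
                      bool feedback, int steps_per_quarter, bool dense) {
  const int n_years = seedfall.size();
  const int n_q = 4 * n_years;
  const double dt = 0.25 / steps_per_quarter;
  Deriv deriv{fr_kind, c, shape, alpha, mu1, mu2, h, feedback};

  NumericVector q_M(n_q), q_time(n_q);
  IntegerVector q_year(n_q), q_quarter(n_q);
  const long n_dense = dense ? (long)n_years * 4 * steps_per_quarter + 1 : 0;
  NumericVector d_t(dense ? n_dense : 0), d_M(dense ? n_dense : 0),
                d_F(dense ? n_dense : 0);

  double M = m0, F = 0.0;
  long floored = 0, di = 0;
  if (dense) { d_t[di] = 0.0; d_M[di] = M; d_F[di] = F; ++di; }

  for (int y = 0; y < n_years; ++y) {
    F = 0.0;  // no seed carry-over between annual cycles
    const double Fy = seedfall[y];
    for (int q = 0; q < 4; ++q) {
      const int qi = 4 * y + q;
      q_M[qi] = M;
      q_time[qi] = y + 0.25 * q;
      q_year[qi] = y;
      q_quarter[qi] = q;
      const double S = (q == 0) ? Fy / 0.25 : 0.0;
      for (int s = 0; s < steps_per_quarter; ++s) {
        // At the start of the delivery quarter F rises from the reset value
        // of 0 through the functional response's saturation scale within a
        // time ~1/S, a boundary layer that can be narrower than dt for
        // large crops. Substep the first two base steps to resolve it.
        int n_sub = 1;
        if (q == 0 && S > 0.0 && s < 2) n_sub = (s == 0) ? 64 : 8;
        const double h_sub = dt / n_sub;
        for (int u = 0; u < n_sub; ++u) {
          double k1M, k1F, k2M, k2F, k3M, k3F, k4M, k4F;
          deriv(M, F, S, k1M, k1F);
          deriv(M + 0.5 * h_sub * k1M, F + 0.5 * h_sub * k1F, S, k2M, k2F);
          deriv(M + 0.5 * h_sub * k2M, F + 0.5 * h_sub * k2F, S, k3M, k3F);
          deriv(M + h_sub * k3M, F + h_sub * k3F, S, k4M, k4F);
          M += h_sub / 6.0 * (k1M + 2.0 * k2M + 2.0 * k3M + k4M);
          F += h_sub / 6.0 * (k1F + 2.0 * k2F + 2.0 * k3F + k4F);
        }
        if (M < 0.0) { M = 0.0; ++floored; }
        if (F < 0.0) { F = 0.0; ++floored; }
        if (!std::isfinite(M) || !std::isfinite(F)) {
          stop("non-finite state at t = %f (year %d, quarter %d): "
               "M = %f, F = %f", y + 0.25 * q + (s + 1) * dt, y + 1, q + 1,
               M, F);
        }
        if (dense) {
          d_t[di] = y + 0.25 * q + (s + 1) * dt;
          d_M[di] = M; d_F[di] = F; ++di;
        }
      }
    }
  }

  List out = List::create(
    _["q_time"] = q_time, _["q_year"] = q_year, _["q_quarter"] = q_quarter,
    _["q_M"] = q_M, _["n_floored"] = (double)floored);
  if (dense) {
    out["t"] = d_t; out["M"] = d_M; out["F"] = d_F;
  }
  return out;
}
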