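// Method-of-steps integrator for the delayed HPA-axis system.
//
// State layout (7 components):
//   0 cs    stored CRH
//   1 c     circulating CRH
//   2 a     circulating ACTH
//   3 r     available pituitary GR
//   4 o     circulating cortisol
//   5 o_exo circulating dexamethasone (cortisol equivalents)
//   6 a_exo circulating cosyntropin (ACTH equivalents)
//
// Fixed-step explicit RK4 with a dense history built from cubic Hermite
// interpolation of stored (t, y, y') knots. The delayed terms a(t - t_d) and
// a_exo(t - t_d) are read from that history; with step <= t_d every stage
// lookup lands in already-computed territory, so the scheme stays explicit.
// Rectangle inputs (stress steps, dose pulses) define mandatory breakpoints:
// integration restarts exactly there and piecewise-constant forcing is
// sampled per segment, so no step ever straddles a discontinuity. Nodes are
// duplicated at breakpoints carrying left/right derivatives, which keeps the
// Hermite history one-sided around the jump.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Par {
  double q0, q1, q2, gc_max, n, k, b, c_inf_bar, t_c;
  double p2, p3, p4, p5, p6, t_d, I0, p7, p8;
};

Par as_par(const NumericVector& p) {
  Par P;
  P.q0 = p["q0"]; P.q1 = p["q1"]; P.q2 = p["q2"];
  P.gc_max = p["gc_max"]; P.n = p["n"]; P.k = p["k"]; P.b = p["b"];
  P.c_inf_bar = p["c_inf_bar"]; P.t_c = p["t_c"];
  P.p2 = p["p2"]; P.p3 = p["p3"]; P.p4 = p["p4"]; P.p5 = p["p5"];
  P.p6 = p["p6"]; P.t_d = p["t_d"]; P.I0 = p["I0"];
  P.p7 = p["p7"]; P.p8 = p["p8"];
  return P;
}

typedef std::array<double, 7> State;

inline void rhs(const double* y, double a_del, double aexo_del,
                double I, double Pio, double Pia,
                const Par& P, bool clamp_c, double* f) {
  const double cs = y[0], c = y[1], a = y[2], r = y[3], o = y[4];
  const double oe = y[5], ae = y[6];
  // stored-CRH synthesis target: DEX does not reach the brain compartment,
  // so only endogenous cortisol enters here
  f[0] = (P.c_inf_bar + std::exp(-P.b * o) - cs) / P.t_c;
  if (clamp_c) {
    f[1] = 0.0;
  } else {
    const double hcs = 1.0 - std::exp(-P.k * cs);
    const double x = P.q1 * c;
    const double xn = std::pow(x, P.n);
    f[1] = P.q0 * I * hcs + P.gc_max * xn / (1.0 + xn) - P.q2 * c;
  }
  const double orp = (o + oe) * r;  // cortisol(-equivalent).GR complex
  f[2] = c / (1.0 + P.p2 * orp) - P.p3 * a;
  f[3] = orp * orp / (P.p4 + orp * orp) + P.p5 - P.p6 * r;
  f[4] = a_del + aexo_del - o;
  f[5] = Pio - P.p7 * oe;
  f[6] = Pia - P.p8 * ae;
}

struct HistoryStore {
  std::vector<double> t;
  std::vector<State> y;
  std::vector<State> f;

  void push(double ti, const State& yi, const State& fi) {
    t.push_back(ti); y.push_back(yi); f.push_back(fi);
  }

  // cubic Hermite evaluation of components 2 (a) and 6 (a_exo) at time s
  void delayed(double s, double& a_del, double& aexo_del) const {
    if (s <= t.front()) {
      a_del = y.front()[2]; aexo_del = y.front()[6];
      return;
    }
    if (s >= t.back()) {
      a_del = y.back()[2]; aexo_del = y.back()[6];
      return;
    }
    // last index with t[j] <= s (duplicated breakpoint nodes resolve to the
    // right-hand copy so the one-sided derivative is used)
    size_t j = std::upper_bound(t.begin(), t.end(), s) - t.begin() - 1;
    while (j + 1 < t.size() && t[j + 1] <= t[j]) ++j;
    if (j + 1 >= t.size()) { a_del = y.back()[2]; aexo_del = y.back()[6]; return; }
    const double h = t[j + 1] - t[j];
    if (h <= 0.0) { a_del = y[j][2]; aexo_del = y[j][6]; return; }
    const double u = (s - t[j]) / h;
    const double u2 = u * u, u3 = u2 * u;
    const double h00 = 2 * u3 - 3 * u2 + 1, h10 = u3 - 2 * u2 + u;
    const double h01 = -2 * u3 + 3 * u2,    h11 = u3 - u2;
    a_del   = h00 * y[j][2] + h * h10 * f[j][2] + h01 * y[j + 1][2] + h * h11 * f[j + 1][2];
    aexo_del = h00 * y[j][6] + h * h10 * f[j][6] + h01 * y[j + 1][6] + h * h11 * f[j + 1][6];
  }
};

inline void stage_delay(const HistoryStore& H, double t_stage, const double* y_stage,
                        double t_d, double& a_del, double& aexo_del) {
  if (t_d <= 0.0) { a_del = y_stage[2]; aexo_del = y_stage[6]; }
  else H.delayed(t_stage - t_d, a_del, aexo_del);
}

} // namespace

// [[Rcpp::export(name = ".integrate_core")]]
List integrate_core(NumericVector params,
                    NumericVector hist_times,
                    NumericMatrix hist_states,
                    NumericMatrix hist_derivs,
                    double t0, double t1,
                    NumericMatrix input_steps,  // cols: start, end, amp
                    NumericMatrix pulses,       // cols: comp (0 dex, 1 acth), start, end, height
                    double step,
                    bool clamp_c) {
  const Par P = as_par(params);
  if (step <= 0) stop("step must be positive");
  if (P.t_d > 0 && step > P.t_d + 1e-12)
    stop("step (%g) must not exceed the delay t_d (%g)", step, P.t_d);
  if (t1 <= t0) stop("t_span must have positive length");
  const int m = hist_times.size();
  if (m < 1) stop("history must contain at least one knot");
  if (std::abs(hist_times[m - 1] - t0) > 1e-9)
    stop("history must end exactly at t0");
  if (P.t_d > 0 && hist_times[0] > t0 - P.t_d + 1e-9)
    stop("history does not cover the lookback window [t0 - t_d, t0]");

  HistoryStore H;
  const size_t n_est = m + (size_t)((t1 - t0) / step) + 16;
  H.t.reserve(n_est); H.y.reserve(n_est); H.f.reserve(n_est);
  for (int i = 0; i < m; ++i) {
    State yi, fi;
    for (int j = 0; j < 7; ++j) { yi[j] = hist_states(i, j); fi[j] = hist_derivs(i, j); }
    if (*std::min_element(yi.begin(), yi.end()) < 0)
      stop("history states must be nonnegative");
    H.push(hist_times[i], yi, fi);
  }

  // segment breakpoints: every rectangle edge inside (t0, t1)
  std::vector<double> bp;
  bp.push_back(t0); bp.push_back(t1);
  for (int i = 0; i < input_steps.nrow(); ++i) {
    for (int col = 0; col < 2; ++col) {
      double v = input_steps(i, col);
      if (v > t0 + 1e-12 && v < t1 - 1e-12) bp.push_back(v);
    }
  }
  for (int i = 0; i < pulses.nrow(); ++i) {
    for (int col = 1; col < 3; ++col) {
      double v = pulses(i, col);
      if (v > t0 + 1e-12 && v < t1 - 1e-12) bp.push_back(v);
    }
  }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::abs(a - b) < 1e-12; }),
           bp.end());

  std::vector<double> out_I;
  out_I.resize(H.t.size(), NA_REAL);

  State y = H.y.back();

  for (size_t seg = 0; seg + 1 < bp.size(); ++seg) {
    const double ta = bp[seg], tb = bp[seg + 1];
    const double tmid = 0.5 * (ta + tb);
    // piecewise-constant forcing, sampled at the segment midpoint
    double I = P.I0, Pio = 0.0, Pia = 0.0;
    for (int i = 0; i < input_steps.nrow(); ++i)
      if (input_steps(i, 0) <= tmid && tmid < input_steps(i, 1))
        I += input_steps(i, 2);
    for (int i = 0; i < pulses.nrow(); ++i)
      if (pulses(i, 1) <= tmid && tmid < pulses(i, 2)) {
        if (pulses(i, 0) < 0.5) Pio += pulses(i, 3); else Pia += pulses(i, 3);
      }

    const int nseg = std::max(1, (int)std::ceil((tb - ta) / step - 1e-9));
    const double h = (tb - ta) / nseg;

    // restart node: duplicate the last knot with the right-sided derivative
    {
      State f0;
      double a_del, aexo_del;
      stage_delay(H, ta, y.data(), P.t_d, a_del, aexo_del);
      rhs(y.data(), a_del, aexo_del, I, Pio, Pia, P, clamp_c, f0.data());
      H.push(ta, y, f0);
      out_I.push_back(I);
    }

    for (int i = 1; i <= nseg; ++i) {
      const double t = ta + (i - 1) * h;
      const double tn = (i == nseg) ? tb : ta + i * h;
      State k1, k2, k3, k4, ytmp;
      double a_del, aexo_del;

      k1 = H.f.back();  // derivative stored at the current node

      for (int j = 0; j < 7; ++j) ytmp[j] = y[j] + 0.5 * h * k1[j];
      stage_delay(H, t + 0.5 * h, ytmp.data(), P.t_d, a_del, aexo_del);
      rhs(ytmp.data(), a_del, aexo_del, I, Pio, Pia, P, clamp_c, k2.data());

      for (int j = 0; j < 7; ++j) ytmp[j] = y[j] + 0.5 * h * k2[j];
      stage_delay(H, t + 0.5 * h, ytmp.data(), P.t_d, a_del, aexo_del);
      rhs(ytmp.data(), a_del, aexo_del, I, Pio, Pia, P, clamp_c, k3.data());

      for (int j = 0; j < 7; ++j) ytmp[j] = y[j] + h * k3[j];
      stage_delay(H, tn, ytmp.data(), P.t_d, a_del, aexo_del);
      rhs(ytmp.data(), a_del, aexo_del, I, Pio, Pia, P, clamp_c, k4.data());

      for (int j = 0; j < 7; ++j)
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

      for (int j = 0; j < 7; ++j)
        if (!std::isfinite(y[j]))
          stop("integration failed (non-finite state) at t = %g", tn);

      State fn;
      stage_delay(H, tn, y.data(), P.t_d, a_del, aexo_del);
      rhs(y.data(), a_del, aexo_del, I, Pio, Pia, P, clamp_c, fn.data());
      H.push(tn, y, fn);
      out_I.push_back(I);
    }
  }

  const size_t n = H.t.size();
  NumericVector times(n), Iout(n);
  NumericMatrix states(n, 7), derivs(n, 7);
  for (size_t i = 0; i < n; ++i) {
    times[i] = H.t[i];
    Iout[i] = out_I[i];
    for (int j = 0; j < 7; ++j) {
      states(i, j) = H.y[i][j];
      derivs(i, j) = H.f[i][j];
    }
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["derivs"] = derivs, _["I"] = Iout,
                      _["n_history"] = m);
}
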