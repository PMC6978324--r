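#include <Rcpp.h>
using namespace Rcpp;

// Tilted double-well: U(x) = -dE*G(x;cE,w) - dS*G(x;cS,w) + B*G(x;mid,wb)
//                            + 0.5*kc*|x - mid|^2
// G(x;c,w) = exp(-|x-c|^2 / (2 w^2)).  Depths are the sodium-adjusted
// effective depths; all energies in kT units of the spec.
struct DoubleWell {
  double cEx, cEy, cSx, cSy;   // well centers
  double dE, dS;               // effective depths
  double B, w2, wb2, kc;       // barrier height, widths^2, confinement
  double mx, my;               // midpoint (barrier + confinement center)

  inline void grad(double x, double y, double &gx, double &gy) const {
    const double dxE = x - cEx, dyE = y - cEy;
    const double dxS = x - cSx, dyS = y - cSy;
    const double dxm = x - mx,  dym = y - my;
    const double gE = std::exp(-(dxE * dxE + dyE * dyE) / (2.0 * w2));
    const double gS = std::exp(-(dxS * dxS + dyS * dyS) / (2.0 * w2));
    const double gB = std::exp(-(dxm * dxm + dym * dym) / (2.0 * wb2));
    gx = dE * gE * dxE / w2 + dS * gS * dxS / w2 - B * gB * dxm / wb2 + kc * dxm;
    gy = dE * gE * dyE / w2 + dS * gS * dyS / w2 - B * gB * dym / wb2 + kc * dym;
  }
};

static DoubleWell unpack(const NumericVector &p) {
  DoubleWell dw;
  dw.cEx = p[0]; dw.cEy = p[1]; dw.cSx = p[2]; dw.cSy = p[3];
  dw.dE = p[4]; dw.dS = p[5]; dw.B = p[6];
  dw.w2 = p[7] * p[7]; dw.wb2 = p[8] * p[8]; dw.kc = p[9];
  dw.mx = 0.5 * (dw.cEx + dw.cSx); dw.my = 0.5 * (dw.cEy + dw.cSy);
  return dw;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_overdamped(NumericVector pars, int n_steps,
                                      double dt, double kT,
                                      NumericVector start) {
  const DoubleWell dw = unpack(pars);
  NumericMatrix out(n_steps + 1, 2);
  double x = start[0], y = start[1];
  out(0, 0) = x; out(0, 1) = y;
  const double noise = std::sqrt(2.0 * kT * dt);
  double gx, gy;
  for (int i = 1; i <= n_steps; ++i) {
    dw.grad(x, y, gx, gy);
    x += -gx * dt + noise * norm_rand();
    y += -gy * dt + noise * norm_rand();
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("position became non-finite at step %d: time step dt = %g is too "
           "large for this potential stiffness", i, dt);
    out(i, 0) = x; out(i, 1) = y;
  }
  return out;
}

// One-sided harmonic restraint on the Euclidean deviation from `reference`;
// the per-step target is supplied precomputed (linear ramp then hold).
// The bias log records, for each integration step, the target in force,
// the deviation at the start of the step and the bias energy there.
// [[Rcpp::export]]
List cpp_simulate_targeted(NumericVector pars, NumericVector reference,
                           NumericVector targets, double k_force,
                           double dt, double kT, NumericVector start) {
  const DoubleWell dw = unpack(pars);
  const int n_steps = targets.size();
  NumericMatrix pos(n_steps + 1, 2);
  NumericVector dev(n_steps), ebias(n_steps);
  double x = start[0], y = start[1];
  pos(0, 0) = x; pos(0, 1) = y;
  const double noise = std::sqrt(2.0 * kT * dt);
  double gx, gy;
  for (int i = 0; i < n_steps; ++i) {
    dw.grad(x, y, gx, gy);
    const double rx = x - reference[0], ry = y - reference[1];
    const double d = std::sqrt(rx * rx + ry * ry);
    dev[i] = d;
    const double tgt = targets[i];
    if (d > tgt) {
      const double excess = d - tgt;
      ebias[i] = 0.5 * k_force * excess * excess;
      if (d > 0) {  // bias force: -k (d - target) * (r / d)
        gx += k_force * excess * rx / d;
        gy += k_force * excess * ry / d;
      }
    } else {
      ebias[i] = 0.0;
    }
    x += -gx * dt + noise * norm_rand();
    y += -gy * dt + noise * norm_rand();
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("position became non-finite at step %d: time step dt = %g is too "
           "large for this potential stiffness or bias force constant", i + 1, dt);
    pos(i + 1, 0) = x; pos(i + 1, 1) = y;
  }
  return List::create(_["positions"] = pos, _["deviation"] = dev,
                      _["bias_energy"] = ebias);
}

// Chain sampling by inverse-CDF on precomputed cumulative rows.
// States are 1-based.  T is assumed row-stochastic (validated in R).
// [[Rcpp::export]]
IntegerVector cpp_sample_markov_chain(NumericMatrix T, int n_steps,
                                      int start_state) {
  const int n = T.nrow();
  NumericMatrix cum(n, n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) { s += T(i, j); cum(i, j) = s; }
    cum(i, n - 1) = 1.0;  // guard against rounding
  }
  IntegerVector out(n_steps + 1);
  int s = start_state - 1;
  out[0] = s + 1;
  for (int t = 1; t <= n_steps; ++t) {
    const double u = unif_rand();
    int j = 0;
    while (j < n - 1 && cum(s, j) < u) ++j;
    s = j;
    out[t] = s + 1;
  }
  return out;
}
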