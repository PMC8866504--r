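#include <Rcpp.h>
using namespace Rcpp;

// Coupled forward-Euler integration of the sensory neurons, the 30-neuron
// graded-potential network, the point-agent kinematics, and the (optionally
// time-varying) chemical synapse strengths. One call simulates one run.
//
// The per-step ordering mirrors the plain-R sensory steppers exactly
// (voltage derivative with the current conductance, then the stimulus rate
// variable, then the channel states with their sum conserved, then the
// conductance), so the two routes agree to machine precision on matched
// inputs. All neuron voltages update synchronously from the state at time t.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static double field_c(int kind, const NumericVector& ep, double px, double py,
                      double x, double y, double t) {
  if (kind == 0) { // isotropic
    return ep[0];
  } else if (kind == 1) { // conical
    double kappa = ep[0], r_max = ep[1];
    bool literal = ep[2] != 0.0;
    if (literal) return kappa * std::sqrt(x * x + y * y);
    double d = std::sqrt((x - px) * (x - px) + (y - py) * (y - py));
    double c = kappa * (r_max - d);
    return c > 0 ? c : 0.0;
  }
  // gaussian diffusion from a point deposit
  double N0 = ep[0], Dc = ep[1], dc = ep[2], t0 = ep[3];
  double r2 = (x - px) * (x - px) + (y - py) * (y - py);
  double tt = t + t0;
  return N0 / (4.0 * M_PI * dc * Dc * tt) * std::exp(-r2 / (400.0 * Dc * tt));
}

// [[Rcpp::export]]
List sim_run_cpp(IntegerVector chem_pre, IntegerVector chem_post,
                 NumericVector chem_E,
                 IntegerVector gap_a, IntegerVector gap_b, NumericVector gap_w,
                 NumericMatrix chem_guideposts, double liquid_delta_t,
                 double liquid_t0,
                 NumericVector b, NumericVector tau, NumericVector osc_sign,
                 double w_osc, double w_nmj,
                 IntegerVector dorsal_idx, IntegerVector ventral_idx,
                 NumericVector sensory, IntegerVector ablated,
                 int env_kind, NumericVector env_par, double c_scale,
                 double peak_x, double peak_y,
                 double x0, double y0, double theta0,
                 double duration, double dt, double speed,
                 int record_every, double stim_time, double stim_dc,
                 double capture_radius, bool record_voltages) {
  const int n = b.size();
  const int nc = chem_pre.size();
  const int ng = gap_a.size();
  const int K = chem_guideposts.ncol();
  const int ASEL = 0, ASER = 1; // roster order contract
  const double T_osc = 4.2;

  // sensory parameter unpacking (fixed order)
  const double tau_R = sensory[0], beta_R = sensory[1], tau_aR = sensory[2],
               gamma_R = sensory[3], E_R_ext = sensory[4],
               tau_L = sensory[5], beta_L = sensory[6], tau_aL = sensory[7],
               gamma_L = sensory[8], E_L_Ca = sensory[9],
               in_thres = sensory[10], xi_range = sensory[11];

  std::vector<double> V(n, 0.0), newV(n, 0.0), f(n, 0.0);
  std::vector<double> S_w(n, 0.0), S_wE(n, 0.0), S_g(n, 0.0), S_gV(n, 0.0);
  // hot-loop caches (avoid Rcpp bounds-checked accessors per step)
  const std::vector<int> cpre(chem_pre.begin(), chem_pre.end());
  const std::vector<int> cpost(chem_post.begin(), chem_post.end());
  const std::vector<double> cE(chem_E.begin(), chem_E.end());
  const std::vector<int> ga_(gap_a.begin(), gap_a.end());
  const std::vector<int> gb_(gap_b.begin(), gap_b.end());
  const std::vector<double> gw(gap_w.begin(), gap_w.end());
  const std::vector<double> b_(b.begin(), b.end());
  const std::vector<double> tau_(tau.begin(), tau.end());
  const std::vector<double> osg(osc_sign.begin(), osc_sign.end());
  const std::vector<int> abl(ablated.begin(), ablated.end());
  const double* gpp = chem_guideposts.begin(); // column-major nc x K
  double uR = 1.0, hR = 0.0, aR = 0.0, gR = 0.0;
  double uL = 1.0, hL = 0.0, aL = 0.0, gL = 0.0;
  double x = x0, y = y0, theta = theta0;

  const int n_steps = (int)std::floor(duration / dt + 0.5);
  if (record_every < 1) record_every = n_steps; // record only first and last

  int n_rows = n_steps / record_every + 1;
  if (n_steps % record_every != 0) n_rows += 1;
  NumericMatrix traj(n_rows, 13);
  NumericMatrix volts(record_voltages ? n_rows : 1, record_voltages ? n : 1);
  int row = 0;

  std::vector<double> w_now(nc);
  if (K == 1) {
    for (int e = 0; e < nc; ++e) w_now[e] = gpp[e];
  }
  double C_prev = field_c(env_kind, env_par, peak_x, peak_y, x, y, 0.0);
  const double r0 = std::sqrt((x - peak_x) * (x - peak_x) +
                              (y - peak_y) * (y - peak_y));
  double r_prev = r0, r_int = 0.0, min_r = r0;
  bool captured = (r0 <= capture_radius), diverged = false;
  double t_end = duration;

  for (int i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    const double C_now = field_c(env_kind, env_par, peak_x, peak_y, x, y, t);
    double dC = (C_now - C_prev) / c_scale;
    if (dC > 1.0) dC = 1.0;
    if (dC < -1.0) dC = -1.0;
    if (stim_time >= 0.0 && t >= stim_time && t < stim_time + dt) dC = stim_dc;

    for (int j = 0; j < n; ++j) {
      f[j] = abl[j] ? 0.0 : sigmoid(V[j] + b_[j]);
    }
    double sumD = 0.0, sumVv = 0.0;
    for (int k = 0; k < dorsal_idx.size(); ++k) sumD += f[dorsal_idx[k]];
    for (int k = 0; k < ventral_idx.size(); ++k) sumVv += f[ventral_idx[k]];
    const double phi = w_nmj * (sumD - sumVv);

    if (i % record_every == 0 || i == n_steps) {
      traj(row, 0) = t;      traj(row, 1) = x;      traj(row, 2) = y;
      traj(row, 3) = theta;  traj(row, 4) = phi;    traj(row, 5) = C_now;
      traj(row, 6) = dC;
      traj(row, 7) = f[dorsal_idx[0]];  traj(row, 8) = f[dorsal_idx[1]];
      traj(row, 9) = f[ventral_idx[0]]; traj(row, 10) = f[ventral_idx[1]];
      traj(row, 11) = V[ASEL];          traj(row, 12) = V[ASER];
      if (record_voltages) {
        for (int j = 0; j < n; ++j) volts(row, j) = V[j];
      }
      ++row;
    }
    if (i == n_steps) break;

    // chemical weights at time t (K == 1 means fixed weights, set once)
    if (K != 1) {
      double s = (t - liquid_t0) / liquid_delta_t;
      int k = (int)std::floor(s);
      if (k < 0) k = 0;
      if (k > K - 2) k = K - 2;
      double frac = s - k;
      for (int e = 0; e < nc; ++e) {
        const double a = gpp[(size_t)k * nc + e], bb = gpp[(size_t)(k + 1) * nc + e];
        // equal guideposts short-circuit keeps sigma = 0 schedules bit-equal
        // to the fixed-weight model
        w_now[e] = (a == bb) ? a : (1.0 - frac) * a + frac * bb;
      }
    }

    // synaptic conductance accumulators from the state at t:
    // S_w = sum w f, S_wE = sum w f E (chemical); S_g = sum w_g,
    // S_gV = sum w_g V_j (electrical)
    std::fill(S_w.begin(), S_w.end(), 0.0);
    std::fill(S_wE.begin(), S_wE.end(), 0.0);
    std::fill(S_g.begin(), S_g.end(), 0.0);
    std::fill(S_gV.begin(), S_gV.end(), 0.0);
    for (int e = 0; e < nc; ++e) {
      const int post = cpost[e];
      const double wf = w_now[e] * f[cpre[e]];
      S_w[post] += wf;
      S_wE[post] += wf * cE[e];
    }
    for (int e = 0; e < ng; ++e) {
      const int a = ga_[e], bb = gb_[e];
      S_g[a] += gw[e];
      S_gV[a] += gw[e] * V[bb];
      S_g[bb] += gw[e];
      S_gV[bb] += gw[e] * V[a];
    }

    // ASER: graded OFF-cell (explicit: its total conductance is bounded)
    {
      const double I_chem_R = S_wE[ASER] - V[ASER] * S_w[ASER];
      const double I_gap_R = S_gV[ASER] - V[ASER] * S_g[ASER];
      const double dV = (-V[ASER] + I_chem_R + I_gap_R -
                         gR * (V[ASER] - E_R_ext)) / tau_R;
      if (dC < 0) aR = -dC; else aR += dt * (-aR / tau_aR);
      const double du = -aR * uR + beta_R * hR;
      uR += dt * du;
      hR -= dt * du;
      gR = std::tanh(gamma_R * hR);
      newV[ASER] = V[ASER] + dt * dV;
    }
    // ASEL: stochastic all-or-none ON-cell
    {
      const double dV = (-V[ASEL] - gL * (V[ASEL] - E_L_Ca)) / tau_L;
      if (dC > 0) {
        const double net_L = std::tanh(
            (S_wE[ASEL] - V[ASEL] * S_w[ASEL]) +
            (S_gV[ASEL] - V[ASEL] * S_g[ASEL]));
        const double xi = R::runif(-xi_range, xi_range);
        if (dC + net_L + xi > in_thres) aL = 1.0;
        else aL += dt * (-aL / tau_aL);
      } else {
        aL += dt * (-aL / tau_aL);
      }
      const double du = -aL * uL + beta_L * hL;
      uL += dt * du;
      hL -= dt * du;
      gL = std::tanh(gamma_L * hL);
      newV[ASEL] = V[ASEL] + dt * dV;
    }
    // interneurons and motor neurons: semi-implicit update. The voltage
    // equation is linear in V given the presynaptic outputs, so treating
    // the leak and conductance terms implicitly is unconditionally stable
    // at fixed dt while keeping the same fixed points and O(dt) accuracy.
    const double osc = w_osc * std::sin(2.0 * M_PI * t / T_osc);
    for (int j = 2; j < n; ++j) {
      if (abl[j]) { newV[j] = 0.0; continue; }
      const double a = dt / tau_[j];
      const double drive = S_wE[j] + S_gV[j] + osg[j] * osc;
      newV[j] = (V[j] + a * drive) / (1.0 + a * (1.0 + S_w[j] + S_g[j]));
    }
    if (abl[ASEL]) newV[ASEL] = 0.0;
    if (abl[ASER]) newV[ASER] = 0.0;

    // kinematics
    x += dt * speed * std::cos(theta);
    y += dt * speed * std::sin(theta);
    theta += dt * phi;

    std::swap(V, newV);
    C_prev = C_now;

    const double r = std::sqrt((x - peak_x) * (x - peak_x) +
                               (y - peak_y) * (y - peak_y));
    r_int += 0.5 * (r_prev + r) * dt;
    r_prev = r;
    if (r < min_r) min_r = r;
    if (r <= capture_radius) captured = true;

    bool bad = false;
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(V[j]) || std::fabs(V[j]) > 1e6) { bad = true; break; }
    }
    if (bad || !std::isfinite(x) || !std::isfinite(y)) {
      diverged = true;
      t_end = t + dt;
      break;
    }
  }

  if (diverged && row < n_rows) {
    traj = traj(Range(0, row - 1), _);
    if (record_voltages) volts = volts(Range(0, row - 1), _);
  }

  double ci = NA_REAL;
  if (r0 > 0 && !diverged) ci = 1.0 - r_int / (duration * r0);

  return List::create(
    _["traj"] = traj,
    _["volts"] = record_voltages ? (SEXP)volts : R_NilValue,
    _["ci"] = ci, _["captured"] = captured, _["min_r"] = min_r,
    _["diverged"] = diverged, _["r0"] = r0, _["t_end"] = t_end);
}
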