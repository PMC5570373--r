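#include <Rcpp.h>
using namespace Rcpp;

// Coupled deterministic engine for one simulation run.
//
// State vector (length 64):
//   [0..7]    sNR2A occupancies (8-state)
//   [8..15]   sNR2B
//   [16..23]  pNR2B
//   [24..31]  eNR2B
//   [32..38]  sAMPAR occupancies (7-state)
//   [39..45]  eAMPAR
//   [46]      V spine (mV)
//   [47]      V shaft (mV)
//   [48]      VDCC activation gate, spine
//   [49]      VDCC activation gate, shaft
//   [50..53]  free Ca (uM): PSD, cytosol, neck, shaft
//   [54..57]  buffer-bound Ca (uM): PSD, cytosol, neck, shaft
//   [58..63]  cumulative Ca ions: sNR2A, sNR2B, pNR2B, eNR2B, VDCC spine, VDCC shaft
//
// Fixed-step classical RK4.  Driving glutamate traces are supplied on a grid
// of spacing dt/2 so that RK4 stage times fall exactly on samples.

static const int NS = 64;
static const double IONS = 602.2140857; // ions per uM*um^3

struct Scheme {
  int n;
  std::vector<double> Q0, Q1; // n*n, row i -> column j = rate i->j (post Q10)
  int open;                   // index of open state
};

struct Engine {
  Scheme sc[6]; // sNR2A sNR2B pNR2B eNR2B sAMPAR eAMPAR
  double count[6];
  int glu_zone[6]; // 0 syn, 1 peri, 2 extra
  // electrics
  double cm_s, cm_d;          // pF
  double gl_s, gl_d, e_leak;  // nS, mV
  double g_neck;              // nS ( = 1000/R_MOhm )
  double g_nmda, g_ampa;      // pS per channel (at sim temperature)
  double e_syn;               // reversal for AMPA/NMDA currents
  double mg, mg_k0, mg_slope; // Jahr-Stevens
  // VDCC
  double vdcc_n_s, vdcc_n_d;  // channel counts
  double vdcc_vh, vdcc_k, vdcc_tau; // gate params (tau ms at sim temperature)
  double p_vdcc;              // cm^3/s per channel
  // GHK
  double p_nmda;              // cm^3/s per channel
  double ca_out;              // mM
  double rt_f;                // RT/F in mV (temperature dependent)
  // calcium compartments
  double vol[4];              // um^3
  double pmca_vmax[4], pmca_km; // vmax in ions/ms per compartment
  double ncx_vmax[4], ncx_km;
  double leak_in[4];          // ions/ms, set so rest is a fixed point
  double btot[4], kon_b[4], koff_b[4];
  double gdiff[3];            // um^3/ms couplings: psd-cyt, cyt-neck, neck-shaft
  // influx routing: compartment receiving Ca of each receptor class
  int ca_dest[6];
  double ca_frac_nmda;        // fraction of open NMDARs carrying GHK Ca flux (scale)
};

static inline double mg_block(const Engine& E, double v) {
  return 1.0 / (1.0 + E.mg / E.mg_k0 * std::exp(-E.mg_slope * v));
}

// GHK Ca flux through one channel, ions/ms, positive inward
static inline double ghk_flux(double P, double v, double ca_in_uM, double ca_out_mM,
                              double rt_f) {
  double u = 2.0 * v / rt_f; // zFV/RT
  double ci = ca_in_uM * 1e-9;  // mol/cm^3 (1 uM = 1e-9 mol/cm^3)
  double co = ca_out_mM * 1e-6; // mol/cm^3
  double num, den;
  if (std::abs(u) < 1e-6) { num = ci - co; den = 1.0; u = 1.0; /* limit below */ }
  double eu = std::exp(-u);
  if (std::abs(u) >= 1e-6) { num = ci - co * eu; den = 1.0 - eu; }
  else { num = (ci - co); den = 1.0; }
  // i = P z^2 F^2 V/(RT) (ci - co e^-u)/(1-e^-u);  ions/ms = -i/(2e) * 1e-3
  // z^2 F^2 V/RT = zF*u ; flux_ions_per_s = -P*zF*u*num/den / (2*1.602e-19) ... derive:
  // i [A] = P[cm3/s] * (zF)[C/mol] * u * num[mol/cm3]/den
  double zF = 2.0 * 96485.332;
  double iA = P * zF * u * num / den;
  double ions_per_s = -iA / (2.0 * 1.602176634e-19);
  return ions_per_s * 1e-3; // per ms
}

static void rhs(const Engine& E, double t, const double* y, double* dy,
                const double* glu3, double vcmd_s, double gcl_s,
                double vcmd_d, double gcl_d, double* vout = nullptr) {
  for (int i = 0; i < NS; ++i) dy[i] = 0.0;

  // receptor schemes
  int off = 0;
  double open_frac[6];
  for (int s = 0; s < 6; ++s) {
    const Scheme& S = E.sc[s];
    double glu = glu3[E.glu_zone[s]];
    for (int i = 0; i < S.n; ++i) {
      double out = 0.0, in = 0.0;
      for (int j = 0; j < S.n; ++j) {
        if (j == i) continue;
        double rij = S.Q0[i * S.n + j] + glu * S.Q1[i * S.n + j];
        double rji = S.Q0[j * S.n + i] + glu * S.Q1[j * S.n + i];
        out += rij;
        in += rji * y[off + j];
      }
      dy[off + i] = in - out * y[off + i];
    }
    open_frac[s] = y[off + S.open];
    off += S.n;
  }

  // Membrane potentials are quasi-steady: the compartmental RC time
  // constants (C ~ 10-30 fF against nS-scale conductances) are microseconds,
  // far below every other timescale in the model, so the two-node circuit is
  // solved algebraically at each evaluation.  The Mg-block voltage
  // dependence of the NMDAR conductance is lagged one solve (its
  // contribution to the total conductance is small at rest and the solve is
  // re-evaluated every RK4 stage).
  double vs_prev = y[46], vd_prev = y[47];
  double blk_s = mg_block(E, vs_prev), blk_d = mg_block(E, vd_prev);

  double g_nmda_spine = E.g_nmda * 1e-3 * blk_s *
      (E.count[0] * open_frac[0] + E.count[1] * open_frac[1] +
       E.count[2] * open_frac[2]);                       // nS
  double g_ampa_spine = E.g_ampa * 1e-3 * E.count[4] * open_frac[4];
  double g_nmda_shaft = E.g_nmda * 1e-3 * E.count[3] * open_frac[3] * blk_d;
  double g_ampa_shaft = E.g_ampa * 1e-3 * E.count[5] * open_frac[5];

  // The shaft node integrates with the capacitive load of the surrounding
  // dendrite (cm_d, pF), giving a realistic membrane time constant and hence
  // temporal summation of EPSCs over a train.  The spine head's own
  // capacitance is fF-scale against the nS neck conductance (microsecond RC),
  // so the spine potential is quasi-steady given the shaft potential:
  //   vs = (rhs_s + g_neck * vd) / gs_tot
  double vd = y[47];
  double gs_tot = E.gl_s + g_nmda_spine + g_ampa_spine + E.g_neck + gcl_s;
  double rhs_s = E.gl_s * E.e_leak + (g_nmda_spine + g_ampa_spine) * E.e_syn +
                 gcl_s * vcmd_s;
  double vs = (rhs_s + E.g_neck * vd) / gs_tot;
  double i_neck = E.g_neck * (vs - vd); // pA, into shaft
  dy[47] = (-(E.gl_d * (vd - E.e_leak)) -
            (g_nmda_shaft + g_ampa_shaft) * (vd - E.e_syn) -
            gcl_d * (vd - vcmd_d) + i_neck) / E.cm_d; // pA/pF = mV/ms
  blk_s = mg_block(E, vs);
  blk_d = mg_block(E, vd);

  // VDCC gates
  double minf_s = 1.0 / (1.0 + std::exp(-(vs - E.vdcc_vh) / E.vdcc_k));
  double minf_d = 1.0 / (1.0 + std::exp(-(vd - E.vdcc_vh) / E.vdcc_k));
  dy[48] = (minf_s - y[48]) / E.vdcc_tau;
  dy[49] = (minf_d - y[49]) / E.vdcc_tau;
  double po_vdcc_s = y[48] * y[48];
  double po_vdcc_d = y[49] * y[49];

  // Ca fluxes (ions/ms, inward positive)
  double f_nmda_s2a = E.count[0] * open_frac[0] * blk_s *
                      ghk_flux(E.p_nmda, vs, y[50], E.ca_out, E.rt_f);
  double f_nmda_s2b = E.count[1] * open_frac[1] * blk_s *
                      ghk_flux(E.p_nmda, vs, y[50], E.ca_out, E.rt_f);
  double f_nmda_p2b = E.count[2] * open_frac[2] * blk_s *
                      ghk_flux(E.p_nmda, vs, y[51], E.ca_out, E.rt_f);
  double f_nmda_e2b = E.count[3] * open_frac[3] * blk_d *
                      ghk_flux(E.p_nmda, vd, y[53], E.ca_out, E.rt_f);
  double f_vdcc_s = E.vdcc_n_s * po_vdcc_s *
                    ghk_flux(E.p_vdcc, vs, y[51], E.ca_out, E.rt_f);
  double f_vdcc_d = E.vdcc_n_d * po_vdcc_d *
                    ghk_flux(E.p_vdcc, vd, y[53], E.ca_out, E.rt_f);
  if (f_vdcc_s < 0) f_vdcc_s = 0;
  if (f_vdcc_d < 0) f_vdcc_d = 0;

  // The spine-V slot is carried for storage only (refreshed by the stepper).
  if (vout) { vout[0] = vs; vout[1] = vd; }

  // calcium compartments
  double influx[4] = {0, 0, 0, 0};
  influx[0] += f_nmda_s2a + f_nmda_s2b;
  influx[1] += f_nmda_p2b + f_vdcc_s;
  influx[3] += f_nmda_e2b + f_vdcc_d;

  double jdiff[4] = {0, 0, 0, 0};
  for (int k = 0; k < 3; ++k) {
    double flow = E.gdiff[k] * (y[50 + k] - y[50 + k + 1]); // uM*um^3/ms
    jdiff[k] -= flow / E.vol[k];
    jdiff[k + 1] += flow / E.vol[k + 1];
  }

  for (int c = 0; c < 4; ++c) {
    double ca = y[50 + c], b = y[54 + c];
    double pump = E.pmca_vmax[c] * ca / (ca + E.pmca_km) +
                  E.ncx_vmax[c] * ca / (ca + E.ncx_km); // ions/ms
    double net_ions = influx[c] - pump + E.leak_in[c];
    double buf = E.kon_b[c] * ca * (E.btot[c] - b) - E.koff_b[c] * b; // uM/ms
    dy[50 + c] = net_ions / (IONS * E.vol[c]) - buf + jdiff[c];
    dy[54 + c] = buf;
  }

  // cumulative influx counters (ions)
  dy[58] = std::max(f_nmda_s2a, 0.0);
  dy[59] = std::max(f_nmda_s2b, 0.0);
  dy[60] = std::max(f_nmda_p2b, 0.0);
  dy[61] = std::max(f_nmda_e2b, 0.0);
  dy[62] = f_vdcc_s;
  dy[63] = f_vdcc_d;
}

static Scheme scheme_from_list(List s) {
  Scheme S;
  NumericMatrix q0 = s["Q0"], q1 = s["Q1"];
  S.n = q0.nrow();
  S.Q0.assign(q0.begin(), q0.end()); // column-major; access adjusted below
  S.Q1.assign(q1.begin(), q1.end());
  // convert to row-major i*n+j
  std::vector<double> a(S.n * S.n), b(S.n * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int j = 0; j < S.n; ++j) {
      a[i * S.n + j] = q0(i, j);
      b[i * S.n + j] = q1(i, j);
    }
  S.Q0 = a;
  S.Q1 = b;
  S.open = as<int>(s["open"]) - 1;
  return S;
}

// [[Rcpp::export]]
List engine_cpp(List pars, NumericVector y0, double dt, int n_steps, int stride,
                NumericMatrix glu_half, // (2*n_steps+1) x 3, sampled at dt/2
                NumericVector vcmd_s, NumericVector gcl_s,
                NumericVector vcmd_d, NumericVector gcl_d) {
  Engine E;
  List schemes = pars["schemes"];
  NumericVector counts = pars["counts"];
  IntegerVector zones = pars["zones"];
  for (int s = 0; s < 6; ++s) {
    E.sc[s] = scheme_from_list(schemes[s]);
    E.count[s] = counts[s];
    E.glu_zone[s] = zones[s];
  }
  E.cm_s = pars["cm_s"]; E.cm_d = pars["cm_d"];
  E.gl_s = pars["gl_s"]; E.gl_d = pars["gl_d"]; E.e_leak = pars["e_leak"];
  E.g_neck = pars["g_neck"];
  E.g_nmda = pars["g_nmda"]; E.g_ampa = pars["g_ampa"]; E.e_syn = pars["e_syn"];
  E.mg = pars["mg"]; E.mg_k0 = pars["mg_k0"]; E.mg_slope = pars["mg_slope"];
  E.vdcc_n_s = pars["vdcc_n_s"]; E.vdcc_n_d = pars["vdcc_n_d"];
  E.vdcc_vh = pars["vdcc_vh"]; E.vdcc_k = pars["vdcc_k"]; E.vdcc_tau = pars["vdcc_tau"];
  E.p_vdcc = pars["p_vdcc"]; E.p_nmda = pars["p_nmda"];
  E.ca_out = pars["ca_out"]; E.rt_f = pars["rt_f"];
  NumericVector vol = pars["vol"], pm = pars["pmca_vmax"], nc = pars["ncx_vmax"],
                li = pars["leak_in"], bt = pars["btot"], kb = pars["kon_b"],
                ub = pars["koff_b"], gd = pars["gdiff"];
  for (int c = 0; c < 4; ++c) {
    E.vol[c] = vol[c]; E.pmca_vmax[c] = pm[c]; E.ncx_vmax[c] = nc[c];
    E.leak_in[c] = li[c]; E.btot[c] = bt[c]; E.kon_b[c] = kb[c]; E.koff_b[c] = ub[c];
  }
  E.pmca_km = pars["pmca_km"]; E.ncx_km = pars["ncx_km"];
  for (int k = 0; k < 3; ++k) E.gdiff[k] = gd[k];

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(NS), k2(NS), k3(NS), k4(NS), yt(NS);

  int n_out = n_steps / stride + 1;
  NumericMatrix out(n_out, NS);
  NumericVector t_out(n_out);
  int row = 0;
  for (int i = 0; i < NS; ++i) out(0, i) = y[i];
  t_out[0] = 0.0;
  row = 1;

  int ncmd = vcmd_s.size();
  auto cmd = [&](const NumericVector& v, int idx) -> double {
    if (ncmd == 0) return 0.0;
    return v[std::min(idx, ncmd - 1)];
  };

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    int g0 = 2 * step, g1 = 2 * step + 1, g2 = 2 * step + 2;
    double gA[3] = {glu_half(g0, 0), glu_half(g0, 1), glu_half(g0, 2)};
    double gB[3] = {glu_half(g1, 0), glu_half(g1, 1), glu_half(g1, 2)};
    double gC[3] = {glu_half(g2, 0), glu_half(g2, 1), glu_half(g2, 2)};
    // commands sampled on the dt grid (step index)
    double vs0 = cmd(vcmd_s, step), gs0 = cmd(gcl_s, step);
    double vd0 = cmd(vcmd_d, step), gd0 = cmd(gcl_d, step);
    double vs1 = cmd(vcmd_s, step + 1), gs1 = cmd(gcl_s, step + 1);
    double vd1 = cmd(vcmd_d, step + 1), gd1 = cmd(gcl_d, step + 1);
    double vsm = 0.5 * (vs0 + vs1), gsm = 0.5 * (gs0 + gs1);
    double vdm = 0.5 * (vd0 + vd1), gdm = 0.5 * (gd0 + gd1);

    rhs(E, t, y.data(), k1.data(), gA, vs0, gs0, vd0, gd0);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    rhs(E, t + 0.5 * dt, yt.data(), k2.data(), gB, vsm, gsm, vdm, gdm);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    rhs(E, t + 0.5 * dt, yt.data(), k3.data(), gB, vsm, gsm, vdm, gdm);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + dt * k3[i];
    rhs(E, t + dt, yt.data(), k4.data(), gC, vs1, gs1, vd1, gd1);
    for (int i = 0; i < NS; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    double vprobe[2];
    rhs(E, t + dt, y.data(), yt.data(), gC, vs1, gs1, vd1, gd1, vprobe);
    y[46] = vprobe[0];

    if ((step + 1) % stride == 0 && row < n_out) {
      for (int i = 0; i < NS; ++i) out(row, i) = y[i];
      t_out[row] = (step + 1) * dt;
      ++row;
    }
  }

  return List::create(_["time"] = t_out, _["state"] = out);
}
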