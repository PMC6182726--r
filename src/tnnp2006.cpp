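// Ten Tusscher & Panfilov (2006) human ventricular cardiomyocyte model,
// reimplemented from the published equations. Single-cell formulation with
// per-current conductance scalers (drug block / variability), configurable
// extracellular ions and cell type. Integration: forward Euler for the
// membrane potential and concentrations, Rush-Larsen for the 12 gating
// variables (the scheme used by the original authors' code), default
// dt = 0.02 ms.
//
// State layout (19):
//  0 V (mV), 1 Ki, 2 Nai, 3 Cai, 4 CaSS, 5 CaSR (mM), 6 Rprime,
//  7 m, 8 h, 9 j, 10 d, 11 f, 12 f2, 13 fCass, 14 s, 15 r,
//  16 xs, 17 xr1, 18 xr2
//
// Scaler layout (8): 0 INa, 1 IKr, 2 IKs, 3 IK1, 4 Ito, 5 ICaL,
//  6 INaCa, 7 INaK

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double Rgas = 8314.472;   // J/(kmol K)
static const double Temp = 310.0;      // K
static const double Frdy = 96485.3415; // C/mol
static const double Cm = 0.185;        // uF
static const double Vc = 0.016404;     // cytoplasmic volume scale
static const double Vsr = 0.001094;
static const double Vss = 0.00005468;

static const double pKNa = 0.03;
static const double GNa = 14.838, GK1 = 5.405, GKr = 0.153;
static const double GCaL = 0.0000398;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38;
static const double ksat = 0.1, ncagamma = 0.35, alphanaca = 2.5;
static const double PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
static const double GpK = 0.0146, GpCa = 0.1238, KpCa = 0.0005;
static const double GbNa = 0.00029, GbCa = 0.000592;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045;
static const double k3 = 0.060, k4 = 0.005;
static const double maxsr = 2.5, minsr = 1.0, EC = 1.5;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;

struct Gate { double inf, tau; };

// celltype: 0 = epi, 1 = endo, 2 = mid (M)
static inline double gto_for(int celltype) {
  return (celltype == 1) ? 0.073 : 0.294;
}
static inline double gks_for(int celltype) {
  return (celltype == 2) ? 0.098 : 0.392;
}

struct Derivs {
  double dY[19];
  Gate g[12]; // m h j d f f2 fCass s r xs xr1 xr2
};

static void tnnp_currents(const double *Y, const double *sc,
                          double Ko, double Nao, double Cao,
                          int celltype, double Istim, Derivs &out,
                          double *currents /* may be null, length 15 */) {
  const double V = Y[0], Ki = Y[1], Nai = Y[2], Cai = Y[3];
  const double CaSS = Y[4], CaSR = Y[5], Rp = Y[6];
  const double m = Y[7], h = Y[8], j = Y[9], d = Y[10], f = Y[11];
  const double f2 = Y[12], fCass = Y[13], s = Y[14], r = Y[15];
  const double xs = Y[16], xr1 = Y[17], xr2 = Y[18];

  const double RTF = Rgas * Temp / Frdy;
  const double EK = RTF * std::log(Ko / Ki);
  const double ENa = RTF * std::log(Nao / Nai);
  const double EKs = RTF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  // fast sodium
  const double INa = sc[0] * GNa * m * m * m * h * j * (V - ENa);

  // inward rectifier
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                std::exp(0.1 * (V - EK - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - EK)));
  const double xK1inf = ak1 / (ak1 + bk1);
  const double IK1 = sc[3] * GK1 * std::sqrt(Ko / 5.4) * xK1inf * (V - EK);

  // rapid delayed rectifier
  const double IKr =
      sc[1] * GKr * std::sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);

  // slow delayed rectifier
  const double IKs = sc[2] * gks_for(celltype) * xs * xs * (V - EKs);

  // transient outward
  const double Ito = sc[4] * gto_for(celltype) * r * s * (V - EK);

  // L-type calcium: GHK-type driving term centred at +15 mV,
  // ICaL = g d f f2 fCass 4 (V-15) F^2/(RT) (0.25 CaSS e^z - Cao)/(e^z - 1)
  // with z = 2 (V-15) F/(RT); the z -> 0 limit is taken analytically
  double ICaL;
  {
    const double z = 2.0 * (V - 15.0) * Frdy / (Rgas * Temp);
    double ghk; // = z F (0.25 CaSS e^z - Cao)/(e^z - 1)
    if (std::fabs(z) < 1e-7) {
      ghk = Frdy * (0.25 * CaSS - Cao);
    } else {
      ghk = Frdy * z * (0.25 * CaSS * std::exp(z) - Cao) /
            (std::exp(z) - 1.0);
    }
    ICaL = sc[5] * GCaL * d * f * f2 * fCass * 2.0 * ghk;
  }

  // Na/Ca exchanger
  const double VFRT = V * Frdy / (Rgas * Temp);
  const double INaCa = sc[6] * knaca *
      (std::exp(ncagamma * VFRT) * Nai * Nai * Nai * Cao -
       std::exp((ncagamma - 1.0) * VFRT) * Nao * Nao * Nao * Cai *
           alphanaca) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((ncagamma - 1.0) * VFRT)));

  // Na/K pump
  const double INaK = sc[7] * PNaK * (Ko / (Ko + KmK)) *
      (Nai / (Nai + KmNa)) /
      (1.0 + 0.1245 * std::exp(-0.1 * VFRT) + 0.0353 * std::exp(-VFRT));

  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - ENa);
  const double IbCa = GbCa * (V - ECa);

  // calcium handling
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  const double kcasr =
      maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  const double k1 = k1p / kcasr;
  const double k2 = k2p * kcasr;
  const double O = k1 * CaSS * CaSS * Rp / (k3 + k1 * CaSS * CaSS);
  const double Irel = Vrel * O * (CaSR - CaSS);
  const double Ixfer = Vxfer * (CaSS - Cai);

  const double dRp = -k2 * CaSS * Rp + k4 * (1.0 - Rp);

  const double bufc =
      1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  const double bufsr =
      1.0 / (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  const double bufss =
      1.0 / (1.0 + Bufss * Kbufss / ((CaSS + Kbufss) * (CaSS + Kbufss)));

  const double dCai = bufc *
      ((Ileak - Iup) * Vsr / Vc + Ixfer -
       (IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * Frdy));
  const double dCaSR = bufsr * (Iup - Irel - Ileak);
  const double dCaSS = bufss *
      (-ICaL * Cm / (2.0 * Vss * Frdy) + Irel * Vsr / Vss -
       Ixfer * Vc / Vss);

  const double dNai = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm /
                      (Vc * Frdy);
  const double dKi =
      -(IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK + Istim) * Cm /
      (Vc * Frdy);

  const double Iion = INa + IK1 + IKr + IKs + Ito + ICaL + INaCa + INaK +
                      IpCa + IpK + IbNa + IbCa;
  out.dY[0] = -(Iion + Istim);
  out.dY[1] = dKi;
  out.dY[2] = dNai;
  out.dY[3] = dCai;
  out.dY[4] = dCaSS;
  out.dY[5] = dCaSR;
  out.dY[6] = dRp;

  // gate kinetics (inf / tau in ms)
  // m
  {
    double minf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2);
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    out.g[0].inf = minf;
    out.g[0].tau = am * bm;
  }
  // h
  {
    double hinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    out.g[1].inf = hinf;
    out.g[1].tau = 1.0 / (ah + bh);
  }
  // j
  {
    double jinf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2);
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) /
           (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    out.g[2].inf = jinf;
    out.g[2].tau = 1.0 / (aj + bj);
  }
  // d
  {
    double dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    out.g[3].inf = dinf;
    out.g[3].tau = ad * bd + gd;
  }
  // f
  {
    double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    double tf = 1102.5 * std::exp(-std::pow(V + 27.0, 2) / 225.0) +
                200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    out.g[4].inf = finf;
    out.g[4].tau = tf;
  }
  // f2
  {
    double f2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    double tf2 = 562.0 * std::exp(-std::pow(V + 27.0, 2) / 240.0) +
                 31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                 80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    out.g[5].inf = f2inf;
    out.g[5].tau = tf2;
  }
  // fCass
  {
    double fcinf = 0.6 / (1.0 + std::pow(CaSS / 0.05, 2)) + 0.4;
    double tfc = 80.0 / (1.0 + std::pow(CaSS / 0.05, 2)) + 2.0;
    out.g[6].inf = fcinf;
    out.g[6].tau = tfc;
  }
  // s (epi/M use the +20 formulation; endo uses the +28/1000 variant)
  {
    double sinf, ts;
    if (celltype == 1) {
      sinf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
      ts = 1000.0 * std::exp(-std::pow(V + 67.0, 2) / 1000.0) + 8.0;
    } else {
      sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      ts = 85.0 * std::exp(-std::pow(V + 45.0, 2) / 320.0) +
           5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    }
    out.g[7].inf = sinf;
    out.g[7].tau = ts;
  }
  // r
  {
    double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    double tr = 9.5 * std::exp(-std::pow(V + 40.0, 2) / 1800.0) + 0.8;
    out.g[8].inf = rinf;
    out.g[8].tau = tr;
  }
  // xs
  {
    double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    out.g[9].inf = xsinf;
    out.g[9].tau = axs * bxs + 80.0;
  }
  // xr1
  {
    double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    out.g[10].inf = xr1inf;
    out.g[10].tau = axr1 * bxr1;
  }
  // xr2
  {
    double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    out.g[11].inf = xr2inf;
    out.g[11].tau = axr2 * bxr2;
  }

  // gate derivatives for the plain-RHS interface
  static const int gidx[12] = {7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18};
  for (int k = 0; k < 12; ++k) {
    out.dY[gidx[k]] = (out.g[k].inf - Y[gidx[k]]) / out.g[k].tau;
  }

  if (currents) {
    currents[0] = INa; currents[1] = IK1; currents[2] = IKr;
    currents[3] = IKs; currents[4] = Ito; currents[5] = ICaL;
    currents[6] = INaCa; currents[7] = INaK; currents[8] = IpCa;
    currents[9] = IpK; currents[10] = IbNa; currents[11] = IbCa;
    currents[12] = Irel; currents[13] = Iup; currents[14] = Ileak;
  }
}

// [[Rcpp::export(name = ".tnnp_derivs_cpp")]]
NumericVector tnnp_derivs_cpp(NumericVector state, NumericVector scalers,
                              double Ko, double Nao, double Cao,
                              int celltype, double Istim) {
  if (state.size() != 19) stop("state must have 19 elements");
  if (scalers.size() != 8) stop("scalers must have 8 elements");
  for (int i = 0; i < 19; ++i) {
    if (!std::isfinite(state[i])) stop("non-finite state");
  }
  Derivs d;
  tnnp_currents(&state[0], &scalers[0], Ko, Nao, Cao, celltype, Istim, d,
                nullptr);
  NumericVector out(19);
  for (int i = 0; i < 19; ++i) out[i] = d.dY[i];
  return out;
}

// Paced simulation. Returns per-beat APD90s plus diagnostics and the
// voltage trace of the final beats.
// [[Rcpp::export(name = ".tnnp_paced_cpp")]]
List tnnp_paced_cpp(NumericVector y0, NumericVector scalers,
                    double Ko, double Nao, double Cao, int celltype,
                    double cl_ms, int n_beats, double stim_amp,
                    double stim_dur, double dt,
                    int record_beats, double record_stride_ms,
                    double ead_dvdt_threshold, double ead_sustain_ms) {
  if (y0.size() != 19) stop("initial state must have 19 elements");
  if (scalers.size() != 8) stop("scalers must have 8 elements");
  std::vector<double> Y(y0.begin(), y0.end());
  Derivs d;

  NumericVector apd90(n_beats, NA_REAL);
  LogicalVector ead(n_beats), repol_fail(n_beats);
  NumericVector vmax_v(n_beats), vrest_v(n_beats), dvdtmax_v(n_beats);

  std::vector<double> rec_t, rec_v;
  const int rec_from_beat = std::max(0, n_beats - record_beats);
  const int stride = std::max(1, (int)std::floor(record_stride_ms / dt));

  for (int b = 0; b < n_beats; ++b) {
    const int nstep = (int)std::round(cl_ms / dt);
    double vrest = Y[0];
    double vmax = -1e9, dvdtmax = -1e9, t_up = 0.0, t_vmax = 0.0;
    double apd = NA_REAL;
    bool repolarized = false;
    bool ead_flag = false;
    int ead_run = 0;
    const int ead_need = std::max(1, (int)std::round(ead_sustain_ms / dt));

    for (int istep = 0; istep < nstep; ++istep) {
      const double t = istep * dt;
      const double Istim = (t < stim_dur) ? stim_amp : 0.0;
      tnnp_currents(Y.data(), &scalers[0], Ko, Nao, Cao, celltype, Istim,
                    d, nullptr);
      const double dVdt = d.dY[0];
      // bookkeeping before the update
      if (dVdt > dvdtmax) { dvdtmax = dVdt; t_up = t; }
      // EAD detector: sustained positive dV/dt during late repolarization
      if (t > stim_dur + 30.0 && !repolarized && Y[0] > -60.0 &&
          Y[0] < 0.0 && t > t_vmax + 30.0) {
        if (dVdt > ead_dvdt_threshold) {
          if (++ead_run >= ead_need) ead_flag = true;
        } else {
          ead_run = 0;
        }
      }
      // forward Euler for V and concentrations + Rprime
      for (int k = 0; k < 7; ++k) Y[k] += dt * d.dY[k];
      // Rush-Larsen for gates
      static const int gidx[12] = {7, 8, 9, 10, 11, 12, 13, 14, 15, 16,
                                   17, 18};
      for (int k = 0; k < 12; ++k) {
        const int ix = gidx[k];
        Y[ix] = d.g[k].inf + (Y[ix] - d.g[k].inf) *
                std::exp(-dt / d.g[k].tau);
      }
      if (!std::isfinite(Y[0])) {
        stop("integration failure at beat %d", b + 1);
      }
      if (Y[0] > vmax) { vmax = Y[0]; t_vmax = t; }
      // APD90 (from the maximal-upstroke time to 90% repolarization)
      if (!repolarized && t > t_vmax && vmax > 0.0) {
        const double v90 = vmax - 0.9 * (vmax - vrest);
        if (Y[0] <= v90) {
          apd = t + dt - t_up;
          repolarized = true;
        }
      }
      if (b >= rec_from_beat && istep % stride == 0) {
        rec_t.push_back(b * cl_ms + t);
        rec_v.push_back(Y[0]);
      }
    }
    apd90[b] = apd;
    ead[b] = ead_flag;
    repol_fail[b] = (!repolarized && vmax > 0.0) || (Y[0] > -40.0);
    vmax_v[b] = vmax;
    vrest_v[b] = vrest;
    dvdtmax_v[b] = dvdtmax;
  }

  NumericVector fin(19);
  for (int i = 0; i < 19; ++i) fin[i] = Y[i];
  return List::create(
      _["apd90"] = apd90, _["ead"] = ead, _["repol_fail"] = repol_fail,
      _["vmax"] = vmax_v, _["vrest"] = vrest_v, _["dvdtmax"] = dvdtmax_v,
      _["state"] = fin,
      _["trace_t_ms"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["trace_v_mV"] = NumericVector(rec_v.begin(), rec_v.end()));
}

// Free-running (unpaced) relaxation from a state; returns the state and
// the voltage drift over the interval.
// [[Rcpp::export(name = ".tnnp_rest_cpp")]]
List tnnp_rest_cpp(NumericVector y0, NumericVector scalers, double Ko,
                   double Nao, double Cao, int celltype, double t_ms,
                   double dt) {
  if (y0.size() != 19) stop("initial state must have 19 elements");
  std::vector<double> Y(y0.begin(), y0.end());
  Derivs d;
  const int nstep = (int)std::round(t_ms / dt);
  const double v_start = Y[0];
  for (int istep = 0; istep < nstep; ++istep) {
    tnnp_currents(Y.data(), &scalers[0], Ko, Nao, Cao, celltype, 0.0, d,
                  nullptr);
    for (int k = 0; k < 7; ++k) Y[k] += dt * d.dY[k];
    static const int gidx[12] = {7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17,
                                 18};
    for (int k = 0; k < 12; ++k) {
      const int ix = gidx[k];
      Y[ix] = d.g[k].inf + (Y[ix] - d.g[k].inf) *
              std::exp(-dt / d.g[k].tau);
    }
    if (!std::isfinite(Y[0])) stop("integration failure in rest run");
  }
  NumericVector fin(19);
  for (int i = 0; i < 19; ++i) fin[i] = Y[i];
  // final dV/dt
  tnnp_currents(Y.data(), &scalers[0], Ko, Nao, Cao, celltype, 0.0, d,
                nullptr);
  return List::create(_["state"] = fin, _["v_start"] = v_start,
                      _["v_end"] = Y[0], _["drift_mV"] = Y[0] - v_start,
                      _["dvdt_end"] = d.dY[0]);
}
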