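// Reduced canine-like ventricular myocyte with per-target stochastic gating.
//
// Thirteen targets: INa (7-state Markov: C3-C2-C1-O-I plus burst pathway
// BC-BO whose entry rate is the persistent-INa lever), ICaL (HH d*f gates +
// Ca-dependent fCa per domain), Ito (a*i), IKur (a), IKr (5-state Markov,
// C1-C2-C3-O-I, published-style HERG rates), IKs (x1*x2), IK1 (fast gate),
// INaK, INaCa, IpCa (transport-cycle shot noise), Jrel (4-state RyR Markov
// with luminal-Ca-sensitized opening, per Ca domain), Jup (SERCA), Jleak.
//
// Each target runs in one of three modes: deterministic fractions,
// stochastic Markov sampling over integer channel counts, or
// chemical-Langevin SDE on fractions. Units: mV, ms, mM, pA/pF.

#include <Rcpp.h>
#include "markov_core.h"
using namespace Rcpp;

static const double RTF = 26.712838;    // R*T/F at 310 K, mV
static const double FARADAY = 96485.0;  // C/mol
static const double RATE_CAP = 25.0;    // 1/ms, caps Markov rates (tau >= 0.04 ms)

enum Mode { DET = 0, STOCH = 1, SDE = 2 };

static int parse_mode(const std::string &s) {
  if (s == "deterministic") return DET;
  if (s == "markov" || s == "markov_stochastic") return STOCH;
  if (s == "sde" || s == "sde_langevin") return SDE;
  stop("unknown gating mode '%s'", s.c_str());
  return DET;
}

struct GateP {
  double vh, k;                                  // x_inf = 1/(1+exp(-(V-vh)/k))
  double tau0, tau_amp, tau_vmid, tau_w;         // Gaussian tau bump
  double tau_samp, tau_svmid, tau_sk;            // sigmoidal tau component
  double xinf(double v) const { return 1.0 / (1.0 + std::exp(-(v - vh) / k)); }
  double tau(double v) const {
    double z = (v - tau_vmid) / tau_w;
    double t = tau0 + tau_amp * std::exp(-z * z);
    if (tau_samp != 0.0) t += tau_samp / (1.0 + std::exp((v - tau_svmid) / tau_sk));
    return t;
  }
};

static double getd(const List &l, const char *nm) {
  if (!l.containsElementNamed(nm)) stop("missing config field '%s'", nm);
  return as<double>(l[nm]);
}
static double getd_def(const List &l, const char *nm, double def) {
  if (!l.containsElementNamed(nm)) return def;
  return as<double>(l[nm]);
}

static GateP parse_gate(const List &g) {
  GateP p;
  p.vh = getd(g, "vh"); p.k = getd(g, "k");
  p.tau0 = getd(g, "tau0");
  p.tau_amp = getd_def(g, "tau_amp", 0.0);
  p.tau_vmid = getd_def(g, "tau_vmid", 0.0);
  p.tau_w = getd_def(g, "tau_w", 1.0);
  p.tau_samp = getd_def(g, "tau_samp", 0.0);
  p.tau_svmid = getd_def(g, "tau_svmid", 0.0);
  p.tau_sk = getd_def(g, "tau_sk", 1.0);
  return p;
}

struct Params {
  double cm, nao, ko, cao, vrest;
  double vcyt, vsr;                  // L
  double dt_up, dt_ap, dt_dia;
  int nd; double tau_diff;
  // maximal conductances (mS/uF) / rates, post condition scaling
  double g_na, g_cal, g_to, g_kur, g_kr, g_ks, g_k1;
  double inak_max, knaca, gpca, vup, grel, vleak;
  double gnab, gcab, gkb;            // backgrounds (balanced at init)
  // single-channel conductances (pS) -> channel counts
  double gs_na, gs_cal, gs_to, gs_kur, gs_kr, gs_ks, gs_k1, n_ryr;
  int m_na, m_cal, m_to, m_kur, m_kr, m_ks, m_k1, m_nak, m_ncx, m_pca,
      m_rel, m_up, m_leak;
  // INa kinetics
  double na_mu1, na_mu2, persist_scale;
  GateP h;
  // HH gates
  GateP d, f, a_to, i_to, a_kur, x1, x2, xk1;
  double kmfca, tau_fca, f_tau_scale;
  // IKr rate scales (global kinetics; deactivation-pathway memory)
  double kr_scale, kr_deact;
  // INaK / INaCa parameters
  double km_ko, km_nai, km_na_ncx, km_ca_ncx, ksat, gam, ncx_alpha;
  double km_pca, kup;
  // RyR
  double ryr_ko, ryr_ktrig, ryr_kmca, ryr_hca, ryr_kcsr, ryr_hcsr, ryr_floor, ryr_kom,
         ryr_ki, ryr_kir, ryr_krc;
  // buffers
  double cmdn_b, cmdn_kd, trpn_b, trpn_kd, csqn_b, csqn_kd;
  // derived channel counts
  double N_na, N_cal, N_to, N_kur, N_kr, N_ks, N_k1;
};

static double chan_count(double gmax, double cm, double gs) {
  if (gmax <= 0.0 || gs <= 0.0) return 0.0;
  double n = std::round(1000.0 * gmax * cm / gs);   // gmax*cm in nS, gs in pS
  return n < 1.0 ? 1.0 : n;
}

static Params parse_params(const List &cfg) {
  Params P;
  P.cm = getd(cfg, "cm");
  P.nao = getd(cfg, "nao"); P.ko = getd(cfg, "ko"); P.cao = getd(cfg, "cao");
  P.vrest = getd(cfg, "vrest");
  P.vcyt = getd(cfg, "vcyt"); P.vsr = getd(cfg, "vsr");
  P.dt_up = getd(cfg, "dt_up"); P.dt_ap = getd(cfg, "dt_ap");
  P.dt_dia = getd(cfg, "dt_dia");
  List dom = cfg["domains"];
  P.nd = (int)getd(dom, "n_domains");
  P.tau_diff = getd(dom, "tau_diffusion");
  if (P.nd < 1) stop("n_domains must be >= 1");

  List tg = cfg["targets"];
  List ina = tg["ina"], ical = tg["ical"], ito = tg["ito"], ikur = tg["ikur"],
       ikr = tg["ikr"], iks = tg["iks"], ik1 = tg["ik1"], inak = tg["inak"],
       inaca = tg["inaca"], ipca = tg["ipca"], jrel = tg["jrel"],
       jup = tg["jup"], jleak = tg["jleak"];

  P.m_na = parse_mode(as<std::string>(ina["mode"]));
  P.m_cal = parse_mode(as<std::string>(ical["mode"]));
  P.m_to = parse_mode(as<std::string>(ito["mode"]));
  P.m_kur = parse_mode(as<std::string>(ikur["mode"]));
  P.m_kr = parse_mode(as<std::string>(ikr["mode"]));
  P.m_ks = parse_mode(as<std::string>(iks["mode"]));
  P.m_k1 = parse_mode(as<std::string>(ik1["mode"]));
  P.m_nak = parse_mode(as<std::string>(inak["mode"]));
  P.m_ncx = parse_mode(as<std::string>(inaca["mode"]));
  P.m_pca = parse_mode(as<std::string>(ipca["mode"]));
  P.m_rel = parse_mode(as<std::string>(jrel["mode"]));
  P.m_up = parse_mode(as<std::string>(jup["mode"]));
  P.m_leak = parse_mode(as<std::string>(jleak["mode"]));

  P.g_na = getd(ina, "gmax") * getd_def(ina, "scale", 1.0);
  P.g_cal = getd(ical, "gmax") * getd_def(ical, "scale", 1.0);
  P.g_to = getd(ito, "gmax") * getd_def(ito, "scale", 1.0);
  P.g_kur = getd(ikur, "gmax") * getd_def(ikur, "scale", 1.0);
  P.g_kr = getd(ikr, "gmax") * getd_def(ikr, "scale", 1.0);
  P.g_ks = getd(iks, "gmax") * getd_def(iks, "scale", 1.0);
  P.g_k1 = getd(ik1, "gmax") * getd_def(ik1, "scale", 1.0);
  P.inak_max = getd(inak, "imax") * getd_def(inak, "scale", 1.0);
  P.knaca = getd(inaca, "knaca") * getd_def(inaca, "scale", 1.0);
  P.gpca = getd(ipca, "gpca") * getd_def(ipca, "scale", 1.0);
  P.grel = getd(jrel, "grel") * getd_def(jrel, "scale", 1.0);
  P.vup = getd(jup, "vup") * getd_def(jup, "scale", 1.0);
  P.vleak = getd(jleak, "vleak") * getd_def(jleak, "scale", 1.0);

  P.gs_na = getd(ina, "g_single"); P.gs_cal = getd(ical, "g_single");
  P.gs_to = getd(ito, "g_single"); P.gs_kur = getd(ikur, "g_single");
  P.gs_kr = getd(ikr, "g_single"); P.gs_ks = getd(iks, "g_single");
  P.gs_k1 = getd(ik1, "g_single");
  P.n_ryr = getd(jrel, "n_channels");

  P.na_mu1 = getd(ina, "mu1"); P.na_mu2 = getd(ina, "mu2");
  P.persist_scale = getd_def(ina, "persist_scale", 1.0);
  P.h = parse_gate(ina["h_gate"]);
  P.d = parse_gate(ical["d_gate"]); P.f = parse_gate(ical["f_gate"]);
  P.kmfca = getd(ical, "kmfca"); P.tau_fca = getd(ical, "tau_fca");
  P.f_tau_scale = getd_def(ical, "f_tau_scale", 1.0);
  P.a_to = parse_gate(ito["a_gate"]); P.i_to = parse_gate(ito["i_gate"]);
  P.a_kur = parse_gate(ikur["a_gate"]);
  P.x1 = parse_gate(iks["x1_gate"]); P.x2 = parse_gate(iks["x2_gate"]);
  P.xk1 = parse_gate(ik1["x_gate"]);
  P.kr_scale = getd_def(ikr, "rate_scale", 1.0);
  P.kr_deact = getd_def(ikr, "deact_scale", 1.0);

  P.km_ko = getd(inak, "km_ko"); P.km_nai = getd(inak, "km_nai");
  P.km_na_ncx = getd(inaca, "km_na"); P.km_ca_ncx = getd(inaca, "km_ca");
  P.ksat = getd(inaca, "ksat"); P.gam = getd(inaca, "gamma");
  P.ncx_alpha = getd(inaca, "alpha");
  P.km_pca = getd(ipca, "km");
  P.kup = getd(jup, "km");

  List ryr = cfg["ryr"];
  P.ryr_ko = getd(ryr, "k_open"); P.ryr_kmca = getd(ryr, "km_ca");
  P.ryr_hca = getd_def(ryr, "h_ca", 4.0);
  P.ryr_ktrig = getd_def(ryr, "k_trig", 0.0);
  P.ryr_kcsr = getd(ryr, "k_csr"); P.ryr_hcsr = getd(ryr, "h_csr");
  P.ryr_floor = getd(ryr, "floor"); P.ryr_kom = getd(ryr, "k_close");
  P.ryr_ki = getd(ryr, "k_inact"); P.ryr_kir = getd(ryr, "k_recover");
  P.ryr_krc = getd(ryr, "k_reset");

  List buf = cfg["buffers"];
  P.cmdn_b = getd(buf, "cmdn_b"); P.cmdn_kd = getd(buf, "cmdn_kd");
  P.trpn_b = getd(buf, "trpn_b"); P.trpn_kd = getd(buf, "trpn_kd");
  P.csqn_b = getd(buf, "csqn_b"); P.csqn_kd = getd(buf, "csqn_kd");

  List bg = cfg["background"];
  P.gnab = getd_def(bg, "gnab", 0.0);
  P.gcab = getd_def(bg, "gcab", 0.0);
  P.gkb = getd_def(bg, "gkb", 0.0);

  P.N_na = chan_count(P.g_na, P.cm, P.gs_na);
  P.N_cal = chan_count(P.g_cal, P.cm, P.gs_cal);
  P.N_to = chan_count(P.g_to, P.cm, P.gs_to);
  P.N_kur = chan_count(P.g_kur, P.cm, P.gs_kur);
  P.N_kr = chan_count(P.g_kr, P.cm, P.gs_kr);
  P.N_ks = chan_count(P.g_ks, P.cm, P.gs_ks);
  P.N_k1 = chan_count(P.g_k1, P.cm, P.gs_k1);
  return P;
}

// ---- state layout --------------------------------------------------------

struct Layout {
  int nd;
  int vm, nai, ki, cai, casr;
  int ina, ikr;                // 7 and 5 states
  int cal_d, cal_f, cal_fca;   // nd each
  int to_a, to_i, kur_a, ks_x1, ks_x2, k1_x;
  int ryr;                     // 4 * nd
  int n;
};

static Layout make_layout(int nd) {
  Layout L; L.nd = nd;
  int i = 0;
  L.vm = i++; L.nai = i++; L.ki = i++;
  L.cai = i; i += nd;
  L.casr = i; i += nd;
  L.ina = i; i += 7;
  L.ikr = i; i += 5;
  L.cal_d = i; i += nd; L.cal_f = i; i += nd; L.cal_fca = i; i += nd;
  L.to_a = i++; L.to_i = i++; L.kur_a = i++;
  L.ks_x1 = i++; L.ks_x2 = i++; L.k1_x = i++;
  L.ryr = i; i += 4 * nd;
  L.n = i;
  return L;
}

static CharacterVector state_names(const Layout &L) {
  CharacterVector nm(L.n);
  nm[L.vm] = "vm"; nm[L.nai] = "nai"; nm[L.ki] = "ki";
  for (int d = 0; d < L.nd; ++d) {
    nm[L.cai + d] = "cai" + std::to_string(d + 1);
    nm[L.casr + d] = "casr" + std::to_string(d + 1);
  }
  const char *ina_s[7] = {"c3", "c2", "c1", "o", "i", "bc", "bo"};
  for (int k = 0; k < 7; ++k) nm[L.ina + k] = std::string("ina_") + ina_s[k];
  const char *ikr_s[5] = {"c1", "c2", "c3", "o", "i"};
  for (int k = 0; k < 5; ++k) nm[L.ikr + k] = std::string("ikr_") + ikr_s[k];
  for (int d = 0; d < L.nd; ++d) {
    nm[L.cal_d + d] = "cal_d" + std::to_string(d + 1);
    nm[L.cal_f + d] = "cal_f" + std::to_string(d + 1);
    nm[L.cal_fca + d] = "cal_fca" + std::to_string(d + 1);
  }
  nm[L.to_a] = "to_a"; nm[L.to_i] = "to_i"; nm[L.kur_a] = "kur_a";
  nm[L.ks_x1] = "ks_x1"; nm[L.ks_x2] = "ks_x2"; nm[L.k1_x] = "k1_x";
  const char *ryr_s[4] = {"c", "o", "i", "r"};
  for (int d = 0; d < L.nd; ++d)
    for (int k = 0; k < 4; ++k)
      nm[L.ryr + 4 * d + k] = std::string("ryr_") + ryr_s[k] + std::to_string(d + 1);
  return nm;
}

// ---- rate matrices -------------------------------------------------------

static double cap(double r) { return r > RATE_CAP ? RATE_CAP : r; }

static double alpha_m(double v) {
  double x = v + 47.13;
  if (std::fabs(x) < 1e-6) return 3.2;
  return 0.32 * x / (1.0 - std::exp(-0.1 * x));
}
static double beta_m(double v) { return 0.08 * std::exp(-v / 11.0); }

// INa states: 0 C3, 1 C2, 2 C1, 3 O, 4 I, 5 BC, 6 BO
static void ina_rates(const Params &P, double v, double *Q) {
  std::fill(Q, Q + 49, 0.0);
  double am = alpha_m(v), bm = beta_m(v);
  double hi = P.h.xinf(v), th = P.h.tau(v);
  double ah = cap(hi / th), bh = cap((1.0 - hi) / th);
  double mu1 = P.na_mu1 * P.persist_scale, mu2 = P.na_mu2;
  Q[0 * 7 + 1] = 3 * am; Q[1 * 7 + 0] = bm;
  Q[1 * 7 + 2] = 2 * am; Q[2 * 7 + 1] = 2 * bm;
  Q[2 * 7 + 3] = am;     Q[3 * 7 + 2] = 3 * bm;
  Q[3 * 7 + 4] = bh;     Q[4 * 7 + 0] = ah;       // inactivation / recovery
  Q[3 * 7 + 6] = mu1;    Q[4 * 7 + 6] = mu1;      // burst entry
  Q[6 * 7 + 3] = mu2;                             // burst exit via open
  Q[5 * 7 + 6] = am;     Q[6 * 7 + 5] = bm;       // burst activation
  Q[5 * 7 + 0] = mu2;                             // burst mode exit at rest
}

// IKr states: 0 C1, 1 C2, 2 C3, 3 O, 4 I (published-style HERG rates).
// deact_scale slows the closing pathway only, lengthening the channel's
// memory of recent diastolic intervals beyond a single beat.
static void ikr_rates(const Params &P, double v, double *Q) {
  std::fill(Q, Q + 25, 0.0);
  double s = P.kr_scale, d = P.kr_deact;
  Q[0 * 5 + 1] = cap(s * 0.022348 * std::exp(0.01176 * v));
  Q[1 * 5 + 0] = cap(s * d * 0.047002 * std::exp(-0.0631 * v));
  Q[1 * 5 + 2] = cap(s * 0.023761);
  Q[2 * 5 + 1] = cap(s * d * 0.036778);
  Q[2 * 5 + 3] = cap(s * 0.013733 * std::exp(0.038198 * v));
  Q[3 * 5 + 2] = cap(s * d * 6.89e-5 * std::exp(-0.04178 * v));
  Q[3 * 5 + 4] = cap(0.090821 * std::exp(0.023391 * v));
  Q[4 * 5 + 3] = cap(0.006497 * std::exp(-0.03268 * v));
}

// RyR states: 0 C, 1 O, 2 I, 3 R; opening driven by the local L-type Ca
// trigger flux (flux-triggered CICR, the common-pool stand-in for subspace
// Ca) plus steep cytosolic-Ca activation (Hill h_ca), both modulated by
// luminal (SR) sensitization rising above k_csr.
static void ryr_rates(const Params &P, double cai, double casr,
                      double ical_cellEq, double *Q) {
  std::fill(Q, Q + 16, 0.0);
  double cah = std::pow(cai / P.ryr_kmca, P.ryr_hca);
  double trig = ical_cellEq < 0.0 ? -ical_cellEq : 0.0;   // pA/pF inward
  double lum = P.ryr_floor +
    (1.0 - P.ryr_floor) / (1.0 + std::pow(P.ryr_kcsr / std::max(casr, 1e-6), P.ryr_hcsr));
  double kopen = (P.ryr_ko * (cah / (1.0 + cah)) + P.ryr_ktrig * trig) * lum;
  if (kopen > 8.0) kopen = 8.0;   // release onset bounded for sampling cost
  Q[0 * 4 + 1] = kopen;
  Q[1 * 4 + 0] = P.ryr_kom;
  Q[1 * 4 + 2] = P.ryr_ki;
  Q[2 * 4 + 3] = P.ryr_kir;
  Q[3 * 4 + 0] = P.ryr_krc;
}

// ---- currents ------------------------------------------------------------

struct Currents {
  double ina, ical, ito, ikur, ikr, iks, ik1;
  double inak, inaca, ipca, inab, icab, ikb, im;
  std::vector<double> ical_d, inaca_d, ipca_d, icab_d, jrel, jup, jleak;
};

static double frac_of(const double *state, int idx, int mode, double N) {
  double x = state[idx];
  if (mode == STOCH && N > 0.0) return x / N;
  return x;
}

static void compute_currents(const Params &P, const Layout &L,
                             const double *s, Currents &C) {
  int nd = L.nd;
  double v = s[L.vm], nai = s[L.nai], ki = s[L.ki];
  double ena = RTF * std::log(P.nao / nai);
  double ek = RTF * std::log(P.ko / ki);
  double eks = RTF * std::log((P.ko + 0.01833 * P.nao) / (ki + 0.01833 * nai));

  // INa: open + burst-open occupancy
  double po_na, po_bo;
  if (P.m_na == STOCH && P.N_na > 0) {
    po_na = s[L.ina + 3] / P.N_na; po_bo = s[L.ina + 6] / P.N_na;
  } else { po_na = s[L.ina + 3]; po_bo = s[L.ina + 6]; }
  C.ina = P.g_na * (po_na + po_bo) * (v - ena);

  // IKr
  double po_kr = (P.m_kr == STOCH && P.N_kr > 0) ? s[L.ikr + 3] / P.N_kr
                                                 : s[L.ikr + 3];
  C.ikr = P.g_kr * std::sqrt(P.ko / 5.4) * po_kr * (v - ek);

  // HH-gated K currents
  double a = frac_of(s, L.to_a, P.m_to, P.N_to);
  double i_ = frac_of(s, L.to_i, P.m_to, P.N_to);
  C.ito = P.g_to * a * i_ * (v - ek);
  double aur = frac_of(s, L.kur_a, P.m_kur, P.N_kur);
  C.ikur = P.g_kur * aur * (v - ek);
  double xs1 = frac_of(s, L.ks_x1, P.m_ks, P.N_ks);
  double xs2 = frac_of(s, L.ks_x2, P.m_ks, P.N_ks);
  C.iks = P.g_ks * xs1 * xs2 * (v - eks);
  double xk1 = frac_of(s, L.k1_x, P.m_k1, P.N_k1);
  C.ik1 = P.g_k1 * std::sqrt(P.ko / 5.4) * xk1 * (v - ek);

  // INaK
  double sig = (std::exp(P.nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / RTF) +
                       0.0365 * sig * std::exp(-v / RTF));
  double nai15 = std::pow(nai, 1.5), km15 = std::pow(P.km_nai, 1.5);
  C.inak = P.inak_max * fnak * (P.ko / (P.ko + P.km_ko)) *
           (nai15 / (nai15 + km15));

  // per-domain Ca-coupled currents and fluxes
  C.ical_d.assign(nd, 0.0); C.inaca_d.assign(nd, 0.0);
  C.ipca_d.assign(nd, 0.0); C.icab_d.assign(nd, 0.0);
  C.jrel.assign(nd, 0.0); C.jup.assign(nd, 0.0); C.jleak.assign(nd, 0.0);
  double Ncal_d = P.N_cal / nd;
  double exp_gv = std::exp(P.gam * v / RTF);
  double exp_g1v = std::exp((P.gam - 1.0) * v / RTF);
  double ncx_den_v = 1.0 + P.ksat * exp_g1v;
  double kmna3 = std::pow(P.km_na_ncx, 3.0), nao3 = std::pow(P.nao, 3.0);
  double nai3 = nai * nai * nai;
  for (int d = 0; d < nd; ++d) {
    double cai = s[L.cai + d], casr = s[L.casr + d];
    double ecal = 7.7 - 13.0287 * std::log(cai);      // LR-style Ca driving
    double dd = frac_of(s, L.cal_d + d, P.m_cal, Ncal_d);
    double ff = frac_of(s, L.cal_f + d, P.m_cal, Ncal_d);
    double fca = s[L.cal_fca + d];
    C.ical_d[d] = (P.g_cal / nd) * dd * ff * fca * (v - ecal);
    C.inaca_d[d] = (P.knaca / nd) *
      (exp_gv * nai3 * P.cao - P.ncx_alpha * exp_g1v * nao3 * cai) /
      ((kmna3 + nao3) * (P.km_ca_ncx + P.cao) * ncx_den_v);
    C.ipca_d[d] = (P.gpca / nd) * cai / (cai + P.km_pca);
    double eca = 0.5 * RTF * std::log(P.cao / cai);
    C.icab_d[d] = (P.gcab / nd) * (v - eca);
    double po_ryr = (P.m_rel == STOCH && P.n_ryr > 0)
                      ? s[L.ryr + 4 * d + 1] / (P.n_ryr / nd)
                      : s[L.ryr + 4 * d + 1];
    C.jrel[d] = P.grel * po_ryr * (casr - cai);
    double c2 = cai * cai;
    C.jup[d] = P.vup * c2 / (c2 + P.kup * P.kup);
    C.jleak[d] = P.vleak * (casr - cai);
  }
  C.ical = 0; C.inaca = 0; C.ipca = 0; C.icab = 0;
  for (int d = 0; d < nd; ++d) {
    C.ical += C.ical_d[d]; C.inaca += C.inaca_d[d];
    C.ipca += C.ipca_d[d]; C.icab += C.icab_d[d];
  }
  C.inab = P.gnab * (v - ena);
  // K+ background shares the inward-rectifier voltage profile so that the
  // resting-balance leak does not oppose the plateau
  C.ikb = P.gkb * P.xk1.xinf(v) * (v - ek);
  C.im = C.ina + C.ical + C.ito + C.ikur + C.ikr + C.iks + C.ik1 +
         C.inak + C.inaca + C.ipca + C.inab + C.icab + C.ikb;
}

// ---- gating updates ------------------------------------------------------

static void hh_gate_update(double *x, int mode, double N, double xinf,
                           double tau, double dt, RngEngine &rng) {
  double a = xinf / tau, b = (1.0 - xinf) / tau;
  if (mode == DET) {
    *x += (xinf - *x) * (1.0 - std::exp(-dt / tau));
  } else if (mode == STOCH) {
    *x = bvr::hh_binom_step(*x, N, a, b, dt, rng);
  } else {
    *x = bvr::hh_sde_step(*x, a, b, N >= 1.0 ? N : 1.0, dt, rng);
  }
}

static void scheme_update(double *st, const double *Q, int n, int mode,
                          double N, double dt, RngEngine &rng) {
  if (mode == DET) bvr::markov_step_det(st, Q, n, dt);
  else if (mode == STOCH) bvr::markov_step_stoch(st, Q, n, dt, rng);
  else bvr::markov_step_cle(st, Q, n, dt, N >= 1.0 ? N : 1.0, rng);
}

// shot-noise factor for transport fluxes: Poisson count of elementary
// transport events in dt, normalized by its mean (1 when deterministic)
static double shot_factor(double events, RngEngine &rng) {
  if (events <= 0.0) return 1.0;
  return rng.pois(events) / events;
}

// streams per cell: 13 targets + vm noise
enum Stream { S_NA = 0, S_CAL, S_TO, S_KUR, S_KR, S_KS, S_K1, S_NAK, S_NCX,
              S_PCA, S_REL, S_UP, S_LEAK, S_VM, S_COUNT };

struct CellRng {
  std::vector<RngEngine> eng;
  CellRng(std::uint64_t master, int cell) {
    for (int k = 0; k < S_COUNT; ++k) {
      std::uint64_t t = master + 0x9E3779B97F4A7C15ULL * (std::uint64_t)(cell * 64 + k + 1);
      eng.emplace_back(splitmix64(t));
    }
  }
};

// one forward step of a single cell; returns deterministic dVm/dt
static double step_cell(const Params &P, const Layout &L, double *s,
                        double dt, double istim, double iinj, double igap,
                        double alpha, CellRng &R, Currents &C) {
  compute_currents(P, L, s, C);
  double v = s[L.vm];
  int nd = L.nd;

  // transport shot noise (applied to the concentration/current effect of
  // this step; events = elementary transport cycles in dt)
  double f_nak = 1.0, f_ncx = 1.0;
  std::vector<double> f_pca(nd, 1.0), f_up(nd, 1.0), f_leak(nd, 1.0);
  const double E_PER_PAMS = 6241.5;   // elementary charges per pA*ms
  if (P.m_nak != DET)
    f_nak = shot_factor(std::fabs(C.inak) * P.cm * E_PER_PAMS * dt, R.eng[S_NAK]);
  if (P.m_ncx != DET)
    f_ncx = shot_factor(std::fabs(C.inaca) * P.cm * E_PER_PAMS * dt, R.eng[S_NCX]);
  double vd = P.vcyt / nd;                    // L per domain
  const double IONS_PER_MMOL_L = 6.022e20;    // ions per (mM * L)
  for (int d = 0; d < nd; ++d) {
    if (P.m_pca != DET)
      f_pca[d] = shot_factor(std::fabs(C.ipca_d[d]) * P.cm * E_PER_PAMS * dt / 2.0,
                             R.eng[S_PCA]);
    if (P.m_up != DET)
      f_up[d] = shot_factor(C.jup[d] * vd * IONS_PER_MMOL_L * dt / 2.0, R.eng[S_UP]);
    if (P.m_leak != DET)
      f_leak[d] = shot_factor(std::fabs(C.jleak[d]) * vd * IONS_PER_MMOL_L * dt,
                              R.eng[S_LEAK]);
  }

  // gating updates (old Vm, old Ca)
  double Q7[49], Q5[25], Q4[16];
  ina_rates(P, v, Q7);
  scheme_update(s + L.ina, Q7, 7, P.m_na, P.N_na, dt, R.eng[S_NA]);
  ikr_rates(P, v, Q5);
  scheme_update(s + L.ikr, Q5, 5, P.m_kr, P.N_kr, dt, R.eng[S_KR]);
  double Ncal_d = P.N_cal / nd, Nryr_d = P.n_ryr / nd;
  for (int d = 0; d < nd; ++d) {
    double cai = s[L.cai + d];
    hh_gate_update(s + L.cal_d + d, P.m_cal, Ncal_d, P.d.xinf(v), P.d.tau(v),
                   dt, R.eng[S_CAL]);
    hh_gate_update(s + L.cal_f + d, P.m_cal, Ncal_d, P.f.xinf(v),
                   P.f.tau(v) * P.f_tau_scale, dt, R.eng[S_CAL]);
    double r = cai / P.kmfca;
    double fca_inf = 1.0 / (1.0 + r * r);
    s[L.cal_fca + d] += (fca_inf - s[L.cal_fca + d]) *
                        (1.0 - std::exp(-dt / P.tau_fca));
    ryr_rates(P, cai, s[L.casr + d], C.ical_d[d] * nd, Q4);
    scheme_update(s + L.ryr + 4 * d, Q4, 4, P.m_rel, Nryr_d, dt, R.eng[S_REL]);
  }
  hh_gate_update(s + L.to_a, P.m_to, P.N_to, P.a_to.xinf(v), P.a_to.tau(v),
                 dt, R.eng[S_TO]);
  hh_gate_update(s + L.to_i, P.m_to, P.N_to, P.i_to.xinf(v), P.i_to.tau(v),
                 dt, R.eng[S_TO]);
  hh_gate_update(s + L.kur_a, P.m_kur, P.N_kur, P.a_kur.xinf(v), P.a_kur.tau(v),
                 dt, R.eng[S_KUR]);
  hh_gate_update(s + L.ks_x1, P.m_ks, P.N_ks, P.x1.xinf(v), P.x1.tau(v),
                 dt, R.eng[S_KS]);
  hh_gate_update(s + L.ks_x2, P.m_ks, P.N_ks, P.x2.xinf(v), P.x2.tau(v),
                 dt, R.eng[S_KS]);
  hh_gate_update(s + L.k1_x, P.m_k1, P.N_k1, P.xk1.xinf(v), P.xk1.tau(v),
                 dt, R.eng[S_K1]);

  // concentrations (flux balance); stimulus and injection carried by K+
  // pA/pF -> mM/ms: I*Cm [pA] = 1e-15 C/ms; /F -> mol/ms; /V [L] -> M/ms; *1e3
  double conv_na = P.cm / (FARADAY * P.vcyt) * 1e-12;
  double ik_sum = C.ito + C.ikur + C.ikr + C.iks + C.ik1 + C.ikb;
  s[L.nai] += -(C.ina + C.inab + 3.0 * C.inak * f_nak + 3.0 * C.inaca * f_ncx) *
              conv_na * dt;
  s[L.ki] += -(ik_sum - 2.0 * C.inak * f_nak + istim + iinj) * conv_na * dt;
  double bsr_k = P.csqn_b * P.csqn_kd;
  for (int d = 0; d < nd; ++d) {
    double cai = s[L.cai + d], casr = s[L.casr + d];
    double bi = 1.0 / (1.0 + P.cmdn_b * P.cmdn_kd / std::pow(P.cmdn_kd + cai, 2) +
                       P.trpn_b * P.trpn_kd / std::pow(P.trpn_kd + cai, 2));
    double bsr = 1.0 / (1.0 + bsr_k / std::pow(P.csqn_kd + casr, 2));
    double imem = C.ical_d[d] + C.icab_d[d] + C.ipca_d[d] * f_pca[d] -
                  2.0 * C.inaca_d[d] * f_ncx;
    double conv_ca = P.cm / (2.0 * FARADAY * vd) * 1e-12;
    double jnet = C.jrel[d] + C.jleak[d] * f_leak[d] - C.jup[d] * f_up[d];
    s[L.cai + d] += bi * (-imem * conv_ca + jnet) * dt;
    s[L.casr + d] += bsr * (-jnet * P.vcyt / P.vsr) * dt;
    if (s[L.cai + d] < 1e-8) s[L.cai + d] = 1e-8;
    if (s[L.casr + d] < 1e-6) s[L.casr + d] = 1e-6;
  }

  // inter-domain Ca diffusion (complete graph): deviations from the mean
  // relax exactly as exp(-nd dt / tau); total mass conserved
  if (nd > 1) {
    double relax = std::exp(-nd * dt / P.tau_diff);
    for (int blk = 0; blk < 2; ++blk) {
      int base = blk == 0 ? L.cai : L.casr;
      double mean = 0.0;
      for (int d = 0; d < nd; ++d) mean += s[base + d];
      mean /= nd;
      for (int d = 0; d < nd; ++d)
        s[base + d] = mean + (s[base + d] - mean) * relax;
    }
  }

  // membrane potential
  double dvdt = -(C.im + istim + iinj + igap);
  double noise = (alpha > 0.0) ? alpha * std::sqrt(dt) * R.eng[S_VM].norm() : 0.0;
  s[L.vm] = v + dvdt * dt + noise;
  if (s[L.vm] < -150.0 || s[L.vm] > 100.0) {
    stop("membrane potential out of bounds (%.1f mV): numerical blow-up "
         "(vm=%.2f, nai=%.3f, ki=%.1f, cai=%.2e)", s[L.vm], v, s[L.nai],
         s[L.ki], s[L.cai]);
  }
  return dvdt;
}

// ---- initialization ------------------------------------------------------

static void stationary_scheme(double *st, const double *Q, int n, int mode,
                              double N) {
  std::vector<double> pi = bvr::stationary_dist(Q, n);
  if (mode == STOCH && N > 0) {
    long total = (long)std::llround(N), used = 0; int big = 0;
    for (int i = 0; i < n; ++i) {
      st[i] = std::floor(pi[i] * N);
      used += (long)st[i];
      if (pi[i] > pi[big]) big = i;
    }
    st[big] += (double)(total - used);   // exact count conservation
  } else {
    for (int i = 0; i < n; ++i) st[i] = pi[i];
  }
}

// [[Rcpp::export]]
List cpp_init_cell(List cfg) {
  Params P = parse_params(cfg);
  Layout L = make_layout(P.nd);
  std::vector<double> s(L.n, 0.0);
  List init = cfg["init"];
  double v = P.vrest;
  s[L.vm] = v;
  s[L.nai] = getd(init, "nai"); s[L.ki] = getd(init, "ki");
  for (int d = 0; d < P.nd; ++d) {
    s[L.cai + d] = getd(init, "cai");
    s[L.casr + d] = getd(init, "casr");
  }
  double Q7[49], Q5[25], Q4[16];
  ina_rates(P, v, Q7);
  stationary_scheme(&s[L.ina], Q7, 7, P.m_na, P.N_na);
  ikr_rates(P, v, Q5);
  stationary_scheme(&s[L.ikr], Q5, 5, P.m_kr, P.N_kr);
  double Ncal_d = P.N_cal / P.nd, Nryr_d = P.n_ryr / P.nd;
  for (int d = 0; d < P.nd; ++d) {
    double cai = s[L.cai + d];
    double dd = P.d.xinf(v), ff = P.f.xinf(v);
    double r = cai / P.kmfca;
    s[L.cal_d + d] = (P.m_cal == STOCH) ? std::round(dd * Ncal_d) : dd;
    s[L.cal_f + d] = (P.m_cal == STOCH) ? std::round(ff * Ncal_d) : ff;
    s[L.cal_fca + d] = 1.0 / (1.0 + r * r);
    ryr_rates(P, cai, s[L.casr + d], 0.0, Q4);
    stationary_scheme(&s[L.ryr + 4 * d], Q4, 4, P.m_rel, Nryr_d);
  }
  auto hh_init = [&](int idx, const GateP &g, int mode, double N) {
    double x = g.xinf(v);
    s[idx] = (mode == STOCH) ? std::round(x * N) : x;
  };
  hh_init(L.to_a, P.a_to, P.m_to, P.N_to);
  hh_init(L.to_i, P.i_to, P.m_to, P.N_to);
  hh_init(L.kur_a, P.a_kur, P.m_kur, P.N_kur);
  hh_init(L.ks_x1, P.x1, P.m_ks, P.N_ks);
  hh_init(L.ks_x2, P.x2, P.m_ks, P.N_ks);
  hh_init(L.k1_x, P.xk1, P.m_k1, P.N_k1);

  // balance background conductances so the configured resting state is an
  // equilibrium of every ion species (and therefore of Vm)
  Params P0 = P;
  P0.gnab = P0.gcab = P0.gkb = 0.0; P0.vleak = 0.0;
  Currents C;
  compute_currents(P0, L, s.data(), C);
  double ena = RTF * std::log(P.nao / s[L.nai]);
  double ek = RTF * std::log(P.ko / s[L.ki]);
  double eca = 0.5 * RTF * std::log(P.cao / s[L.cai]);
  double na_flux = C.ina + 3.0 * C.inak + 3.0 * C.inaca;
  double gnab = -na_flux / (v - ena);
  double ca_flux = C.ical + C.ipca - 2.0 * C.inaca;
  double gcab = (-ca_flux) / (v - eca);
  double ik_sum = C.ito + C.ikur + C.ikr + C.iks + C.ik1;
  // the K+ background carries the inward-rectifier shape; divide it out
  double gkb = (2.0 * C.inak - ik_sum) / (P.xk1.xinf(v) * (v - ek));
  // SR balance: leak returns what SERCA pumps at rest (minus resting release)
  double dca = s[L.casr] - s[L.cai];
  double po_rest = (P.m_rel == STOCH && P.n_ryr > 0)
                     ? s[L.ryr + 1] / (P.n_ryr / P.nd) : s[L.ryr + 1];
  double vleak = C.jup[0] / dca - P.grel * po_rest;
  bool balanced = gnab >= 0.0 && gcab >= 0.0 && gkb >= 0.0 && vleak >= 0.0;
  if (gnab < 0.0) gnab = 0.0;
  if (gcab < 0.0) gcab = 0.0;
  if (gkb < 0.0) gkb = 0.0;
  if (vleak < 0.0) vleak = 0.0;

  NumericVector sv(s.begin(), s.end());
  sv.attr("names") = state_names(L);
  return List::create(_["state"] = sv,
                      _["gnab"] = gnab, _["gcab"] = gcab, _["gkb"] = gkb,
                      _["vleak"] = vleak, _["balanced"] = balanced);
}

// [[Rcpp::export]]
List cpp_compute_currents(List cfg, NumericVector state) {
  Params P = parse_params(cfg);
  Layout L = make_layout(P.nd);
  if (state.size() != L.n) stop("state vector has wrong length");
  Currents C;
  compute_currents(P, L, REAL(state), C);
  return List::create(
      _["ina"] = C.ina, _["ical"] = C.ical, _["ito"] = C.ito,
      _["ikur"] = C.ikur, _["ikr"] = C.ikr, _["iks"] = C.iks,
      _["ik1"] = C.ik1, _["inak"] = C.inak, _["inaca"] = C.inaca,
      _["ipca"] = C.ipca, _["inab"] = C.inab, _["icab"] = C.icab,
      _["ikb"] = C.ikb, _["im"] = C.im,
      _["jrel"] = NumericVector(C.jrel.begin(), C.jrel.end()),
      _["jup"] = NumericVector(C.jup.begin(), C.jup.end()),
      _["jleak"] = NumericVector(C.jleak.begin(), C.jleak.end()));
}

// [[Rcpp::export]]
NumericVector cpp_step_cell(List cfg, NumericVector state, double dt,
                            double istim, double iinject, double vm_noise_alpha,
                            int seed) {
  Params P = parse_params(cfg);
  Layout L = make_layout(P.nd);
  if (state.size() != L.n) stop("state vector has wrong length");
  std::vector<double> s(state.begin(), state.end());
  CellRng R((std::uint64_t)seed, 0);
  Currents C;
  if (dt > 0.0) step_cell(P, L, s.data(), dt, istim, iinject, 0.0,
                          vm_noise_alpha, R, C);
  NumericVector out(s.begin(), s.end());
  out.attr("names") = state_names(L);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ca_diffusion_step(NumericVector ca, double tau, double dt) {
  if (tau <= 0.0) stop("tau must be positive");
  int n = ca.size();
  NumericVector out = clone(ca);
  if (n < 2 || dt <= 0.0) return out;
  double mean = 0.0;
  for (int d = 0; d < n; ++d) mean += ca[d];
  mean /= n;
  double relax = std::exp(-n * dt / tau);
  for (int d = 0; d < n; ++d) out[d] = mean + (ca[d] - mean) * relax;
  return out;
}

// ---- pacing driver -------------------------------------------------------

struct BeatState {
  double stim_t = 0.0, baseline = 0.0, peak = -1e9, up_t = -1.0,
         cross_t = -1.0, prev_vm = 0.0;
  bool injecting = false;
  void reset(double t, double vm) {
    stim_t = t; baseline = vm; peak = -1e9; up_t = -1.0; cross_t = -1.0;
    prev_vm = vm; injecting = false;
  }
};

// [[Rcpp::export]]
List cpp_simulate(List cfgs, List states0, List proto, double g_gap,
                  NumericVector inject_amp, int seed,
                  IntegerVector cell_stream) {
  int nc = cfgs.size();
  if ((int)states0.size() != nc) stop("one initial state per cell required");
  if ((int)cell_stream.size() != nc) stop("one RNG stream index per cell required");
  std::vector<Params> P; std::vector<Layout> L;
  std::vector<std::vector<double>> S;
  std::vector<CellRng> R;
  for (int c = 0; c < nc; ++c) {
    P.push_back(parse_params(cfgs[c]));
    L.push_back(make_layout(P[c].nd));
    NumericVector st = states0[c];
    if ((int)st.size() != L[c].n) stop("state vector %d has wrong length", c + 1);
    S.emplace_back(st.begin(), st.end());
    R.emplace_back((std::uint64_t)seed, cell_stream[c]);
  }
  std::string mode = as<std::string>(proto["mode"]);
  bool fixed_di = (mode == "fixed_DI" || mode == "fixed_di");
  if (fixed_di && nc != 1) stop("fixed-DI pacing supports a single cell only");
  double cl = getd_def(proto, "cl", 1000.0);
  double di = getd_def(proto, "di", 0.0);
  int n_beats = (int)getd(proto, "n_beats");
  double stim_amp = getd(proto, "stim_amp");    // negative = depolarizing
  double stim_dur = getd(proto, "stim_dur");
  double alpha = getd_def(proto, "vm_noise_alpha", 0.0);
  bool record_trace = as<bool>(proto["record_trace"]);
  bool record_im = as<bool>(proto["record_im"]);
  double record_dt = getd_def(proto, "record_dt", 0.5);
  double max_apd = getd_def(proto, "max_apd", 2500.0);

  // per-cell per-beat outputs
  NumericMatrix apd(n_beats, nc), up_times(n_beats, nc), peaks(n_beats, nc);
  LogicalMatrix valid(n_beats, nc);
  std::fill(apd.begin(), apd.end(), NA_REAL);
  std::fill(up_times.begin(), up_times.end(), NA_REAL);
  NumericVector stim_times(n_beats, NA_REAL);

  int im_cols = record_im ? (int)std::ceil(cl / record_dt) : 0;
  NumericMatrix im_beats(record_im ? n_beats : 0, im_cols);
  if (record_im) std::fill(im_beats.begin(), im_beats.end(), NA_REAL);

  std::vector<double> tr_t;
  std::vector<std::vector<double>> tr_vm(nc), tr_im(nc);
  std::vector<double> tr_cai, tr_casr;

  std::vector<BeatState> B(nc);
  std::vector<Currents> C(nc);
  std::vector<double> dvdt(nc, 0.0);
  std::vector<double> igap(nc, 0.0);

  double t = 0.0;
  long n_steps = 0;
  int beat = -1;
  double next_stim = 0.0, stim_end = -1.0;
  bool stim_on = false;
  double next_rec = 0.0;
  double end_t = fixed_di ? 1e18 : n_beats * cl;
  const Params &P0 = P[0];

  while (true) {
    // stimulus onset
    if (!stim_on && next_stim >= 0.0 && t >= next_stim - 1e-9) {
      ++beat;
      if (beat >= n_beats) break;
      stim_times[beat] = t;
      stim_on = true;
      stim_end = t + stim_dur;
      for (int c = 0; c < nc; ++c) {
        // previous beat that never crossed its APD90 level: repol failure
        if (beat > 0 && B[c].cross_t < 0.0) valid(beat - 1, c) = false;
        B[c].reset(t, S[c][L[c].vm]);
      }
      if (fixed_di) next_stim = -1.0;   // scheduled after APD90 detection
      else next_stim = (beat + 1 < n_beats) ? (beat + 1) * cl : end_t + 1.0;
    }
    if (stim_on && t >= stim_end - 1e-9) stim_on = false;
    if (!fixed_di && t >= end_t - 1e-9) break;
    if (fixed_di && beat == n_beats - 1 && B[0].cross_t > 0.0) break;
    if (fixed_di && beat >= 0 && B[0].cross_t < 0.0 &&
        t - B[0].stim_t > max_apd) {
      stop("APD90 undetectable during fixed-DI pacing (beat %d, t=%.0f ms)",
           beat + 1, t);
    }

    // choose shared dt
    double dt = P0.dt_dia;
    for (int c = 0; c < nc; ++c) {
      double d_c = stim_on ? P[c].dt_up
                   : (std::fabs(dvdt[c]) > 10.0 ? P[c].dt_up
                      : (S[c][L[c].vm] > -70.0 ? P[c].dt_ap : P[c].dt_dia));
      if (d_c < dt) dt = d_c;
    }
    if (stim_on && t + dt > stim_end) dt = stim_end - t;
    if (!stim_on && next_stim > t && t + dt > next_stim) dt = next_stim - t;
    if (t + dt > end_t && !fixed_di) dt = end_t - t;
    if (dt <= 0.0) dt = 1e-6;

    // coupling currents from current voltages (chain topology, sealed ends)
    if (nc > 1 && g_gap > 0.0) {
      for (int c = 0; c < nc; ++c) {
        double sum = 0.0;
        if (c > 0) sum += S[c][L[c].vm] - S[c - 1][L[c - 1].vm];
        if (c < nc - 1) sum += S[c][L[c].vm] - S[c + 1][L[c + 1].vm];
        igap[c] = g_gap * sum;
      }
    }

    double istim = stim_on ? stim_amp : 0.0;
    for (int c = 0; c < nc; ++c) {
      double iinj = B[c].injecting ? inject_amp[c] : 0.0;
      dvdt[c] = step_cell(P[c], L[c], S[c].data(), dt, istim, iinj,
                          igap[c], alpha, R[c], C[c]);
    }
    double t_new = t + dt;
    ++n_steps;

    // beat bookkeeping
    for (int c = 0; c < nc; ++c) {
      if (beat < 0) continue;
      BeatState &b = B[c];
      double vm_old = b.prev_vm, vm_new = S[c][L[c].vm];
      if (vm_new > b.peak) b.peak = vm_new;
      if (b.up_t < 0.0 && vm_old < -40.0 && vm_new >= -40.0 &&
          (vm_new - vm_old) / dt > 5.0) {
        b.up_t = t + (-40.0 - vm_old) / (vm_new - vm_old) * dt;
        b.injecting = true;
      }
      if (b.up_t >= 0.0 && b.cross_t < 0.0 && b.peak > b.baseline + 30.0) {
        double level = b.baseline + 0.1 * (b.peak - b.baseline);
        if (vm_old > level && vm_new <= level) {
          b.cross_t = t + (vm_old - level) / (vm_old - vm_new) * dt;
          apd(beat, c) = b.cross_t - b.up_t;
          up_times(beat, c) = b.up_t;
          peaks(beat, c) = b.peak;
          valid(beat, c) = true;
          b.injecting = false;
          if (fixed_di && c == 0) next_stim = b.cross_t + di;
        }
      }
      b.prev_vm = vm_new;
    }

    // recording at record_dt resolution
    if ((record_trace || record_im) && t_new >= next_rec - 1e-9) {
      if (record_trace) {
        tr_t.push_back(t_new);
        for (int c = 0; c < nc; ++c) {
          tr_vm[c].push_back(S[c][L[c].vm]);
          tr_im[c].push_back(C[c].im);
        }
        double mcai = 0.0, mcasr = 0.0;
        for (int d = 0; d < L[0].nd; ++d) {
          mcai += S[0][L[0].cai + d]; mcasr += S[0][L[0].casr + d];
        }
        tr_cai.push_back(mcai / L[0].nd);
        tr_casr.push_back(mcasr / L[0].nd);
      }
      next_rec += record_dt;
    }
    // beat-aligned Im sampling: last value in each record_dt bin
    if (record_im && beat >= 0) {
      int col = (int)std::floor((t_new - B[0].stim_t) / record_dt);
      if (col >= 0 && col < im_cols) im_beats(beat, col) = C[0].im;
    }
    t = t_new;
  }

  List out = List::create(
      _["apd"] = apd, _["upstroke_times"] = up_times, _["valid"] = valid,
      _["peaks"] = peaks, _["stim_times"] = stim_times);
  List fs(nc);
  for (int c = 0; c < nc; ++c) {
    NumericVector sv(S[c].begin(), S[c].end());
    sv.attr("names") = state_names(L[c]);
    fs[c] = sv;
  }
  out["final_states"] = fs;
  out["n_steps"] = (double)n_steps;
  if (record_trace) {
    List tr = List::create(_["time"] = NumericVector(tr_t.begin(), tr_t.end()));
    for (int c = 0; c < nc; ++c) {
      std::string sfx = nc > 1 ? "_" + std::to_string(c + 1) : "";
      tr["vm" + sfx] = NumericVector(tr_vm[c].begin(), tr_vm[c].end());
      tr["im" + sfx] = NumericVector(tr_im[c].begin(), tr_im[c].end());
    }
    tr["cai"] = NumericVector(tr_cai.begin(), tr_cai.end());
    tr["casr"] = NumericVector(tr_casr.begin(), tr_casr.end());
    out["trace"] = tr;
  }
  if (record_im) out["im_beats"] = im_beats;
  return out;
}
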