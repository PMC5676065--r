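#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;
using mitosim::RNG;

// ---------------------------------------------------------------------------
// Parameter blocks (mirrors the R-side config; see R/config.R for units)
// ---------------------------------------------------------------------------

struct MitoRates {
  double k_sox, w_flux, leak_gain, w_h;
  double k_atp;
  double k_dmg_F, k_rep_F, s_upr;
  double k_dmg_P, k_rep_P;
  double k_dmg_dna, k_deg_dna, k_repl, adv_mut;
  int n_dna_init, n_dna_target;
  double band1, band2, band3;      // stress-state band edges on defect d
  double state_fast, state_slow;   // per-min hazards toward / away from target band
};

struct CellRates {
  double k_sod, k_cat, k_sox_decay;
  double K_g, k_import, upr_K, upr_n, tau_tf, ros_K, ros_m;
  double a_upr, a_daf, a_skn, a_cat;  // antioxidant boosts
  double c_upr, c_daf;             // chaperone boosts
  double eps_nad;                  // NADPH floor for peroxide clearance
  double w_sox_dmg;                // weight of superoxide in the damaging-ROS mix
  double sox_dmg_K;                // saturation constant of superoxide damage (nM)
  double k_nad_syn, k_nad_decay, beta_ros, beta_upr, ros_floor;
  double k_atp_use;
  double k_biog, b_nad, mito_cap;
  double k_mitophagy, d_daf;
  double u_mitoph;                 // optional UPRmt (TIMM-23/PINK-1) mitophagy suppression, off by default
  double state_mult[4];
  double k_death, tau_d, recover_frac;
  int defective_include_s2;        // 0: S3 only (default); 1: S2+S3
  double atp_init, nad_init;
};

struct DrugParams {
  double EC50_r, E_r, IC50_b;      // rapamycin / bafilomycin mitophagy Hill
  double B_r;                      // rapamycin (mTOR) suppression of biogenesis
  double k_pq;                     // paraquat redox-cycling slope (nM/min per uM per mito)
  double pt_K, pt_daf, pt_skn, pt_sirt;  // pterostilbene Hill constants
};

struct Scheme {                    // one dosing window
  int agent;                       // 0 rapa, 1 baf, 2 pq, 3 pt
  double dose, t_start, t_end, refresh, halflife;  // halflife <= 0: no decay
};

struct Ablations { double sod2, daf16, skn1; };

struct Mito {
  double F, Pdam, age;
  int Nwt, Nmut, state;
};

struct Cell {
  double sox, h2o2, nad, atp;
  double atfs1, upr, daf16, skn1;
  double threshold_c, t_comp;
  int life;                        // 0 healthy, 1 compromised, 2 dead
  long cum_mitoph, cum_biog;
  std::vector<Mito> mitos;
  RNG rng;
  Cell() : rng(0) {}
};

// ---------------------------------------------------------------------------
// Small shared kernels
// ---------------------------------------------------------------------------

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

static inline double heteroplasmy(const Mito &m) {
  int tot = m.Nwt + m.Nmut;
  return tot > 0 ? static_cast<double>(m.Nmut) / tot : 0.0;
}

static inline double defect_fraction(const Mito &m, const MitoRates &mr) {
  return clamp01(1.0 - m.F * (1.0 - mr.w_h * heteroplasmy(m)));
}

static inline int target_band(double d, const MitoRates &mr) {
  if (d < mr.band1) return 0;
  if (d < mr.band2) return 1;
  if (d < mr.band3) return 2;
  return 3;
}

// Normalised saturating NAD+ factor, g(1) = 1.
static inline double g_nad(double nad, double K_g) {
  return nad <= 0.0 ? 0.0 : nad * (1.0 + K_g) / (nad + K_g);
}

// One stochastic stress-state move: at most one band per call, biased toward
// the defect-determined target band, with a small symmetric leak.
static inline int state_step(int state, double d, double dt,
                             double fast, double slow,
                             const MitoRates &mr, RNG &rng) {
  int tgt = target_band(d, mr);
  double p_up = 0.0, p_dn = 0.0;
  if (state < tgt)      { p_up = fast; p_dn = (state > 0) ? slow : 0.0; }
  else if (state > tgt) { p_dn = fast; p_up = (state < 3) ? slow : 0.0; }
  else                  { p_up = (state < 3) ? slow : 0.0;
                          p_dn = (state > 0) ? slow : 0.0; }
  double u = rng.runif();
  double pu = 1.0 - std::exp(-p_up * dt);
  double pd = 1.0 - std::exp(-p_dn * dt);
  if (u < pu) return state + 1;
  if (u < pu + pd) return state - 1;
  return state;
}

// Split n_new replication events between wt and mut templates; the damaged
// class replicates with advantage adv (clonal expansion).
static inline void replicate_pool(int &Nwt, int &Nmut, int n_new, double adv,
                                  RNG &rng) {
  if (n_new <= 0) return;
  double w = adv * Nmut;
  double p_mut = (w + Nwt) > 0.0 ? w / (w + Nwt) : 0.0;
  int new_mut = rng.rbinom(n_new, p_mut);
  Nmut += new_mut;
  Nwt += n_new - new_mut;
}

struct MitoEnv {
  double ros, chap, upr, gnad, pq_boost;
};

// Superoxide output of one organelle (nM/min at the cell pool).
static inline double mito_sox_production(const Mito &m, const MitoRates &mr,
                                         const MitoEnv &env) {
  double d = defect_fraction(m, mr);
  // electron input is largely substrate-driven; damaged complexes divert it
  // to superoxide rather than shutting it off, hence no NAD+ factor here
  double flux = mr.w_flux * m.F + (1.0 - mr.w_flux);
  return mr.k_sox * flux * (1.0 + mr.leak_gain * d) + env.pq_boost;
}

// Advance one mitochondrion by dt: deterministic OXPHOS / proteostasis flows,
// then stochastic mtDNA events, then the stress-state machine.
static void mito_step(Mito &m, const MitoRates &mr, const MitoEnv &env,
                      double dt, RNG &rng) {
  double syn = env.gnad / (1.0 + mr.s_upr * env.upr);
  m.F += dt * (-mr.k_dmg_F * env.ros * m.F +
               mr.k_rep_F * env.chap * syn * (1.0 - m.F));
  m.F = clamp01(m.F);
  m.Pdam += dt * (mr.k_dmg_P * env.ros * (1.0 - m.Pdam) -
                  mr.k_rep_P * env.chap * syn * m.Pdam);
  m.Pdam = clamp01(m.Pdam);

  // oxidative hits convert intact copies to the damaged class
  int hits = rng.rpois(mr.k_dmg_dna * env.ros * m.Nwt * dt);
  if (hits > m.Nwt) hits = m.Nwt;
  m.Nwt -= hits; m.Nmut += hits;

  // turnover: degradation (sparing the last copy) then homeostatic,
  // advantage-biased replication toward the copy-number target
  int tot = m.Nwt + m.Nmut;
  if (tot > 1) {
    double p_deg = 1.0 - std::exp(-mr.k_deg_dna * dt);
    int lw = rng.rbinom(m.Nwt, p_deg);
    int lm = rng.rbinom(m.Nmut, p_deg);
    if (lw + lm >= tot) {            // keep at least one copy
      if (m.Nwt > 0) { lw = m.Nwt - 1; lm = m.Nmut; }
      else           { lm = m.Nmut - 1; lw = 0; }
    }
    m.Nwt -= lw; m.Nmut -= lm;
  }
  int deficit = mr.n_dna_target - (m.Nwt + m.Nmut);
  if (deficit > 0) {
    int n_new = rng.rpois(mr.k_repl * deficit * dt);
    if (n_new > deficit) n_new = deficit;
    replicate_pool(m.Nwt, m.Nmut, n_new, mr.adv_mut, rng);
  }

  double d = defect_fraction(m, mr);
  m.state = state_step(m.state, d, dt, mr.state_fast, mr.state_slow, mr, rng);
  m.age += dt;
}

struct DrugsNow {
  double mitoph_mult;              // rapamycin/bafilomycin on the mitophagy hazard
  double biog_mult;                // rapamycin (mTOR) suppression of biogenesis
  double pq_boost;                 // per-mito superoxide add-on (nM/min)
  double pt_daf, pt_skn;           // pterostilbene drives on DAF-16 / SKN-1
  double pt_sirt;                  // sirtuin multiplier (>= 1)
};

// Advance one cell (and its mitochondria) by dt.
static void cell_step(Cell &c, const MitoRates &mr, const CellRates &cr,
                      const DrugsNow &dn, const Ablations &ab, double dt) {
  if (c.life == 2) return;
  RNG &rng = c.rng;
  int n = static_cast<int>(c.mitos.size());

  double gnad = g_nad(c.nad, cr.K_g);
  double ros = c.sox + c.h2o2;          // signalling mix (what TFs sense)
  // membrane-confined superoxide damages matrix targets far less than the
  // diffusible peroxide it dismutates into, and its direct targets (Fe-S
  // clusters) saturate
  double ros_dmg = c.h2o2 + cr.w_sox_dmg * c.sox * cr.sox_dmg_K /
                             (cr.sox_dmg_K + c.sox);

  // (1) superoxide production pooled from the organelle population
  MitoEnv env;
  env.ros = ros_dmg;
  env.upr = c.upr;
  env.gnad = gnad;
  env.pq_boost = dn.pq_boost;
  env.chap = 1.0 + cr.c_upr * c.upr + cr.c_daf * c.daf16;

  double Q = 0.0, sumF = 0.0;
  for (int i = 0; i < n; ++i) {
    Q += mito_sox_production(c.mitos[i], mr, env);
    sumF += c.mitos[i].F;
  }
  double meanF = n > 0 ? sumF / n : 0.0;

  // (2) dismutation and clearance (explicit Euler on the two fast pools)
  double boost = 1.0 + cr.a_upr * c.upr + cr.a_daf * c.daf16 + cr.a_skn * c.skn1;
  double sod_act = cr.k_sod * (1.0 - ab.sod2) * boost;
  // peroxide clearance is NADPH-limited and only weakly TF-inducible
  double cat_act = cr.k_cat * (1.0 + cr.a_cat * c.skn1) *
                   (cr.eps_nad + (1.0 - cr.eps_nad) * c.nad);
  // only enzymatic dismutation yields peroxide; the spontaneous elimination
  // channel (k_sox_decay) routes superoxide to non-peroxide sinks
  double sox_new = c.sox + dt * (Q - (sod_act + cr.k_sox_decay) * c.sox);
  double h2o2_new = c.h2o2 + dt * (sod_act * c.sox - cat_act * c.h2o2);
  c.sox = sox_new < 0.0 ? 0.0 : sox_new;
  c.h2o2 = h2o2_new < 0.0 ? 0.0 : h2o2_new;

  // (3)-(4) ATFS-1 import competition and UPRmt activation
  double import_eff = clamp01(cr.k_import * meanF);
  c.atfs1 = 1.0 - import_eff;
  double an = std::pow(c.atfs1, cr.upr_n);
  c.upr = an / (std::pow(cr.upr_K, cr.upr_n) + an);

  // (5) DAF-16 / SKN-1 relax toward ROS- and drug-driven targets
  double rosm = std::pow(ros, cr.ros_m);
  double ros_drive = rosm / (std::pow(cr.ros_K, cr.ros_m) + rosm);
  double daf_tgt = clamp01((ros_drive + dn.pt_daf) * (1.0 - ab.daf16));
  double skn_tgt = clamp01((ros_drive + dn.pt_skn) * (1.0 - ab.skn1));
  c.daf16 += dt * (daf_tgt - c.daf16) / cr.tau_tf;
  c.skn1 += dt * (skn_tgt - c.skn1) / cr.tau_tf;
  c.daf16 = clamp01(c.daf16);
  c.skn1 = clamp01(c.skn1);

  // (7) NAD+: sirtuin-scaled salvage vs stress-accelerated consumption
  // stress-driven NAD+ consumption: redox drain past the tolerance floor
  // plus the persistent damage-response (UPRmt-gated) drain
  double over = ros_dmg > cr.ros_floor ? (ros_dmg - cr.ros_floor) / 100.0 : 0.0;
  double stress = cr.beta_ros * over * over + cr.beta_upr * c.upr * c.upr;
  c.nad += dt * (cr.k_nad_syn * dn.pt_sirt - cr.k_nad_decay * (1.0 + stress) * c.nad);
  if (c.nad < 0.0) c.nad = 0.0;

  // (8) ATP: OXPHOS output saturating in NAD+, first-order consumption
  c.atp += dt * (mr.k_atp * sumF * gnad - cr.k_atp_use * c.atp);
  if (c.atp < 0.0) c.atp = 0.0;

  // (9) advance each organelle
  for (int i = 0; i < n; ++i) mito_step(c.mitos[i], mr, env, dt, rng);

  // (10a) selective mitophagy
  double sirt = c.nad * dn.pt_sirt;
  for (int i = static_cast<int>(c.mitos.size()) - 1; i >= 0; --i) {
    double hz = cr.k_mitophagy * cr.state_mult[c.mitos[i].state] *
                dn.mitoph_mult * (1.0 + cr.d_daf * c.daf16) /
                (1.0 + cr.u_mitoph * c.upr);
    if (rng.rbernoulli(1.0 - std::exp(-hz * dt))) {
      c.mitos.erase(c.mitos.begin() + i);
      ++c.cum_mitoph;
    }
  }

  // (10b) biogenesis under a soft carrying capacity, boosted by sirtuin tone
  int count = static_cast<int>(c.mitos.size());
  double cap_term = 1.0 - count / cr.mito_cap;
  if (cap_term < 0.0) cap_term = 0.0;
  double lam = cr.k_biog * cap_term * (1.0 + cr.b_nad * sirt) * dn.biog_mult;
  if (count < 2.0 * cr.mito_cap &&
      rng.rbernoulli(1.0 - std::exp(-lam * dt))) {
    Mito nm;
    nm.F = rng.rtri(0.93, 0.97, 1.0);
    nm.Pdam = 0.0; nm.age = 0.0; nm.state = 0;
    nm.Nwt = 0; nm.Nmut = 0;
    int pw = 0, pm = 0;
    for (size_t i = 0; i < c.mitos.size(); ++i) {
      pw += c.mitos[i].Nwt; pm += c.mitos[i].Nmut;
    }
    if (pw + pm == 0) { nm.Nwt = mr.n_dna_init; }
    else {
      int w = pw, m2 = pm;
      // sample the new organelle's genomes from the cell-wide pool proportions
      double adv_w = mr.adv_mut * m2;
      double p_mut = adv_w / (adv_w + w);
      nm.Nmut = rng.rbinom(mr.n_dna_init, p_mut);
      nm.Nwt = mr.n_dna_init - nm.Nmut;
    }
    c.mitos.push_back(nm);
    ++c.cum_biog;
  }

  // (11) compromised / death state machine with hysteresis
  count = static_cast<int>(c.mitos.size());
  double frac_def = 1.0;
  if (count > 0) {
    int ndef = 0;
    for (int i = 0; i < count; ++i) {
      int s = c.mitos[i].state;
      if (s == 3 || (cr.defective_include_s2 && s == 2)) ++ndef;
    }
    frac_def = static_cast<double>(ndef) / count;
  }
  if (c.life == 0) {
    if (frac_def > c.threshold_c) { c.life = 1; c.t_comp = 0.0; }
  } else if (c.life == 1) {
    if (frac_def < cr.recover_frac) {
      c.life = 0; c.t_comp = 0.0;
    } else {
      c.t_comp += dt;
      double hz = cr.k_death * (1.0 + c.t_comp / cr.tau_d);
      if (rng.rbernoulli(1.0 - std::exp(-hz * dt))) c.life = 2;
    }
  }
}

// ---------------------------------------------------------------------------
// Dosing schedule -> momentary drug effects
// ---------------------------------------------------------------------------

static double scheme_level(const Scheme &s, double t) {
  if (t < s.t_start || t >= s.t_end) return 0.0;
  if (s.halflife <= 0.0) return s.dose;
  double el = t - s.t_start;
  double since = el - std::floor(el / s.refresh) * s.refresh;
  return s.dose * std::pow(0.5, since / s.halflife);
}

static DrugsNow drugs_at(const std::vector<Scheme> &schemes,
                         const DrugParams &dp, double t) {
  double rapa = 0.0, baf = 0.0, pq = 0.0, pt = 0.0;
  for (size_t i = 0; i < schemes.size(); ++i) {
    double lvl = scheme_level(schemes[i], t);
    switch (schemes[i].agent) {
      case 0: rapa += lvl; break;
      case 1: baf += lvl; break;
      case 2: pq += lvl; break;
      case 3: pt += lvl; break;
    }
  }
  DrugsNow dn;
  dn.mitoph_mult = (1.0 + dp.E_r * rapa / (dp.EC50_r + rapa)) /
                   (1.0 + baf / dp.IC50_b);
  dn.biog_mult = 1.0 / (1.0 + dp.B_r * rapa / (dp.EC50_r + rapa));
  dn.pq_boost = dp.k_pq * pq;
  double pth = pt / (dp.pt_K + pt);
  dn.pt_daf = dp.pt_daf * pth;
  dn.pt_skn = dp.pt_skn * pth;
  dn.pt_sirt = 1.0 + dp.pt_sirt * pth;
  return dn;
}

// ---------------------------------------------------------------------------
// Config marshalling
// ---------------------------------------------------------------------------

static MitoRates read_mito_rates(const List &m) {
  MitoRates r;
  r.k_sox = as<double>(m["k_sox"]);
  r.w_flux = as<double>(m["w_flux"]);
  r.leak_gain = as<double>(m["leak_gain"]);
  r.w_h = as<double>(m["w_h"]);
  r.k_atp = as<double>(m["k_atp"]);
  r.k_dmg_F = as<double>(m["k_dmg_F"]);
  r.k_rep_F = as<double>(m["k_rep_F"]);
  r.s_upr = as<double>(m["s_upr"]);
  r.k_dmg_P = as<double>(m["k_dmg_P"]);
  r.k_rep_P = as<double>(m["k_rep_P"]);
  r.k_dmg_dna = as<double>(m["k_dmg_dna"]);
  r.k_deg_dna = as<double>(m["k_deg_dna"]);
  r.k_repl = as<double>(m["k_repl"]);
  r.adv_mut = as<double>(m["adv_mut"]);
  r.n_dna_init = as<int>(m["n_dna_init"]);
  r.n_dna_target = as<int>(m["n_dna_target"]);
  NumericVector bands = m["bands"];
  r.band1 = bands[0]; r.band2 = bands[1]; r.band3 = bands[2];
  r.state_fast = as<double>(m["state_fast"]);
  r.state_slow = as<double>(m["state_slow"]);
  return r;
}

static CellRates read_cell_rates(const List &cc) {
  CellRates r;
  r.k_sod = as<double>(cc["k_sod"]);
  r.k_cat = as<double>(cc["k_cat"]);
  r.k_sox_decay = as<double>(cc["k_sox_decay"]);
  r.K_g = as<double>(cc["K_g"]);
  r.k_import = as<double>(cc["k_import"]);
  r.upr_K = as<double>(cc["upr_K"]);
  r.upr_n = as<double>(cc["upr_n"]);
  r.tau_tf = as<double>(cc["tau_tf"]);
  r.ros_K = as<double>(cc["ros_K"]);
  r.ros_m = as<double>(cc["ros_m"]);
  r.a_upr = as<double>(cc["a_upr"]);
  r.a_daf = as<double>(cc["a_daf"]);
  r.a_skn = as<double>(cc["a_skn"]);
  r.a_cat = as<double>(cc["a_cat"]);
  r.c_upr = as<double>(cc["c_upr"]);
  r.c_daf = as<double>(cc["c_daf"]);
  r.eps_nad = as<double>(cc["eps_nad"]);
  r.w_sox_dmg = as<double>(cc["w_sox_dmg"]);
  r.sox_dmg_K = as<double>(cc["sox_dmg_K"]);
  r.k_nad_syn = as<double>(cc["k_nad_syn"]);
  r.k_nad_decay = as<double>(cc["k_nad_decay"]);
  r.beta_ros = as<double>(cc["beta_ros"]);
  r.beta_upr = as<double>(cc["beta_upr"]);
  r.ros_floor = as<double>(cc["ros_floor"]);
  r.k_atp_use = as<double>(cc["k_atp_use"]);
  r.k_biog = as<double>(cc["k_biog"]);
  r.b_nad = as<double>(cc["b_nad"]);
  r.mito_cap = as<double>(cc["mito_cap"]);
  r.k_mitophagy = as<double>(cc["k_mitophagy"]);
  r.d_daf = as<double>(cc["d_daf"]);
  r.u_mitoph = as<double>(cc["u_mitoph"]);
  NumericVector sm = cc["state_mult"];
  for (int i = 0; i < 4; ++i) r.state_mult[i] = sm[i];
  r.k_death = as<double>(cc["k_death"]);
  r.tau_d = as<double>(cc["tau_d"]);
  r.recover_frac = as<double>(cc["recover_frac"]);
  r.defective_include_s2 = as<int>(cc["defective_include_s2"]);
  r.atp_init = as<double>(cc["atp_init"]);
  r.nad_init = as<double>(cc["nad_init"]);
  return r;
}

static DrugParams read_drug_params(const List &d) {
  DrugParams p;
  p.EC50_r = as<double>(d["EC50_r"]);
  p.E_r = as<double>(d["E_r"]);
  p.IC50_b = as<double>(d["IC50_b"]);
  p.B_r = as<double>(d["B_r"]);
  p.k_pq = as<double>(d["k_pq"]);
  p.pt_K = as<double>(d["pt_K"]);
  p.pt_daf = as<double>(d["pt_daf"]);
  p.pt_skn = as<double>(d["pt_skn"]);
  p.pt_sirt = as<double>(d["pt_sirt"]);
  return p;
}

static std::vector<Scheme> read_schemes(const List &pl) {
  std::vector<Scheme> out;
  for (int i = 0; i < pl.size(); ++i) {
    List s = pl[i];
    Scheme sc;
    sc.agent = as<int>(s["agent_code"]);
    sc.dose = as<double>(s["dose"]);
    sc.t_start = as<double>(s["t_start"]);
    sc.t_end = as<double>(s["t_end"]);
    sc.refresh = as<double>(s["refresh_every"]);
    sc.halflife = as<double>(s["decay_halflife"]);
    out.push_back(sc);
  }
  return out;
}

static Mito fresh_mito(const MitoRates &mr, RNG &rng) {
  Mito m;
  m.F = rng.rtri(0.93, 0.97, 1.0);
  m.Pdam = 0.0;
  m.age = 0.0;
  m.state = 0;
  m.Nwt = mr.n_dna_init;
  m.Nmut = 0;
  return m;
}

// ---------------------------------------------------------------------------
// Full population run
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_simulation(List cfg) {
  List sim = cfg["simulation"];
  double t_end = as<double>(sim["t_end"]);
  double dt = as<double>(sim["dt"]);
  int n_cells = as<int>(sim["n_cells"]);
  int n_mito = as<int>(sim["n_mito_init"]);
  int n_record = as<int>(sim["n_record"]);
  double seed = as<double>(sim["seed"]);

  MitoRates mr = read_mito_rates(cfg["mitochondrion"]);
  CellRates cr = read_cell_rates(cfg["cell"]);
  DrugParams dp = read_drug_params(cfg["drugs"]);
  std::vector<Scheme> schemes = read_schemes(cfg["perturbations"]);
  List abl = cfg["ablations"];
  Ablations ab;
  ab.sod2 = as<double>(abl["sod2"]);
  ab.daf16 = as<double>(abl["daf16"]);
  ab.skn1 = as<double>(abl["skn1"]);

  std::uint64_t master = static_cast<std::uint64_t>(seed);

  std::vector<Cell> cells(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    Cell &c = cells[i];
    c.rng = RNG(mitosim::stream_seed(master, i + 1));
    c.sox = 0.0; c.h2o2 = 0.0;
    c.nad = cr.nad_init; c.atp = cr.atp_init;
    c.atfs1 = 0.0; c.upr = 0.0; c.daf16 = 0.0; c.skn1 = 0.0;
    c.t_comp = 0.0; c.life = 0;
    c.cum_mitoph = 0; c.cum_biog = 0;
    c.threshold_c = c.rng.rtri(0.60, 0.625, 0.75);
    c.mitos.reserve(2 * static_cast<int>(cr.mito_cap));
    for (int j = 0; j < n_mito; ++j) c.mitos.push_back(fresh_mito(mr, c.rng));
  }

  NumericVector time_grid(n_record);
  for (int j = 0; j < n_record; ++j)
    time_grid[j] = t_end * j / (n_record - 1.0);

  NumericMatrix rec_sox(n_record, n_cells), rec_h2o2(n_record, n_cells),
      rec_nad(n_record, n_cells), rec_atp(n_record, n_cells),
      rec_meanF(n_record, n_cells), rec_upr(n_record, n_cells),
      rec_daf16(n_record, n_cells), rec_skn1(n_record, n_cells),
      rec_atfs1(n_record, n_cells), rec_resp(n_record, n_cells);
  IntegerMatrix rec_count(n_record, n_cells), rec_nwt(n_record, n_cells),
      rec_nmut(n_record, n_cells), rec_life(n_record, n_cells),
      rec_s0(n_record, n_cells), rec_s1(n_record, n_cells),
      rec_s2(n_record, n_cells), rec_s3(n_record, n_cells);
  NumericMatrix rec_cmitoph(n_record, n_cells), rec_cbiog(n_record, n_cells);

  int n_steps = static_cast<int>(std::floor(t_end / dt + 0.5));
  int next_rec = 0;

  for (int step = 0; step <= n_steps; ++step) {
    double t = step * dt;

    // record at grid points (first matching, before stepping past them)
    if (next_rec < n_record && t >= time_grid[next_rec] - 1e-9) {
      for (int i = 0; i < n_cells; ++i) {
        Cell &c = cells[i];
        rec_sox(next_rec, i) = c.sox;
        rec_h2o2(next_rec, i) = c.h2o2;
        rec_nad(next_rec, i) = c.nad;
        rec_atp(next_rec, i) = c.atp;
        rec_upr(next_rec, i) = c.upr;
        rec_daf16(next_rec, i) = c.daf16;
        rec_skn1(next_rec, i) = c.skn1;
        rec_atfs1(next_rec, i) = c.atfs1;
        int cnt = static_cast<int>(c.mitos.size());
        rec_count(next_rec, i) = cnt;
        int nwt = 0, nmut = 0, s[4] = {0, 0, 0, 0};
        double sumF = 0.0, resp = 0.0;
        double gn = g_nad(c.nad, cr.K_g);
        for (int k = 0; k < cnt; ++k) {
          const Mito &m = c.mitos[k];
          nwt += m.Nwt; nmut += m.Nmut; ++s[m.state]; sumF += m.F;
          resp += gn * m.F;
        }
        rec_nwt(next_rec, i) = nwt;
        rec_nmut(next_rec, i) = nmut;
        rec_s0(next_rec, i) = s[0]; rec_s1(next_rec, i) = s[1];
        rec_s2(next_rec, i) = s[2]; rec_s3(next_rec, i) = s[3];
        rec_meanF(next_rec, i) = cnt > 0 ? sumF / cnt : 0.0;
        rec_resp(next_rec, i) = resp;
        rec_life(next_rec, i) = c.life;
        rec_cmitoph(next_rec, i) = static_cast<double>(c.cum_mitoph);
        rec_cbiog(next_rec, i) = static_cast<double>(c.cum_biog);
      }
      ++next_rec;
    }
    if (step == n_steps) break;

    DrugsNow dn = drugs_at(schemes, dp, t);
    for (int i = 0; i < n_cells; ++i)
      cell_step(cells[i], mr, cr, dn, ab, dt);

    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["time"] = time_grid,
      _["sox"] = rec_sox, _["h2o2"] = rec_h2o2,
      _["nad"] = rec_nad, _["atp"] = rec_atp,
      _["mean_F"] = rec_meanF, _["resp"] = rec_resp,
      _["upr"] = rec_upr, _["daf16"] = rec_daf16,
      _["skn1"] = rec_skn1, _["atfs1"] = rec_atfs1,
      _["mito_count"] = rec_count, _["n_wt"] = rec_nwt,
      _["n_mut"] = rec_nmut, _["life"] = rec_life,
      _["s0"] = rec_s0, _["s1"] = rec_s1,
      _["s2"] = rec_s2, _["s3"] = rec_s3,
      _["cum_mitophagy"] = rec_cmitoph, _["cum_biogenesis"] = rec_cbiog);
}

// ---------------------------------------------------------------------------
// Exported kernels (single-agent surfaces reuse the engine's inner functions)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_step_mito(List mito, List env, List mito_rates, double dt,
                   double seed, int n_steps) {
  MitoRates mr = read_mito_rates(mito_rates);
  Mito m;
  m.F = as<double>(mito["F"]);
  m.Pdam = as<double>(mito["Pdam"]);
  m.age = as<double>(mito["age"]);
  m.Nwt = as<int>(mito["n_wt"]);
  m.Nmut = as<int>(mito["n_mut"]);
  m.state = as<int>(mito["state"]);
  MitoEnv e;
  e.ros = as<double>(env["ros"]);
  e.chap = as<double>(env["chaperones"]);
  e.upr = as<double>(env["upr"]);
  e.gnad = as<double>(env["g_nad"]);
  e.pq_boost = 0.0;
  RNG rng(static_cast<std::uint64_t>(seed));
  for (int i = 0; i < n_steps; ++i) mito_step(m, mr, e, dt, rng);
  return List::create(_["F"] = m.F, _["Pdam"] = m.Pdam, _["age"] = m.age,
                      _["n_wt"] = m.Nwt, _["n_mut"] = m.Nmut,
                      _["state"] = m.state);
}

// [[Rcpp::export]]
IntegerVector cpp_state_path(int state, double d, double dt, double fast,
                             double slow, NumericVector bands, double seed,
                             int n_steps) {
  MitoRates mr = MitoRates();
  mr.band1 = bands[0]; mr.band2 = bands[1]; mr.band3 = bands[2];
  RNG rng(static_cast<std::uint64_t>(seed));
  IntegerVector out(n_steps);
  int s = state;
  for (int i = 0; i < n_steps; ++i) {
    s = state_step(s, d, dt, fast, slow, mr, rng);
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_replicate_mtdna(int n_wt, int n_mut, int n_new, double adv,
                                  double seed) {
  if (n_wt + n_mut == 0) stop("mtDNA pool is empty");
  RNG rng(static_cast<std::uint64_t>(seed));
  int w = n_wt, m = n_mut;
  replicate_pool(w, m, n_new, adv, rng);
  return IntegerVector::create(w, m);
}

// [[Rcpp::export]]
List cpp_step_cell(List cell, List mito_rates, List cell_rates,
                   List drugs_now, List ablations, double dt, double seed,
                   int n_steps) {
  MitoRates mr = read_mito_rates(mito_rates);
  CellRates cr = read_cell_rates(cell_rates);
  DrugsNow dn;
  dn.mitoph_mult = as<double>(drugs_now["mitophagy_mult"]);
  dn.biog_mult = as<double>(drugs_now["biog_mult"]);
  dn.pq_boost = as<double>(drugs_now["pq_boost"]);
  dn.pt_daf = as<double>(drugs_now["pt_daf"]);
  dn.pt_skn = as<double>(drugs_now["pt_skn"]);
  dn.pt_sirt = as<double>(drugs_now["pt_sirt"]);
  Ablations ab;
  ab.sod2 = as<double>(ablations["sod2"]);
  ab.daf16 = as<double>(ablations["daf16"]);
  ab.skn1 = as<double>(ablations["skn1"]);

  Cell c;
  c.sox = as<double>(cell["sox"]);
  c.h2o2 = as<double>(cell["h2o2"]);
  c.nad = as<double>(cell["nad"]);
  c.atp = as<double>(cell["atp"]);
  c.atfs1 = as<double>(cell["atfs1_nuc"]);
  c.upr = as<double>(cell["upr"]);
  c.daf16 = as<double>(cell["daf16"]);
  c.skn1 = as<double>(cell["skn1"]);
  c.threshold_c = as<double>(cell["threshold_c"]);
  c.t_comp = as<double>(cell["t_compromised"]);
  c.life = as<int>(cell["life"]);
  c.cum_mitoph = 0; c.cum_biog = 0;
  if (c.life == 2) stop("cannot step a dead cell");
  List ml = cell["mitos"];
  NumericVector mF = ml["F"], mP = ml["Pdam"], mA = ml["age"];
  IntegerVector mw = ml["n_wt"], mm = ml["n_mut"], ms = ml["state"];
  for (int i = 0; i < mF.size(); ++i) {
    Mito m;
    m.F = mF[i]; m.Pdam = mP[i]; m.age = mA[i];
    m.Nwt = mw[i]; m.Nmut = mm[i]; m.state = ms[i];
    c.mitos.push_back(m);
  }
  c.rng = RNG(static_cast<std::uint64_t>(seed));
  for (int k = 0; k < n_steps; ++k) cell_step(c, mr, cr, dn, ab, dt);

  int n = static_cast<int>(c.mitos.size());
  NumericVector oF(n), oP(n), oA(n);
  IntegerVector ow(n), om(n), os(n);
  for (int i = 0; i < n; ++i) {
    oF[i] = c.mitos[i].F; oP[i] = c.mitos[i].Pdam; oA[i] = c.mitos[i].age;
    ow[i] = c.mitos[i].Nwt; om[i] = c.mitos[i].Nmut; os[i] = c.mitos[i].state;
  }
  return List::create(
      _["sox"] = c.sox, _["h2o2"] = c.h2o2, _["nad"] = c.nad,
      _["atp"] = c.atp, _["atfs1_nuc"] = c.atfs1, _["upr"] = c.upr,
      _["daf16"] = c.daf16, _["skn1"] = c.skn1,
      _["threshold_c"] = c.threshold_c, _["t_compromised"] = c.t_comp,
      _["life"] = c.life,
      _["n_mitophagy"] = static_cast<double>(c.cum_mitoph),
      _["n_biogenesis"] = static_cast<double>(c.cum_biog),
      _["mitos"] = List::create(_["F"] = oF, _["Pdam"] = oP, _["age"] = oA,
                                _["n_wt"] = ow, _["n_mut"] = om,
                                _["state"] = os));
}

// [[Rcpp::export]]
NumericVector cpp_runif(int n, double seed) {
  RNG rng(static_cast<std::uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.runif();
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rtri(int n, double a, double c, double b, double seed) {
  RNG rng(static_cast<std::uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rtri(a, c, b);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_rpois(int n, double lambda, double seed) {
  RNG rng(static_cast<std::uint64_t>(seed));
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rpois(lambda);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_rbinom(int n, int size, double prob, double seed) {
  RNG rng(static_cast<std::uint64_t>(seed));
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rbinom(size, prob);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_stream_seeds(double seed, int n) {
  NumericVector out(n);
  std::uint64_t master = static_cast<std::uint64_t>(seed);
  for (int i = 0; i < n; ++i) {
    std::uint64_t s = mitosim::stream_seed(master, i);
    out[i] = static_cast<double>(s >> 33);  // 31-bit, R-integer safe
  }
  return out;
}
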