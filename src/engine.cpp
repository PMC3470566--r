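// Core simulation engine: operator-split implicit-Euler integration of the
// coupled cable / Markov-state / ion-concentration system on a branched tree.
//
// The step mirrors step_reference() in R/solver.R:
//   (1) explicit Hodgkin-Huxley gate updates and NKCC1 carrier update,
//   (2) implicit Markov updates (5/6-state Na schemes, 6-state GABA-A),
//   (3) direct implicit voltage solve on the tree (Hines elimination),
//       with voltage clamp by exact row substitution,
//   (4) concentration / glial-buffer / longitudinal-diffusion updates from
//       the per-ion membrane currents evaluated at the new voltage.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY_C = 96485.332;

static inline double eval_rate(int type, double p1, double p2, double p3,
                               double v, double ligand) {
  switch (type) {
  case 1: return p1;
  case 2: return p1 * std::exp((v - p2) / p3);
  case 3: {
    double x = v - p2;
    if (std::fabs(x) < 1e-6) return p1 * p3;
    return p1 * x / (1.0 - std::exp(-x / p3));
  }
  case 4: return p1 * ligand;
  case 5: {
    double x = p2 - v;
    if (std::fabs(x) < 1e-6) return p1 * p3;
    return p1 * x / (1.0 - std::exp(-x / p3));
  }
  }
  return 0.0;
}

struct Scheme {
  int ns;
  std::vector<int> from, to, type;
  std::vector<double> p1, p2, p3;
  void init(const NumericMatrix& m, int nstates) {
    ns = nstates;
    int k = m.nrow();
    from.resize(k); to.resize(k); type.resize(k);
    p1.resize(k); p2.resize(k); p3.resize(k);
    for (int i = 0; i < k; ++i) {
      from[i] = (int)m(i, 0); to[i] = (int)m(i, 1); type[i] = (int)m(i, 2);
      p1[i] = m(i, 3); p2[i] = m(i, 4); p3[i] = m(i, 5);
    }
  }
};

// implicit update: solve (I - dt * Q^T) p' = p, clip, renormalise
static void markov_step(const Scheme& s, double* p, double v, double ligand,
                        double dt) {
  double A[6][6];
  double Q[6][6];
  int n = s.ns;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Q[i][j] = 0.0;
  for (size_t k = 0; k < s.from.size(); ++k) {
    double r = eval_rate(s.type[k], s.p1[k], s.p2[k], s.p3[k], v, ligand);
    Q[s.from[k]][s.to[k]] += r;
  }
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) rs += Q[i][j];
    Q[i][i] = -rs;
  }
  // A = I - dt * Q^T
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A[i][j] = (i == j ? 1.0 : 0.0) - dt * Q[j][i];
  double b[6];
  for (int i = 0; i < n; ++i) b[i] = p[i];
  // Gaussian elimination with partial pivoting
  int piv[6];
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int c = 0; c < n; ++c) {
    int best = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[best][c])) best = r;
    if (best != c) {
      for (int j = 0; j < n; ++j) std::swap(A[c][j], A[best][j]);
      std::swap(b[c], b[best]);
    }
    double d = A[c][c];
    if (std::fabs(d) < 1e-300)
      stop("implicit Markov solve failed: singular system (v=%f)", v);
    for (int r = c + 1; r < n; ++r) {
      double f = A[r][c] / d;
      if (f == 0.0) continue;
      for (int j = c; j < n; ++j) A[r][j] -= f * A[c][j];
      b[r] -= f * b[c];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double sum = b[c];
    for (int j = c + 1; j < n; ++j) sum -= A[c][j] * p[j];
    p[c] = sum / A[c][c];
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    if (p[i] < 0.0) p[i] = 0.0;  // roundoff only: (I - dt Q^T) is an M-matrix
    tot += p[i];
  }
  for (int i = 0; i < n; ++i) p[i] /= tot;
}

// [[Rcpp::export]]
List engine_run(List mc, List st, List pc) {
  // ---- model ---------------------------------------------------------------
  const int n = as<int>(mc["n"]);
  IntegerVector parent = mc["parent"];
  NumericVector area = mc["area"], vol_i = mc["vol_i"], vol_o = mc["vol_o"];
  NumericVector g_ax = mc["g_ax"], surf_i = mc["surf_i"],
    surf_o = mc["surf_o"], ddist = mc["ddist"];
  const double cm = as<double>(mc["cm"]);
  const double rtf = as<double>(mc["rtf"]);
  NumericVector d_ion = mc["d_ion"];
  NumericMatrix hh_g = mc["hh_g"];
  IntegerVector chan_ion = mc["chan_ion"];
  NumericVector chan_erev = mc["chan_erev"], chan_nafrac = mc["chan_nafrac"];
  IntegerVector gate_chan = mc["gate_chan"];
  NumericVector gate_exp = mc["gate_exp"];
  NumericMatrix gate_pars = mc["gate_pars"];
  NumericVector na_gbar = mc["na_gbar"], na_fraction = mc["na_fraction"];
  Scheme na5s, na6s, gabas;
  na5s.init(as<NumericMatrix>(mc["na5_trans"]), 5);
  na6s.init(as<NumericMatrix>(mc["na6_trans"]), 6);
  gabas.init(as<NumericMatrix>(mc["gaba_trans"]), 6);
  NumericVector gaba_gbar = mc["gaba_gbar"];
  const double hco3_frac = as<double>(mc["hco3_frac"]);
  const double e_hco3 = as<double>(mc["e_hco3"]);
  NumericVector kcc2_U = mc["kcc2_U"];
  const double kcc2_km_k = as<double>(mc["kcc2_km_k"]);
  const double kcc2_km_cl = as<double>(mc["kcc2_km_cl"]);
  NumericVector nkcc1_U = mc["nkcc1_U"];
  const double nk_km_na = as<double>(mc["nkcc1_km_na"]);
  const double nk_km_k = as<double>(mc["nkcc1_km_k"]);
  const double nk_km_cl = as<double>(mc["nkcc1_km_cl"]);
  const double nk_kt = as<double>(mc["nkcc1_kt"]);
  const double nk_ke = as<double>(mc["nkcc1_ke"]);
  NumericVector nak_imax = mc["nak_imax"];
  const double nak_km_na = as<double>(mc["nak_km_na"]);
  const double nak_km_k = as<double>(mc["nak_km_k"]);
  NumericVector capump_imax = mc["capump_imax"];
  const double capump_km = as<double>(mc["capump_km"]);
  NumericVector nacax_scale = mc["nacax_scale"];
  const double nx_km_na = as<double>(mc["nacax_km_na"]);
  const double nx_km_ca = as<double>(mc["nacax_km_ca"]);
  const double nx_gamma = as<double>(mc["nacax_gamma"]);
  const double nx_ksat = as<double>(mc["nacax_ksat"]);
  NumericVector gleak_na = mc["gleak_na"], gleak_k = mc["gleak_k"],
    gleak_cl = mc["gleak_cl"];
  const double buf_total = as<double>(mc["buf_total"]);
  const double buf_kf = as<double>(mc["buf_kf"]);
  const double buf_kb = as<double>(mc["buf_kb"]);
  const double k_o_rest = as<double>(mc["k_o_rest"]);
  const int nchan = hh_g.ncol();
  const int ngate = gate_chan.size();

  // ---- state ---------------------------------------------------------------
  std::vector<double> v = as<std::vector<double> >(st["v"]);
  NumericMatrix conc0 = st["conc"];
  std::vector<double> conc(conc0.begin(), conc0.end());  // col-major n x 8
  NumericMatrix gates0 = st["gates"];
  std::vector<double> gates(gates0.begin(), gates0.end());
  NumericMatrix na50 = st["na5"];
  std::vector<double> na5(na50.begin(), na50.end());
  NumericMatrix na60 = st["na6"];
  std::vector<double> na6(na60.begin(), na60.end());
  NumericMatrix gaba0 = st["gaba"];
  std::vector<double> gab(gaba0.begin(), gaba0.end());
  std::vector<double> y = as<std::vector<double> >(st["y"]);
  std::vector<double> kb = as<std::vector<double> >(st["kb"]);

  // ---- protocol ------------------------------------------------------------
  const int nsteps = as<int>(pc["nsteps"]);
  const double dt = as<double>(pc["dt"]);
  IntegerVector inj_comp = pc["inj_comp"];
  NumericVector inj_t0 = pc["inj_t0"], inj_t1 = pc["inj_t1"],
    inj_amp = pc["inj_amp"];
  IntegerVector noise_comp = pc["noise_comp"];
  NumericVector noise_mean = pc["noise_mean"], noise_sd = pc["noise_sd"];
  List train_onsets = pc["train_onsets"];
  NumericVector train_peak = pc["train_peak"], train_sq = pc["train_sq"],
    train_tau = pc["train_tau"];
  List train_targets = pc["train_targets"];
  NumericVector gaba_scale = pc["gaba_scale"];
  IntegerVector glut_comp = pc["glut_comp"];
  NumericVector glut_onsets = pc["glut_onsets"];
  const double glut_gmax = as<double>(pc["glut_gmax"]);
  const double glut_tau_r = as<double>(pc["glut_tau_r"]);
  const double glut_tau_d = as<double>(pc["glut_tau_d"]);
  IntegerVector clamp_comp = pc["clamp_comp"];
  NumericVector clamp_times = pc["clamp_times"], clamp_vals = pc["clamp_vals"];
  const int k_mode = as<int>(pc["k_mode"]);
  NumericVector k_times = pc["k_times"], k_vals = pc["k_vals"];
  const bool kcc2_frozen = as<bool>(pc["kcc2_frozen_k"]);
  const double kcc2_scale = as<double>(pc["kcc2_scale"]);
  const double na_scale = as<double>(pc["na_scale"]);
  const bool conc_dyn = as<bool>(pc["conc_dyn"]);
  const bool diffusion_on = as<bool>(pc["diffusion_on"]);
  const bool buffer_on = as<bool>(pc["buffer_on"]);
  const int stride = as<int>(pc["record_stride"]);

  const int ntrain = train_onsets.size();
  std::vector<std::vector<double> > tr_on(ntrain);
  std::vector<std::vector<int> > tr_tg(ntrain);
  for (int k = 0; k < ntrain; ++k) {
    tr_on[k] = as<std::vector<double> >(train_onsets[k]);
    tr_tg[k] = as<std::vector<int> >(train_targets[k]);
  }
  std::vector<int> tr_ptr(ntrain, -1);  // index of last onset <= t
  std::vector<double> glut_on = as<std::vector<double> >(glut_onsets);
  int glut_ptr = -1;
  double glut_norm = 1.0;
  if (glut_on.size() > 0) {
    double tp = std::log(glut_tau_d / glut_tau_r) * glut_tau_r * glut_tau_d /
      (glut_tau_d - glut_tau_r);
    glut_norm = std::exp(-tp / glut_tau_d) - std::exp(-tp / glut_tau_r);
  }

  const int nclamp = clamp_comp.size();
  std::vector<bool> clamped(n, false);
  for (int j = 0; j < nclamp; ++j) clamped[clamp_comp[j]] = true;

  // children lists for clamp-current bookkeeping
  std::vector<std::vector<int> > children(n);
  for (int i = 1; i < n; ++i) children[parent[i]].push_back(i);

  // ---- recording -----------------------------------------------------------
  const int nrec = nsteps / stride + 1;
  NumericMatrix rec_v(nrec, n), rec_ecl(nrec, n), rec_egaba(nrec, n),
    rec_igcl(nrec, n), rec_ighco3(nrec, n), rec_ikcc2(nrec, n);
  std::vector<NumericMatrix> rec_conc;
  for (int j = 0; j < 8; ++j) rec_conc.push_back(NumericMatrix(nrec, n));
  NumericMatrix rec_clamp(nrec, std::max(nclamp, 1));
  NumericVector rec_t(nrec);
  NumericMatrix charge(n, 5);  // cumulative I*dt per ion (mA ms / cm2)
  std::vector<double> spike_t;
  std::vector<int> spike_c;
  std::vector<double> last_spike(n, -1e9);

  std::vector<double> Ana(n), Bna(n), Ak(n), Bk(n), Acl(n), Bcl(n),
    Aca(n), Bca(n), Ah(n), Bh(n);
  std::vector<double> diag(n), rhs(n), vnew(n), iinj(n);
  std::vector<double> ligand(n), gglut(n);
  std::vector<double> e_na(n), e_k(n), e_cl(n), e_ca(n);
  std::vector<double> i_kcc2v(n), i_nkcc1v(n);

  const bool have_noise = noise_comp.size() > 0;
  GetRNGstate();

  int irec = 0;
  // record a sample from the current state (currents from state occupancies)
  auto record = [&](double tnow) {
    rec_t[irec] = tnow;
    for (int i = 0; i < n; ++i) {
      rec_v(irec, i) = v[i];
      for (int j = 0; j < 8; ++j) rec_conc[j](irec, i) = conc[j * n + i];
      double ecl = -rtf * std::log(conc[6 * n + i] / conc[2 * n + i]);
      rec_ecl(irec, i) = ecl;
      rec_egaba(irec, i) = (1 - hco3_frac) * ecl + hco3_frac * e_hco3;
      double gg = gaba_gbar[i] * gaba_scale[i] * gab[3 * n + i];
      rec_igcl(irec, i) = (1 - hco3_frac) * gg * (v[i] - ecl);
      rec_ighco3(irec, i) = hco3_frac * gg * (v[i] - e_hco3);
      double ko = kcc2_frozen ? k_o_rest : conc[5 * n + i];
      double num = conc[1 * n + i] * conc[2 * n + i] - ko * conc[6 * n + i];
      double den = (conc[1 * n + i] + kcc2_km_k) * (conc[2 * n + i] + kcc2_km_cl) +
        (ko + kcc2_km_k) * (conc[6 * n + i] + kcc2_km_cl);
      rec_ikcc2(irec, i) = kcc2_U[i] * kcc2_scale * num / den;
    }
    ++irec;
  };
  record(0.0);

  for (int step = 0; step < nsteps; ++step) {
    const double tnow = step * dt;
    const double tnew = tnow + dt;

    // ---- stimuli ----
    std::fill(ligand.begin(), ligand.end(), 0.0);
    for (int k = 0; k < ntrain; ++k) {
      while (tr_ptr[k] + 1 < (int)tr_on[k].size() &&
             tr_on[k][tr_ptr[k] + 1] <= tnew) ++tr_ptr[k];
      if (tr_ptr[k] < 0) continue;
      double dtau = tnew - tr_on[k][tr_ptr[k]];
      double c = (dtau <= train_sq[k]) ? train_peak[k]
        : train_peak[k] * std::exp(-(dtau - train_sq[k]) / train_tau[k]);
      if (c < 1e-12) continue;
      for (size_t m = 0; m < tr_tg[k].size(); ++m) ligand[tr_tg[k][m]] += c;
    }
    double gglut_now = 0.0;
    if (glut_on.size() > 0) {
      while (glut_ptr + 1 < (int)glut_on.size() &&
             glut_on[glut_ptr + 1] <= tnew) ++glut_ptr;
      for (int q = glut_ptr; q >= 0; --q) {
        double dtau = tnew - glut_on[q];
        if (dtau > 10.0 * glut_tau_d) break;
        gglut_now += (std::exp(-dtau / glut_tau_d) -
                      std::exp(-dtau / glut_tau_r)) / glut_norm;
      }
      gglut_now *= glut_gmax;  // S (absolute), applied per target compartment
    }
    std::fill(iinj.begin(), iinj.end(), 0.0);
    for (int k = 0; k < inj_comp.size(); ++k) {
      if (tnow >= inj_t0[k] && tnow < inj_t1[k]) iinj[inj_comp[k]] += inj_amp[k];
    }
    if (have_noise) {
      for (int k = 0; k < noise_comp.size(); ++k) {
        iinj[noise_comp[k]] += noise_mean[k] + noise_sd[k] * norm_rand();
      }
    }

    // ---- (1) explicit gate updates at old voltage ----
    for (int k = 0; k < ngate; ++k) {
      const double vh = gate_pars(k, 0), sl = gate_pars(k, 1),
        tb = gate_pars(k, 2), ta = gate_pars(k, 3), tv = gate_pars(k, 4),
        s1 = gate_pars(k, 5), s2 = gate_pars(k, 6);
      double* x = &gates[k * n];
      for (int i = 0; i < n; ++i) {
        double xinf = 1.0 / (1.0 + std::exp(-(v[i] - vh) / sl));
        double tau = tb + ta / (std::exp((v[i] - tv) / s1) +
                                std::exp(-(v[i] - tv) / s2));
        double xn = x[i] + dt * (xinf - x[i]) / tau;
        x[i] = xn < 0.0 ? 0.0 : (xn > 1.0 ? 1.0 : xn);
      }
    }
    // NKCC1 carrier update, then cycle flux with the updated split
    for (int i = 0; i < n; ++i) {
      double lo = (conc[4 * n + i] / nk_km_na) * (conc[5 * n + i] / nk_km_k) *
        (conc[6 * n + i] / nk_km_cl) * (conc[6 * n + i] / nk_km_cl);
      double p_o = lo / (1.0 + lo);
      double li = (conc[0 * n + i] / nk_km_na) * (conc[1 * n + i] / nk_km_k) *
        (conc[2 * n + i] / nk_km_cl) * (conc[2 * n + i] / nk_km_cl);
      double p_i = li / (1.0 + li);
      double dy = (1.0 - y[i]) * (nk_kt * p_i + nk_ke * (1.0 - p_i)) -
        y[i] * (nk_kt * p_o + nk_ke * (1.0 - p_o));
      double yn = y[i] + dt * dy;
      y[i] = yn < 0.0 ? 0.0 : (yn > 1.0 ? 1.0 : yn);
      i_nkcc1v[i] = nkcc1_U[i] *
        (y[i] * nk_kt * p_o - (1.0 - y[i]) * nk_kt * p_i);
    }

    // ---- (2) implicit Markov updates ----
    {
      double pbuf[6];
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < 5; ++j) pbuf[j] = na5[j * n + i];
        markov_step(na5s, pbuf, v[i], 0.0, dt);
        for (int j = 0; j < 5; ++j) na5[j * n + i] = pbuf[j];
        for (int j = 0; j < 6; ++j) pbuf[j] = na6[j * n + i];
        markov_step(na6s, pbuf, v[i], 0.0, dt);
        for (int j = 0; j < 6; ++j) na6[j * n + i] = pbuf[j];
        if (!(ligand[i] <= 0.0 && gab[0 * n + i] >= 1.0 - 1e-14)) {
          for (int j = 0; j < 6; ++j) pbuf[j] = gab[j * n + i];
          markov_step(gabas, pbuf, v[i], ligand[i], dt);
          for (int j = 0; j < 6; ++j) gab[j * n + i] = pbuf[j];
        }
      }
    }

    // ---- (3) assemble per-ion linear currents and solve for voltage ----
    for (int i = 0; i < n; ++i) {
      e_na[i] = rtf * std::log(conc[4 * n + i] / conc[0 * n + i]);
      e_k[i] = rtf * std::log(conc[5 * n + i] / conc[1 * n + i]);
      e_cl[i] = -rtf * std::log(conc[6 * n + i] / conc[2 * n + i]);
      e_ca[i] = 0.5 * rtf * std::log(conc[7 * n + i] / conc[3 * n + i]);
      Ana[i] = Bna[i] = Ak[i] = Bk[i] = Acl[i] = Bcl[i] = 0.0;
      Aca[i] = Bca[i] = Ah[i] = Bh[i] = 0.0;
    }
    for (int c = 0; c < nchan; ++c) {
      for (int i = 0; i < n; ++i) {
        double open = 1.0;
        for (int k = 0; k < ngate; ++k) {
          if (gate_chan[k] != c) continue;
          double xg = gates[k * n + i];
          int e = (int)gate_exp[k];
          for (int q = 0; q < e; ++q) open *= xg;
        }
        double gch = hh_g(i, c) * open;
        if (gch == 0.0) continue;
        switch (chan_ion[c]) {
        case 0: Ana[i] += gch; Bna[i] -= gch * e_na[i]; break;
        case 1: Ak[i] += gch; Bk[i] -= gch * e_k[i]; break;
        case 2: Aca[i] += gch; Bca[i] -= gch * e_ca[i]; break;
        default: {
          double f = chan_nafrac[c], eh = chan_erev[c];
          Ana[i] += f * gch; Bna[i] -= f * gch * eh;
          Ak[i] += (1 - f) * gch; Bk[i] -= (1 - f) * gch * eh;
        }
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double o5 = na5[3 * n + i], o6 = na6[3 * n + i];
      double gna = na_scale * na_gbar[i] *
        ((1.0 - na_fraction[i]) * o5 + na_fraction[i] * o6);
      Ana[i] += gna; Bna[i] -= gna * e_na[i];
      double gg = gaba_gbar[i] * gaba_scale[i] * gab[3 * n + i];
      Acl[i] += (1 - hco3_frac) * gg;
      Bcl[i] -= (1 - hco3_frac) * gg * e_cl[i];
      Ah[i] += hco3_frac * gg;
      Bh[i] -= hco3_frac * gg * e_hco3;
      Ana[i] += gleak_na[i]; Bna[i] -= gleak_na[i] * e_na[i];
      Ak[i] += gleak_k[i]; Bk[i] -= gleak_k[i] * e_k[i];
      Acl[i] += gleak_cl[i]; Bcl[i] -= gleak_cl[i] * e_cl[i];
      // glutamate-like conductance (E = 0 mV, split between Na and K)
      bool isglut = false;
      for (int k = 0; k < glut_comp.size(); ++k)
        if (glut_comp[k] == i) { isglut = true; break; }
      if (isglut && gglut_now > 0.0) {
        double gd = gglut_now / area[i];  // S -> S/cm2
        Ana[i] += 0.5 * gd; Ak[i] += 0.5 * gd;
      }
      // Na/K pump
      double kmna = 1.0 + nak_km_na / conc[0 * n + i];
      double kmk = 1.0 + nak_km_k / conc[5 * n + i];
      double ipump = nak_imax[i] / (kmna * kmna * kmna * kmk * kmk);
      Bna[i] += 3.0 * ipump; Bk[i] -= 2.0 * ipump;
      // KCC2
      double ko = kcc2_frozen ? k_o_rest : conc[5 * n + i];
      double num = conc[1 * n + i] * conc[2 * n + i] - ko * conc[6 * n + i];
      double den = (conc[1 * n + i] + kcc2_km_k) *
        (conc[2 * n + i] + kcc2_km_cl) +
        (ko + kcc2_km_k) * (conc[6 * n + i] + kcc2_km_cl);
      double ikcc2 = kcc2_U[i] * kcc2_scale * num / den;
      i_kcc2v[i] = ikcc2;
      Bk[i] += ikcc2; Bcl[i] -= ikcc2;
      // NKCC1 stoichiometric currents
      Bna[i] += -0.5 * i_nkcc1v[i];
      Bk[i] += -0.5 * i_nkcc1v[i];
      Bcl[i] += i_nkcc1v[i];
      // Na/Ca exchanger and calcium pump (explicit in voltage)
      double ef = std::exp(nx_gamma * v[i] / rtf);
      double er = std::exp(-(1.0 - nx_gamma) * v[i] / rtf);
      double nai = conc[0 * n + i], nao = conc[4 * n + i];
      double cai = conc[3 * n + i], cao = conc[7 * n + i];
      double ix = nacax_scale[i] *
        (nai * nai * nai * cao * ef - nao * nao * nao * cai * er) /
        ((nx_km_na * nx_km_na * nx_km_na + nao * nao * nao) *
         (nx_km_ca + cao) * (1.0 + nx_ksat * er));
      double icap = capump_imax[i] * cai / (cai + capump_km);
      Bna[i] += 3.0 * ix;
      Bca[i] += -2.0 * ix + icap;
    }

    // voltage system
    for (int i = 0; i < n; ++i) {
      double Atot = Ana[i] + Ak[i] + Acl[i] + Aca[i] + Ah[i];
      double Btot = Bna[i] + Bk[i] + Bcl[i] + Bca[i] + Bh[i];
      double ci = cm * area[i] * 1e-3;
      diag[i] = ci / dt + area[i] * Atot;
      rhs[i] = ci / dt * v[i] - area[i] * Btot + iinj[i];
    }
    for (int i = 1; i < n; ++i) {
      diag[i] += g_ax[i];
      diag[parent[i]] += g_ax[i];
    }
    // clamp command values
    for (int j = 0; j < nclamp; ++j) {
      int i = clamp_comp[j];
      double cmd = clamp_vals[0];
      for (int q = 0; q < clamp_times.size(); ++q)
        if (clamp_times[q] <= tnow) cmd = clamp_vals[q];
      vnew[i] = cmd;
    }
    // Hines elimination (children have larger indices than parents)
    for (int i = n - 1; i >= 1; --i) {
      if (clamped[i]) continue;
      int p = parent[i];
      if (clamped[p]) { rhs[i] += g_ax[i] * vnew[p]; continue; }
      double f = g_ax[i] / diag[i];
      diag[p] -= g_ax[i] * f;
      rhs[p] += rhs[i] * f;
    }
    if (!clamped[0]) vnew[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      if (clamped[i]) continue;
      int p = parent[i];
      if (clamped[p]) vnew[i] = rhs[i] / diag[i];
      else vnew[i] = (rhs[i] + g_ax[i] * vnew[p]) / diag[i];
    }
    for (int i = 0; i < n; ++i) {
      if (!R_finite(vnew[i]))
        stop("voltage became non-finite at t=%f ms in compartment %d",
             tnew, i + 1);
    }

    // clamp (electrode) current, in mA
    double clamp_now[64];
    for (int j = 0; j < nclamp && j < 64; ++j) {
      int i = clamp_comp[j];
      double Atot = Ana[i] + Ak[i] + Acl[i] + Aca[i] + Ah[i];
      double Btot = Bna[i] + Bk[i] + Bcl[i] + Bca[i] + Bh[i];
      double ci = cm * area[i] * 1e-3;
      double iax = 0.0;
      if (parent[i] >= 0) iax += g_ax[i] * (vnew[parent[i]] - vnew[i]);
      for (size_t q = 0; q < children[i].size(); ++q) {
        int ch = children[i][q];
        iax += g_ax[ch] * (vnew[ch] - vnew[i]);
      }
      clamp_now[j] = ci * (vnew[i] - v[i]) / dt +
        area[i] * (Atot * vnew[i] + Btot) - iax - iinj[i];
    }

    // ---- (4) concentrations from per-ion currents at the new voltage ----
    if (conc_dyn) {
      for (int i = 0; i < n; ++i) {
        double I[4];
        I[0] = Ana[i] * vnew[i] + Bna[i];
        I[1] = Ak[i] * vnew[i] + Bk[i];
        I[2] = Acl[i] * vnew[i] + Bcl[i];
        I[3] = Aca[i] * vnew[i] + Bca[i];
        double Ih = Ah[i] * vnew[i] + Bh[i];
        charge(i, 0) += I[0] * dt; charge(i, 1) += I[1] * dt;
        charge(i, 2) += I[2] * dt; charge(i, 3) += I[3] * dt;
        charge(i, 4) += Ih * dt;
        static const double zval[4] = {1.0, 1.0, -1.0, 2.0};
        for (int j = 0; j < 4; ++j) {
          double dmol = -I[j] * area[i] * dt / (zval[j] * FARADAY_C);
          conc[j * n + i] += dmol / vol_i[i];
          conc[(j + 4) * n + i] -= dmol / vol_o[i];
          if (conc[j * n + i] <= 0.0 || conc[(j + 4) * n + i] <= 0.0)
            stop("homeostasis failure: ion %d driven non-positive in compartment %d at t=%f",
                 j + 1, i + 1, tnew);
        }
      }
      if (buffer_on) {
        for (int i = 0; i < n; ++i) {
          double free = buf_total - kb[i];
          double dkb = (buf_kf * conc[5 * n + i] * free - buf_kb * kb[i]) * dt;
          if (dkb < -kb[i]) dkb = -kb[i];
          if (dkb > free) dkb = free;
          conc[5 * n + i] -= dkb;
          kb[i] += dkb;
        }
      }
      if (diffusion_on) {
        for (int i = 1; i < n; ++i) {
          int p = parent[i];
          for (int j = 0; j < 4; ++j) {
            double f = d_ion[j] * surf_i[i] *
              (conc[j * n + p] - conc[j * n + i]) / ddist[i] * dt;
            conc[j * n + i] += f / vol_i[i];
            conc[j * n + p] -= f / vol_i[p];
            int jo = j + 4;
            f = d_ion[j] * surf_o[i] *
              (conc[jo * n + p] - conc[jo * n + i]) / ddist[i] * dt;
            conc[jo * n + i] += f / vol_o[i];
            conc[jo * n + p] -= f / vol_o[p];
          }
        }
      }
      if (k_mode == 1) {
        for (int i = 0; i < n; ++i) conc[5 * n + i] = k_o_rest;
      } else if (k_mode == 2) {
        double kval = k_vals[0];
        if (k_times.size() > 1) {
          if (tnew >= k_times[k_times.size() - 1])
            kval = k_vals[k_vals.size() - 1];
          else {
            for (int q = 0; q + 1 < k_times.size(); ++q) {
              if (tnew >= k_times[q] && tnew < k_times[q + 1]) {
                double w = (tnew - k_times[q]) / (k_times[q + 1] - k_times[q]);
                kval = k_vals[q] * (1 - w) + k_vals[q + 1] * w;
                break;
              }
            }
          }
        }
        for (int i = 0; i < n; ++i) conc[5 * n + i] = kval;
      }
    }

    // spikes: upward 0 mV crossing with 2 ms refractory
    for (int i = 0; i < n; ++i) {
      if (v[i] < 0.0 && vnew[i] >= 0.0 && tnew - last_spike[i] > 2.0) {
        last_spike[i] = tnew;
        spike_t.push_back(tnew);
        spike_c.push_back(i);
      }
      v[i] = vnew[i];
    }

    if ((step + 1) % stride == 0 && irec < nrec) {
      record(tnew);
      if (nclamp > 0)
        for (int j = 0; j < nclamp && j < 64; ++j)
          rec_clamp(irec - 1, j) = clamp_now[j] * 1e6;  // mA -> nA
      if ((step % 2000) == 0) Rcpp::checkUserInterrupt();
    }
  }
  PutRNGstate();

  // ---- pack results --------------------------------------------------------
  NumericMatrix conc_out(n, 8), gates_out(n, ngate), na5_out(n, 5),
    na6_out(n, 6), gab_out(n, 6);
  std::copy(conc.begin(), conc.end(), conc_out.begin());
  std::copy(gates.begin(), gates.end(), gates_out.begin());
  std::copy(na5.begin(), na5.end(), na5_out.begin());
  std::copy(na6.begin(), na6.end(), na6_out.begin());
  std::copy(gab.begin(), gab.end(), gab_out.begin());
  List conc_rec(8);
  for (int j = 0; j < 8; ++j) conc_rec[j] = rec_conc[j];
  return List::create(
    _["t"] = rec_t, _["v"] = rec_v, _["conc"] = conc_rec,
    _["e_cl"] = rec_ecl, _["e_gaba"] = rec_egaba,
    _["i_gaba_cl"] = rec_igcl, _["i_gaba_hco3"] = rec_ighco3,
    _["i_kcc2"] = rec_ikcc2, _["clamp_i"] = rec_clamp,
    _["spike_t"] = wrap(spike_t), _["spike_comp"] = wrap(spike_c),
    _["charge"] = charge,
    _["final_state"] = List::create(
      _["v"] = wrap(v), _["conc"] = conc_out, _["gates"] = gates_out,
      _["na5"] = na5_out, _["na6"] = na6_out, _["gaba"] = gab_out,
      _["y"] = wrap(y), _["kb"] = wrap(kb))
  );
}
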