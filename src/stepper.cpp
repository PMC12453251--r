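// IMEX time stepper for the cartilage reaction-diffusion system.
// Diffusion is integrated implicitly (backward Euler, tridiagonal solves
// with ghost-node boundary rows); reactions explicitly. Column order of the
// state matrix: C, Cs, Ch, Cc, MP, L2, D.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Prefactored tridiagonal solver for M = I - dt*delta*L, L the discrete
// Laplacian with either zero-flux (cell) or Robin (protein/drug) rows.
struct DiffSolve {
  int n = 0;
  bool active = false;
  std::vector<double> sub, cp, m; // subdiagonal, modified super, inv pivots

  void init(int n_, double dt, double delta, double dx, bool robin,
            double alpha) {
    n = n_;
    active = delta > 0.0;
    if (!active) return;
    const double r = dt * delta / (dx * dx);
    std::vector<double> a(n, 0.0), b(n, 0.0), c(n, 0.0);
    for (int i = 1; i < n - 1; ++i) {
      a[i] = -r; b[i] = 1.0 + 2.0 * r; c[i] = -r;
    }
    const double bedge = robin ? 1.0 + r * (2.0 + 2.0 * dx * alpha)
                               : 1.0 + 2.0 * r;
    b[0] = bedge;      c[0] = -2.0 * r;
    b[n - 1] = bedge;  a[n - 1] = -2.0 * r;
    sub = a;
    cp.assign(n, 0.0);
    m.assign(n, 0.0);
    m[0] = 1.0 / b[0];
    cp[0] = c[0] * m[0];
    for (int i = 1; i < n; ++i) {
      m[i] = 1.0 / (b[i] - a[i] * cp[i - 1]);
      if (i < n - 1) cp[i] = c[i] * m[i];
    }
  }

  void solve(std::vector<double>& d) const {
    if (!active) return;
    d[0] *= m[0];
    for (int i = 1; i < n; ++i) d[i] = (d[i] - sub[i] * d[i - 1]) * m[i];
    for (int i = n - 2; i >= 0; --i) d[i] -= cp[i] * d[i + 1];
  }
};

double trap_mean(const std::vector<double>& v) {
  const int n = (int)v.size();
  double s = 0.5 * (v[0] + v[n - 1]);
  for (int i = 1; i < n - 1; ++i) s += v[i];
  return s / (n - 1);
}

} // namespace

// [[Rcpp::export(name = ".oa_step_core")]]
List oa_step_core(NumericMatrix init, List par, double dx, double dt,
                  int n_steps, int rec_every, NumericMatrix u2_iv,
                  NumericVector d_days) {
  const int n = init.nrow();
  if (init.ncol() != 7) stop("init must have 7 columns");
  auto P = [&](const char* k) { return as<double>(par[k]); };

  const double A = P("A"), lCCs = P("lambda_CCs"), lCCh = P("lambda_CCh"),
               lChCc = P("lambda_ChCc"), lCsMP = P("lambda_CsMP"),
               lCL2 = P("lambda_CL2"), muC = P("mu_C"), muCs0 = P("mu_Cs0"),
               muCh = P("mu_Ch"), muMP = P("mu_MP"), muL2 = P("mu_L2"),
               muL2MP = P("mu_L2MP"), muMPL2 = P("mu_MPL2"),
               muDCs = P("mu_DCs"), muCsD = P("mu_CsD"), dC = P("delta_C"),
               dMP = P("delta_MP"), dL2 = P("delta_L2"), dD = P("delta_D"),
               KL2 = P("K_L2"), aD = P("alpha_D"), aU2 = P("alpha_U2"),
               awMP = P("alpha_w_MP"), awL2 = P("alpha_w_L2"),
               TwMP = P("T_w_MP"), TwL2 = P("T_w_L2"), gD = P("gamma_D"),
               gU2 = P("gamma_U2"), muD = P("mu_D"), omD = P("omega_D"),
               alpha = P("bc_leak_alpha"), dpy = P("days_per_year");
  const bool female = as<int>(par["female"]) != 0;
  const bool mucs_dec = as<int>(par["mu_cs_decreasing"]) != 0;
  const bool cc_clamp = as<int>(par["cc_clamp"]) != 0;
  const double chdiv = as<double>(par["ch_div"]); // 1 or 1 + lambda_ChCc

  DiffSolve sC, sCs, sCh, sMP, sL2, sD;
  sC.init(n, dt, dC, dx, false, 0.0);
  sCs.init(n, dt, dC, dx, false, 0.0);
  sCh.init(n, dt, dC / chdiv, dx, false, 0.0);
  sMP.init(n, dt, dMP, dx, true, alpha);
  sL2.init(n, dt, dL2, dx, true, alpha);
  sD.init(n, dt, dD, dx, true, alpha);

  std::vector<double> C(n), Cs(n), Ch(n), Cc(n), MP(n), L2(n), D(n);
  for (int i = 0; i < n; ++i) {
    C[i] = init(i, 0); Cs[i] = init(i, 1); Ch[i] = init(i, 2);
    Cc[i] = init(i, 3); MP[i] = init(i, 4); L2[i] = init(i, 5);
    D[i] = init(i, 6);
  }
  std::vector<double> Chold(n), w(n);

  const int n_rec = n_steps / rec_every + 1;
  NumericVector times(n_rec);
  NumericMatrix avg(n_rec, 7);
  NumericVector prof(Dimension(n, 7, n_rec));
  NumericVector clip_max(7);

  auto record = [&](int slot, double t) {
    times[slot] = t;
    const std::vector<double>* sp[7] = {&C, &Cs, &Ch, &Cc, &MP, &L2, &D};
    for (int s = 0; s < 7; ++s) {
      avg(slot, s) = trap_mean(*sp[s]);
      for (int i = 0; i < n; ++i) prof[i + n * s + n * 7 * slot] = (*sp[s])[i];
    }
  };
  record(0, 0.0);

  // drug-input bookkeeping
  const int n_iv = u2_iv.nrow();
  int iv_idx = 0;
  const int n_dd = d_days.size();
  int dd_idx = 0;
  double hd = 0.0;
  const double hd_decay = std::exp(-muD * dt);
  // exact mean of the exponential impulse input over one step, so the
  // integrated drug dose is independent of dt
  const double hd_step_avg = (1.0 - hd_decay) / (muD * dt);

  auto clipv = [&](std::vector<double>& v, int s) {
    for (int i = 0; i < n; ++i)
      if (v[i] < 0.0) {
        if (-v[i] > clip_max[s]) clip_max[s] = -v[i];
        v[i] = 0.0;
      }
  };

  int slot = 1;
  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;

    // UC-II indicator over [start, end) intervals (sorted, disjoint)
    while (iv_idx < n_iv && t >= u2_iv(iv_idx, 1)) ++iv_idx;
    const double hu2 =
        (iv_idx < n_iv && t >= u2_iv(iv_idx, 0) && t < u2_iv(iv_idx, 1))
            ? 1.0 : 0.0;
    // fisetin impulse superposition, advanced by exact exponential decay
    if (k > 0) hd *= hd_decay;
    while (dd_idx < n_dd && d_days[dd_idx] <= t) {
      hd += std::exp(-muD * (t - d_days[dd_idx]));
      ++dd_idx;
    }
    const double u2_src = aU2 * gU2 * hu2;
    const double d_src = gD * hd * hd_step_avg;

    const double ty = t / dpy;
    const double muCs =
        mucs_dec ? muCs0 / (1.0 + ty / 90.0) : muCs0 * (1.0 + ty / 90.0);
    const double dpMP = female ? awMP / (1.0 + ty * ty / (TwMP * TwMP)) : 0.0;
    const double dpL2 = female ? awL2 / (1.0 + ty * ty / (TwL2 * TwL2)) : 0.0;

    // production-destruction split, semi-implicit in each species' own
    // loss terms: X <- (X + dt*P) / (1 + dt*Lambda). First-order accurate,
    // unconditionally stable and positivity-preserving for the stiff
    // protein kinetics; couplings are evaluated at the step start.
    Chold = Ch;
    for (int i = 0; i < n; ++i) {
      const double block = 1.0 / (1.0 + L2[i] / KL2);
      const double hyp_rate = lCCh * block;           // per unit C
      const double Cn =
          (C[i] + dt * A) / (1.0 + dt * (lCCs + hyp_rate + muC));
      const double Csn = (Cs[i] + dt * lCCs * C[i]) /
                         (1.0 + dt * (muCs + muCsD * D[i]));
      const double Chn = (Ch[i] + dt * hyp_rate * C[i] / chdiv) /
                         (1.0 + dt * muCh / chdiv);
      const double MPn =
          (MP[i] + dt * (lCsMP * Cs[i] / (1.0 + aD * D[i]) + dpMP * MP[i])) /
          (1.0 + dt * (muL2MP * L2[i] + muMP));
      const double L2n = (L2[i] + dt * (u2_src + lCL2 * C[i])) /
                         (1.0 + dt * (muMPL2 * MP[i] + muL2 + dpL2));
      const double Dn =
          (D[i] + dt * d_src) / (1.0 + dt * (muDCs * Cs[i] + omD));
      C[i] = Cn; Cs[i] = Csn; Ch[i] = Chn; MP[i] = MPn; L2[i] = L2n;
      D[i] = Dn;
    }
    sC.solve(C); sCs.solve(Cs); sCh.solve(Ch);
    sMP.solve(MP); sL2.solve(L2); sD.solve(D);
    clipv(C, 0); clipv(Cs, 1); clipv(Ch, 2);
    clipv(MP, 4); clipv(L2, 5); clipv(D, 6);
    // discrete calcification bookkeeping: Cc gains lambda_ChCc * dCh
    for (int i = 0; i < n; ++i) {
      double dCh = Ch[i] - Chold[i];
      if (cc_clamp && dCh < 0.0) dCh = 0.0;
      Cc[i] += lChCc * dCh;
    }
    clipv(Cc, 3);

    if ((k + 1) % rec_every == 0) record(slot++, (k + 1) * dt);
  }

  return List::create(_["times"] = times, _["averages"] = avg,
                      _["profiles"] = prof, _["clip_max"] = clip_max);
}
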