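#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Single-cell replication mechanics over an origin triplet.
//
// Time is measured in replicated base pairs (rbp): forks move at 1 bp per
// time unit. A licenced origin i with potential firing time t[i] is obscured
// iff a fork launched from an already-fired origin j reaches x[i] strictly
// before (ties count as obscured) t[i]; forks are blocked by collisions, which
// for three origins reduces to: a fork from j cannot pass a fired origin lying
// strictly between j and its target. Processing licenced origins in firing-time
// order makes this exact (a fired origin beat every incoming fork by
// definition, so the fired set at time t[i] is already complete).
// ---------------------------------------------------------------------------

// returns true if the cell is in a prohibited (double-overrun / empty) state
static bool resolve3(const int* lic, const double* t, const double* x,
                     int* fired, int* obsc) {
  int ord[3], nl = 0;
  for (int i = 0; i < 3; ++i) {
    fired[i] = 0; obsc[i] = 0;
    if (lic[i]) ord[nl++] = i;
  }
  if (nl == 0) return true;
  for (int a = 1; a < nl; ++a)
    for (int b = a; b > 0 && t[ord[b]] < t[ord[b - 1]]; --b)
      std::swap(ord[b], ord[b - 1]);
  for (int a = 0; a < nl; ++a) {
    int i = ord[a];
    double best = R_PosInf; int bestj = -1;
    for (int j = 0; j < 3; ++j) {
      if (!fired[j]) continue;
      bool blocked = false;
      for (int k = 0; k < 3; ++k)
        if (fired[k] && (x[k] - x[i]) * (x[k] - x[j]) < 0.0) { blocked = true; break; }
      if (blocked) continue;
      double arr = t[j] + std::fabs(x[i] - x[j]);
      if (arr < best) { best = arr; bestj = j; }
    }
    if (bestj >= 0 && best <= t[i]) obsc[i] = bestj + 1;
    else fired[i] = 1;
  }
  int nf = fired[0] + fired[1] + fired[2];
  if (nf == 0) return true;
  if (nf == 1 && (fired[0] || fired[2])) return true;
  return false;
}

// single-cell profile value at position xm: 1 iff replicated by a
// rightward-moving fork. The first fork to arrive wins; at a collision point
// (tied arrivals) the position belongs to the leftward-moving fork, matching
// the half-open convention [origin, collision).
static inline int prof_at(const int* fired, const double* t, const double* x,
                          double xm) {
  double bl = R_PosInf, br = R_PosInf;
  for (int i = 0; i < 3; ++i) {
    if (!fired[i]) continue;
    double arr = t[i] + std::fabs(xm - x[i]);
    if (x[i] <= xm) { if (arr < bl) bl = arr; }
    else            { if (arr < br) br = arr; }
  }
  return (bl < br) ? 1 : 0;
}

// [[Rcpp::export]]
List cpp_resolve_cell(IntegerVector lic, NumericVector t, NumericVector x) {
  int l[3]; double tt[3]; int f[3], o[3];
  for (int i = 0; i < 3; ++i) { l[i] = lic[i]; tt[i] = t[i]; }
  bool bad = resolve3(l, tt, &x[0], f, o);
  return List::create(_["realized"] = IntegerVector(f, f + 3),
                      _["obscured_by"] = IntegerVector(o, o + 3),
                      _["prohibited"] = bad);
}

// [[Rcpp::export]]
List cpp_simulate_cells(NumericVector mu, NumericVector sigma, NumericVector q,
                        NumericVector x, int n, int max_resample) {
  IntegerMatrix lic(n, 3), fired(n, 3), obsc(n, 3);
  NumericMatrix tms(n, 3);
  IntegerVector attempts(n);
  int l[3], f[3], o[3]; double t[3];
  for (int c = 0; c < n; ++c) {
    int a = 0; bool bad = true;
    while (bad) {
      if (++a > max_resample)
        stop("cell resampling exceeded max_resample: the parameter regime is "
             "almost surely degenerate (admissible states have negligible "
             "probability, e.g. only one end origin can ever fire)");
      for (int i = 0; i < 3; ++i) {
        l[i] = (unif_rand() < q[i]) ? 1 : 0;
        t[i] = l[i] ? (mu[i] + sigma[i] * norm_rand()) : R_PosInf;
      }
      bad = resolve3(l, t, &x[0], f, o);
    }
    attempts[c] = a;
    for (int i = 0; i < 3; ++i) {
      lic(c, i) = l[i];
      tms(c, i) = l[i] ? t[i] : NA_REAL;
      fired(c, i) = f[i];
      obsc(c, i) = o[i];
    }
  }
  return List::create(_["licenced"] = lic, _["times"] = tms,
                      _["realized"] = fired, _["obscured_by"] = obsc,
                      _["attempts"] = attempts);
}

// [[Rcpp::export]]
IntegerMatrix cpp_cell_profiles(NumericMatrix tms, IntegerMatrix fired,
                                NumericVector x, NumericVector box_mid) {
  int n = tms.nrow(), nb = box_mid.size();
  IntegerMatrix out(n, nb);
  int f[3]; double t[3];
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < 3; ++i) {
      f[i] = fired(c, i);
      t[i] = f[i] ? tms(c, i) : R_PosInf;
    }
    for (int j = 0; j < nb; ++j) out(c, j) = prof_at(f, t, &x[0], box_mid[j]);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_profile_tally(NumericMatrix tms, IntegerMatrix fired,
                                NumericVector x, NumericVector box_mid) {
  int n = tms.nrow(), nb = box_mid.size();
  IntegerVector tally(nb);
  int f[3]; double t[3];
  for (int c = 0; c < n; ++c) {
    for (int i = 0; i < 3; ++i) {
      f[i] = fired(c, i);
      t[i] = f[i] ? tms(c, i) : R_PosInf;
    }
    for (int j = 0; j < nb; ++j) tally[j] += prof_at(f, t, &x[0], box_mid[j]);
  }
  return tally;
}

// Collision points of positionally adjacent realized origins (no realized
// origin in between): x_ij = (x_i + x_j + t_j - t_i) / 2. Up to two per cell;
// pair codes 12, 23, 13. NA-padded.
// [[Rcpp::export]]
List cpp_collisions(NumericMatrix tms, IntegerMatrix fired, NumericVector x) {
  int n = tms.nrow();
  NumericMatrix pos(n, 2);
  IntegerMatrix pair(n, 2);
  std::fill(pos.begin(), pos.end(), NA_REAL);
  std::fill(pair.begin(), pair.end(), NA_INTEGER);
  for (int c = 0; c < n; ++c) {
    int idx[3], nf = 0;
    for (int i = 0; i < 3; ++i) if (fired(c, i)) idx[nf++] = i;
    int k = 0;
    for (int a = 0; a + 1 < nf; ++a) {
      int i = idx[a], j = idx[a + 1];
      pos(c, k) = 0.5 * (x[i] + x[j] + tms(c, j) - tms(c, i));
      pair(c, k) = (i + 1) * 10 + (j + 1);
      ++k;
    }
  }
  return List::create(_["pair"] = pair, _["position"] = pos);
}

// ---------------------------------------------------------------------------
// Reversible-jump MCMC chain over (mu, sigma, q, b, tau) and the latent
// population of M cells (licenced sets + firing times), targeting the
// log-normal likelihood of the boxed strand counts.
// ---------------------------------------------------------------------------

struct ChainWorkspace {
  int M, nb;
  std::vector<int> lic, fired, obsc;     // M x 3, row-major
  std::vector<double> tms;               // M x 3
  std::vector<signed char> prof;         // M x nb
  std::vector<int> tally;                // nb
};

// [[Rcpp::export]]
List cpp_run_chain(NumericVector cf, NumericVector cr,
                   NumericVector x, NumericVector box_mid,
                   List init, List priors, List control) {
  const int nb = cf.size();
  if (cr.size() != nb || box_mid.size() != nb)
    stop("count and box vectors must have equal length");

  // --- control ------------------------------------------------------------
  const int M           = as<int>(control["M"]);
  const int n_sweeps    = as<int>(control["n_sweeps"]);
  const int burn_in     = as<int>(control["burn_in"]);
  const int thin        = as<int>(control["thin"]);
  const double cellfrac = as<double>(control["cell_frac"]);
  const bool adapt      = as<bool>(control["adapt"]);
  const bool upd_times  = as<bool>(control["update_times"]);
  const bool recentre   = as<bool>(control["recentre"]);
  const int snap_every  = as<int>(control["snap_every"]);
  const int n_sub       = std::min(as<int>(control["n_sub"]), M);
  const int check_every = as<int>(control["check_every"]);
  LogicalVector s_mu    = control["sample_mu"];
  LogicalVector s_sig   = control["sample_sigma"];
  LogicalVector s_q     = control["sample_q"];
  LogicalVector upd_lic = control["update_lic"];
  const bool s_b        = as<bool>(control["sample_b"]);
  const bool s_tau      = as<bool>(control["sample_tau"]);
  NumericVector sc0     = control["scale_t"];
  double scale_t[3] = { sc0[0], sc0[1], sc0[2] };
  double scale_tau = as<double>(control["scale_tau"]);
  double scale_b   = as<double>(control["scale_b"]);
  double scale_s[3] = { 0.15, 0.15, 0.15 };  // log-scale sd of the sigma rescaling move
  double scale_m[3] = { sc0[0], sc0[1], sc0[2] };  // sd of the mu translation move

  // --- priors ---------------------------------------------------------------
  const double a_sig = as<double>(priors["a_sigma"]);
  const double b_sig = as<double>(priors["b_sigma"]);
  const double a_q   = as<double>(priors["a_q"]);
  const double b_q   = as<double>(priors["b_q"]);
  const double a_tau = as<double>(priors["a_tau"]);
  const double b_tau = as<double>(priors["b_tau"]);

  // --- parameter state ------------------------------------------------------
  NumericVector mu0 = init["mu"], sig0 = init["sigma"], q0 = init["q"];
  double mu[3]  = { mu0[0], mu0[1], mu0[2] };
  double sig[3] = { sig0[0], sig0[1], sig0[2] };
  double qv[3]  = { q0[0], q0[1], q0[2] };
  double b   = as<double>(init["b"]);
  double tau = as<double>(init["tau"]);

  // --- latent state ---------------------------------------------------------
  ChainWorkspace w;
  w.M = M; w.nb = nb;
  w.lic.assign(M * 3, 0); w.fired.assign(M * 3, 0); w.obsc.assign(M * 3, 0);
  w.tms.assign(M * 3, R_PosInf);
  w.prof.assign((size_t)M * nb, 0);
  w.tally.assign(nb, 0);
  {
    IntegerMatrix lic0 = init["licenced"];
    NumericMatrix tms0 = init["times"];
    if (lic0.nrow() != M || tms0.nrow() != M)
      stop("init latent state must have M rows");
    int f[3], o[3]; double t[3]; int l[3];
    for (int c = 0; c < M; ++c) {
      for (int i = 0; i < 3; ++i) {
        l[i] = lic0(c, i);
        t[i] = l[i] ? tms0(c, i) : R_PosInf;
        if (l[i] && !R_finite(t[i])) stop("licenced origin with non-finite time in init");
      }
      if (resolve3(l, t, &x[0], f, o)) stop("prohibited cell in init latent state");
      for (int i = 0; i < 3; ++i) {
        w.lic[c * 3 + i] = l[i];
        w.tms[c * 3 + i] = t[i];
        w.fired[c * 3 + i] = f[i];
        w.obsc[c * 3 + i] = o[i];
      }
      for (int j = 0; j < nb; ++j) {
        int v = prof_at(f, t, &x[0], box_mid[j]);
        w.prof[(size_t)c * nb + j] = (signed char)v;
        w.tally[j] += v;
      }
    }
  }

  // --- likelihood cache -----------------------------------------------------
  std::vector<double> lcf(nb), lcr(nb), llbox(nb), llbuf(nb);
  for (int j = 0; j < nb; ++j) {
    if (cf[j] <= 0.0 || cr[j] <= 0.0) stop("counts must be strictly positive (apply the zero floor first)");
    lcf[j] = std::log(cf[j]); lcr[j] = std::log(cr[j]);
  }
  auto box_ll = [&](int j, double F, double bb, double tt) -> double {
    double mf = (1.0 - bb) * F + 0.5 * bb;
    double mr = 1.0 - mf;
    double zf = lcf[j] - std::log(mf) + 0.5 / tt;
    double zr = lcr[j] - std::log(mr) + 0.5 / tt;
    return std::log(tt / (2.0 * M_PI)) - lcf[j] - lcr[j]
           - 0.5 * tt * (zf * zf + zr * zr);
  };
  double ll_total = 0.0;
  for (int j = 0; j < nb; ++j) {
    llbox[j] = box_ll(j, w.tally[j] / (double)M, b, tau);
    ll_total += llbox[j];
  }
  if (!R_finite(ll_total)) stop("non-finite initial log-likelihood");

  // --- output buffers -------------------------------------------------------
  const int n_keep = (n_sweeps > burn_in) ? (n_sweeps - burn_in) / thin : 0;
  NumericMatrix samples(n_keep, 12);
  colnames(samples) = CharacterVector::create("mu1", "mu2", "mu3",
      "sigma1", "sigma2", "sigma3", "q1", "q2", "q3", "b", "tau", "loglik");
  NumericMatrix derived(n_keep, 9);
  colnames(derived) = CharacterVector::create("real1", "real2", "real3",
      "obsc12", "obsc13", "obsc21", "obsc23", "obsc31", "obsc32");
  const int n_snap = (snap_every > 0 && n_keep > 0) ? (n_keep + snap_every - 1) / snap_every : 0;
  NumericVector snap_t(Dimension(n_snap, n_sub, 3));
  IntegerVector snap_lic(Dimension(n_snap, n_sub, 3));
  IntegerVector snap_fired(Dimension(n_snap, n_sub, 3));
  IntegerVector snap_sample(n_snap);
  std::fill(snap_t.begin(), snap_t.end(), NA_REAL);

  // move accounting: 0..2 time per origin, 3..5 RJ per origin, 6 tau, 7 b,
  // 8..10 sigma rescaling per origin, 11..13 mu translation per origin
  const int NMOVE = 14;
  long att[NMOVE] = {0}, acc[NMOVE] = {0};   // overall (post burn-in)
  long watt[NMOVE] = {0}, wacc[NMOVE] = {0}; // adaptation window
  int windows = 0;

  std::vector<signed char> rowbuf(nb);
  std::vector<int> chg; chg.reserve(nb);
  std::vector<double> chg_ll; chg_ll.reserve(nb);
  // scratch state for full-population (rescaling) proposals
  std::vector<double> scr_tms(M * 3);
  std::vector<int> scr_fired(M * 3), scr_obsc(M * 3), scr_tally(nb);
  std::vector<signed char> scr_prof((size_t)M * nb);

  const int n_up = std::max(1, (int)std::lround(cellfrac * M));
  int lic_cand[3], n_lic_cand = 0;
  for (int i = 0; i < 3; ++i) if (upd_lic[i]) lic_cand[n_lic_cand++] = i;

  auto cell_delta = [&](int c, const int* f2, const double* t2) -> double {
    // tentative profile row for cell c and the resulting log-lik change
    chg.clear(); chg_ll.clear();
    double dll = 0.0;
    const signed char* row = &w.prof[(size_t)c * nb];
    for (int j = 0; j < nb; ++j) {
      int v = prof_at(f2, t2, &x[0], box_mid[j]);
      rowbuf[j] = (signed char)v;
      if (v != row[j]) {
        double F2 = (w.tally[j] + v - row[j]) / (double)M;
        double l2 = box_ll(j, F2, b, tau);
        dll += l2 - llbox[j];
        chg.push_back(j); chg_ll.push_back(l2);
      }
    }
    return dll;
  };
  auto commit_cell = [&](int c, const int* l2, const double* t2,
                         const int* f2, const int* o2) {
    const signed char* row = &w.prof[(size_t)c * nb];
    for (size_t u = 0; u < chg.size(); ++u) {
      int j = chg[u];
      w.tally[j] += rowbuf[j] - row[j];
      ll_total += chg_ll[u] - llbox[j];
      llbox[j] = chg_ll[u];
    }
    for (size_t u = 0; u < chg.size(); ++u) w.prof[(size_t)c * nb + chg[u]] = rowbuf[chg[u]];
    for (int i = 0; i < 3; ++i) {
      w.lic[c * 3 + i] = l2[i];
      w.tms[c * 3 + i] = t2[i];
      w.fired[c * 3 + i] = f2[i];
      w.obsc[c * 3 + i] = o2[i];
    }
  };

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    const bool tracking = sweep > burn_in;

    // (1) Metropolis random-walk on firing times of a fraction of cells
    if (upd_times) {
      for (int u = 0; u < n_up; ++u) {
        int c = (int)(unif_rand() * M); if (c >= M) c = M - 1;
        int cand[3], nc = 0;
        for (int i = 0; i < 3; ++i) if (w.lic[c * 3 + i]) cand[nc++] = i;
        if (nc == 0) continue;
        int i = cand[std::min((int)(unif_rand() * nc), nc - 1)];
        ++watt[i]; if (tracking) ++att[i];
        double told = w.tms[c * 3 + i];
        double tnew = told + scale_t[i] * norm_rand();
        int l2[3], f2[3], o2[3]; double t2[3];
        for (int k = 0; k < 3; ++k) { l2[k] = w.lic[c * 3 + k]; t2[k] = w.tms[c * 3 + k]; }
        t2[i] = tnew;
        if (resolve3(l2, t2, &x[0], f2, o2)) continue;
        double dll = cell_delta(c, f2, t2);
        double zo = (told - mu[i]) / sig[i], zn = (tnew - mu[i]) / sig[i];
        double dpr = 0.5 * (zo * zo - zn * zn);
        if (std::log(unif_rand()) < dll + dpr) {
          commit_cell(c, l2, t2, f2, o2);
          ++wacc[i]; if (tracking) ++acc[i];
        }
      }
    }

    // (2) reversible-jump licencing birth/death
    if (n_lic_cand > 0) {
      for (int u = 0; u < n_up; ++u) {
        int c = (int)(unif_rand() * M); if (c >= M) c = M - 1;
        int i = lic_cand[std::min((int)(unif_rand() * n_lic_cand), n_lic_cand - 1)];
        ++watt[3 + i]; if (tracking) ++att[3 + i];
        int l2[3], f2[3], o2[3]; double t2[3];
        for (int k = 0; k < 3; ++k) { l2[k] = w.lic[c * 3 + k]; t2[k] = w.tms[c * 3 + k]; }
        double logr;
        if (l2[i]) {                       // death
          if (qv[i] >= 1.0) continue;
          l2[i] = 0; t2[i] = R_PosInf;
          logr = std::log((1.0 - qv[i]) / qv[i]);
        } else {                           // birth, proposal = conditional prior
          if (qv[i] <= 0.0) continue;
          l2[i] = 1; t2[i] = mu[i] + sig[i] * norm_rand();
          logr = std::log(qv[i] / (1.0 - qv[i]));
        }
        if (resolve3(l2, t2, &x[0], f2, o2)) continue;
        logr += cell_delta(c, f2, t2);
        if (std::log(unif_rand()) < logr) {
          commit_cell(c, l2, t2, f2, o2);
          ++wacc[3 + i]; if (tracking) ++acc[3 + i];
        }
      }
    }

    // (3) conjugate Gibbs updates of mu_i, sigma_i^2, q_i
    for (int i = 0; i < 3; ++i) {
      int n_i = 0; double sum = 0.0;
      for (int c = 0; c < M; ++c)
        if (w.lic[c * 3 + i]) { ++n_i; sum += w.tms[c * 3 + i]; }
      if (s_mu[i] && n_i > 0)
        mu[i] = sum / n_i + (sig[i] / std::sqrt((double)n_i)) * norm_rand();
      if (s_sig[i] && n_i > 0) {
        double ss = 0.0;
        for (int c = 0; c < M; ++c)
          if (w.lic[c * 3 + i]) {
            double d = w.tms[c * 3 + i] - mu[i];
            ss += d * d;
          }
        double shape = a_sig + 0.5 * n_i, rate = b_sig + 0.5 * ss;
        double g = R::rgamma(shape, 1.0 / rate);
        sig[i] = std::sqrt(1.0 / g);
      }
      if (s_q[i]) {
        double qd = R::rbeta(a_q + n_i, b_q + (M - n_i));
        if (qd < 1e-12) qd = 1e-12;
        if (qd > 1.0 - 1e-12) qd = 1.0 - 1e-12;
        qv[i] = qd;
      }
    }

    // (3b) joint sigma rescaling: sigma_i' = sigma_i exp(eps) with all of
    // origin i's latent times rescaled about mu_i (non-centred move; the
    // latent z-scores are held fixed, so the time-prior terms and the
    // Jacobian reduce to -2 a_sig eps - b_sig (1/sigma'^2 - 1/sigma^2) and
    // only the likelihood change remains to evaluate). Breaks the slow
    // coupling between sigma_i and the spread of the latent times.
    if (upd_times) {
      for (int i = 0; i < 3; ++i) {
        if (!s_sig[i]) continue;
        ++watt[8 + i]; if (tracking) ++att[8 + i];
        double eps = scale_s[i] * norm_rand();
        double r = std::exp(eps);
        double signew = sig[i] * r;
        // tentative full-population rescale
        bool ok = true;
        std::fill(scr_tally.begin(), scr_tally.end(), 0);
        int f2[3], o2[3], l2[3]; double t2[3];
        for (int c = 0; c < M && ok; ++c) {
          for (int k = 0; k < 3; ++k) {
            l2[k] = w.lic[c * 3 + k];
            t2[k] = w.tms[c * 3 + k];
          }
          if (l2[i]) t2[i] = mu[i] + r * (t2[i] - mu[i]);
          if (resolve3(l2, t2, &x[0], f2, o2)) { ok = false; break; }
          for (int k = 0; k < 3; ++k) {
            scr_tms[c * 3 + k] = t2[k];
            scr_fired[c * 3 + k] = f2[k];
            scr_obsc[c * 3 + k] = o2[k];
          }
          for (int j = 0; j < nb; ++j) {
            int v = prof_at(f2, t2, &x[0], box_mid[j]);
            scr_prof[(size_t)c * nb + j] = (signed char)v;
            scr_tally[j] += v;
          }
        }
        if (!ok) continue;
        double ll2 = 0.0;
        for (int j = 0; j < nb; ++j) {
          llbuf[j] = box_ll(j, scr_tally[j] / (double)M, b, tau);
          ll2 += llbuf[j];
        }
        double logr = ll2 - ll_total - 2.0 * a_sig * eps
                      - b_sig * (1.0 / (signew * signew) - 1.0 / (sig[i] * sig[i]));
        if (R_finite(ll2) && std::log(unif_rand()) < logr) {
          sig[i] = signew;
          for (int c = 0; c < M; ++c)
            if (w.lic[c * 3 + i]) {
              w.tms[c * 3 + i] = scr_tms[c * 3 + i];
              for (int k = 0; k < 3; ++k) {
                w.fired[c * 3 + k] = scr_fired[c * 3 + k];
                w.obsc[c * 3 + k] = scr_obsc[c * 3 + k];
              }
            }
          std::copy(scr_prof.begin(), scr_prof.end(), w.prof.begin());
          std::copy(scr_tally.begin(), scr_tally.end(), w.tally.begin());
          ll_total = ll2; llbox.swap(llbuf);
          ++wacc[8 + i]; if (tracking) ++acc[8 + i];
        }
      }
    }

    // (3c) joint mu translation: mu_i' = mu_i + delta with all of origin i's
    // latent times shifted by delta. The flat mu prior and the time prior
    // (which depends on t - mu only) cancel, leaving the likelihood ratio.
    if (upd_times) {
      for (int i = 0; i < 3; ++i) {
        if (!s_mu[i]) continue;
        ++watt[11 + i]; if (tracking) ++att[11 + i];
        double delta = scale_m[i] * norm_rand();
        bool ok = true;
        std::fill(scr_tally.begin(), scr_tally.end(), 0);
        int f2[3], o2[3], l2[3]; double t2[3];
        for (int c = 0; c < M && ok; ++c) {
          for (int k = 0; k < 3; ++k) {
            l2[k] = w.lic[c * 3 + k];
            t2[k] = w.tms[c * 3 + k];
          }
          if (l2[i]) t2[i] += delta;
          if (resolve3(l2, t2, &x[0], f2, o2)) { ok = false; break; }
          for (int k = 0; k < 3; ++k) {
            scr_tms[c * 3 + k] = t2[k];
            scr_fired[c * 3 + k] = f2[k];
            scr_obsc[c * 3 + k] = o2[k];
          }
          for (int j = 0; j < nb; ++j) {
            int v = prof_at(f2, t2, &x[0], box_mid[j]);
            scr_prof[(size_t)c * nb + j] = (signed char)v;
            scr_tally[j] += v;
          }
        }
        if (!ok) continue;
        double ll2 = 0.0;
        for (int j = 0; j < nb; ++j) {
          llbuf[j] = box_ll(j, scr_tally[j] / (double)M, b, tau);
          ll2 += llbuf[j];
        }
        if (R_finite(ll2) && std::log(unif_rand()) < ll2 - ll_total) {
          mu[i] += delta;
          for (int c = 0; c < M; ++c)
            if (w.lic[c * 3 + i]) {
              w.tms[c * 3 + i] = scr_tms[c * 3 + i];
              for (int k = 0; k < 3; ++k) {
                w.fired[c * 3 + k] = scr_fired[c * 3 + k];
                w.obsc[c * 3 + k] = scr_obsc[c * 3 + k];
              }
            }
          std::copy(scr_prof.begin(), scr_prof.end(), w.prof.begin());
          std::copy(scr_tally.begin(), scr_tally.end(), w.tally.begin());
          ll_total = ll2; llbox.swap(llbuf);
          ++wacc[11 + i]; if (tracking) ++acc[11 + i];
        }
      }
    }

    // (4) Metropolis updates of tau (log walk) and b (logit walk)
    if (s_tau) {
      ++watt[6]; if (tracking) ++att[6];
      double taup = tau * std::exp(scale_tau * norm_rand());
      double ll2 = 0.0;
      for (int j = 0; j < nb; ++j) {
        llbuf[j] = box_ll(j, w.tally[j] / (double)M, b, taup);
        ll2 += llbuf[j];
      }
      double logr = ll2 - ll_total + a_tau * (std::log(taup) - std::log(tau))
                    - b_tau * (taup - tau);
      if (R_finite(ll2) && std::log(unif_rand()) < logr) {
        tau = taup; ll_total = ll2; llbox.swap(llbuf);
        ++wacc[6]; if (tracking) ++acc[6];
      }
    }
    if (s_b) {
      ++watt[7]; if (tracking) ++att[7];
      double lb = std::log(b / (1.0 - b)) + scale_b * norm_rand();
      double bp = 1.0 / (1.0 + std::exp(-lb));
      double ll2 = 0.0;
      for (int j = 0; j < nb; ++j) {
        llbuf[j] = box_ll(j, w.tally[j] / (double)M, bp, tau);
        ll2 += llbuf[j];
      }
      double logr = ll2 - ll_total
                    + std::log(bp * (1.0 - bp)) - std::log(b * (1.0 - b));
      if (R_finite(ll2) && std::log(unif_rand()) < logr) {
        b = bp; ll_total = ll2; llbox.swap(llbuf);
        ++wacc[7]; if (tracking) ++acc[7];
      }
    }

    // (5) recentring: subtract mean(mu) from all mu and all latent times
    if (recentre) {
      double cm = (mu[0] + mu[1] + mu[2]) / 3.0;
      if (cm != 0.0) {
        for (int i = 0; i < 3; ++i) mu[i] -= cm;
        for (int c = 0; c < M; ++c)
          for (int i = 0; i < 3; ++i)
            if (w.lic[c * 3 + i]) w.tms[c * 3 + i] -= cm;
      }
    }

    // Robbins-Monro adaptation of proposal scales during burn-in only
    if (adapt && sweep <= burn_in && sweep % 100 == 0) {
      ++windows;
      double gain = 1.0 / std::sqrt((double)windows);
      for (int m = 0; m < NMOVE; ++m) {
        if (watt[m] == 0) continue;
        double rate = wacc[m] / (double)watt[m];
        double f = std::exp(gain * (rate - 0.3));
        if (m < 3) scale_t[m] *= f;
        else if (m == 6) scale_tau *= f;
        else if (m == 7) scale_b *= f;
        else if (m >= 8 && m < 11) scale_s[m - 8] *= f;
        else if (m >= 11) scale_m[m - 11] *= f;
        // RJ moves (3..5) have no tunable scale
        watt[m] = 0; wacc[m] = 0;
      }
    }

    // periodic audit: incremental tallies must match a from-scratch recount
    if (check_every > 0 && sweep % check_every == 0) {
      std::vector<int> fresh(nb, 0);
      int f[3], o[3], l[3]; double t[3];
      for (int c = 0; c < M; ++c) {
        for (int i = 0; i < 3; ++i) { l[i] = w.lic[c * 3 + i]; t[i] = w.tms[c * 3 + i]; }
        if (resolve3(l, t, &x[0], f, o))
          stop("internal error: prohibited cell in chain state");
        for (int j = 0; j < nb; ++j) fresh[j] += prof_at(f, t, &x[0], box_mid[j]);
      }
      for (int j = 0; j < nb; ++j)
        if (fresh[j] != w.tally[j])
          stop("internal error: incremental profile tally diverged from recount");
      double lt = 0.0;
      for (int j = 0; j < nb; ++j) {
        llbox[j] = box_ll(j, w.tally[j] / (double)M, b, tau);
        lt += llbox[j];
      }
      ll_total = lt;
      if (!R_finite(ll_total)) stop("non-finite log-likelihood in chain");
    }

    // record retained sample
    if (tracking && (sweep - burn_in) % thin == 0) {
      int r = (sweep - burn_in) / thin - 1;
      if (r < n_keep) {
        samples(r, 0) = mu[0]; samples(r, 1) = mu[1]; samples(r, 2) = mu[2];
        samples(r, 3) = sig[0]; samples(r, 4) = sig[1]; samples(r, 5) = sig[2];
        samples(r, 6) = qv[0]; samples(r, 7) = qv[1]; samples(r, 8) = qv[2];
        samples(r, 9) = b; samples(r, 10) = tau; samples(r, 11) = ll_total;
        int nreal[3] = {0, 0, 0};
        int nobs[3][3] = {{0}};
        for (int c = 0; c < M; ++c)
          for (int i = 0; i < 3; ++i) {
            if (w.fired[c * 3 + i]) ++nreal[i];
            int oj = w.obsc[c * 3 + i];
            if (oj > 0) ++nobs[i][oj - 1];
          }
        derived(r, 0) = nreal[0] / (double)M;
        derived(r, 1) = nreal[1] / (double)M;
        derived(r, 2) = nreal[2] / (double)M;
        derived(r, 3) = nobs[0][1] / (double)M;  // obsc12
        derived(r, 4) = nobs[0][2] / (double)M;  // obsc13
        derived(r, 5) = nobs[1][0] / (double)M;  // obsc21
        derived(r, 6) = nobs[1][2] / (double)M;  // obsc23
        derived(r, 7) = nobs[2][0] / (double)M;  // obsc31
        derived(r, 8) = nobs[2][1] / (double)M;  // obsc32
        if (snap_every > 0 && r % snap_every == 0) {
          int s = r / snap_every;
          if (s < n_snap) {
            snap_sample[s] = r + 1;
            for (int c = 0; c < n_sub; ++c)
              for (int i = 0; i < 3; ++i) {
                size_t off = (size_t)s + (size_t)n_snap * (c + (size_t)n_sub * i);
                snap_lic[off] = w.lic[c * 3 + i];
                snap_fired[off] = w.fired[c * 3 + i];
                snap_t[off] = w.lic[c * 3 + i] ? w.tms[c * 3 + i] : NA_REAL;
              }
          }
        }
      }
    }
  }

  NumericVector acc_rate(NMOVE);
  CharacterVector acc_names = CharacterVector::create(
      "t1", "t2", "t3", "rj1", "rj2", "rj3", "tau", "b",
      "rescale1", "rescale2", "rescale3", "shift1", "shift2", "shift3");
  for (int m = 0; m < NMOVE; ++m)
    acc_rate[m] = att[m] > 0 ? acc[m] / (double)att[m] : NA_REAL;
  acc_rate.names() = acc_names;

  IntegerMatrix lic_out(M, 3), fired_out(M, 3), obsc_out(M, 3);
  NumericMatrix tms_out(M, 3);
  for (int c = 0; c < M; ++c)
    for (int i = 0; i < 3; ++i) {
      lic_out(c, i) = w.lic[c * 3 + i];
      fired_out(c, i) = w.fired[c * 3 + i];
      obsc_out(c, i) = w.obsc[c * 3 + i];
      tms_out(c, i) = w.lic[c * 3 + i] ? w.tms[c * 3 + i] : NA_REAL;
    }
  IntegerVector tally_out(w.tally.begin(), w.tally.end());

  return List::create(
      _["samples"] = samples,
      _["derived"] = derived,
      _["snapshots"] = List::create(_["times"] = snap_t, _["licenced"] = snap_lic,
                                    _["realized"] = snap_fired,
                                    _["sample_index"] = snap_sample),
      _["accept"] = acc_rate,
      _["scales"] = List::create(_["t"] = NumericVector(scale_t, scale_t + 3),
                                 _["tau"] = scale_tau, _["b"] = scale_b),
      _["final"] = List::create(_["licenced"] = lic_out, _["times"] = tms_out,
                                _["realized"] = fired_out, _["obscured_by"] = obsc_out,
                                _["tally"] = tally_out, _["loglik"] = ll_total));
}
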