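// Core simulation loops.
//
// The R surface defines the model (jump distributions, candidate
// predicates, bookkeeping rules); this file implements the same rules in
// a fused per-step loop so that multi-day runs with 1e4-1e5 cells are
// feasible. Cross-checks against the R implementations live in the test
// suite.
//
// Blocked jump directions: the mixed jump distribution transfers the mass
// of crowd-blocked directions to the no-jump outcome. Sampling a direction
// from the *unblocked* distribution and treating a blocked draw as "stay"
// realises exactly that distribution, so the engine samples first and
// checks the destination after.
//
// All randomness comes from R's global RNG stream (unif_rand / R::rpois),
// so a run is reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---- lattice direction tables (must match jump_vectors(3) in R:
// lexicographic by (dx, dy, dz), dx fastest) ----
static int DX[26], DY[26], DZ[26];
static double ULEN[26];
static bool dirs_ready = false;

static void init_dirs() {
  if (dirs_ready) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        DX[k] = dx; DY[k] = dy; DZ[k] = dz;
        ULEN[k] = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        ++k;
      }
  dirs_ready = true;
}

// Base-walk probability tables: prob[s][0..26] for previous-direction
// state s in 0..25 (last jump) or 26 (none / isotropic).
static void build_base_tables(double p0, double kappa,
                              std::vector< std::vector<double> > &prob) {
  prob.assign(27, std::vector<double>(27, 0.0));
  for (int s = 0; s <= 26; ++s) {
    double w[26], tot = 0.0;
    for (int j = 0; j < 26; ++j) {
      double wt;
      if (s == 26 || kappa == 0.0) {
        wt = 1.0 / ULEN[j];
      } else {
        double cosphi = (DX[s] * DX[j] + DY[s] * DY[j] + DZ[s] * DZ[j]) /
          (ULEN[s] * ULEN[j]);
        wt = std::exp(kappa * cosphi) / ULEN[j];
      }
      w[j] = wt; tot += wt;
    }
    prob[s][0] = p0;
    for (int j = 0; j < 26; ++j) prob[s][j + 1] = (1.0 - p0) * w[j] / tot;
  }
}

// chemotaxis-only probabilities for unit vector v (26 entries)
static void chemo_probs(const double v[3], double pc[26]) {
  double tot = 0.0;
  for (int j = 0; j < 26; ++j) {
    double c = (DX[j] * v[0] + DY[j] * v[1] + DZ[j] * v[2]) / ULEN[j];
    pc[j] = (c >= 0.0) ? c * c / ULEN[j] : 0.0;
    tot += pc[j];
  }
  if (tot > 0.0) for (int j = 0; j < 26; ++j) pc[j] /= tot;
}

static inline int sample27(const double *p) {
  double u = unif_rand(), acc = 0.0;
  for (int i = 0; i < 27; ++i) {
    acc += p[i];
    if (u < acc) return i;
  }
  return 0;  // numerical slack: treat as no jump
}

// ---------------------------------------------------------------------
// Free-space walk (no lattice bounds, no crowding), optionally under a
// uniform chemotactic attraction C. Used for motility calibration and
// the chemotaxis index.
// [[Rcpp::export]]
List cpp_free_walk(int n_traj, int n_steps, double p0, double kappa,
                   NumericVector C, bool positions) {
  init_dirs();
  std::vector< std::vector<double> > base;
  build_base_tables(p0, kappa, base);

  double cn = std::sqrt(C[0] * C[0] + C[1] * C[1] + C[2] * C[2]);
  double alpha = std::min(1.0, cn);
  double mixed[27][27];
  for (int s = 0; s <= 26; ++s)
    for (int i = 0; i < 27; ++i) mixed[s][i] = base[s][i];
  if (alpha > 0.0) {
    double v[3] = { C[0] / cn, C[1] / cn, C[2] / cn };
    double pc[26];
    chemo_probs(v, pc);
    for (int s = 0; s <= 26; ++s) {
      mixed[s][0] = (1.0 - alpha) * base[s][0];
      for (int j = 0; j < 26; ++j)
        mixed[s][j + 1] = (1.0 - alpha) * base[s][j + 1] + alpha * pc[j];
    }
  }

  IntegerVector odx(n_traj), ody(n_traj), odz(n_traj);
  NumericVector opath(n_traj);
  IntegerVector ptraj, pstep, px, py, pz;
  if (positions) {
    R_xlen_t nrec = (R_xlen_t)n_traj * (n_steps + 1);
    ptraj = IntegerVector(nrec); pstep = IntegerVector(nrec);
    px = IntegerVector(nrec); py = IntegerVector(nrec); pz = IntegerVector(nrec);
  }
  R_xlen_t rec = 0;
  for (int t = 0; t < n_traj; ++t) {
    int x = 0, y = 0, z = 0, prev = 26;
    double path = 0.0;
    if (positions) {
      ptraj[rec] = t + 1; pstep[rec] = 0; px[rec] = 0; py[rec] = 0; pz[rec] = 0;
      ++rec;
    }
    for (int s = 0; s < n_steps; ++s) {
      int i = sample27(mixed[prev]);
      if (i > 0) {
        x += DX[i - 1]; y += DY[i - 1]; z += DZ[i - 1];
        path += ULEN[i - 1];
        prev = i - 1;
      }
      if (positions) {
        ptraj[rec] = t + 1; pstep[rec] = s + 1;
        px[rec] = x; py[rec] = y; pz[rec] = z;
        ++rec;
      }
    }
    odx[t] = x; ody[t] = y; odz[t] = z; opath[t] = path;
  }
  List out = List::create(_["dx"] = odx, _["dy"] = ody, _["dz"] = odz,
                          _["path"] = opath);
  if (positions) {
    out["traj"] = ptraj; out["step"] = pstep;
    out["x"] = px; out["y"] = py; out["z"] = pz;
  }
  return out;
}

// ---------------------------------------------------------------------
// Full blob simulation.

struct Blob {
  int half, L;
  long nsites;
  std::vector<int> rank2lin, lin2rank;
  std::vector<double> rankr2;
  std::vector<int16_t> cx, cy, cz;       // coords by linear index
  std::vector<uint8_t> avail, occ, nearportal;
  int noff[26];
  long n_avail;
  long first_hole;   // lowest rank that is not available
  long top;          // highest rank that is available

  void build(long max_cells) {
    double rmax = std::cbrt(3.0 * max_cells / (4.0 * M_PI));
    half = (int)std::ceil(rmax) + 4;
    L = 2 * half + 1;
    nsites = (long)L * L * L;
    cx.resize(nsites); cy.resize(nsites); cz.resize(nsites);
    std::vector<double> r2(nsites);
    for (long i = 0; i < nsites; ++i) {
      int x = (int)(i % L) - half;
      int y = (int)((i / L) % L) - half;
      int z = (int)(i / ((long)L * L)) - half;
      cx[i] = (int16_t)x; cy[i] = (int16_t)y; cz[i] = (int16_t)z;
      r2[i] = (double)(x * x + y * y + z * z);
    }
    rank2lin.resize(nsites);
    for (long i = 0; i < nsites; ++i) rank2lin[i] = (int)i;
    std::sort(rank2lin.begin(), rank2lin.end(), [&](int a, int b) {
      if (r2[a] != r2[b]) return r2[a] < r2[b];
      if (cx[a] != cx[b]) return cx[a] < cx[b];
      if (cy[a] != cy[b]) return cy[a] < cy[b];
      return cz[a] < cz[b];
    });
    lin2rank.resize(nsites);
    rankr2.resize(nsites);
    for (long r = 0; r < nsites; ++r) {
      lin2rank[rank2lin[r]] = (int)r;
      rankr2[r] = r2[rank2lin[r]];
    }
    avail.assign(nsites, 0);
    occ.assign(nsites, 0);
    nearportal.assign(nsites, 0);
    for (int k = 0; k < 26; ++k)
      noff[k] = DX[k] + L * DY[k] + L * L * DZ[k];
    n_avail = 0; first_hole = 0; top = -1;
  }

  double R() const { return std::cbrt(3.0 * n_avail / (4.0 * M_PI)); }

  bool edge(int lin) const {
    return std::abs((int)cx[lin]) >= half - 1 ||
           std::abs((int)cy[lin]) >= half - 1 ||
           std::abs((int)cz[lin]) >= half - 1;
  }

  void add_site() {
    while (first_hole < (long)nsites && avail[rank2lin[first_hole]])
      ++first_hole;
    if (first_hole >= (long)nsites || edge(rank2lin[first_hole]))
      stop("lattice headroom exhausted; increase `headroom`");
    avail[rank2lin[first_hole]] = 1;
    ++n_avail;
    if (first_hole > top) top = first_hole;
    ++first_hole;
  }

  // retire the farthest unoccupied available site; false if none free
  bool remove_site() {
    for (long r = top; r >= 0; --r) {
      int lin = rank2lin[r];
      if (avail[lin] && occ[lin] == 0) {
        avail[lin] = 0;
        --n_avail;
        if (r < first_hole) first_hole = r;
        while (top >= 0 && !avail[rank2lin[top]]) --top;
        return true;
      }
    }
    return false;
  }

  // exit-candidate predicate: whole Moore block inside; second shell
  // touches outside; not in the follicle cap
  bool candidate(int lin, double cap) const {
    if ((double)cx[lin] / R() > cap) return false;
    if (edge(lin)) return false;
    bool shell_out = false;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int s = lin + a + L * b + L * L * c;
          if (!avail[s]) return false;
          if (!shell_out) {
            for (int k = 0; k < 26; ++k)
              if (!avail[s + noff[k]]) { shell_out = true; break; }
          }
        }
    return shell_out;
  }
};

// [[Rcpp::export]]
List cpp_run_simulation(
    int n0, int n_steps, double dt_min, double t_res_min, double p_e,
    double p0, double kappa, double ke_global,
    double tag_fraction, double tag_ke, double tag_window_min,
    int portal_mode, int n_portals_fixed, bool portal_at_center,
    double exit_a, double exit_b, double exit_mult,
    double cap_threshold, double min_sep, double entry_fraction,
    double f_in_fixed, int influx_mode, NumericVector a_signal,
    NumericVector inf_par, double headroom, int record_every,
    int n_init_tag, double init_tag_radius, double init_tag_ke,
    double chemo_cutoff) {
  init_dirs();
  std::vector< std::vector<double> > base;
  build_base_tables(p0, kappa, base);

  Blob B;
  B.build((long)std::ceil((double)n0 * headroom));

  // dense initial packing: one cell per available site
  std::vector<int> cpos, cprev, centry, cid;
  std::vector<double> cke;
  std::vector<uint8_t> ctag;
  cpos.reserve(2 * n0);
  for (int r = 0; r < n0; ++r) {
    int lin = B.rank2lin[r];
    B.avail[lin] = 1; B.occ[lin] = 1;
    cpos.push_back(lin); cprev.push_back(26); centry.push_back(0);
    cid.push_back(r + 1); cke.push_back(ke_global); ctag.push_back(0);
  }
  B.n_avail = n0; B.first_hole = n0; B.top = n0 - 1;
  int next_id = n0 + 1;

  // optional initial tagging within a sphere around the centre
  if (n_init_tag > 0) {
    std::vector<int> inside;
    double d2 = init_tag_radius * init_tag_radius;
    for (size_t i = 0; i < cpos.size(); ++i) {
      int lin = cpos[i];
      double r2 = (double)(B.cx[lin] * B.cx[lin] + B.cy[lin] * B.cy[lin] +
                           B.cz[lin] * B.cz[lin]);
      if (r2 <= d2) inside.push_back((int)i);
    }
    int ntag = std::min((int)inside.size(), n_init_tag);
    for (int k = 0; k < ntag; ++k) {   // partial Fisher-Yates
      int j = k + (int)std::floor(unif_rand() * (inside.size() - k));
      std::swap(inside[k], inside[j]);
      ctag[inside[k]] = 1;
      cke[inside[k]] = init_tag_ke;
    }
  }

  // portals
  std::vector<int> plin;
  long relaxed_sep = 0, placement_failures = 0;
  bool portals_dirty = true;

  auto rebuild_nearportal = [&]() {
    std::fill(B.nearportal.begin(), B.nearportal.end(), 0);
    for (size_t j = 0; j < plin.size(); ++j) {
      int s = plin[j];
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c)
            B.nearportal[s + a + B.L * b + B.L * B.L * c] = 1;
    }
    portals_dirty = false;
  };

  // distance to the nearest other portal (optionally excluding index j0,
  // e.g. the portal currently being relocated)
  auto min_portal_dist = [&](int lin, long j0 = -1) {
    double best = 1e30;
    for (size_t j = 0; j < plin.size(); ++j) {
      if ((long)j == j0) continue;
      double ddx = B.cx[lin] - B.cx[plin[j]];
      double ddy = B.cy[lin] - B.cy[plin[j]];
      double ddz = B.cz[lin] - B.cz[plin[j]];
      double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (d < best) best = d;
    }
    return best;
  };

  // sample a new portal site among boundary-layer candidates
  auto place_one = [&]() -> bool {
    double Rn = B.R();
    double inner = std::max(0.0, Rn - 3.5);
    long lo = std::lower_bound(B.rankr2.begin(),
                               B.rankr2.begin() + B.n_avail,
                               inner * inner) - B.rankr2.begin();
    long span = B.n_avail - lo;
    if (span <= 0) return false;
    for (int tr = 0; tr < 200; ++tr) {
      long r = lo + (long)std::floor(unif_rand() * span);
      int lin = B.rank2lin[r];
      if (!B.avail[lin] || !B.candidate(lin, cap_threshold)) continue;
      if (tr < 100 && min_portal_dist(lin) < min_sep) continue;
      if (tr >= 100) ++relaxed_sep;
      plin.push_back(lin);
      portals_dirty = true;
      return true;
    }
    // exhaustive fallback
    for (long r = B.n_avail - 1; r >= lo; --r) {
      int lin = B.rank2lin[r];
      if (B.avail[lin] && B.candidate(lin, cap_threshold)) {
        plin.push_back(lin);
        ++relaxed_sep;
        portals_dirty = true;
        return true;
      }
    }
    ++placement_failures;
    return false;
  };

  auto relocate_invalid = [&]() {
    for (long j = 0; j < (long)plin.size(); ++j) {
      if (B.candidate(plin[j], cap_threshold)) continue;
      // nearest valid candidate within Chebyshev radius 3 that keeps the
      // portal separation (overlapping neighbourhoods would cut the
      // union egress flux)
      int bestlin = -1; double bestd = 1e30;
      int x0 = B.cx[plin[j]], y0 = B.cy[plin[j]], z0 = B.cz[plin[j]];
      for (int a = -3; a <= 3; ++a)
        for (int b = -3; b <= 3; ++b)
          for (int c = -3; c <= 3; ++c) {
            if (a == 0 && b == 0 && c == 0) continue;
            int x = x0 + a, y = y0 + b, z = z0 + c;
            if (std::abs(x) >= B.half - 1 || std::abs(y) >= B.half - 1 ||
                std::abs(z) >= B.half - 1) continue;
            int lin = (x + B.half) + B.L * ((y + B.half) +
                       (long)B.L * (z + B.half));
            if (!B.avail[lin] || !B.candidate(lin, cap_threshold)) continue;
            if (min_portal_dist(lin, j) < min_sep) continue;
            double d = (double)(a * a + b * b + c * c);
            if (d < bestd) { bestd = d; bestlin = lin; }
          }
      if (bestlin >= 0) {
        plin[j] = bestlin;
        portals_dirty = true;
      } else {
        // no separated candidate nearby: retire this portal and draw a
        // fresh separated location
        plin.erase(plin.begin() + j);
        --j;
        portals_dirty = true;
        place_one();
      }
    }
  };

  auto target_portals = [&](long N) -> int {
    if (portal_mode == 0) return n_portals_fixed;
    double ne = exit_mult * (0.02 / p_e) * exit_a *
      std::pow((double)N, exit_b) / t_res_min;
    long t = std::lround(ne);
    return (int)std::max(0L, t);
  };

  if (portal_at_center) {
    int clin = B.half + B.L * (B.half + (long)B.L * B.half);
    plin.push_back(clin);
  } else {
    int tgt = target_portals(n0);
    for (int j = 0; j < tgt; ++j) place_one();
  }
  rebuild_nearportal();

  // vascular state
  double aG = inf_par[0], bG = inf_par[1], dG = inf_par[2],
         aV = inf_par[3], bV = inf_par[4], nV = inf_par[5], dV = inf_par[6];
  double MG = bG * n0 / dG, V = 1.0;
  double cg_eq = bG / dG;

  // transit log (closed records)
  std::vector<int> t_id, t_entry, t_exit, t_tag;
  std::vector<double> t_ke;

  // recorded series
  int n_rec = n_steps / record_every + 1;
  NumericVector r_t(n_rec), r_V(n_rec), r_A(n_rec), r_F(n_rec), r_pocc(n_rec);
  IntegerVector r_N(n_rec), r_P(n_rec), r_tagged(n_rec);
  int rec_i = 0;

  long crowding_exceptions = 0, deferred_removals = 0, deferred_arrivals = 0;
  long total_entries = 0, total_exits = 0;
  long pending_in = 0, pending_rm = 0;

  std::vector<int> order;   // shuffled cell order
  std::vector<int> shared;  // cells on doubly occupied sites

  auto record_row = [&](double t, double A, double F_in) {
    r_t[rec_i] = t;
    r_N[rec_i] = (int)cpos.size();
    r_P[rec_i] = (int)plin.size();
    r_V[rec_i] = V; r_A[rec_i] = A; r_F[rec_i] = F_in;
    long socc = 0, scnt = 0;
    for (size_t j = 0; j < plin.size(); ++j) {
      int s = plin[j];
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            socc += B.occ[s + a + B.L * b + (long)B.L * B.L * c];
            ++scnt;
          }
    }
    r_pocc[rec_i] = scnt ? (double)socc / scnt : NA_REAL;
    long ntag = 0;
    for (size_t i = 0; i < ctag.size(); ++i) ntag += ctag[i];
    r_tagged[rec_i] = (int)ntag;
    ++rec_i;
  };

  // sample a move for cell i; returns direction 0..26 (0 = no jump)
  double Cvec[3];
  auto sample_move = [&](size_t i, bool forced) -> int {
    const double *pb = base[cprev[i]].data();
    double alpha = 0.0;
    double pc[26];
    if (cke[i] > 0.0 && !plin.empty()) {
      Cvec[0] = Cvec[1] = Cvec[2] = 0.0;
      int lin = cpos[i];
      for (size_t j = 0; j < plin.size(); ++j) {
        double ddx = B.cx[plin[j]] - B.cx[lin];
        double ddy = B.cy[plin[j]] - B.cy[lin];
        double ddz = B.cz[plin[j]] - B.cz[lin];
        double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (r2 == 0.0) continue;
        double g = cke[i] / r2;
        if (g < chemo_cutoff) continue;
        if (g > 1.0) g = 1.0;
        double r = std::sqrt(r2);
        Cvec[0] += g * ddx / r; Cvec[1] += g * ddy / r; Cvec[2] += g * ddz / r;
      }
      double cn = std::sqrt(Cvec[0] * Cvec[0] + Cvec[1] * Cvec[1] +
                            Cvec[2] * Cvec[2]);
      if (cn > 1e-12) {
        alpha = std::min(1.0, cn);
        double v[3] = { Cvec[0] / cn, Cvec[1] / cn, Cvec[2] / cn };
        chemo_probs(v, pc);
      }
    }
    double p[27];
    if (alpha > 0.0) {
      p[0] = (1.0 - alpha) * pb[0];
      for (int j = 0; j < 26; ++j)
        p[j + 1] = (1.0 - alpha) * pb[j + 1] + alpha * pc[j];
    } else {
      for (int j = 0; j < 27; ++j) p[j] = pb[j];
    }
    if (!forced) return sample27(p);
    // forced move: exclude no-jump, zero inadmissible, renormalise
    int lin = cpos[i];
    double tot = 0.0;
    for (int j = 0; j < 26; ++j) {
      int dest = lin + B.noff[j];
      if (!B.avail[dest] || B.occ[dest] >= 2) p[j + 1] = 0.0;
      tot += p[j + 1];
    }
    if (tot <= 0.0) return -1;
    double u = unif_rand() * tot, acc = 0.0;
    for (int j = 0; j < 26; ++j) {
      acc += p[j + 1];
      if (u < acc) return j + 1;
    }
    return -1;
  };

  int consecutive_jams = 0;

  for (int step = 0; step < n_steps; ++step) {
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
    double t = step * dt_min;
    long N = (long)cpos.size();

    // (1) vascular / influx update
    double A = (a_signal.size() > step) ? a_signal[step] : 0.0;
    double F_in;
    if (influx_mode == 1) {
      MG += dt_min * (bG * n0 + aG * n0 * A - dG * MG);
      double x = std::pow((MG / std::max(1L, N)) / cg_eq, nV);
      double H = x / (x + std::pow(bV, nV));
      V += dt_min * (aV * H - dV) * V;
      F_in = V * n0 / t_res_min;
    } else {
      F_in = (double)n0 / t_res_min;
    }
    if (f_in_fixed > 0.0) F_in = f_in_fixed;

    // (2) ingress
    long arrivals = (long)R::rpois(F_in * dt_min) + pending_in;
    pending_in = 0;
    if (arrivals > 0) {
      double er2 = entry_fraction * entry_fraction * B.R() * B.R();
      long ecount = std::lower_bound(B.rankr2.begin(),
                                     B.rankr2.begin() + B.n_avail,
                                     er2 + 1e-9) - B.rankr2.begin();
      for (long k = 0; k < arrivals; ++k) {
        bool placed = false;
        for (int tr = 0; tr < 50 && ecount > 0; ++tr) {
          long r = (long)std::floor(unif_rand() * ecount);
          int lin = B.rank2lin[r];
          if (B.avail[lin] && B.occ[lin] < 2) {
            ++B.occ[lin];
            cpos.push_back(lin); cprev.push_back(26);
            centry.push_back(step); cid.push_back(next_id++);
            bool tag = (t < tag_window_min) && (unif_rand() < tag_fraction);
            ctag.push_back(tag ? 1 : 0);
            cke.push_back(tag ? tag_ke : ke_global);
            B.add_site();
            ++total_entries;
            placed = true;
            break;
          }
        }
        if (!placed) { ++pending_in; ++deferred_arrivals; }
      }
    }

    // (3) motility + chemotaxis moves, freshly shuffled order
    N = (long)cpos.size();
    order.resize(N);
    for (long i = 0; i < N; ++i) order[i] = (int)i;
    for (long i = N - 1; i > 0; --i) {
      long j = (long)std::floor(unif_rand() * (i + 1));
      std::swap(order[i], order[j]);
    }
    for (long oi = 0; oi < N; ++oi) {
      int i = order[oi];
      int mv = sample_move(i, false);
      if (mv > 0) {
        int dest = cpos[i] + B.noff[mv - 1];
        if (B.avail[dest] && B.occ[dest] < 2) {
          --B.occ[cpos[i]];
          ++B.occ[dest];
          cpos[i] = dest;
          cprev[i] = mv - 1;
        }
        // blocked draw = failed move: stay, previous direction unchanged
      }
    }

    // (4) forced resolution of shared sites
    shared.clear();
    for (long oi = 0; oi < N; ++oi) {
      int i = order[oi];
      if (B.occ[cpos[i]] == 2) shared.push_back(i);
    }
    long jams = 0;
    for (size_t k = 0; k < shared.size(); ++k) {
      int i = shared[k];
      int mv = sample_move(i, true);
      if (mv > 0) {
        int dest = cpos[i] + B.noff[mv - 1];
        --B.occ[cpos[i]];
        ++B.occ[dest];
        cpos[i] = dest;
        cprev[i] = mv - 1;
      } else {
        ++crowding_exceptions;
        ++jams;
      }
    }
    // Strong global chemotaxis legitimately jams large fractions of the
    // population in saturated double-occupancy zones around the portals;
    // only a near-total persistent jam indicates a genuine deadlock.
    if (N > 0 && jams > (long)(0.95 * N)) {
      if (++consecutive_jams > 200)
        stop("crowding deadlock: over 95%% of cells jammed for 200 consecutive steps");
    } else consecutive_jams = 0;

    // (5) egress
    for (long i = (long)cpos.size() - 1; i >= 0; --i) {
      if (!B.nearportal[cpos[i]]) continue;
      if (unif_rand() >= p_e) continue;
      t_id.push_back(cid[i]); t_entry.push_back(centry[i]);
      t_exit.push_back(step); t_tag.push_back(ctag[i]);
      t_ke.push_back(cke[i]);
      --B.occ[cpos[i]];
      ++total_exits;
      ++pending_rm;
      size_t last = cpos.size() - 1;
      cpos[i] = cpos[last]; cprev[i] = cprev[last]; centry[i] = centry[last];
      cid[i] = cid[last]; cke[i] = cke[last]; ctag[i] = ctag[last];
      cpos.pop_back(); cprev.pop_back(); centry.pop_back();
      cid.pop_back(); cke.pop_back(); ctag.pop_back();
    }
    while (pending_rm > 0) {
      if (B.remove_site()) --pending_rm;
      else { ++deferred_removals; break; }
    }

    // (6) blob/portal bookkeeping
    if (!portal_at_center) {
      relocate_invalid();
      int tgt = target_portals((long)cpos.size());
      while ((int)plin.size() > tgt) {
        plin.pop_back();
        portals_dirty = true;
      }
      while ((int)plin.size() < tgt) {
        if (!place_one()) break;
      }
      if (portals_dirty) rebuild_nearportal();
    }

    // (7) recording
    if (step % record_every == 0) record_row(t, A, F_in);
  }
  if (rec_i < n_rec)
    record_row(n_steps * dt_min,
               (a_signal.size() >= n_steps && n_steps > 0) ? a_signal[n_steps - 1] : 0.0,
               f_in_fixed > 0 ? f_in_fixed :
                 (influx_mode == 1 ? V * n0 / t_res_min : (double)n0 / t_res_min));

  // open records for cells still inside
  long n_open = (long)cpos.size();
  for (long i = 0; i < n_open; ++i) {
    t_id.push_back(cid[i]); t_entry.push_back(centry[i]);
    t_exit.push_back(-1); t_tag.push_back(ctag[i]); t_ke.push_back(cke[i]);
  }

  IntegerVector px(plin.size()), py(plin.size()), pz(plin.size());
  for (size_t j = 0; j < plin.size(); ++j) {
    px[j] = B.cx[plin[j]]; py[j] = B.cy[plin[j]]; pz[j] = B.cz[plin[j]];
  }

  return List::create(
    _["series"] = List::create(
      _["t_min"] = r_t[Range(0, rec_i - 1)],
      _["n_cells"] = r_N[Range(0, rec_i - 1)],
      _["n_portals"] = r_P[Range(0, rec_i - 1)],
      _["V"] = r_V[Range(0, rec_i - 1)],
      _["A"] = r_A[Range(0, rec_i - 1)],
      _["F_in"] = r_F[Range(0, rec_i - 1)],
      _["portal_occ"] = r_pocc[Range(0, rec_i - 1)],
      _["tagged_alive"] = r_tagged[Range(0, rec_i - 1)]),
    _["transits"] = List::create(
      _["id"] = t_id, _["entry_step"] = t_entry, _["exit_step"] = t_exit,
      _["tagged"] = t_tag, _["K_E"] = t_ke),
    _["portals"] = List::create(_["x"] = px, _["y"] = py, _["z"] = pz),
    _["counters"] = List::create(
      _["crowding_exceptions"] = (double)crowding_exceptions,
      _["deferred_removals"] = (double)deferred_removals,
      _["deferred_arrivals"] = (double)deferred_arrivals,
      _["total_entries"] = (double)total_entries,
      _["total_exits"] = (double)total_exits,
      _["relaxed_separation"] = (double)relaxed_sep,
      _["placement_failures"] = (double)placement_failures),
    _["final_n"] = (int)cpos.size());
}
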