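// Exact Gillespie (direct method) kernels for the two lattice models of
// ParA-mediated plasmid positioning:
//   * diffusion/immobilization model on a 1d nucleoid lattice
//   * directed-motion ParA polymer model on a thin 2d strip lattice
// Channel propensities are aggregated per lattice column in a binary sum
// tree (O(log n) selection/update); the firing sub-reaction is resolved by
// scanning the short axis, which is at most a handful of sites.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Binary sum tree over non-negative channel propensities.
struct SumTree {
  int n;                       // leaf count (power of two)
  std::vector<double> v;       // 1-based heap; leaves at [n, 2n)
  void init(int leaves) {
    n = 1;
    while (n < leaves) n <<= 1;
    v.assign(2 * n, 0.0);
  }
  void set(int i, double x) {
    int k = n + i;
    v[k] = x;
    for (k >>= 1; k >= 1; k >>= 1) v[k] = v[2 * k] + v[2 * k + 1];
  }
  double total() const { return v[1]; }
  int sample(double u) const {  // u in [0, total)
    int k = 1;
    while (k < n) {
      k <<= 1;
      if (u >= v[k]) { u -= v[k]; ++k; }
    }
    return k - n;
  }
};

inline double rng_u() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

inline int rng_int(int n) {  // uniform on 0..n-1
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// ---------------------------------------------------------------------------
// Diffusion/immobilization model (1d lattice)
// ---------------------------------------------------------------------------

struct DIModel {
  // parameters
  double dx, D_A, D_P, k_on, k_AB, k_B, k_W, k_off;
  int max_bound, immobilize_threshold;
  double density_per_um;       // <0 disables replenishment at growth
  double hopA, hopP;           // per-direction hop rates D/dx^2

  // state
  int n;                       // current long-axis length (sites)
  std::vector<int> A;          // nucleoid-bound ParA-ATP per site
  std::vector<int> psite;      // plasmid site (0-based)
  std::vector<int> pbound;     // ParA-ATP bound per plasmid
  long long A_ADP, A_CYTO;

  // channels: [0, ncap) columns; [ncap, ncap+pcap) plasmids; then kW, kOn
  int ncap, pcap;
  SumTree tree;

  long long total_parA() const {
    long long s = A_ADP + A_CYTO;
    for (int i = 0; i < n; ++i) s += A[i];
    for (size_t p = 0; p < pbound.size(); ++p) s += pbound[p];
    return s;
  }

  double col_prop(int i) const {
    if (A[i] == 0) return 0.0;
    int dirs = (i > 0) + (i < n - 1);
    return A[i] * (hopA * dirs + k_off);
  }

  double plasmid_prop(int p) const {
    int i = psite[p], b = pbound[p];
    double a = 0.0;
    if (b < immobilize_threshold) a += hopP * ((i > 0) + (i < n - 1));
    if (b < max_bound) a += k_AB * A[i];
    a += k_B * b;
    return a;
  }

  void upd_col(int i) { if (i >= 0 && i < n) tree.set(i, col_prop(i)); }
  void upd_plasmid(int p) { tree.set(ncap + p, plasmid_prop(p)); }
  void upd_globals() {
    tree.set(ncap + pcap, k_W * (double)A_ADP);
    tree.set(ncap + pcap + 1, k_on * (double)A_CYTO);
  }

  void rebuild() {
    tree.init(ncap + pcap + 2);
    for (int i = 0; i < n; ++i) tree.set(i, col_prop(i));
    for (size_t p = 0; p < psite.size(); ++p) upd_plasmid((int)p);
    upd_globals();
  }

  // Fire the channel with index c, using fresh uniforms for sub-selection.
  void fire(int c) {
    if (c < ncap) {                       // mobile ParA-ATP at column c
      int i = c;
      double u = rng_u() * col_prop(i);
      int dirs = (i > 0) + (i < n - 1);
      double hop_tot = A[i] * hopA * dirs;
      if (u < hop_tot) {                  // hop
        int j;
        if (i == 0) j = 1;
        else if (i == n - 1) j = n - 2;
        else j = (u < hop_tot / 2) ? i - 1 : i + 1;
        --A[i]; ++A[j];
        upd_col(i); upd_col(j);
        for (size_t p = 0; p < psite.size(); ++p)
          if (psite[p] == i || psite[p] == j) upd_plasmid((int)p);
      } else {                            // spontaneous hydrolysis k_off
        --A[i]; ++A_ADP;
        upd_col(i); upd_globals();
        for (size_t p = 0; p < psite.size(); ++p)
          if (psite[p] == i) upd_plasmid((int)p);
      }
    } else if (c < ncap + pcap) {         // plasmid channel
      int p = c - ncap, i = psite[p], b = pbound[p];
      double u = rng_u() * plasmid_prop(p);
      double hop_tot = (b < immobilize_threshold)
        ? hopP * ((i > 0) + (i < n - 1)) : 0.0;
      double bind = (b < max_bound) ? k_AB * A[i] : 0.0;
      if (u < hop_tot) {                  // plasmid hop
        int j;
        if (i == 0) j = 1;
        else if (i == n - 1) j = n - 2;
        else j = (u < hop_tot / 2) ? i - 1 : i + 1;
        psite[p] = j;
        upd_plasmid(p);
      } else if (u < hop_tot + bind) {    // ParA-ATP -> plasmid binding
        --A[i]; ++pbound[p];
        if (pbound[p] > max_bound) stop("plasmid bound count exceeded maximum");
        upd_col(i);
        for (size_t q = 0; q < psite.size(); ++q)
          if (psite[q] == i) upd_plasmid((int)q);
      } else {                            // bound hydrolysis k_B
        --pbound[p]; ++A_ADP;
        if (pbound[p] < 0) stop("plasmid bound count underflow");
        upd_plasmid(p); upd_globals();
      }
    } else if (c == ncap + pcap) {        // k_W maturation
      --A_ADP; ++A_CYTO;
      if (A_ADP < 0) stop("ParA-ADP count underflow");
      upd_globals();
    } else {                              // k_on nucleoid binding
      --A_CYTO;
      if (A_CYTO < 0) stop("cytoplasmic ParA-ATP count underflow");
      int i = rng_int(n);
      ++A[i];
      upd_col(i); upd_globals();
      for (size_t p = 0; p < psite.size(); ++p)
        if (psite[p] == i) upd_plasmid((int)p);
    }
  }

  void grow() {
    int pos = rng_int(n + 1);             // insert before index pos
    A.insert(A.begin() + pos, 2, 0);
    n += 2;
    for (size_t p = 0; p < psite.size(); ++p)
      if (psite[p] >= pos) psite[p] += 2;
    if (density_per_um > 0) {
      long long target = (long long)std::llround(density_per_um * n * dx);
      long long deficit = target - total_parA();
      if (deficit > 0) A_ADP += deficit;
    }
    rebuild();
  }

  void duplicate() {
    if (psite.empty()) stop("cannot duplicate: no plasmid present");
    int k = rng_int((int)psite.size());
    psite.push_back(psite[k]);
    pbound.push_back(0);
    if ((int)psite.size() > pcap) stop("plasmid capacity exceeded");
    rebuild();
  }
};

// ---------------------------------------------------------------------------
// Directed-motion polymer model (thin 2d strip lattice)
// ---------------------------------------------------------------------------

struct DMModel {
  double dx, D_A, D_P, k_on, k_B, k_mB, k_W, k_dm, k_p, k_dp;
  bool wall;
  double leak;
  double density_per_um;
  double hopA, hopP;

  int n, S;                               // long-axis columns, short-axis rows
  std::vector<int> m;                     // mobile counts, column-major [i*S+j]
  std::vector<char> poly;                 // polymeric occupancy 0/1
  std::vector<int> polycol;               // per-column polymeric subunit count
  std::vector<int> pcount;                // plasmids per column
  std::vector<int> psite;                 // plasmid column (0-based)
  long long A_ADP, A_CYTO;

  int ncap, pcap;
  SumTree tree;

  long long total_parA() const {
    long long s = A_ADP + A_CYTO;
    for (int k = 0; k < n * S; ++k) s += m[k] + poly[k];
    return s;
  }

  // Long-axis crossing factor for a mobile hop a -> b. A plasmid column is
  // a hard wall in the wild type: molecules may hop into it (where the
  // ParB-parC complex hydrolyzes them at k_mB) but not out, so nothing
  // diffuses past. In the perturbed-nucleoid variants the wall is off and
  // boundary hops run at leak * the normal rate in both directions.
  double cross(int a, int b) const {
    bool pa = pcount[a] > 0, pb = pcount[b] > 0;
    if (!pa && !pb) return 1.0;
    if (wall) return pa ? 0.0 : 1.0;
    return leak;
  }

  double col_prop(int i) const {
    double a = 0.0;
    bool haspl = pcount[i] > 0;
    double cl = (i > 0) ? cross(i, i - 1) : 0.0;
    double cr = (i < n - 1) ? cross(i, i + 1) : 0.0;
    for (int j = 0; j < S; ++j) {
      int k = i * S + j;
      int mm = m[k];
      if (mm > 0) {
        double dirs = cl + cr + (j > 0) + (j < S - 1);
        a += mm * hopA * dirs;
        if (haspl) a += k_mB * mm;
        // nucleation anchored at (i -> i+1)
        if (i < n - 1 && !poly[k] && !poly[k + S] && m[k + S] > 0)
          a += k_p * (double)mm * m[k + S];
        if (!poly[k]) {
          // elongation of a tip at i-1 (polymer occupying i-1, i-2)
          if (i >= 2 && poly[k - S] && poly[k - 2 * S]) a += k_p * mm;
          // elongation of a tip at i+1 (polymer occupying i+1, i+2)
          if (i <= n - 3 && poly[k + S] && poly[k + 2 * S]) a += k_p * mm;
        }
      }
      if (poly[k]) {
        a += k_dp;
        if (haspl) a += k_B;
      }
    }
    return a;
  }

  double plasmid_prop(int p) const {
    int i = psite[p];
    double a = 0.0;
    int blocked = polycol[i] + (i > 0 ? polycol[i - 1] : 0) +
                  (i < n - 1 ? polycol[i + 1] : 0);
    if (blocked == 0) a += hopP * ((i > 0) + (i < n - 1));
    if (i > 0) a += k_dm * polycol[i - 1];
    if (i < n - 1) a += k_dm * polycol[i + 1];
    return a;
  }

  void upd_col(int i) { if (i >= 0 && i < n) tree.set(i, col_prop(i)); }
  void upd_cols_around(int i) { for (int c = i - 3; c <= i + 3; ++c) upd_col(c); }
  // After a change to the mobile count at column x only (no polymer or
  // plasmid change), the affected column channels are x-1 (nucleation
  // anchor) and x itself.
  void upd_mobile_at(int x) { upd_col(x - 1); upd_col(x); }
  void upd_all_plasmids() {
    for (size_t p = 0; p < psite.size(); ++p)
      tree.set(ncap + (int)p, plasmid_prop((int)p));
  }
  void upd_globals() {
    tree.set(ncap + pcap, k_W * (double)A_ADP);
    tree.set(ncap + pcap + 1, k_on * (double)A_CYTO);
  }
  void rebuild() {
    tree.init(ncap + pcap + 2);
    for (int i = 0; i < n; ++i) tree.set(i, col_prop(i));
    upd_all_plasmids();
    upd_globals();
  }

  // Remove a polymeric subunit at (i, j); caller decides where the mass
  // goes. A polymer has >= 2 subunits by the nucleation definition, so a
  // surviving isolated subunit is reclassified as mobile at its own site.
  void remove_subunit(int i, int j, bool to_mobile) {
    int k = i * S + j;
    poly[k] = 0; --polycol[i];
    if (to_mobile) ++m[k]; else ++A_ADP;
    for (int s = -1; s <= 1; s += 2) {
      int x = i + s;
      if (x < 0 || x >= n) continue;
      int kx = x * S + j;
      if (poly[kx]) {
        bool left = (x > 0) && poly[kx - S];
        bool right = (x < n - 1) && poly[kx + S];
        if (!left && !right) {            // isolated singleton -> mobile
          poly[kx] = 0; --polycol[x]; ++m[kx];
        }
      }
    }
  }

  void fire(int c) {
    if (c < ncap) {
      int i = c;
      double u = rng_u() * col_prop(i);
      bool haspl = pcount[i] > 0;
      double cl = (i > 0) ? cross(i, i - 1) : 0.0;
      double cr = (i < n - 1) ? cross(i, i + 1) : 0.0;
      for (int j = 0; j < S; ++j) {
        int k = i * S + j;
        int mm = m[k];
        if (mm > 0) {
          double aL = mm * hopA * cl, aR = mm * hopA * cr;
          double aU = mm * hopA * (j > 0 ? 1.0 : 0.0);
          double aD = mm * hopA * (j < S - 1 ? 1.0 : 0.0);
          if (u < aL) { --m[k]; ++m[k - S]; upd_mobile_at(i); upd_col(i - 2); return; }
          u -= aL;
          if (u < aR) { --m[k]; ++m[k + S]; upd_mobile_at(i); upd_col(i + 1); return; }
          u -= aR;
          if (u < aU) { --m[k]; ++m[k - 1]; upd_mobile_at(i); return; }
          u -= aU;
          if (u < aD) { --m[k]; ++m[k + 1]; upd_mobile_at(i); return; }
          u -= aD;
          if (haspl) {
            double aH = k_mB * mm;
            if (u < aH) {                 // mobile hydrolysis at plasmid
              --m[k]; ++A_ADP;
              upd_mobile_at(i); upd_globals();
              return;
            }
            u -= aH;
          }
          if (i < n - 1 && !poly[k] && !poly[k + S] && m[k + S] > 0) {
            double aN = k_p * (double)mm * m[k + S];
            if (u < aN) {                 // nucleation: two subunits form
              --m[k]; --m[k + S];
              poly[k] = 1; poly[k + S] = 1;
              ++polycol[i]; ++polycol[i + 1];
              upd_cols_around(i); upd_all_plasmids();
              return;
            }
            u -= aN;
          }
          if (!poly[k]) {
            if (i >= 2 && poly[k - S] && poly[k - 2 * S]) {
              double aE = k_p * mm;
              if (u < aE) {               // elongation towards the left tip
                --m[k]; poly[k] = 1; ++polycol[i];
                upd_cols_around(i); upd_all_plasmids();
                return;
              }
              u -= aE;
            }
            if (i <= n - 3 && poly[k + S] && poly[k + 2 * S]) {
              double aE = k_p * mm;
              if (u < aE) {
                --m[k]; poly[k] = 1; ++polycol[i];
                upd_cols_around(i); upd_all_plasmids();
                return;
              }
              u -= aE;
            }
          }
        }
        if (poly[k]) {
          if (u < k_dp) {                 // spontaneous depolymerization
            remove_subunit(i, j, true);
            upd_cols_around(i); upd_all_plasmids();
            return;
          }
          u -= k_dp;
          if (haspl) {
            if (u < k_B) {                // polymeric hydrolysis at plasmid
              remove_subunit(i, j, false);
              upd_cols_around(i); upd_all_plasmids(); upd_globals();
              return;
            }
            u -= k_B;
          }
        }
      }
      // Floating-point slack: re-fire deterministically on the first
      // available sub-reaction is avoided by treating this as a no-op.
      upd_col(i);
    } else if (c < ncap + pcap) {
      int p = c - ncap, i = psite[p];
      double u = rng_u() * plasmid_prop(p);
      int blocked = polycol[i] + (i > 0 ? polycol[i - 1] : 0) +
                    (i < n - 1 ? polycol[i + 1] : 0);
      double hop_tot = (blocked == 0) ? hopP * ((i > 0) + (i < n - 1)) : 0.0;
      if (u < hop_tot) {                  // free plasmid diffusion
        int jto;
        if (i == 0) jto = 1;
        else if (i == n - 1) jto = n - 2;
        else jto = (u < hop_tot / 2) ? i - 1 : i + 1;
        --pcount[i]; ++pcount[jto];
        psite[p] = jto;
        upd_cols_around(i); upd_cols_around(jto); upd_all_plasmids();
        return;
      }
      u -= hop_tot;
      // directed step: pick the side, then a random subunit row there
      int target = -1;
      if (i > 0 && u < k_dm * polycol[i - 1]) target = i - 1;
      else target = i + 1;
      if (target < 0 || target >= n || polycol[target] == 0) { upd_all_plasmids(); return; }
      int pick = rng_int(polycol[target]);
      for (int j = 0; j < S; ++j) {
        if (poly[target * S + j]) {
          if (pick == 0) {
            remove_subunit(target, j, false);   // subunit -> ParA-ADP
            break;
          }
          --pick;
        }
      }
      --pcount[i]; ++pcount[target];
      psite[p] = target;
      upd_cols_around(i); upd_cols_around(target);
      upd_all_plasmids(); upd_globals();
    } else if (c == ncap + pcap) {
      --A_ADP; ++A_CYTO;
      if (A_ADP < 0) stop("ParA-ADP count underflow");
      upd_globals();
    } else {
      --A_CYTO;
      if (A_CYTO < 0) stop("cytoplasmic ParA-ATP count underflow");
      int i = rng_int(n), j = rng_int(S);
      ++m[i * S + j];
      upd_mobile_at(i); upd_globals();
    }
  }

  void grow() {
    int pos = rng_int(n + 1);
    m.insert(m.begin() + (size_t)pos * S, 2 * S, 0);
    poly.insert(poly.begin() + (size_t)pos * S, 2 * S, 0);
    polycol.insert(polycol.begin() + pos, 2, 0);
    pcount.insert(pcount.begin() + pos, 2, 0);
    n += 2;
    for (size_t p = 0; p < psite.size(); ++p)
      if (psite[p] >= pos) psite[p] += 2;
    // An insertion inside a polymer run splits it; clean up singletons on
    // both cut faces.
    for (int side = 0; side < 2; ++side) {
      int x = side == 0 ? pos - 1 : pos + 2;
      if (x < 0 || x >= n) continue;
      for (int j = 0; j < S; ++j) {
        int kx = x * S + j;
        if (poly[kx]) {
          bool left = (x > 0) && poly[kx - S];
          bool right = (x < n - 1) && poly[kx + S];
          if (!left && !right) { poly[kx] = 0; --polycol[x]; ++m[kx]; }
        }
      }
    }
    if (density_per_um > 0) {
      long long target = (long long)std::llround(density_per_um * n * dx);
      long long deficit = target - total_parA();
      if (deficit > 0) A_ADP += deficit;
    }
    rebuild();
  }

  void duplicate() {
    if (psite.empty()) stop("cannot duplicate: no plasmid present");
    int k = rng_int((int)psite.size());
    psite.push_back(psite[k]);
    ++pcount[psite[k]];
    if ((int)psite.size() > pcap) stop("plasmid capacity exceeded");
    rebuild();
  }

  // Mean polymer length (runs of >= 2 consecutive polymeric sites per row).
  double mean_polymer_length() const {
    long long tot = 0; int nruns = 0;
    for (int j = 0; j < S; ++j) {
      int run = 0;
      for (int i = 0; i <= n; ++i) {
        bool p = (i < n) && poly[i * S + j];
        if (p) ++run;
        else if (run > 0) { tot += run; ++nruns; run = 0; }
      }
    }
    return nruns ? (double)tot / nruns : NA_REAL;
  }
};

// helpers specialized per model ---------------------------------------------

inline int di_bound(const DIModel &m, int p) { return m.pbound[p]; }
inline int di_bound(const DMModel &, int) { return NA_INTEGER; }

inline void record_kymo_row(const DIModel &m, double t,
                            std::vector<double> &kt, std::vector<int> &ks,
                            std::vector<int> &km, std::vector<int> &kp) {
  for (int i = 0; i < m.n; ++i) {
    kt.push_back(t); ks.push_back(i + 1);
    km.push_back(m.A[i]); kp.push_back(0);
  }
}
inline void record_kymo_row(const DMModel &m, double t,
                            std::vector<double> &kt, std::vector<int> &ks,
                            std::vector<int> &km, std::vector<int> &kp) {
  for (int i = 0; i < m.n; ++i) {
    int ms = 0;
    for (int j = 0; j < m.S; ++j) ms += m.m[i * m.S + j];
    kt.push_back(t); ks.push_back(i + 1);
    km.push_back(ms); kp.push_back(m.polycol[i]);
  }
}

inline double dm_polylen(const DIModel &) { return NA_REAL; }
inline double dm_polylen(const DMModel &m) { return m.mean_polymer_length(); }

// ---------------------------------------------------------------------------
// Shared driver: interleave SSA steps with scheduled events.
// ---------------------------------------------------------------------------

template <typename M>
static List run_model(M &mod, double T, double growth_interval,
                      NumericVector duplication_times, double output_interval,
                      bool record_kymo, bool is_dm) {
  double t = 0.0, t_end = T;
  double next_growth = std::isfinite(growth_interval) ? growth_interval : R_PosInf;
  double next_out = 0.0;                  // sample at t = 0 as well
  std::vector<double> dup(duplication_times.begin(), duplication_times.end());
  std::sort(dup.begin(), dup.end());
  size_t dup_i = 0;

  std::vector<double> out_t, out_pos;
  std::vector<int> out_pl, out_site, out_bound;
  std::vector<double> kymo_t;
  std::vector<int> kymo_site, kymo_mobile, kymo_poly;
  std::vector<double> poly_mean_t, poly_mean;
  std::vector<double> cyto_t;
  std::vector<long long> cyto_adp, cyto_atp, tot_parA;
  std::vector<int> out_nlong;

  long long expected = mod.total_parA();
  long long n_events = 0;

  mod.rebuild();
  for (;;) {
    double a0 = mod.tree.total();
    double tau = (a0 > 0) ? -std::log(rng_u()) / a0 : R_PosInf;
    double t_dup = dup_i < dup.size() ? dup[dup_i] : R_PosInf;
    double t_sched = std::min(std::min(next_out, next_growth),
                              std::min(t_dup, t_end));
    if (t + tau >= t_sched) {
      t = t_sched;
      bool done = false;
      if (t >= t_end) done = true;
      if (t == next_out || done) {
        // conservation audit at every sample
        if (mod.total_parA() != expected)
          stop("ParA mass conservation violated at t=%f", t);
        for (size_t p = 0; p < mod.psite.size(); ++p) {
          out_t.push_back(t);
          out_pl.push_back((int)p + 1);
          out_site.push_back(mod.psite[p] + 1);
          out_pos.push_back((mod.psite[p] + 0.5) * mod.dx);
          out_bound.push_back(di_bound(mod, (int)p));
        }
        cyto_t.push_back(t);
        cyto_adp.push_back(mod.A_ADP);
        cyto_atp.push_back(mod.A_CYTO);
        tot_parA.push_back(mod.total_parA());
        out_nlong.push_back(mod.n);
        if (record_kymo) record_kymo_row(mod, t, kymo_t, kymo_site,
                                         kymo_mobile, kymo_poly);
        if (is_dm) {
          poly_mean_t.push_back(t);
          poly_mean.push_back(dm_polylen(mod));
        }
        if (!done) next_out += output_interval;
      }
      if (done) break;
      if (t == next_growth) {
        mod.grow();
        expected = mod.total_parA();
        next_growth += growth_interval;
      }
      while (dup_i < dup.size() && dup[dup_i] <= t) {
        mod.duplicate();
        ++dup_i;
      }
    } else {
      t += tau;
      double u = rng_u() * a0;
      mod.fire(mod.tree.sample(u));
      ++n_events;
      if ((n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(
    _["trajectory"] = DataFrame::create(
      _["t"] = out_t, _["plasmid"] = out_pl, _["site"] = out_site,
      _["pos_um"] = out_pos, _["bound"] = out_bound),
    _["pools"] = DataFrame::create(
      _["t"] = cyto_t,
      _["A_ADP"] = NumericVector(cyto_adp.begin(), cyto_adp.end()),
      _["A_CYTO"] = NumericVector(cyto_atp.begin(), cyto_atp.end()),
      _["total_parA"] = NumericVector(tot_parA.begin(), tot_parA.end()),
      _["n_long"] = out_nlong),
    _["n_events"] = (double)n_events,
    _["n_long"] = mod.n);
  if (record_kymo) {
    out["kymograph"] = DataFrame::create(
      _["t"] = kymo_t, _["site"] = kymo_site,
      _["mobile"] = kymo_mobile, _["polymer"] = kymo_poly);
  }
  if (is_dm) {
    out["polymer_length"] = DataFrame::create(
      _["t"] = poly_mean_t, _["mean_length"] = poly_mean);
  }
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_di(int n_long, double dx,
                     IntegerVector mobile,
                     IntegerVector plasmid_site, IntegerVector plasmid_bound,
                     double A_ADP, double A_CYTO,
                     double D_A, double D_P, double k_on, double k_AB,
                     double k_B, double k_W, double k_off,
                     int max_bound, int immobilize_threshold,
                     double density_per_um,
                     double T, double growth_interval,
                     NumericVector duplication_times,
                     double output_interval, bool record_kymo) {
  DIModel mod;
  mod.dx = dx; mod.D_A = D_A; mod.D_P = D_P; mod.k_on = k_on;
  mod.k_AB = k_AB; mod.k_B = k_B; mod.k_W = k_W; mod.k_off = k_off;
  mod.max_bound = max_bound; mod.immobilize_threshold = immobilize_threshold;
  mod.density_per_um = density_per_um;
  mod.hopA = D_A / (dx * dx); mod.hopP = D_P / (dx * dx);
  mod.n = n_long;
  mod.A.assign(mobile.begin(), mobile.end());
  mod.psite.assign(plasmid_site.begin(), plasmid_site.end());
  for (size_t p = 0; p < mod.psite.size(); ++p) --mod.psite[p];  // 0-based
  mod.pbound.assign(plasmid_bound.begin(), plasmid_bound.end());
  mod.A_ADP = (long long)A_ADP; mod.A_CYTO = (long long)A_CYTO;
  int n_grow = std::isfinite(growth_interval)
    ? (int)std::floor(T / growth_interval) + 1 : 0;
  mod.ncap = n_long + 2 * n_grow + 2;
  mod.pcap = (int)mod.psite.size() + duplication_times.size() + 1;

  RNGScope scope;
  return run_model(mod, T, growth_interval, duplication_times,
                   output_interval, record_kymo, false);
}

// [[Rcpp::export]]
List cpp_simulate_dm(int n_long, int n_short, double dx,
                     IntegerVector mobile, IntegerVector polymer,
                     IntegerVector plasmid_site,
                     double A_ADP, double A_CYTO,
                     double D_A, double D_P, double k_on, double k_B,
                     double k_mB, double k_W, double k_dm, double k_p,
                     double k_dp, bool wall, double leak,
                     double density_per_um,
                     double T, double growth_interval,
                     NumericVector duplication_times,
                     double output_interval, bool record_kymo) {
  DMModel mod;
  mod.dx = dx; mod.D_A = D_A; mod.D_P = D_P; mod.k_on = k_on;
  mod.k_B = k_B; mod.k_mB = k_mB; mod.k_W = k_W; mod.k_dm = k_dm;
  mod.k_p = k_p; mod.k_dp = k_dp; mod.wall = wall; mod.leak = leak;
  mod.density_per_um = density_per_um;
  mod.hopA = D_A / (dx * dx); mod.hopP = D_P / (dx * dx);
  mod.n = n_long; mod.S = n_short;
  mod.m.assign(mobile.begin(), mobile.end());
  mod.poly.assign(polymer.begin(), polymer.end());
  if ((int)mod.m.size() != n_long * n_short ||
      (int)mod.poly.size() != n_long * n_short)
    stop("mobile/polymer must have n_long * n_short entries");
  mod.polycol.assign(n_long, 0);
  for (int i = 0; i < n_long; ++i)
    for (int j = 0; j < n_short; ++j)
      if (mod.poly[i * n_short + j]) ++mod.polycol[i];
  mod.pcount.assign(n_long, 0);
  mod.psite.assign(plasmid_site.begin(), plasmid_site.end());
  for (size_t p = 0; p < mod.psite.size(); ++p) {
    --mod.psite[p];
    ++mod.pcount[mod.psite[p]];
  }
  mod.A_ADP = (long long)A_ADP; mod.A_CYTO = (long long)A_CYTO;
  int n_grow = std::isfinite(growth_interval)
    ? (int)std::floor(T / growth_interval) + 1 : 0;
  mod.ncap = n_long + 2 * n_grow + 2;
  mod.pcap = (int)mod.psite.size() + duplication_times.size() + 1;

  RNGScope scope;
  return run_model(mod, T, growth_interval, duplication_times,
                   output_interval, record_kymo, true);
}
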