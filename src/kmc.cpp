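// Off-lattice diffusion-reaction kinetic Monte Carlo core for 2D
// membrane-protein clustering.
//
// Geometry: each molecule is a rigid rod of `n_dom` collinear discs of
// radius `site_radius` (1.5 nm), lying in the membrane plane; the first
// disc is the EC1 (N-terminal) domain, whose centre is the molecule's
// position, and the rod extends opposite the orientation vector. A
// cis-donor site sits on the EC1 surface at +90 deg from the rod axis and
// a cis-acceptor site at -90 deg (opposing sides).
//
// Bonds: nonspecific, between EC1 centres within `cutoff_ns` (3.2 nm),
// unpolarized, at most one per pair; specific, donor site to acceptor site
// within `cutoff_sp` (1.2 nm) with relative orientation within `angle_sp`
// (30 deg), at most one outgoing and one incoming per molecule (linear
// oligomers). Formation probability on*dt per eligible pair per step;
// each existing bond breaks with probability off*dt per step.
//
// Moves: every connected cluster takes a rigid Brownian move (translation
// variance 4*D*dt split over x/y, rotation RMS D_rot*dt about the
// centroid); bonded molecules additionally jiggle individually (bonds act
// as flexible tethers, so clusters anneal), subject to the same excluded
// volume and to their bond criteria. Excluded volume rejects any move
// that brings two discs of different molecules closer than one disc
// diameter. Periodic boundary conditions throughout; raw coordinates of a
// cluster are kept contiguous (image-shifted at bond formation) so rigid
// rotation is well defined.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// internal xoshiro256++ RNG, seeded from R's RNG stream: set.seed() fully
// determines the run while avoiding per-event R RNG call overhead
struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  void seed_from_r() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    for (int i = 0; i < 16; ++i) next();
  }
  double runif() {   // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double rnorm() {   // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u = runif(), v = runif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 2.0 * M_PI * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
  int rbinom_small(int n, double p) {
    // waiting-time skipping; n * p is small in all uses here
    if (p <= 0.0 || n <= 0) return 0;
    if (p >= 1.0) return n;
    int count = 0;
    double lq = std::log1p(-p);
    double pos = 0.0;
    for (;;) {
      pos += std::floor(std::log(runif()) / lq) + 1.0;
      if (pos > n) break;
      ++count;
    }
    return count;
  }
};

inline double wrap_min_image(double d, double box) {
  return d - box * std::round(d / box);
}

inline double wrap_angle(double a) {
  const double two_pi = 2.0 * M_PI;
  a -= two_pi * std::floor(a / two_pi);   // [0, 2pi)
  if (a > M_PI) a -= two_pi;
  return a;
}

// linked-list grid over all domain discs (disc id = molecule * n_dom + m)
struct Grid {
  int ncell;
  double cell, box;
  std::vector<int> head, nxt, cell_of;
  void init(int n_entries, double box_, double min_cell) {
    box = box_;
    ncell = std::max(1, (int)std::floor(box / min_cell));
    cell = box / ncell;
    head.assign((size_t)ncell * ncell, -1);
    nxt.assign(n_entries, -1);
    cell_of.assign(n_entries, -1);
  }
  int cell_index(double xr, double yr) const {
    double wx = xr - box * std::floor(xr / box);
    double wy = yr - box * std::floor(yr / box);
    int cx = (int)(wx / cell); if (cx >= ncell) cx = ncell - 1;
    int cy = (int)(wy / cell); if (cy >= ncell) cy = ncell - 1;
    return cy * ncell + cx;
  }
  void insert(int e, double xr, double yr) {
    int c = cell_index(xr, yr);
    cell_of[e] = c;
    nxt[e] = head[c];
    head[c] = e;
  }
  void remove(int e) {
    int c = cell_of[e];
    int h = head[c];
    if (h == e) { head[c] = nxt[e]; return; }
    while (h != -1) {
      if (nxt[h] == e) { nxt[h] = nxt[e]; return; }
      h = nxt[h];
    }
  }
  void move(int e, double xr, double yr) {
    int c = cell_index(xr, yr);
    if (c == cell_of[e]) return;
    remove(e);
    cell_of[e] = c;
    nxt[e] = head[c];
    head[c] = e;
  }
};

struct KmcSystem {
  int n, n_dom;
  double box, spacing;               // disc-centre spacing along the rod
  std::vector<double> x, y, th;      // EC1 raw coords (nm), orientation (rad)
  std::vector<double> shx, shy;      // accumulated box-multiple shifts
  std::vector<double> dxr, dyr;      // disc raw coords, n * n_dom entries
  std::vector<int> spec_out, spec_in;
  std::vector<std::pair<int, int>> ns_bonds;   // i < j
  std::unordered_set<long long> ns_set;
  std::vector<std::vector<int>> adj;           // union adjacency (multigraph)
  std::vector<int> comp;
  std::vector<std::vector<int>> members;
  std::vector<int> free_slots;
  Grid grid;

  void set_discs(int i) {
    if (n_dom == 1) {
      dxr[i] = x[i];
      dyr[i] = y[i];
      return;
    }
    double cs = std::cos(th[i]), sn = std::sin(th[i]);
    for (int m = 0; m < n_dom; ++m) {
      dxr[i * n_dom + m] = x[i] - m * spacing * cs;
      dyr[i * n_dom + m] = y[i] - m * spacing * sn;
    }
  }
  void grid_sync(int i) {
    for (int m = 0; m < n_dom; ++m) {
      int e = i * n_dom + m;
      grid.move(e, dxr[e], dyr[e]);
    }
  }

  long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * n + j;
  }
  bool ns_bonded(int i, int j) const { return ns_set.count(key(i, j)) > 0; }

  void rebuild_component(int start) {
    std::vector<int> olds = members[comp[start]];
    std::vector<char> seen(n, 0);
    std::vector<int> stack;
    bool first = true;
    int reuse = comp[start];
    for (int s : olds) {
      if (seen[s]) continue;
      std::vector<int> grp;
      stack.push_back(s);
      seen[s] = 1;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        grp.push_back(u);
        for (int v : adj[u]) if (!seen[v]) { seen[v] = 1; stack.push_back(v); }
      }
      int cid;
      if (first) { cid = reuse; members[cid] = grp; first = false; }
      else if (!free_slots.empty()) {
        cid = free_slots.back(); free_slots.pop_back();
        members[cid] = grp;
      } else {
        cid = (int)members.size(); members.push_back(grp);
      }
      for (int u : grp) comp[u] = cid;
    }
  }

  void merge_components(int i, int j) {
    int a = comp[i], b = comp[j];
    if (a == b) return;
    // image-shift the smaller component so the new bond is contiguous in
    // raw space; shifts are multiples of the box length
    double dxm = wrap_min_image(x[j] - x[i], box);
    double dym = wrap_min_image(y[j] - y[i], box);
    double sx = (x[i] + dxm) - x[j];
    double sy = (y[i] + dym) - y[j];
    if (members[a].size() < members[b].size()) {
      std::swap(a, b);
      sx = -sx; sy = -sy;
    }
    for (int u : members[b]) {
      x[u] += sx; y[u] += sy;
      shx[u] += sx; shy[u] += sy;
      for (int m = 0; m < n_dom; ++m) {
        dxr[u * n_dom + m] += sx;
        dyr[u * n_dom + m] += sy;
      }
      comp[u] = a;
      members[a].push_back(u);
    }
    members[b].clear();
    free_slots.push_back(b);
  }

  void add_ns_bond(int i, int j) {
    if (i > j) std::swap(i, j);
    ns_bonds.emplace_back(i, j);
    ns_set.insert(key(i, j));
    adj[i].push_back(j);
    adj[j].push_back(i);
    merge_components(i, j);
  }

  void add_spec_bond(int i, int j) {   // donor of i -> acceptor of j
    spec_out[i] = j;
    spec_in[j] = i;
    adj[i].push_back(j);
    adj[j].push_back(i);
    merge_components(i, j);
  }

  void drop_adj(int i, int j) {
    auto rm = [&](int u, int v) {
      auto &av = adj[u];
      for (size_t k = 0; k < av.size(); ++k) {
        if (av[k] == v) { av[k] = av.back(); av.pop_back(); return; }
      }
    };
    rm(i, j); rm(j, i);
  }

  void remove_ns_bond(size_t idx) {
    int i = ns_bonds[idx].first, j = ns_bonds[idx].second;
    ns_set.erase(key(i, j));
    ns_bonds[idx] = ns_bonds.back();
    ns_bonds.pop_back();
    drop_adj(i, j);
    rebuild_component(i);
  }

  void remove_spec_bond(int i) {
    int j = spec_out[i];
    spec_out[i] = -1;
    spec_in[j] = -1;
    drop_adj(i, j);
    rebuild_component(i);
  }
};

}  // namespace

// [[Rcpp::export(name = ".kmc_run_cpp")]]
List kmc_run_cpp(int n, double box, double dt,
                 double D_trans_um2s, double D_rot_deg_ns,
                 double on_ns, double off_ns,
                 double on_sp, double off_sp,
                 double cutoff_ns, double cutoff_sp, double angle_sp_deg,
                 double site_radius, int n_dom, double t_end,
                 int sample_every, int plateau_window, double plateau_tol,
                 bool cluster_d_inverse_n, bool hard_core,
                 bool internal_moves, bool intercluster_only,
                 int rxn_every, double min_run_time) {
  if (n < 1 || box <= 0 || dt <= 0 || n_dom < 1)
    stop("invalid geometry/time step");
  if (rxn_every < 1) rxn_every = 1;
  double dt_rxn = dt * rxn_every;    // reaction sub-sampling interval
  double p_on_ns = on_ns * dt_rxn, p_off_ns = off_ns * dt_rxn;
  double p_on_sp = on_sp * dt_rxn, p_off_sp = off_sp * dt_rxn;
  if (p_on_ns > 1 || p_off_ns > 1 || p_on_sp > 1 || p_off_sp > 1)
    stop("rate * reaction interval exceeds 1; reduce dt or rxn_every");

  Xoshiro rng;
  rng.seed_from_r();

  if (!hard_core) n_dom = 1;   // rod discs only matter for excluded volume
  KmcSystem S;
  S.n = n; S.n_dom = n_dom; S.box = box;
  S.spacing = 2.0 * site_radius;
  S.x.resize(n); S.y.resize(n); S.th.resize(n);
  S.shx.assign(n, 0.0); S.shy.assign(n, 0.0);
  S.dxr.resize((size_t)n * n_dom); S.dyr.resize((size_t)n * n_dom);
  S.spec_out.assign(n, -1); S.spec_in.assign(n, -1);
  S.adj.assign(n, {});
  S.comp.resize(n);
  S.members.assign(n, {});

  double hc_dist = 2.0 * site_radius;          // disc contact distance
  double hc2 = hc_dist * hc_dist;
  double reach = std::max(cutoff_ns, 2.0 * site_radius + cutoff_sp);
  reach = std::max(reach, hc_dist);
  S.grid.init(n * n_dom, box, reach);

  // random initial placement with excluded-volume rejection and retries
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int attempt = 0; attempt < 5000 && !placed; ++attempt) {
      S.x[i] = rng.runif() * box;
      S.y[i] = rng.runif() * box;
      S.th[i] = rng.runif() * 2.0 * M_PI;
      S.set_discs(i);
      bool ok = true;
      if (hard_core) {
        for (int j = 0; j < i && ok; ++j) {
          for (int mi = 0; mi < n_dom && ok; ++mi) {
            for (int mj = 0; mj < n_dom && ok; ++mj) {
              double ddx = wrap_min_image(
                S.dxr[j * n_dom + mj] - S.dxr[i * n_dom + mi], box);
              double ddy = wrap_min_image(
                S.dyr[j * n_dom + mj] - S.dyr[i * n_dom + mi], box);
              if (ddx * ddx + ddy * ddy < hc2) ok = false;
            }
          }
        }
      }
      placed = ok;
    }
    if (!placed) stop("placement failure: box too crowded");
    S.comp[i] = i;
    S.members[i] = {i};
  }
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < n_dom; ++m) {
      int e = i * n_dom + m;
      S.grid.insert(e, S.dxr[e], S.dyr[e]);
    }
  std::vector<double> x0(S.x), y0(S.y);      // initial positions

  double D_nm = D_trans_um2s * 1e6;            // nm^2/s
  double sd_xy_mono = std::sqrt(2.0 * D_nm * dt);
  double sd_th = D_rot_deg_ns * (dt * 1e9) * M_PI / 180.0;
  double cut_ns2 = cutoff_ns * cutoff_ns;
  double cut_sp2 = cutoff_sp * cutoff_sp;
  double angle_sp = angle_sp_deg * M_PI / 180.0;
  double pair_reach2 = reach * reach;

  long long max_steps = (long long)std::llround(t_end / dt);
  long long min_steps = (long long)std::llround(min_run_time / dt);
  if (sample_every < 1) sample_every = 1;

  std::vector<double> tr_time, tr_mean;
  std::vector<int> sizes_flat, sizes_len;
  std::vector<int> compsize_mol;
  long long invariant_violations = 0;

  struct Cand { int type; int i; int j; };     // 0 = nonspecific, 1 = specific
  std::vector<Cand> cands;
  cands.reserve(256);
  std::vector<int> unit_ids;
  std::vector<double> px, py, pdx, pdy;        // proposed poses and discs

  // would disc at (wx, wy) belonging to `mol` overlap any disc of a
  // molecule for which skip(owner) is false?
  auto disc_overlaps = [&](double wx, double wy, int mol,
                           const std::vector<char> &in_unit) -> bool {
    int ci = S.grid.cell_index(wx, wy);
    int cx = ci % S.grid.ncell, cy = ci / S.grid.ncell;
    for (int ox = -1; ox <= 1; ++ox) {
      for (int oy = -1; oy <= 1; ++oy) {
        int gx = (cx + ox + S.grid.ncell) % S.grid.ncell;
        int gy = (cy + oy + S.grid.ncell) % S.grid.ncell;
        for (int e = S.grid.head[gy * S.grid.ncell + gx]; e != -1;
             e = S.grid.nxt[e]) {
          int owner = e / n_dom;
          if (owner == mol || (!in_unit.empty() && in_unit[owner])) continue;
          double ddx = wrap_min_image(S.dxr[e] - wx, box);
          double ddy = wrap_min_image(S.dyr[e] - wy, box);
          if (ddx * ddx + ddy * ddy < hc2) return true;
        }
      }
    }
    return false;
  };
  std::vector<char> no_unit;                   // empty = only self skipped
  std::vector<char> in_unit(n, 0);

  // does molecule i at pose (nx, ny, nth) satisfy all its bond criteria?
  auto bonds_ok = [&](int i, double nx, double ny, double nth) -> bool {
    for (int v : S.adj[i]) {
      double dx = wrap_min_image(S.x[v] - nx, box);
      double dy = wrap_min_image(S.y[v] - ny, box);
      if (S.ns_bonded(i, v)) {
        if (dx * dx + dy * dy > cut_ns2) return false;
      }
      if (S.spec_out[i] == v || S.spec_in[i] == v) {
        if (std::fabs(wrap_angle(nth - S.th[v])) > angle_sp) return false;
        double uxi = -std::sin(nth) * site_radius;
        double uyi = std::cos(nth) * site_radius;
        double uxv = -std::sin(S.th[v]) * site_radius;
        double uyv = std::cos(S.th[v]) * site_radius;
        double ex, ey;
        if (S.spec_out[i] == v) {     // donor_i -> acceptor_v
          ex = dx - uxv - uxi;
          ey = dy - uyv - uyi;
        } else {                      // donor_v -> acceptor_i
          ex = -dx - uxi - uxv;
          ey = -dy - uyi - uyv;
        }
        if (ex * ex + ey * ey > cut_sp2) return false;
      }
    }
    return true;
  };

  bool equilibrated = false;
  long long step = 0;

  for (step = 0; step < max_steps; ++step) {
    // --- diffusion: every connected component moves as one rigid unit ---
    unit_ids.clear();
    for (size_t c = 0; c < S.members.size(); ++c)
      if (!S.members[c].empty()) unit_ids.push_back((int)c);
    for (int cid : unit_ids) {
      auto &m = S.members[cid];
      double sd_xy = sd_xy_mono;
      if (cluster_d_inverse_n && m.size() > 1)
        sd_xy = sd_xy_mono / std::sqrt((double)m.size());
      double dx = rng.rnorm() * sd_xy;
      double dy = rng.rnorm() * sd_xy;
      double dth = rng.rnorm() * sd_th;
      double cx = 0, cy = 0;
      for (int i : m) { cx += S.x[i]; cy += S.y[i]; }
      cx /= m.size(); cy /= m.size();
      double cs = std::cos(dth), sn = std::sin(dth);
      px.resize(m.size()); py.resize(m.size());
      bool reject = false;
      for (size_t k = 0; k < m.size(); ++k) {
        int i = m[k];
        double rx = S.x[i] - cx, ry = S.y[i] - cy;
        px[k] = cx + cs * rx - sn * ry + dx;
        py[k] = cy + sn * rx + cs * ry + dy;
      }
      if (hard_core) {
        for (int i : m) in_unit[i] = 1;
        for (size_t k = 0; k < m.size() && !reject; ++k) {
          int i = m[k];
          double ncs = std::cos(S.th[i] + dth), nsn = std::sin(S.th[i] + dth);
          for (int md = 0; md < n_dom && !reject; ++md) {
            double wx = px[k] - md * S.spacing * ncs;
            double wy = py[k] - md * S.spacing * nsn;
            if (disc_overlaps(wx, wy, i, in_unit)) reject = true;
          }
        }
        for (int i : m) in_unit[i] = 0;
      }
      if (reject) continue;
      for (size_t k = 0; k < m.size(); ++k) {
        int i = m[k];
        S.x[i] = px[k]; S.y[i] = py[k]; S.th[i] += dth;
        S.set_discs(i);
        S.grid_sync(i);
      }
    }

    // --- internal moves: bonds are flexible tethers; bonded molecules
    // jiggle individually subject to excluded volume and bond criteria ---
    if (internal_moves) {
      for (int i = 0; i < n; ++i) {
        if (S.adj[i].empty()) continue;
        double nx2 = S.x[i] + rng.rnorm() * sd_xy_mono;
        double ny2 = S.y[i] + rng.rnorm() * sd_xy_mono;
        double nth = S.th[i] + rng.rnorm() * sd_th;
        if (!bonds_ok(i, nx2, ny2, nth)) continue;
        if (hard_core) {
          double ncs = std::cos(nth), nsn = std::sin(nth);
          bool reject = false;
          for (int md = 0; md < n_dom && !reject; ++md) {
            double wx = nx2 - md * S.spacing * ncs;
            double wy = ny2 - md * S.spacing * nsn;
            if (disc_overlaps(wx, wy, i, no_unit)) reject = true;
          }
          if (reject) continue;
        }
        S.x[i] = nx2; S.y[i] = ny2; S.th[i] = nth;
        S.set_discs(i);
        S.grid_sync(i);
      }
    }

    // periodic re-centring of raw coordinates (keeps clusters contiguous;
    // box-multiple shifts do not change wrapped positions or the grid)
    if ((step & 4095) == 0) {
      for (int cid : unit_ids) {
        auto &m = S.members[cid];
        if (m.empty()) continue;
        double cx = 0, cy = 0;
        for (int i : m) { cx += S.x[i]; cy += S.y[i]; }
        cx /= m.size(); cy /= m.size();
        double sx = -box * std::floor(cx / box);
        double sy = -box * std::floor(cy / box);
        if (sx != 0 || sy != 0) {
          for (int i : m) {
            S.x[i] += sx; S.y[i] += sy;
            S.shx[i] += sx; S.shy[i] += sy;
            for (int md = 0; md < n_dom; ++md) {
              S.dxr[i * n_dom + md] += sx;
              S.dyr[i * n_dom + md] += sy;
            }
          }
        }
      }
    }

    // --- association: EC1-based eligible-pair search on the disc grid ---
    bool do_rxn = (step % rxn_every) == 0;
    cands.clear();
    if (do_rxn) {
    for (int i = 0; i < n; ++i) {
      int e_i = i * n_dom;                     // EC1 disc of i
      int ci = S.grid.cell_of[e_i];
      int cx = ci % S.grid.ncell, cy = ci / S.grid.ncell;
      for (int ox = -1; ox <= 1; ++ox) {
        for (int oy = -1; oy <= 1; ++oy) {
          int gx = (cx + ox + S.grid.ncell) % S.grid.ncell;
          int gy = (cy + oy + S.grid.ncell) % S.grid.ncell;
          for (int e = S.grid.head[gy * S.grid.ncell + gx]; e != -1;
               e = S.grid.nxt[e]) {
            if (e % n_dom != 0) continue;      // only EC1 discs react
            int j = e / n_dom;
            if (j <= i) continue;
            if (intercluster_only && S.comp[i] == S.comp[j]) continue;
            double dx = wrap_min_image(S.x[j] - S.x[i], box);
            double dy = wrap_min_image(S.y[j] - S.y[i], box);
            double d2 = dx * dx + dy * dy;
            if (d2 > pair_reach2) continue;
            if (p_on_ns > 0 && d2 < cut_ns2 && !S.ns_bonded(i, j))
              cands.push_back({0, i, j});
            if (p_on_sp > 0 &&
                std::fabs(wrap_angle(S.th[i] - S.th[j])) < angle_sp) {
              double dxi = -std::sin(S.th[i]) * site_radius;
              double dyi = std::cos(S.th[i]) * site_radius;
              double dxj = -std::sin(S.th[j]) * site_radius;
              double dyj = std::cos(S.th[j]) * site_radius;
              if (S.spec_out[i] < 0 && S.spec_in[j] < 0) {
                double ex = dx - dxj - dxi;    // (r_j - u_j) - (r_i + u_i)
                double ey = dy - dyj - dyi;
                if (ex * ex + ey * ey < cut_sp2) cands.push_back({1, i, j});
              }
              if (S.spec_out[j] < 0 && S.spec_in[i] < 0) {
                double ex = -dx - dxi - dxj;   // (r_i - u_i) - (r_j + u_j)
                double ey = -dy - dyi - dyj;
                if (ex * ex + ey * ey < cut_sp2) cands.push_back({1, j, i});
              }
            }
          }
        }
      }
    }
    }
    // visit candidates in random order (avoids valence ordering bias)
    for (int k = (int)cands.size() - 1; k > 0; --k) {
      int r = (int)std::floor(rng.runif() * (k + 1));
      std::swap(cands[k], cands[r]);
    }
    for (auto &cd : cands) {
      if (intercluster_only && S.comp[cd.i] == S.comp[cd.j]) continue;
      if (cd.type == 0) {
        if (rng.runif() < p_on_ns) S.add_ns_bond(cd.i, cd.j);
      } else {
        if (S.spec_out[cd.i] >= 0 || S.spec_in[cd.j] >= 0) continue;
        if (rng.runif() < p_on_sp) S.add_spec_bond(cd.i, cd.j);
      }
    }

    // --- dissociation: each bond breaks independently ---
    if (do_rxn && !S.ns_bonds.empty() && p_off_ns > 0) {
      int nbreak = rng.rbinom_small((int)S.ns_bonds.size(), p_off_ns);
      for (int b = 0; b < nbreak && !S.ns_bonds.empty(); ++b) {
        int idx = (int)std::floor(rng.runif() * S.ns_bonds.size());
        S.remove_ns_bond(idx);
      }
    }
    if (do_rxn && p_off_sp > 0) {
      int nsp = 0;
      for (int i = 0; i < n; ++i) if (S.spec_out[i] >= 0) ++nsp;
      int nbreak = rng.rbinom_small(nsp, p_off_sp);
      if (nbreak > 0) {
        std::vector<int> donors;
        donors.reserve(nsp);
        for (int i = 0; i < n; ++i) if (S.spec_out[i] >= 0) donors.push_back(i);
        for (int b = 0; b < nbreak && !donors.empty(); ++b) {
          int idx = (int)std::floor(rng.runif() * donors.size());
          S.remove_spec_bond(donors[idx]);
          donors[idx] = donors.back();
          donors.pop_back();
        }
      }
    }

    // --- sampling, trace, plateau detection ---
    if (step % sample_every == 0) {
      // structural invariants: specific-bond valence (in/out degree <= 1,
      // no self bonds, spec_in consistent with spec_out) and cluster
      // partition = connected components of the bond graph
      {
        std::vector<int> indeg(n, 0);
        for (int i = 0; i < n; ++i) {
          int j = S.spec_out[i];
          if (j >= 0) {
            if (j == i || S.spec_in[j] != i) ++invariant_violations;
            if (++indeg[j] > 1) ++invariant_violations;
          }
        }
        std::vector<int> lbl(n, -1);
        std::vector<int> stack;
        int nlbl = 0;
        for (int s0 = 0; s0 < n; ++s0) {
          if (lbl[s0] != -1) continue;
          stack.push_back(s0);
          lbl[s0] = nlbl;
          while (!stack.empty()) {
            int u = stack.back(); stack.pop_back();
            for (int v : S.adj[u]) if (lbl[v] == -1) {
              lbl[v] = nlbl;
              stack.push_back(v);
            }
          }
          ++nlbl;
        }
        for (int i = 0; i < n; ++i)
          for (int v : S.adj[i])
            if (lbl[v] != lbl[i] || S.comp[v] != S.comp[i])
              ++invariant_violations;
        for (int i = 0; i < n; ++i)
          if ((int)S.members[S.comp[i]].size() == 0) ++invariant_violations;
      }
      int ncomp = 0;
      for (auto &m : S.members) if (!m.empty()) ++ncomp;
      tr_time.push_back((step + 1) * dt);
      tr_mean.push_back((double)n / ncomp);
      int len = 0;
      for (auto &m : S.members) {
        if (m.empty()) continue;
        sizes_flat.push_back((int)m.size());
        ++len;
      }
      sizes_len.push_back(len);
      for (int i = 0; i < n; ++i)
        compsize_mol.push_back((int)S.members[S.comp[i]].size());
      int ns_rec = (int)tr_mean.size();
      if (step >= min_steps && ns_rec >= 2 * plateau_window) {
        double m1 = 0, m2 = 0;
        for (int k = ns_rec - plateau_window; k < ns_rec; ++k) m1 += tr_mean[k];
        for (int k = ns_rec - 2 * plateau_window;
             k < ns_rec - plateau_window; ++k) m2 += tr_mean[k];
        m1 /= plateau_window; m2 /= plateau_window;
        if (std::fabs(m1 - m2) / std::max(m2, 1e-12) < plateau_tol) {
          equilibrated = true;
          ++step;
          break;
        }
      }
    }
    if ((step & 16383) == 0) Rcpp::checkUserInterrupt();
  }

  // final configuration (wrapped positions, degrees)
  NumericVector fx(n), fy(n), fth(n);
  for (int i = 0; i < n; ++i) {
    fx[i] = S.x[i] - box * std::floor(S.x[i] / box);
    fy[i] = S.y[i] - box * std::floor(S.y[i] / box);
    double a = S.th[i] * 180.0 / M_PI;
    a -= 360.0 * std::floor(a / 360.0);
    fth[i] = a;
  }
  IntegerVector ns_i(S.ns_bonds.size()), ns_j(S.ns_bonds.size());
  for (size_t b = 0; b < S.ns_bonds.size(); ++b) {
    ns_i[b] = S.ns_bonds[b].first + 1;
    ns_j[b] = S.ns_bonds[b].second + 1;
  }
  IntegerVector so(n);
  for (int i = 0; i < n; ++i) so[i] = S.spec_out[i] + 1;  // 0 = none
  // unwrapped squared displacement from the initial position
  NumericVector disp2(n);
  for (int i = 0; i < n; ++i) {
    double ux = (S.x[i] - S.shx[i]) - x0[i];
    double uy = (S.y[i] - S.shy[i]) - y0[i];
    disp2[i] = ux * ux + uy * uy;
  }

  int n_samples = (int)tr_time.size();
  IntegerMatrix csm(n, n_samples);
  for (int s = 0; s < n_samples; ++s)
    for (int i = 0; i < n; ++i)
      csm(i, s) = compsize_mol[(size_t)s * n + i];

  return List::create(
    _["time"] = wrap(tr_time),
    _["mean_size"] = wrap(tr_mean),
    _["sizes_flat"] = wrap(sizes_flat),
    _["sizes_len"] = wrap(sizes_len),
    _["compsize_mol"] = csm,
    _["x"] = fx, _["y"] = fy, _["orientation"] = fth,
    _["spec_out"] = so, _["ns_i"] = ns_i, _["ns_j"] = ns_j,
    _["disp2"] = disp2,
    _["equilibrated"] = equilibrated,
    _["invariant_violations"] = (double)invariant_violations,
    _["n_steps"] = (double)step,
    _["sample_dt"] = sample_every * dt
  );
}
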