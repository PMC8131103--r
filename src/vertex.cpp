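#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Voronoi/vertex Monte Carlo of a heterogeneous monolayer in a periodic
// square box. Cells are the Voronoi polygons of mobile generator points.
// Per-cell mechanical energy: areal elasticity alpha*(A - A0)^2, contractility
// beta*P^2, and adhesion -1/2 * sum_j gamma(q_i, q_j) * l_ij over cell-cell
// shared edges. Environmental (gap) polygons carry no energy of their own and
// gamma involving them is zero.
//
// The periodic Voronoi polygon of one generator is built by clipping a large
// square with the perpendicular bisectors of nearby generators (periodic
// minimal images; full 3x3 ghost images for small systems), processed in
// order of increasing distance with the standard stop rule: a generator at
// distance d cannot cut the polygon once d > 2 * (max vertex distance).

// labels: 1 = IHOG_RED, 2 = IHOG_GREEN, 3 = HH, 4 = ENV
static inline int type_of(int lab) { return lab <= 2 ? 0 : (lab == 3 ? 1 : 2); }

struct Geom {
  double area = 0.0, perim = 0.0;
  std::vector<int> nb;        // distinct neighbor ids (self-image edges excluded)
  std::vector<double> nblen;  // total shared-edge length per neighbor
};

struct PolyBuf {
  std::vector<double> vx, vy;  // vertex coordinates relative to the generator
  std::vector<int> nb;         // owner of edge (k -> k+1); -2 = initial square
};

struct Cand { double d2, dx, dy; int id; };

struct World {
  int npts = 0;
  double box = 0.0, eps = 0.0;
  std::vector<double> X, Y;
  std::vector<int> lab;
  // uniform grid for candidate gathering
  int nbins = 1; double binw = 1.0;
  std::vector<std::vector<int>> bins;
  std::vector<int> binof;
  double R0 = 1.0;

  void init_grid() {
    R0 = 2.1 * std::sqrt(box * box / std::max(1, npts));
    nbins = std::max(1, (int)std::floor(box / (0.55 * R0)));
    binw = box / nbins;
    bins.assign((size_t)nbins * nbins, {});
    binof.assign(npts, 0);
    for (int i = 0; i < npts; ++i) {
      int b = bin_index(X[i], Y[i]);
      binof[i] = b;
      bins[b].push_back(i);
    }
  }
  int bin_index(double x, double y) const {
    int bx = (int)(x / binw); if (bx >= nbins) bx = nbins - 1; if (bx < 0) bx = 0;
    int by = (int)(y / binw); if (by >= nbins) by = nbins - 1; if (by < 0) by = 0;
    return by * nbins + bx;
  }
  void move_point(int i, double nx, double ny) {
    X[i] = nx; Y[i] = ny;
    int b = bin_index(nx, ny);
    if (b != binof[i]) {
      std::vector<int> &old = bins[binof[i]];
      for (size_t k = 0; k < old.size(); ++k)
        if (old[k] == i) { old[k] = old.back(); old.pop_back(); break; }
      bins[b].push_back(i);
      binof[i] = b;
    }
  }
};

static inline double wrap_coord(double x, double box) {
  x -= box * std::floor(x / box);
  return (x >= box || x < 0) ? 0.0 : x;  // guard the x == box rounding case
}

// Clip convex polygon with half-plane z . d <= |d|^2 / 2. Returns false if
// the plane does not cut.
static bool clip_halfplane(PolyBuf &P, double dx, double dy, int owner,
                           PolyBuf &tmp) {
  const double c = 0.5 * (dx * dx + dy * dy);
  const int n = (int)P.vx.size();
  static std::vector<double> side;
  side.resize(n);
  bool any_out = false, all_out = true;
  for (int k = 0; k < n; ++k) {
    side[k] = P.vx[k] * dx + P.vy[k] * dy - c;
    if (side[k] > 0) any_out = true; else all_out = false;
  }
  if (!any_out) return false;
  if (all_out) stop("degenerate geometry: generator outside its own cell");
  tmp.vx.clear(); tmp.vy.clear(); tmp.nb.clear();
  for (int k = 0; k < n; ++k) {
    int k2 = (k + 1) % n;
    bool in1 = side[k] <= 0, in2 = side[k2] <= 0;
    if (in1) { tmp.vx.push_back(P.vx[k]); tmp.vy.push_back(P.vy[k]); tmp.nb.push_back(P.nb[k]); }
    if (in1 != in2) {
      double t = side[k] / (side[k] - side[k2]);
      tmp.vx.push_back(P.vx[k] + t * (P.vx[k2] - P.vx[k]));
      tmp.vy.push_back(P.vy[k] + t * (P.vy[k2] - P.vy[k]));
      tmp.nb.push_back(in1 ? owner : P.nb[k]);
    }
  }
  P.vx.swap(tmp.vx); P.vy.swap(tmp.vy); P.nb.swap(tmp.nb);
  return true;
}

static double max_r2(const PolyBuf &P) {
  double m = 0.0;
  for (size_t k = 0; k < P.vx.size(); ++k) {
    double r2 = P.vx[k] * P.vx[k] + P.vy[k] * P.vy[k];
    if (r2 > m) m = r2;
  }
  return m;
}

static void gather_grid(const World &w, int i, double R, std::vector<Cand> &out,
                        bool &ok) {
  out.clear();
  const double R2 = R * R;
  int br = (int)std::ceil(R / w.binw);
  if (2 * br + 1 >= w.nbins || R > 0.5 * w.box) { ok = false; return; }
  ok = true;
  int bx = w.binof[i] % w.nbins, by = w.binof[i] / w.nbins;
  for (int oy = -br; oy <= br; ++oy) {
    int yy = (by + oy + w.nbins) % w.nbins;
    for (int ox = -br; ox <= br; ++ox) {
      int xx = (bx + ox + w.nbins) % w.nbins;
      const double hb = 0.5 * w.box;
      for (int q : w.bins[(size_t)yy * w.nbins + xx]) {
        if (q == i) continue;
        double dx = w.X[q] - w.X[i];
        if (dx > hb) dx -= w.box; else if (dx < -hb) dx += w.box;
        double dy = w.Y[q] - w.Y[i];
        if (dy > hb) dy -= w.box; else if (dy < -hb) dy += w.box;
        double d2 = dx * dx + dy * dy;
        if (d2 <= R2) {
          if (d2 < 1e-18) stop("degenerate geometry: duplicate generator points");
          out.push_back({d2, dx, dy, q});
        }
      }
    }
  }
}

static void gather_brute(const World &w, int i, std::vector<Cand> &out) {
  out.clear();
  for (int q = 0; q < w.npts; ++q) {
    for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy) {
      if (q == i && ox == 0 && oy == 0) continue;
      double dx = w.X[q] + ox * w.box - w.X[i];
      double dy = w.Y[q] + oy * w.box - w.Y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 < 1e-18) stop("degenerate geometry: duplicate generator points");
      out.push_back({d2, dx, dy, q});
    }
  }
}

static void finalize_geom(const PolyBuf &P, int self, Geom &g) {
  const int n = (int)P.vx.size();
  if (n < 3) stop("degenerate geometry: polygon with fewer than 3 vertices");
  double a = 0.0, per = 0.0;
  g.nb.clear(); g.nblen.clear();
  for (int k = 0; k < n; ++k) {
    int k2 = (k + 1) % n;
    a += P.vx[k] * P.vy[k2] - P.vx[k2] * P.vy[k];
    double ex = P.vx[k2] - P.vx[k], ey = P.vy[k2] - P.vy[k];
    double l = std::sqrt(ex * ex + ey * ey);
    per += l;
    int o = P.nb[k];
    if (o >= 0 && o != self) {
      bool found = false;
      for (size_t t = 0; t < g.nb.size(); ++t)
        if (g.nb[t] == o) { g.nblen[t] += l; found = true; break; }
      if (!found) { g.nb.push_back(o); g.nblen.push_back(l); }
    }
  }
  g.area = 0.5 * std::fabs(a);
  g.perim = per;
}

static void build_cell(const World &w, int i, Geom &g) {
  static std::vector<Cand> cand;
  static PolyBuf P, tmp;
  double R = w.R0;
  for (;;) {
    bool grid_ok = false;
    if (R <= 0.5 * w.box) gather_grid(w, i, R, cand, grid_ok);
    bool brute = !grid_ok;
    if (brute) gather_brute(w, i, cand);
    std::sort(cand.begin(), cand.end(),
              [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });
    // initial square, half-width H (relative coordinates, generator at origin)
    double H = brute ? w.box : R;
    P.vx = {-H, H, H, -H}; P.vy = {-H, -H, H, H};
    P.nb = {-2, -2, -2, -2};
    double mr2 = max_r2(P);
    for (const Cand &c : cand) {
      if (c.d2 > 4.0 * mr2) break;
      if (clip_halfplane(P, c.dx, c.dy, c.id, tmp)) mr2 = max_r2(P);
    }
    if (brute || 4.0 * mr2 <= R * R) { finalize_geom(P, i, g); return; }
    R *= 1.7;
  }
}

static double gamma_of(int li, int lj, double gII, double gIH, double gHH) {
  int ti = type_of(li), tj = type_of(lj);
  if (ti == 2 || tj == 2) return 0.0;
  if (ti == 0 && tj == 0) return gII;
  if (ti == 1 && tj == 1) return gHH;
  return gIH;
}

// contract_mode: 0 = full polygon perimeter; 1 = free boundary only;
// 2 = shared cell-cell interfaces at half weight (each side of an interface
// carries half its cortical tension, mirroring the 1/2 of the adhesion term)
struct EnergyPars {
  double alpha, beta, A0, gII, gIH, gHH, eps;
  int contract_mode;
};

static double contract_perim(const World &w, int i, const Geom &g,
                             const EnergyPars &ep) {
  if (ep.contract_mode == 0) return g.perim;
  double shared = 0.0;
  for (size_t k = 0; k < g.nb.size(); ++k)
    if (g.nblen[k] >= ep.eps && type_of(w.lab[g.nb[k]]) != 2)
      shared += g.nblen[k];
  double p = (ep.contract_mode == 1) ? g.perim - shared
                                     : g.perim - 0.5 * shared;
  return p > 0 ? p : 0.0;
}

// Total energy: sum of per-cell mechanical terms plus -gamma*l per distinct
// cell-cell edge (the 1/2 in the per-cell form cancels double counting).
static double total_energy(const World &w, const std::vector<Geom> &G,
                           const EnergyPars &ep) {
  double u = 0.0;
  for (int i = 0; i < w.npts; ++i) {
    if (type_of(w.lab[i]) == 2) continue;
    const Geom &g = G[i];
    double pc = contract_perim(w, i, g, ep);
    u += ep.alpha * (g.area - ep.A0) * (g.area - ep.A0) + ep.beta * pc * pc;
    for (size_t k = 0; k < g.nb.size(); ++k) {
      int j = g.nb[k];
      if (j <= i) continue;                 // each unordered edge once
      if (g.nblen[k] < ep.eps) continue;
      u -= gamma_of(w.lab[i], w.lab[j], ep.gII, ep.gIH, ep.gHH) * g.nblen[k];
    }
  }
  return u;
}

// Energy restricted to a set C of (possibly changed) cells: mechanical terms
// of members plus adhesion of every edge touching C, counted once.
static double local_energy(const World &w, const std::vector<int> &C,
                           const std::vector<char> &inC,
                           const std::vector<const Geom *> &G,
                           const EnergyPars &ep) {
  double u = 0.0;
  for (int c : C) {
    if (type_of(w.lab[c]) == 2) continue;
    const Geom &g = *G[c];
    double pc = contract_perim(w, c, g, ep);
    u += ep.alpha * (g.area - ep.A0) * (g.area - ep.A0) + ep.beta * pc * pc;
    for (size_t k = 0; k < g.nb.size(); ++k) {
      int j = g.nb[k];
      double l = g.nblen[k];
      if (l < ep.eps || type_of(w.lab[j]) == 2) continue;
      double gam = gamma_of(w.lab[c], w.lab[j], ep.gII, ep.gIH, ep.gHH);
      u -= inC[j] ? 0.5 * gam * l : gam * l;
    }
  }
  return u;
}

// [[Rcpp::export]]
List vx_tessellate_cpp(NumericVector x, NumericVector y, double box, double eps) {
  World w;
  w.npts = x.size(); w.box = box; w.eps = eps;
  w.X.assign(x.begin(), x.end()); w.Y.assign(y.begin(), y.end());
  w.lab.assign(w.npts, 1);
  w.init_grid();
  std::vector<Geom> G(w.npts);
  for (int i = 0; i < w.npts; ++i) build_cell(w, i, G[i]);
  NumericVector area(w.npts), perim(w.npts);
  std::vector<double> ei, ej, el;
  for (int i = 0; i < w.npts; ++i) {
    area[i] = G[i].area; perim[i] = G[i].perim;
    for (size_t k = 0; k < G[i].nb.size(); ++k) {
      int j = G[i].nb[k];
      if (j > i && G[i].nblen[k] >= eps) {
        ei.push_back(i + 1); ej.push_back(j + 1); el.push_back(G[i].nblen[k]);
      }
    }
  }
  return List::create(_["area"] = area, _["perimeter"] = perim,
                      _["edge_i"] = ei, _["edge_j"] = ej, _["edge_length"] = el);
}

// [[Rcpp::export]]
List vx_energy_cpp(NumericVector x, NumericVector y, IntegerVector labels,
                   double box, double alpha, double beta, double A0,
                   double gII, double gIH, double gHH, double eps,
                   int contract_mode) {
  World w;
  w.npts = x.size(); w.box = box; w.eps = eps;
  w.X.assign(x.begin(), x.end()); w.Y.assign(y.begin(), y.end());
  w.lab.assign(labels.begin(), labels.end());
  w.init_grid();
  std::vector<Geom> G(w.npts);
  for (int i = 0; i < w.npts; ++i) build_cell(w, i, G[i]);
  EnergyPars ep{alpha, beta, A0, gII, gIH, gHH, eps, contract_mode};
  NumericVector e(w.npts);
  for (int i = 0; i < w.npts; ++i) {
    if (type_of(w.lab[i]) == 2) { e[i] = NA_REAL; continue; }
    double pc = contract_perim(w, i, G[i], ep);
    double u = alpha * (G[i].area - A0) * (G[i].area - A0) + beta * pc * pc;
    for (size_t k = 0; k < G[i].nb.size(); ++k) {
      int j = G[i].nb[k];
      if (G[i].nblen[k] < eps) continue;
      u -= 0.5 * gamma_of(w.lab[i], w.lab[j], gII, gIH, gHH) * G[i].nblen[k];
    }
    e[i] = u;
  }
  return List::create(_["cell_energy"] = e,
                      _["total"] = total_energy(w, G, ep));
}

// [[Rcpp::export]]
List vx_simulate_cpp(NumericVector x0, NumericVector y0, IntegerVector labels,
                     double box, double alpha, double beta, double A0,
                     double gII, double gIH, double gHH, double kBT, double eps,
                     double total_steps_d, double burn_in_d,
                     double snapshot_interval_d, int snapshot_count,
                     double max_disp0, double accept_lo, double accept_hi,
                     int adapt_interval, double disp_min, double disp_max,
                     int recompute_interval, int trace_moves, int seed,
                     LogicalVector mobile, int contract_mode, double hop_frac,
                     double swap_frac, double anneal_factor) {
  World w;
  w.npts = x0.size(); w.box = box; w.eps = eps;
  w.X.assign(x0.begin(), x0.end()); w.Y.assign(y0.begin(), y0.end());
  w.lab.assign(labels.begin(), labels.end());
  w.init_grid();
  const long long total_steps = (long long)total_steps_d;
  const long long burn_in = (long long)burn_in_d;
  const long long snap_int = (long long)snapshot_interval_d;
  EnergyPars ep{alpha, beta, A0, gII, gIH, gHH, eps, contract_mode};
  Xoshiro rng((uint64_t)seed);

  std::vector<Geom> cache(w.npts);
  for (int i = 0; i < w.npts; ++i) build_cell(w, i, cache[i]);
  double U = total_energy(w, cache, ep);
  // Gap polygons carry no energy, so their cached geometry is refreshed
  // lazily: a gap point whose polygon changed is only marked stale and
  // rebuilt when it is next selected as the mover. Cell polygons are always
  // kept current.
  std::vector<char> stale(w.npts, 0);

  double max_disp = max_disp0;
  long long win_acc = 0, win_tot = 0, tot_acc = 0;
  std::vector<char> inC(w.npts, 0);
  std::vector<int> C;
  std::vector<Geom> tmp_geom;
  std::vector<const Geom *> Gb(w.npts), Ga(w.npts);

  // outputs
  std::vector<double> cs_snap, cs_id, cs_lab, cs_area, cs_per;
  std::vector<double> es_snap, es_i, es_j, es_li, es_lj, es_len;
  std::vector<double> tr_step, tr_U, tr_rate, tr_disp;
  std::vector<double> mv_dU; std::vector<int> mv_acc;
  int recorded = 0;

  auto record_snapshot = [&](int snap_id) {
    // emitted from cell-side geometry only (gap caches may be stale)
    for (int i = 0; i < w.npts; ++i) {
      if (type_of(w.lab[i]) == 2) continue;
      cs_snap.push_back(snap_id); cs_id.push_back(i + 1);
      cs_lab.push_back(w.lab[i]);
      cs_area.push_back(cache[i].area); cs_per.push_back(cache[i].perim);
      for (size_t k = 0; k < cache[i].nb.size(); ++k) {
        int j = cache[i].nb[k];
        if (cache[i].nblen[k] < eps) continue;
        if (type_of(w.lab[j]) != 2 && j <= i) continue;  // cell pair once
        es_snap.push_back(snap_id); es_i.push_back(i + 1); es_j.push_back(j + 1);
        es_li.push_back(w.lab[i]); es_lj.push_back(w.lab[j]);
        es_len.push_back(cache[i].nblen[k]);
      }
    }
  };

  std::vector<int> movable, cellular;
  for (int i = 0; i < w.npts; ++i) if (mobile[i]) movable.push_back(i);
  for (int i = 0; i < w.npts; ++i) if (type_of(w.lab[i]) != 2) cellular.push_back(i);
  if (movable.empty()) stop("no mobile points");

  // adhesion energy of all cell-cell edges touching cell c, from the cache
  auto adhesion_around = [&](int c) {
    double u = 0.0;
    const Geom &g = cache[c];
    for (size_t k = 0; k < g.nb.size(); ++k) {
      int j = g.nb[k];
      if (g.nblen[k] < eps || type_of(w.lab[j]) == 2) continue;
      u -= gamma_of(w.lab[c], w.lab[j], gII, gIH, gHH) * g.nblen[k];
    }
    return u;
  };

  double kT_cur = kBT;
  for (long long step = 0; step < total_steps; ++step) {
    // geometric annealing: start burn-in at anneal_factor * kBT, reach kBT
    // at the end of burn-in; all snapshots are collected at kBT itself
    if (anneal_factor != 1.0 && burn_in > 0 && step % 1000 == 0) {
      double f = (step >= burn_in) ? 0.0 : 1.0 - (double)step / (double)burn_in;
      kT_cur = kBT * std::pow(anneal_factor, f);
    }
    // identity-exchange move: swap the labels of two cells with different
    // labels. The tessellation is untouched, so dU involves only the
    // adhesion terms around the two cells (the direct p-q edge, if any, is
    // symmetric under the swap). This samples the label field over the
    // current geometry and lets unlike cells trade places without moving
    // through the gap-point gas.
    if (swap_frac > 0.0 && cellular.size() >= 2 && rng.unif() < swap_frac) {
      int a = cellular[rng.unif_int((int)cellular.size())];
      int b = cellular[rng.unif_int((int)cellular.size())];
      if (w.lab[a] != w.lab[b]) {
        double before = adhesion_around(a) + adhesion_around(b);
        std::swap(w.lab[a], w.lab[b]);
        double after = adhesion_around(a) + adhesion_around(b);
        double dU = after - before;
        bool accept = (dU <= 0.0) || (rng.unif() <= std::exp(-dU / kT_cur));
        if ((int)mv_dU.size() < trace_moves) {
          mv_dU.push_back(dU); mv_acc.push_back(accept ? 1 : 0);
        }
        if (accept) { U += dU; ++tot_acc; }
        else std::swap(w.lab[a], w.lab[b]);
      }
      if (recompute_interval > 0 && (step + 1) % recompute_interval == 0) {
        for (int i = 0; i < w.npts; ++i) build_cell(w, i, cache[i]);
        U = total_energy(w, cache, ep);
      }
      if (step >= burn_in && (step - burn_in) % snap_int == 0 &&
          recorded < snapshot_count) {
        ++recorded;
        record_snapshot(recorded);
      }
      continue;
    }
    int p = movable[rng.unif_int((int)movable.size())];
    if (stale[p]) { build_cell(w, p, cache[p]); stale[p] = 0; }
    // two-part symmetric proposal: mostly local displacements (uniform in a
    // disk of radius max_disp, acceptance-tuned) plus an occasional global
    // relocation anywhere in the box, which lets cells exchange between
    // aggregates without diffusing through the gap-point gas.
    bool hop = rng.unif() < hop_frac;
    double ox = w.X[p], oy = w.Y[p];
    double nx, ny;
    if (hop) {
      nx = box * rng.unif();
      ny = box * rng.unif();
    } else {
      double rr = max_disp * std::sqrt(rng.unif());
      double th = 2.0 * M_PI * rng.unif();
      nx = wrap_coord(ox + rr * std::cos(th), box);
      ny = wrap_coord(oy + rr * std::sin(th), box);
    }

    C.clear();
    C.push_back(p); inC[p] = 1;
    for (int j : cache[p].nb) if (!inC[j]) { inC[j] = 1; C.push_back(j); }
    w.move_point(p, nx, ny);
    tmp_geom.resize(1);
    build_cell(w, p, tmp_geom[0]);
    for (int j : tmp_geom[0].nb) if (!inC[j]) { inC[j] = 1; C.push_back(j); }
    tmp_geom.resize(C.size());
    for (size_t k = 1; k < C.size(); ++k)
      if (type_of(w.lab[C[k]]) != 2) build_cell(w, C[k], tmp_geom[k]);
    for (size_t k = 0; k < C.size(); ++k) {
      Gb[C[k]] = &cache[C[k]];
      Ga[C[k]] = &tmp_geom[k];
    }
    // "before" local energy must be evaluated in the pre-move configuration;
    // geometry is already cached, only the set C matters.
    double Ub = local_energy(w, C, inC, Gb, ep);
    double Ua = local_energy(w, C, inC, Ga, ep);
    double dU = Ua - Ub;
    bool accept = (dU <= 0.0) || (rng.unif() <= std::exp(-dU / kT_cur));
    if ((int)mv_dU.size() < trace_moves) {
      mv_dU.push_back(dU); mv_acc.push_back(accept ? 1 : 0);
    }
    if (accept) {
      for (size_t k = 0; k < C.size(); ++k) {
        if (C[k] == p || type_of(w.lab[C[k]]) != 2)
          std::swap(cache[C[k]], tmp_geom[k]);
        else
          stale[C[k]] = 1;
      }
      U += dU;
      ++tot_acc;
      if (!hop) ++win_acc;
    } else {
      w.move_point(p, ox, oy);
    }
    for (int c : C) inC[c] = 0;
    if (!hop) ++win_tot;

    if (adapt_interval > 0 && win_tot >= adapt_interval) {
      double rate = (double)win_acc / (double)win_tot;
      if (rate > accept_hi) max_disp *= 1.1;
      else if (rate < accept_lo) max_disp *= 0.9;
      if (max_disp < disp_min) max_disp = disp_min;
      if (max_disp > disp_max) max_disp = disp_max;
      tr_step.push_back((double)(step + 1)); tr_U.push_back(U);
      tr_rate.push_back(rate); tr_disp.push_back(max_disp);
      win_acc = 0; win_tot = 0;
    }

    if (recompute_interval > 0 && (step + 1) % recompute_interval == 0) {
      for (int i = 0; i < w.npts; ++i) { build_cell(w, i, cache[i]); stale[i] = 0; }
      U = total_energy(w, cache, ep);
    }

    if (step >= burn_in && (step - burn_in) % snap_int == 0 &&
        recorded < snapshot_count) {
      ++recorded;
      record_snapshot(recorded);
    }
  }

  double U_cached = U;
  for (int i = 0; i < w.npts; ++i) build_cell(w, i, cache[i]);
  double U_fresh = total_energy(w, cache, ep);

  return List::create(
    _["cell_snapshot"] = cs_snap, _["cell_id"] = cs_id, _["cell_label"] = cs_lab,
    _["cell_area"] = cs_area, _["cell_perimeter"] = cs_per,
    _["edge_snapshot"] = es_snap, _["edge_i"] = es_i, _["edge_j"] = es_j,
    _["edge_label_i"] = es_li, _["edge_label_j"] = es_lj, _["edge_length"] = es_len,
    _["trace_step"] = tr_step, _["trace_energy"] = tr_U,
    _["trace_accept"] = tr_rate, _["trace_max_disp"] = tr_disp,
    _["move_dU"] = mv_dU, _["move_accepted"] = mv_acc,
    _["final_x"] = NumericVector(w.X.begin(), w.X.end()),
    _["final_y"] = NumericVector(w.Y.begin(), w.Y.end()),
    _["energy_cached"] = U_cached, _["energy_recomputed"] = U_fresh,
    _["accept_rate"] = (double)tot_acc / (double)total_steps,
    _["final_max_disp"] = max_disp, _["n_snapshots"] = recorded);
}

// Absolute-coordinate polygon vertices for rendering tessellations.
// [[Rcpp::export]]
List vx_polygons_cpp(NumericVector x, NumericVector y, double box) {
  World w;
  w.npts = x.size(); w.box = box; w.eps = 0.0;
  w.X.assign(x.begin(), x.end()); w.Y.assign(y.begin(), y.end());
  w.lab.assign(w.npts, 1);
  w.init_grid();
  std::vector<double> pid, px, py;
  Geom g;
  static std::vector<Cand> cand;
  PolyBuf P, tmp;
  for (int i = 0; i < w.npts; ++i) {
    double R = w.R0;
    for (;;) {
      bool grid_ok = false;
      if (R <= 0.5 * w.box) gather_grid(w, i, R, cand, grid_ok);
      bool brute = !grid_ok;
      if (brute) gather_brute(w, i, cand);
      std::sort(cand.begin(), cand.end(),
                [](const Cand &a, const Cand &b) { return a.d2 < b.d2; });
      double H = brute ? w.box : R;
      P.vx = {-H, H, H, -H}; P.vy = {-H, -H, H, H};
      P.nb = {-2, -2, -2, -2};
      double mr2 = max_r2(P);
      for (const Cand &c : cand) {
        if (c.d2 > 4.0 * mr2) break;
        if (clip_halfplane(P, c.dx, c.dy, c.id, tmp)) mr2 = max_r2(P);
      }
      if (brute || 4.0 * mr2 <= R * R) break;
      R *= 1.7;
    }
    for (size_t k = 0; k < P.vx.size(); ++k) {
      pid.push_back(i + 1);
      px.push_back(P.vx[k] + w.X[i]);
      py.push_back(P.vy[k] + w.Y[i]);
    }
  }
  return List::create(_["cell"] = pid, _["x"] = px, _["y"] = py);
}
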