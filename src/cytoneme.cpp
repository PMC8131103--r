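#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// 1-D cytoneme dynamics on a periodic lattice of `surface_length` sites.
// Each simulation step: (1) quasi-equilibrium re-assignment of pairwise
// segment contacts between neighboring cytonemes, (2) synchronous
// elongation/shrinkage of every cytoneme, (3) one Metropolis translocation
// attempt of a randomly chosen cytoneme.
//
// Contact bookkeeping: segments pair level-by-level, so for a neighboring
// pair only levels 1..m (m = min length) exist and the only level that can
// ever be a tip-aligned level is m itself. Per pair we therefore track the
// total established count K and the level-m indicator s_tip, sampled jointly
// as K = s_tip + Binomial(m - 1, p).

struct Pair {
  int i, j;      // cytoneme indices, i < j by construction of the scan
  int K;         // established contacts over levels 1..m
  int s_tip;     // indicator for level m
  bool alive;
};

static inline int wrap(int x, int M) { int r = x % M; return r < 0 ? r + M : r; }

// [[Rcpp::export]]
List cyto_simulate_cpp(IntegerVector positions0, IntegerVector lengths0,
                       int surface_length, double p_elong0, double p_shrink0,
                       double alpha, double eii, double kBT, int neighbor_radius,
                       double total_steps_d, double burn_in_d,
                       double snapshot_interval_d, int snapshot_count,
                       double p_contact_override, bool fixed_lengths, int seed) {
  const int M = surface_length;
  const int n = positions0.size();
  const long long total_steps = (long long)total_steps_d;
  const long long burn_in = (long long)burn_in_d;
  const long long snap_int = (long long)snapshot_interval_d;

  Xoshiro rng((uint64_t)seed);

  std::vector<int> pos(n), len(n), occ(M, -1);
  for (int i = 0; i < n; ++i) {
    pos[i] = positions0[i];
    len[i] = lengths0[i];
    if (occ[pos[i]] != -1) stop("duplicate cytoneme positions");
    occ[pos[i]] = i;
  }

  const double p_int = (p_contact_override >= 0.0)
    ? p_contact_override
    : 1.0 / (1.0 + std::exp(-eii));
  const double q_int = 1.0 - p_int;

  std::vector<Pair> pairs;                 // assignment of the current step
  std::vector<std::vector<int>> by_cyto(n);
  std::vector<int> T(n), site_buf;

  // snapshot output buffers
  std::vector<double> out_snap, out_id, out_pos, out_len, out_con;
  std::vector<double> pr_snap, pr_i, pr_j, pr_K;
  out_snap.reserve((size_t)snapshot_count * n);
  int recorded = 0;

  auto draw_pair = [&](int m, int &K, int &s_tip) {
    s_tip = (rng.unif() < p_int) ? 1 : 0;
    int fails = rng.binom_skip(m - 1, q_int);
    K = s_tip + (m - 1 - fails);
  };

  for (long long step = 0; step < total_steps; ++step) {
    // --- (1) contact assignment -------------------------------------------
    pairs.clear();
    for (int i = 0; i < n; ++i) by_cyto[i].clear();
    for (int i = 0; i < n; ++i) {
      for (int d = 1; d <= neighbor_radius; ++d) {
        int s = wrap(pos[i] + d, M);
        int j = occ[s];
        if (j >= 0 && j != i) {
          int m = std::min(len[i], len[j]);
          Pair p; p.i = i; p.j = j; p.alive = true;
          if (m >= 1) draw_pair(m, p.K, p.s_tip); else { p.K = 0; p.s_tip = 0; }
          int idx = (int)pairs.size();
          pairs.push_back(p);
          by_cyto[i].push_back(idx);
          by_cyto[j].push_back(idx);
        }
      }
    }

    // --- (2) synchronous growth/shrinkage ---------------------------------
    if (!fixed_lengths) {
      for (int i = 0; i < n; ++i) {
        int t = 0;
        for (int idx : by_cyto[i]) {
          const Pair &p = pairs[idx];
          int other = (p.i == i) ? p.j : p.i;
          // tip of i aligns with a segment of `other` only if len[other] >= len[i]
          if (len[i] >= 1 && len[other] >= len[i] && p.s_tip) ++t;
        }
        T[i] = t;
      }
      for (int i = 0; i < n; ++i) {
        double pe = p_elong0 * std::exp(-alpha * len[i]);
        double ps = p_shrink0 * std::exp(-(double)T[i] * eii);
        double r = rng.unif();
        if (len[i] > 0 && r <= ps / (pe + ps)) --len[i]; else ++len[i];
      }
    }

    // --- (3) one translocation attempt ------------------------------------
    {
      int i = rng.unif_int(n);
      int dir = (rng.unif() < 0.5) ? -1 : 1;
      int target = wrap(pos[i] + dir, M);
      if (occ[target] == -1) {
        double K_before = 0.0;
        for (int idx : by_cyto[i]) K_before += pairs[idx].K;
        // tentative neighbor set at the target site (i removed from old site)
        site_buf.clear();
        for (int d = 1; d <= neighbor_radius; ++d) {
          int s1 = wrap(target + d, M), s2 = wrap(target - d, M);
          site_buf.push_back(s1);
          if (s2 != s1) site_buf.push_back(s2);
        }
        std::vector<Pair> fresh;
        double K_after = 0.0;
        for (int s : site_buf) {
          int j = occ[s];
          if (j >= 0 && j != i) {
            int m = std::min(len[i], len[j]);
            Pair p; p.i = std::min(i, j); p.j = std::max(i, j); p.alive = true;
            if (m >= 1) draw_pair(m, p.K, p.s_tip); else { p.K = 0; p.s_tip = 0; }
            fresh.push_back(p);
            K_after += p.K;
          }
        }
        double dE = -eii * (K_after - K_before);
        double r = rng.unif();
        if (dE <= 0.0 || r <= std::exp(-dE / kBT)) {
          occ[pos[i]] = -1; occ[target] = i; pos[i] = target;
          // retire the old pairs of i, install the fresh assignment
          for (int idx : by_cyto[i]) {
            Pair &p = pairs[idx];
            p.alive = false;
            int other = (p.i == i) ? p.j : p.i;
            std::vector<int> &lst = by_cyto[other];
            for (size_t k = 0; k < lst.size(); ++k)
              if (lst[k] == idx) { lst.erase(lst.begin() + k); break; }
          }
          by_cyto[i].clear();
          for (const Pair &p : fresh) {
            int idx = (int)pairs.size();
            pairs.push_back(p);
            by_cyto[p.i].push_back(idx);
            by_cyto[p.j].push_back(idx);
          }
        }
      }
    }

    // --- snapshot ----------------------------------------------------------
    if (step >= burn_in && (step - burn_in) % snap_int == 0 &&
        recorded < snapshot_count) {
      ++recorded;
      for (int i = 0; i < n; ++i) {
        double con = 0.0;
        for (int idx : by_cyto[i]) con += pairs[idx].K;
        out_snap.push_back((double)recorded);
        out_id.push_back((double)(i + 1));
        out_pos.push_back((double)pos[i]);
        out_len.push_back((double)len[i]);
        out_con.push_back(con);
      }
      for (const Pair &p : pairs) {
        if (!p.alive || p.K <= 0) continue;
        pr_snap.push_back((double)recorded);
        pr_i.push_back((double)(std::min(p.i, p.j) + 1));
        pr_j.push_back((double)(std::max(p.i, p.j) + 1));
        pr_K.push_back((double)p.K);
      }
    }
  }

  return List::create(
    _["snapshot"] = out_snap, _["cytoneme"] = out_id, _["position"] = out_pos,
    _["length"] = out_len, _["contacts"] = out_con,
    _["pair_snapshot"] = pr_snap, _["pair_i"] = pr_i, _["pair_j"] = pr_j,
    _["pair_contacts"] = pr_K,
    _["final_positions"] = IntegerVector(pos.begin(), pos.end()),
    _["final_lengths"] = IntegerVector(len.begin(), len.end()),
    _["n_snapshots"] = recorded);
}

// Independent draws of the per-pair established-contact count for a pair with
// m aligned levels at establishment probability p (testing hook).
// [[Rcpp::export]]
IntegerVector cyto_sample_contacts_cpp(int m, double p, int n_draws, int seed) {
  Xoshiro rng((uint64_t)seed);
  IntegerVector out(n_draws);
  double q = 1.0 - p;
  for (int t = 0; t < n_draws; ++t) {
    int s_tip = (rng.unif() < p) ? 1 : 0;
    out[t] = s_tip + (m - 1 - rng.binom_skip(m - 1, q));
  }
  return out;
}
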