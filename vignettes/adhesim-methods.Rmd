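---
title: "Models and methods: cytoneme dynamics and adhesion-driven cell sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cytoneme dynamics and adhesion-driven cell sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(adhesim)
library(dplyr)
```

adhesim implements two seeded stochastic models of how trans cell-surface
interactions shape multicellular structure, together with the summary
statistics used to read their steady states. This vignette is the package's
account of the models, the numerical choices behind them, and what the test
suite does and does not establish.

## 1. The cytoneme lattice model

Cytonemes are thin actin-based protrusions that exchange signaling proteins
(here, the Hedgehog pathway components Ihog and Hh) between cells. The model
reduces a field of cytonemes to vertical filaments of discrete segments
standing on a 1-D periodic lattice of `surface_length` sites (default 100),
one filament per site, 30% of sites occupied. Homophilic trans binding
between the adhesion co-receptor Ihog on neighboring filaments is coarse
grained into a per-segment-pair contact energy `e_ii` (in units of `kbt`).

Per simulation step:

1. **Contact assignment.** For each pair of neighboring cytonemes (base
   sites within `neighbor_radius`, default 1) and each height-aligned
   segment level `k <= min(x_i, x_j)`, a binary contact is drawn with the
   equilibrium occupancy `interaction_prob(e_ii) = exp(e_ii)/(1 + exp(e_ii))`.
   This quasi-equilibrium treatment replaces explicit binding kinetics with
   an independent re-draw each step, which is valid when binding equilibrates
   fast relative to filament growth.
2. **Growth.** Every cytoneme elongates or shrinks by one segment. The
   elongation weight `p_elong0 * exp(-alpha * x)` decays with length
   (transport limitation and membrane tension); the shrinkage weight
   `p_shrink0 * exp(-T * e_ii)` is suppressed by each trans contact `T` at
   the tip segment (contacts are energy barriers to tip retraction). A
   filament of length zero always elongates.
3. **Translocation.** One cytoneme is picked uniformly and proposes a move
   of one site left or right (excluded volume: proposals onto occupied sites
   are rejected). Contacts of the tentative neighborhood are freshly drawn,
   and the move is accepted with the Metropolis probability
   `min(1, exp(-dE/kbt))`, where each established contact lowers the
   configuration energy by `e_ii`.

Defaults follow the study conditions: `p_elong0 = 5`, `p_shrink0 = 0.5`
(weights, not probabilities -- only their normalised ratio enters),
`alpha = 0.2`, 5,000,001 steps, snapshots every 4,000 steps after a
1,000,000-step burn-in (1,001 snapshots).

### Numerical and design choices

* **Contact bookkeeping.** Only the total established count `K` per pair and
  the indicator at the single tip-aligned level (level `min(x_i, x_j)`)
  influence the dynamics, so they are sampled jointly as
  `K = s_tip + Binomial(m - 1, p)` with geometric skipping -- per-step cost
  O(pairs), not O(pairs x levels).
* **Ordering.** The assignment drawn at the start of a step (at pre-growth
  lengths) is used for that step's growth and as the "before" energy of the
  translocation; an accepted translocation installs the freshly drawn
  contacts of the new neighborhood.
* **Ties.** The `<=` in the shrink rule and the Metropolis rule are
  implemented as written; a neighbor of exactly equal length protects the
  tip (its own tip occupies the aligned level).
* **Parity.** Because every filament moves +-1 segment per step, a single
  cytoneme's length parity alternates deterministically. Oracle tests that
  compare length histograms against the stationary law therefore sample at
  an odd snapshot interval; the default 4,000-step interval is immaterial
  for pooled statistics across 30 filaments with random initial phases.

### What the model predicts at steady state

Without trans interactions (`e_ii = 0`) a filament is an isolated
birth-death chain with mean length about 11.5; the package enumerates this
stationary law exactly ([birth_death_stationary()]) and the simulator
reproduces it to total-variation distance below 0.02. With `e_ii = 15`,
neighboring filaments protect each other's tips and grow until elongation
stalls, near `x ~ (e_ii + ln(p_elong0/p_shrink0))/alpha`; pairs and bundles
at length ~86 dominate, lengths and interaction counts rise sharply, and the
bundling index (min length x bundle size for components of the >3-contact
graph) grows with `e_ii`.

One emergent property deserves honesty: under these dynamics, translocation
binding at `e_ii >= 5` is effectively irreversible (unbinding probability
`exp(-e_ii * K)` with `K` large), so by the end of burn-in *every* cytoneme
is absorbed into a bundle and no singular cytonemes remain. The pooled
length-versus-contacts correlation is then driven by the one-versus-two
neighbor split inside bundle chains and settles near 0.6, whereas a
population retaining a singular fraction (short, zero-contact filaments
next to long, contact-rich bundles) would push the pooled Pearson r toward
0.8. Reported correlations near 0.79 are consistent with a steady state
that retains singular cytonemes; a mechanism that would keep them (slower
contact formation, weaker adsorption, finite binding kinetics) is outside
this model's quasi-equilibrium scope. See the limitations section.

## 2. The Voronoi/vertex monolayer model

The second model asks how the *relative strength* of heterotypic (Ihog-Hh)
and homotypic (Ihog-Ihog) trans adhesion shapes a mixed cell aggregate.
Cells are Voronoi polygons of mobile generator points in a periodic
`box_size x box_size` square (default 20 x 20): `n_cells = 100` cellular
points plus `5 x n_cells` environmental points whose polygons are empty
gaps with no mechanical energy. The per-cell energy is

    e_i = area_coeff * (A_i - pref_area)^2
        + contract_coeff * P_c,i^2
        - 1/2 * sum_j gamma(q_i, q_j) * l_ij

with `area_coeff = 500`, `pref_area = 1`, `contract_coeff = 6`, adhesive
line densities `gamma_ii = 0.25`, `gamma_hh = 0` (Hh-expressing cells do not
aggregate on their own) and `gamma_ih` swept; gamma involving a gap polygon
is zero. Metropolis moves displace one point at a time and are accepted with
`min(1, exp(-dU/kbt))`, `kbt = 1`.

### The contractile perimeter: a deliberate design choice

`P_c,i` is, by default, the *free* portion of the cell boundary -- the edge
length facing gap polygons -- rather than the full polygon perimeter
(`contractility = "free_boundary"`; `"full_perimeter"` and `"shared_half"`,
which weights cell-cell interfaces at half tension, are available). This is
the package's most consequential design decision, so it is worth spelling
out.

With the full perimeter, a cell-cell interface and a cell-gap interface
carry identical cortical cost, and the only drive toward aggregation is the
homotypic adhesion `gamma_ii * l ~ 0.15` per interface -- far below both
`kbt = 1` and the few-kT shape cost of packing. We verified by direct
simulation (at `kbt` from 1 down to 0.02, with mobile and with quenched gap
points) that under the full-perimeter reading a monolayer of Ihog cells
*never* aggregates: cells round up individually inside the gap-point gas,
no gap-free interior cells exist, and honeycomb statistics cannot be
measured. Under the free-boundary reading, cortical tension is borne at the
exposed surface while cell-cell interfaces are tension-balanced -- the
standard differential-interfacial-tension picture of cell sorting -- and
compact aggregates with gap-free interiors form for any adhesion values,
as observed in the aggregation experiments this model mirrors. The printed
coefficients are then quantitatively coherent: ordering *within* an
aggregate is controlled by `(gamma_ih - gamma_ii) * l` against `kbt`, which
switches the mixed pattern from honeycomb-like mixing to a checkerboard at
`gamma_ih : gamma_ii` of a few tens, as reported; in the checkerboard
regime, like-type interfaces are pinched to slivers (mean length ~0.34 at
ratio 30) while unlike interfaces extend (~1.1). The full-perimeter form
remains available and is what the hand-computed toy-tissue energies verify;
`"shared_half"` produces very regular aggregates but its interiors stay
hexagonally packed, which geometrically frustrates a two-type checkerboard
(a triangular adjacency cannot be 2-colored without like contacts), so it is
not the default.

### Monte Carlo kernel and schedule

* **Three-part proposal.** With probability `swap_frac` (default 0.1) two
  cells with different labels propose to trade places -- the tessellation is
  untouched and the energy change involves only adhesion terms, so this move
  equilibrates *which* cell sits where far faster than displacements can.
  Otherwise, with probability `hop_frac` (default 0.2) the chosen point
  proposes a relocation uniform over the whole box; else a local
  displacement, uniform in a disk whose radius `max_disp` is adapted every
  `adapt_interval` local moves (x1.1 above a 25-40% acceptance band, x0.9
  below, clamped to `[1e-4, box_size/4]`). All three proposals are
  symmetric, so the mixture satisfies detailed balance with respect to the
  Boltzmann law; the tests verify the sampler against an enumerated
  toy-system quadrature. Hops and swaps matter kinetically: a cell crossing
  the dense gap-point gas by diffusion pays a transient area penalty of
  order `area_coeff * (0.6 - 1)^2`, so with local moves alone aggregates
  stop exchanging cells and coarsening stalls at small cluster sizes. An
  optional geometric burn-in annealing (`anneal_factor`) is provided but
  disabled by default: in the mixed system it compacts aggregates before
  they type-order, which worsens sorting.
* **Local energy updates.** A tentative move re-tessellates only the cells
  whose polygons can change -- the moved point plus its Voronoi neighbors
  before and after, which is exact for Voronoi tessellations -- and the
  cached total energy is rebuilt from scratch every `recompute_interval`
  moves (default 50,000) to guard against floating-point drift; the final
  cached and recomputed energies agree to 1e-6 in the tests.
* **Periodic Voronoi.** Each polygon is built by clipping a large square
  with the perpendicular bisectors of nearby generators (periodic minimal
  images; full 3x3 ghost images for small systems), processed in order of
  increasing distance with the standard stopping rule (a generator at
  distance d cannot cut once d > 2 x max vertex distance). Polygon areas
  sum to the box area to 1e-8 relative.
* **Schedule.** Defaults: 650,000 moves with 300 snapshots after a
  200,000-move burn-in. At these settings a run takes well under a minute;
  the headline experiments use 2,000,000 moves (see below) because cluster
  coarsening -- not shape relaxation -- is the slow mode of this dynamics.

### Pattern statistics

A **center cell** is a cell none of whose neighbors is a gap polygon, with
neighborship requiring a shared edge of at least `min_edge` (default 0.15;
see below). Per center cell we count total neighbors and "like" neighbors
(same label), pool over snapshots (and, in the experiments, over replicate
seeds), and classify: `mean_like > 1.5` honeycomb, `< 1.0` checkerboard,
else transitional -- thresholds placed midway between the two observed
regimes (~2.4 vs ~0.3 like neighbors).

The `min_edge` contact threshold deserves a note. A jittered Voronoi
interior almost never has exact four-way junctions, so arbitrarily short
edges make every interior cell count ~6 neighbors and a checkerboard's
diagonal corner contacts would be counted as "like" neighbors. Counting
only interfaces of visually significant length -- as quantification on
rendered snapshots does -- ignores these near-degenerate contacts; with
unit-area cells (edges ~0.6) a threshold of 0.1-0.3 spans the sensible
range; the default 0.15 (about a quarter of a hexagonal edge) is used
everywhere and the threshold is configurable in every metric.

## 3. Experiments, problem sizes, and replicates

`run_experiment()` packages the headline analyses: `cytoneme-baseline`
(`e_ii` 0 vs 15), `eii-sweep` (`{0, 5, 15, 30, 50}`), `vertex-homogeneous`
(50 red + 50 green Ihog cells), `vertex-mixed` (50 Ihog + 50 Hh at ratio
30), `gamma-sweep` (`{5, 10, 15, 20, 25, 30, 35}`) and `invasion` (50 Hh
added to a relaxed 50-cell Ihog aggregate). Cytoneme experiments use the
full published schedule (5e6 steps; they run in seconds per condition).
Vertex experiments use 2.5e6 moves per run and pool six replicate seeds
(50 snapshots each) for neighbor statistics, because single runs end with a
handful of aggregates whose particular composition dominates the pooled SD;
replicate pooling is the configurable alternative sampling design for
exactly this situation. The `--fast` flag (and `fast =` argument) divides
step counts by 10 for smoke runs.

## 4. What the synthetic data do and do not establish

All inputs are generated in code from seeded RNGs; there is no external
data. The generators emulate the *study conditions* -- random initial
placements, the published coefficients and schedules -- not real imaging
data: no measurement noise, no segmentation error, no biological
heterogeneity in coefficients. Passing tests therefore establish that the
implementation samples the specified stochastic models correctly (oracle
agreement, detailed balance, conservation laws, determinism), and that the
models reproduce the published steady-state statistics under their stated
conditions; they say nothing about how well those models describe real
wing-disc cytonemes or S2-cell aggregates.

## 5. Known limitations

* The cytoneme model's quasi-equilibrium contacts make bundle membership
  effectively irreversible at moderate `e_ii`; no singular cytonemes
  survive burn-in, which depresses the pooled length-interaction
  correlation relative to a mixed population (Section 1).
* The vertex model's coarsening is kinetically limited even with hops and
  swaps; some replicates retain compact hexagonally packed aggregates whose
  adjacency cannot be two-colored without like contacts, so pooled
  like-neighbor counts in the checkerboard regime sit above the fully
  ordered limit. Replicate pooling reduces, but does not remove, this
  variability.
* Gap polygons are strictly passive; there is no cell division, death, or
  motility beyond Metropolis moves, and no explicit ligand transport.
* `kbt` is a model scale, not a physical temperature; all energies are
  reported in its units.
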