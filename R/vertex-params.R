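cell_labels <- c("IHOG_RED", "IHOG_GREEN", "HH", "ENV")

contract_code <- function(mode) {
  match(mode, c("full_perimeter", "free_boundary", "shared_half")) - 1L
}

label_codes <- function(lab) {
  if (is.factor(lab)) lab <- as.character(lab)
  code <- match(lab, cell_labels)
  if (anyNA(code)) stop("unknown cell label; expected one of ",
                        paste(cell_labels, collapse = ", "), call. = FALSE)
  code
}

#' Parameters for the Voronoi/vertex monolayer simulation
#'
#' Cells are Voronoi polygons of mobile generator points in a periodic
#' `box_size` x `box_size` square. `n_cells` points are cellular;
#' `env_factor * n_cells` further points generate empty environmental
#' polygons (gaps) that carry no mechanical energy. The energy of a cell is
#' `area_coeff * (A - pref_area)^2 + contract_coeff * P^2 -
#' 1/2 * sum_j gamma_ij * l_ij`, the adhesion sum running over cell-cell
#' shared edges; the adhesive line density gamma depends on the protein types
#' of the two cells (Ihog-Ihog `gamma_ii`, Ihog-Hh `gamma_ih`, Hh-Hh
#' `gamma_hh`; any pair involving an environmental polygon has gamma = 0).
#' One Monte Carlo step displaces one uniformly chosen point by a uniform
#' draw from a disk of radius `max_disp` and accepts with the Metropolis
#' probability; `max_disp` is adapted every `adapt_interval` steps to keep
#' the acceptance rate inside `accept_window`.
#'
#' @param box_size side length of the periodic square domain.
#' @param n_cells number of cellular generator points.
#' @param env_factor environmental points per cell.
#' @param pref_area preferred cell area A0.
#' @param area_coeff areal elastic coefficient.
#' @param contract_coeff contractile coefficient (multiplies the squared full
#'   perimeter, including cell-environment edges).
#' @param gamma_ii,gamma_ih,gamma_hh adhesive line densities per type pair.
#' @param contractility `"free_boundary"` (default): the contractile term
#'   `contract_coeff * P^2` is borne by the free portion of the cell boundary
#'   (edges facing gaps), so cell-cell interfaces carry no cortical tension
#'   and compact aggregates are mechanically favored, as in
#'   differential-interfacial-tension models of cell sorting.
#'   `"full_perimeter"`: the term uses the full polygon perimeter.
#' @param mobile_env should environmental points attempt Monte Carlo moves?
#'   The default `TRUE` makes all `(1 + env_factor) * n_cells` points mobile;
#'   `FALSE` treats gap generators as a quenched background so only cells
#'   rearrange (diagnostic).
#' @param kbt thermal energy scale of the Metropolis rule.
#' @param anneal_factor burn-in annealing: the run starts at
#'   `anneal_factor * kbt` and cools geometrically to `kbt` by the end of
#'   burn-in (1 disables). Snapshots are always collected at `kbt`.
#'   Annealing carries the monolayer over the kinetic barriers of aggregate
#'   restructuring that local moves cross only slowly at the target
#'   temperature.
#' @param total_steps,burn_in,snapshot_count,snapshot_interval schedule;
#'   `snapshot_interval = NULL` spaces `snapshot_count` snapshots evenly over
#'   `[burn_in, total_steps)`.
#' @param max_disp initial maximum tentative displacement of the local moves.
#' @param hop_frac fraction of tentative moves that are global relocations
#'   (uniform over the box) instead of local displacements. Hops let cells
#'   exchange directly between aggregates; local moves relax shapes and
#'   interfaces. Both proposals are symmetric, so the Metropolis rule leaves
#'   the Boltzmann distribution invariant.
#' @param swap_frac fraction of tentative moves that are identity exchanges:
#'   two cells with different labels trade places (equivalently, labels)
#'   without touching the tessellation, so the energy change involves only
#'   adhesion terms. A symmetric proposal; it equilibrates which cell sits
#'   where in an aggregate far faster than displacement moves can.
#' @param accept_window target acceptance band, length-2 numeric in (0, 1).
#' @param adapt_interval steps between step-size adaptations (0 disables).
#' @param edge_eps minimum shared-edge length for two polygons to count as
#'   neighbors; defaults to `1e-6 * box_size` (numerical slivers ignored).
#' @param recompute_interval steps between full from-scratch rebuilds of the
#'   cached geometry and energy (guards floating-point drift; 0 disables).
#' @param seed integer seed (same seed, identical trajectory).
#' @return A validated parameter list of class `vertex_params`.
#' @export
vertex_params <- function(box_size = 20,
                          n_cells = 100L,
                          env_factor = 5L,
                          pref_area = 1,
                          area_coeff = 500,
                          contract_coeff = 6,
                          gamma_ii = 0.25,
                          gamma_ih = 0.25,
                          gamma_hh = 0,
                          contractility = c("free_boundary", "shared_half", "full_perimeter"),
                          kbt = 1,
                          anneal_factor = 1,
                          total_steps = 650000,
                          burn_in = 200000,
                          snapshot_count = 300L,
                          snapshot_interval = NULL,
                          max_disp = 0.4,
                          hop_frac = 0.2,
                          swap_frac = 0.1,
                          accept_window = c(0.25, 0.40),
                          adapt_interval = 2000L,
                          edge_eps = NULL,
                          recompute_interval = 50000L,
                          mobile_env = TRUE,
                          seed = 1L) {
  contractility <- match.arg(contractility)
  if (is.null(edge_eps)) edge_eps <- 1e-6 * box_size
  if (is.null(snapshot_interval))
    snapshot_interval <- max(1, floor((total_steps - burn_in) /
                                        max(1, snapshot_count - 1)))
  p <- list(box_size = box_size, n_cells = as.integer(n_cells),
            env_factor = as.integer(env_factor), pref_area = pref_area,
            area_coeff = area_coeff, contract_coeff = contract_coeff,
            gamma_ii = gamma_ii, gamma_ih = gamma_ih, gamma_hh = gamma_hh,
            contractility = contractility, kbt = kbt,
            anneal_factor = anneal_factor, total_steps = as.numeric(total_steps),
            burn_in = as.numeric(burn_in),
            snapshot_count = as.integer(snapshot_count),
            snapshot_interval = as.numeric(snapshot_interval),
            max_disp = max_disp, hop_frac = hop_frac,
            swap_frac = swap_frac, accept_window = accept_window,
            adapt_interval = as.integer(adapt_interval),
            edge_eps = edge_eps,
            recompute_interval = as.integer(recompute_interval),
            mobile_env = isTRUE(mobile_env),
            seed = as.integer(seed))
  validate_vertex_params(p)
  structure(p, class = "vertex_params")
}

validate_vertex_params <- function(p) {
  stopifnot(p$box_size > 0, p$n_cells >= 1, p$env_factor >= 0,
            p$hop_frac >= 0, p$hop_frac < 1,
            p$swap_frac >= 0, p$swap_frac < 1, p$anneal_factor >= 1,
            p$area_coeff >= 0, p$contract_coeff >= 0,
            p$gamma_ii >= 0, p$gamma_ih >= 0, p$gamma_hh >= 0,
            p$kbt > 0, p$burn_in < p$total_steps,
            p$max_disp > 0, length(p$accept_window) == 2,
            p$accept_window[1] > 0, p$accept_window[2] < 1,
            p$accept_window[1] < p$accept_window[2],
            p$edge_eps >= 0)
  last <- p$burn_in + (p$snapshot_count - 1) * p$snapshot_interval
  if (last >= p$total_steps)
    stop("snapshot schedule inconsistent: burn_in + (snapshot_count - 1) * ",
         "snapshot_interval must be < total_steps", call. = FALSE)
  invisible(p)
}

#' Seeded random initial tissue
#'
#' Scatters `(1 + env_factor) * n_cells` generator points uniformly in the
#' periodic box; the cellular labels given by `composition` are assigned to a
#' random subset of points and the remainder are environmental.
#'
#' @param params a [vertex_params()] object.
#' @param composition named integer vector over `IHOG_RED`, `IHOG_GREEN`,
#'   `HH` summing to `params$n_cells`.
#' @param seed optional seed overriding `params$seed`.
#' @return A tibble with columns `point`, `x`, `y`, `label` (factor).
#' @examples
#' init_tissue(vertex_params(n_cells = 10), c(IHOG_RED = 5, IHOG_GREEN = 5))
#' @export
init_tissue <- function(params, composition, seed = params$seed) {
  stopifnot(inherits(params, "vertex_params"))
  if (is.null(names(composition)) ||
      !all(names(composition) %in% setdiff(cell_labels, "ENV")))
    stop("composition must be named with cell labels (not ENV)", call. = FALSE)
  if (sum(composition) != params$n_cells)
    stop("composition must sum to n_cells = ", params$n_cells, call. = FALSE)
  n_total <- (1L + params$env_factor) * params$n_cells
  dat <- withr::with_seed(seed, {
    lab <- c(rep(names(composition), times = composition),
             rep("ENV", n_total - params$n_cells))
    tibble::tibble(point = seq_len(n_total),
                   x = stats::runif(n_total, 0, params$box_size),
                   y = stats::runif(n_total, 0, params$box_size),
                   label = factor(sample(lab), levels = cell_labels))
  })
  dat
}

#' Periodic Voronoi tessellation of a point set
#'
#' Partitions the periodic square box into one convex polygon per generator
#' point. Polygon areas sum to `box_size^2` (the tessellation is a partition).
#'
#' @param points tibble/data frame with columns `x`, `y` in
#'   `[0, box_size)`; at least 4 points.
#' @param box_size side length of the periodic box.
#' @param edge_eps shared edges shorter than this are dropped from the edge
#'   table.
#' @return A list with `cells` (tibble: `cell`, `area`, `perimeter`) and
#'   `edges` (tibble: `i`, `j`, `length`; each unordered neighbor pair once,
#'   multiple periodic contacts summed).
#' @export
tessellate <- function(points, box_size, edge_eps = 1e-6 * box_size) {
  stopifnot(nrow(points) >= 4,
            all(points$x >= 0), all(points$x < box_size),
            all(points$y >= 0), all(points$y < box_size))
  raw <- vx_tessellate_cpp(points$x, points$y, box_size, edge_eps)
  list(cells = tibble::tibble(cell = seq_along(raw$area),
                              area = raw$area, perimeter = raw$perimeter),
       edges = tibble::tibble(i = as.integer(raw$edge_i),
                              j = as.integer(raw$edge_j),
                              length = raw$edge_length))
}

#' Mechanical energy of a tissue configuration
#'
#' Per-cell energy under the areal-elasticity + contractility + differential
#' adhesion model; environmental polygons have `NA` energy and contribute
#' nothing.
#'
#' @param points tibble with columns `x`, `y`, `label`.
#' @param params a [vertex_params()] object.
#' @return A list with `cell_energy` (tibble: `cell`, `label`, `energy`) and
#'   `total` (the summed energy; each cell-cell edge contributes
#'   `-gamma * l` in total).
#' @export
tissue_energy <- function(points, params) {
  stopifnot(inherits(params, "vertex_params"))
  raw <- vx_energy_cpp(points$x, points$y, label_codes(points$label),
                       params$box_size, params$area_coeff,
                       params$contract_coeff, params$pref_area,
                       params$gamma_ii, params$gamma_ih, params$gamma_hh,
                       params$edge_eps, contract_code(params$contractility))
  list(cell_energy = tibble::tibble(cell = seq_len(nrow(points)),
                                    label = points$label,
                                    energy = raw$cell_energy),
       total = raw$total)
}

#' Step-size adaptation rule
#'
#' Multiplies the maximum displacement by 1.1 when the recent acceptance rate
#' is above the target band, by 0.9 when below, and clamps the result to
#' `[1e-4, box_size / 4]`.
#'
#' @param accept_rate recent acceptance rate in `[0, 1]`.
#' @param max_disp current maximum displacement.
#' @param params a [vertex_params()] object (supplies the band and box size).
#' @return The new maximum displacement.
#' @export
adapt_step <- function(accept_rate, max_disp, params) {
  stopifnot(accept_rate >= 0, accept_rate <= 1)
  out <- max_disp
  if (accept_rate > params$accept_window[2]) out <- out * 1.1
  else if (accept_rate < params$accept_window[1]) out <- out * 0.9
  min(max(out, 1e-4), params$box_size / 4)
}
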