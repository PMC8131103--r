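#' Toy cytoneme system with an enumerable configuration space
#'
#' A small periodic surface carrying 2-3 cytonemes of fixed lengths, used
#' with translocation-only dynamics (`fixed_lengths = TRUE`) and forced
#' contact establishment (`p_contact_override = 1`) so that the stationary
#' distribution over position configurations is an exact Boltzmann
#' distribution that [enumerate_toy_boltzmann()] computes by full
#' enumeration.
#'
#' @param surface_length number of sites, at most 8.
#' @param lengths fixed segment counts of the 2-3 cytonemes.
#' @param neighbor_radius neighboring distance in sites.
#' @return A list of class `toy_cytoneme_system`.
#' @export
toy_cytoneme_system <- function(surface_length = 6L, lengths = c(2L, 2L),
                                neighbor_radius = 1L) {
  stopifnot(surface_length <= 8, length(lengths) %in% c(2L, 3L),
            all(lengths >= 0), surface_length > length(lengths))
  structure(list(surface_length = as.integer(surface_length),
                 lengths = as.integer(lengths),
                 neighbor_radius = as.integer(neighbor_radius)),
            class = "toy_cytoneme_system")
}

ring_distance <- function(a, b, M) {
  d <- abs(a - b)
  pmin(d, M - d)
}

toy_pair_count <- function(positions, lengths, M, radius) {
  n <- length(positions)
  total <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (ring_distance(positions[i], positions[j], M) <= radius)
      total <- total + min(lengths[i], lengths[j])
  }
  total
}

#' Exact Boltzmann distribution of a toy cytoneme system
#'
#' Enumerates every placement of the (distinguishable) cytonemes on distinct
#' sites, counts the aligned segment pairs between neighbors (all contacts
#' established), and normalises `exp(e_ii * pairs / kbt)`.
#'
#' @param toy a [toy_cytoneme_system()].
#' @param e_ii interaction strength per established pair.
#' @param kbt thermal energy scale.
#' @return Tibble with `key` (comma-separated 0-based positions), `pairs`
#'   and `prob` (summing to 1).
#' @examples
#' enumerate_toy_boltzmann(toy_cytoneme_system(), e_ii = 0)  # uniform
#' @export
enumerate_toy_boltzmann <- function(toy, e_ii, kbt = 1) {
  stopifnot(inherits(toy, "toy_cytoneme_system"))
  M <- toy$surface_length
  n <- length(toy$lengths)
  n_states <- prod(M - seq_len(n) + 1)
  if (n_states > 1e4) stop("toy state space too large to enumerate",
                           call. = FALSE)
  grids <- as.matrix(do.call(expand.grid, rep(list(0:(M - 1)), n)))
  grids <- grids[apply(grids, 1, function(p) !anyDuplicated(p)), , drop = FALSE]
  pairs <- vapply(seq_len(nrow(grids)), function(r) {
    toy_pair_count(grids[r, ], toy$lengths, M, toy$neighbor_radius)
  }, integer(1))
  w <- exp(e_ii * pairs / kbt)
  tibble::tibble(key = apply(grids, 1, paste, collapse = ","),
                 pairs = as.integer(pairs), prob = w / sum(w))
}

#' Exact stationary length distribution of an isolated cytoneme
#'
#' An isolated cytoneme (no neighbors, no contacts) is a birth-death chain on
#' the non-negative integers: from length 0 it always elongates; from length
#' `x > 0` it shrinks with probability `p_s / (p_e(x) + p_s)` and elongates
#' otherwise, with `p_e(x) = p_elong0 * exp(-alpha * x)` and
#' `p_s = p_shrink0`. The stationary distribution follows from detailed
#' balance by direct enumeration, truncated where the tail mass is below
#' machine noise.
#'
#' @param params a [cytoneme_params()] object (only the growth parameters are
#'   used).
#' @param max_length truncation bound.
#' @return Tibble with `length` and `prob` (summing to 1).
#' @export
birth_death_stationary <- function(params, max_length = 200L) {
  up <- function(x) {
    pe <- params$p_elong0 * exp(-params$alpha * x)
    ps <- params$p_shrink0
    if (x == 0) 1 else pe / (pe + ps)
  }
  down <- function(x) {
    pe <- params$p_elong0 * exp(-params$alpha * x)
    params$p_shrink0 / (pe + params$p_shrink0)
  }
  w <- numeric(max_length + 1)
  w[1] <- 1
  for (x in seq_len(max_length))
    w[x + 1] <- w[x] * up(x - 1) / down(x)
  tibble::tibble(length = 0:max_length, prob = w / sum(w))
}

#' Hand-specified toy tissues with known geometry and energy
#'
#' A fixed catalogue of small periodic point layouts whose Voronoi geometry
#' and mechanical energy are computable by hand. The stored reference values
#' are literals, independent of the tessellation code, so geometry tests
#' cannot drift with the implementation.
#'
#' \describe{
#'   \item{"grid-4"}{4 cells on a square grid in a 2 x 2 box: unit squares,
#'     `A = 1`, `P = 4`; each cell touches each axis neighbor twice around
#'     the periodic boundary (total shared length 2 per neighbor pair).}
#'   \item{"two-squares"}{a 4 x 4 box tiled by 16 unit squares; two adjacent
#'     cells are Ihog cells sharing a single edge of length 1, the rest are
#'     environment.}
#'   \item{"hex-7"}{a central generator ringed by 6 generators at unit
#'     distance in an 8 x 8 box; the central cell is a regular hexagon with
#'     `A = sqrt(3)/2`, `P = 2*sqrt(3)`, sharing an edge of `1/sqrt(3)` with
#'     each of its 6 neighbors. Reference values cover the central cell.}
#' }
#'
#' @param name one of `"grid-4"`, `"two-squares"`, `"hex-7"`.
#' @param params a [vertex_params()] supplying the energy coefficients used
#'   for the reference energies (box size is overridden by the catalogue;
#'   contractility is evaluated on the full perimeter, matching the
#'   hand-computed values).
#' @return A list with `points` (tibble `x`, `y`, `label`), `box_size`,
#'   `params` (coefficients with the catalogue box), and `reference` (a list
#'   of hand-computed values; see each entry's fields).
#' @export
make_toy_tissue <- function(name,
                            params = vertex_params(contractility = "full_perimeter")) {
  params$contractility <- "full_perimeter"
  ap <- params$area_coeff; bt <- params$contract_coeff
  A0 <- params$pref_area; gII <- params$gamma_ii
  lab <- function(x) factor(x, levels = cell_labels)
  if (name == "grid-4") {
    pts <- tibble::tibble(
      x = c(0.5, 1.5, 0.5, 1.5), y = c(0.5, 0.5, 1.5, 1.5),
      label = lab(rep("IHOG_RED", 4)))
    # each cell: A = 1, P = 4; neighbors: the other cell in its row (shared
    # length 1 + 1 across the boundary) and in its column (same); energy
    # = ap*(1-A0)^2 + bt*16 - 0.5*gII*(2 + 2)
    ref <- list(area = rep(1, 4), perimeter = rep(4, 4),
                shared_per_neighbor = 2,
                cell_energy = rep(ap * (1 - A0)^2 + bt * 16 - 2 * gII, 4),
                total_energy = 4 * (ap * (1 - A0)^2 + bt * 16) - 4 * 2 * gII)
  } else if (name == "two-squares") {
    g <- expand.grid(x = 0:3 + 0.5, y = 0:3 + 0.5)
    labels <- rep("ENV", 16)
    a <- which(g$x == 1.5 & g$y == 0.5)
    b <- which(g$x == 2.5 & g$y == 0.5)
    labels[c(a, b)] <- "IHOG_RED"
    pts <- tibble::tibble(x = g$x, y = g$y, label = lab(labels))
    e_cell <- ap * (1 - A0)^2 + bt * 16 - 0.5 * gII * 1
    ref <- list(cells = c(a, b), area = c(1, 1), perimeter = c(4, 4),
                shared_edge = 1, adhesive_term = -0.5 * gII * 1,
                cell_energy = c(e_cell, e_cell),
                total_energy = 2 * (ap * (1 - A0)^2 + bt * 16) - gII * 1)
  } else if (name == "hex-7") {
    th <- seq(0, 5) * pi / 3
    pts <- tibble::tibble(x = c(4, 4 + cos(th)), y = c(4, 4 + sin(th)),
                          label = lab(rep("IHOG_RED", 7)))
    A <- sqrt(3) / 2; P <- 2 * sqrt(3)
    ref <- list(center = 1L, area = A, perimeter = P,
                n_neighbors = 6L, shared_edge = 1 / sqrt(3),
                cell_energy = ap * (A - A0)^2 + bt * P^2 - 0.5 * gII * P)
  } else stop("unknown toy tissue: ", name, call. = FALSE)
  params$box_size <- if (name == "grid-4") 2 else if (name == "two-squares") 4 else 8
  params$edge_eps <- 1e-6 * params$box_size
  list(points = pts, box_size = params$box_size, params = params,
       reference = ref)
}
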