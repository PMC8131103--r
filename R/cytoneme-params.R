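#' Parameters for the cytoneme lattice simulation
#'
#' The cell surface is a periodic 1-D lattice of `surface_length` integer
#' sites; each cytoneme occupies one site (at most one per site) and carries a
#' non-negative integer number of segments. Per step, pairwise segment
#' contacts between neighboring cytonemes are re-drawn from the equilibrium
#' occupancy probability (a quasi-equilibrium approximation of the binding
#' kinetics), every cytoneme elongates or shrinks by one segment, and one
#' randomly picked cytoneme attempts a Metropolis translocation by one site.
#'
#' @param surface_length integer, number of lattice sites on the cell surface.
#' @param occupancy_fraction fraction of sites seeded with cytonemes at start.
#' @param p_elong0 base elongation weight at zero length (dimensionless; it
#'   only ever enters through the normalised ratio with the shrinkage weight,
#'   so values above 1 are legitimate).
#' @param p_shrink0 intrinsic shrinkage weight without any trans interaction.
#' @param alpha per-segment exponential decay coefficient of the elongation
#'   weight (membrane tension / transport limitation).
#' @param e_ii strength of the homophilic trans interaction per established
#'   segment pair, in units of `kbt`.
#' @param kbt thermal energy scale used in the Metropolis acceptance rule.
#' @param neighbor_radius lattice distance (sites) within which two cytonemes
#'   count as neighboring and their aligned segments may interact.
#' @param total_steps,burn_in_steps,snapshot_interval,snapshot_count schedule:
#'   snapshots are recorded every `snapshot_interval` steps starting at
#'   `burn_in_steps`, `snapshot_count` of them in total.
#' @param seed integer seed; fixes the initial placement and the whole
#'   trajectory (same seed, bit-identical snapshots).
#' @param p_contact_override optional probability in `[0, 1]` that, when set,
#'   replaces the logistic contact-establishment probability. Diagnostic
#'   switch used to force deterministic contacts in enumeration tests.
#' @param fixed_lengths if `TRUE`, skip elongation/shrinkage so that only
#'   translocation moves act (diagnostic switch for equilibrium-sampling
#'   checks on toy systems).
#' @return A validated parameter list of class `cytoneme_params`.
#' @examples
#' p <- cytoneme_params(total_steps = 2000, burn_in_steps = 1000,
#'                      snapshot_interval = 10, snapshot_count = 101)
#' @export
cytoneme_params <- function(surface_length = 100L,
                            occupancy_fraction = 0.30,
                            p_elong0 = 5,
                            p_shrink0 = 0.5,
                            alpha = 0.2,
                            e_ii = 0,
                            kbt = 1,
                            neighbor_radius = 1L,
                            total_steps = 5e6 + 1,
                            burn_in_steps = 1e6,
                            snapshot_interval = 4000,
                            snapshot_count = 1001L,
                            seed = 1L,
                            p_contact_override = NULL,
                            fixed_lengths = FALSE) {
  p <- list(surface_length = as.integer(surface_length),
            occupancy_fraction = occupancy_fraction,
            p_elong0 = p_elong0, p_shrink0 = p_shrink0, alpha = alpha,
            e_ii = e_ii, kbt = kbt,
            neighbor_radius = as.integer(neighbor_radius),
            total_steps = as.numeric(total_steps),
            burn_in_steps = as.numeric(burn_in_steps),
            snapshot_interval = as.numeric(snapshot_interval),
            snapshot_count = as.integer(snapshot_count),
            seed = as.integer(seed),
            p_contact_override = p_contact_override,
            fixed_lengths = isTRUE(fixed_lengths))
  validate_cytoneme_params(p)
  structure(p, class = "cytoneme_params")
}

validate_cytoneme_params <- function(p) {
  stopifnot(p$surface_length > 0,
            p$occupancy_fraction > 0, p$occupancy_fraction <= 1,
            p$p_elong0 > 0, p$p_shrink0 > 0,
            p$alpha >= 0, p$e_ii >= 0, p$kbt > 0,
            p$neighbor_radius >= 1,
            p$burn_in_steps < p$total_steps,
            p$snapshot_interval >= 1, p$snapshot_count >= 1)
  if (!is.null(p$p_contact_override))
    stopifnot(p$p_contact_override >= 0, p$p_contact_override <= 1)
  last <- p$burn_in_steps + (p$snapshot_count - 1) * p$snapshot_interval
  if (last >= p$total_steps)
    stop("snapshot schedule inconsistent: burn_in_steps + ",
         "(snapshot_count - 1) * snapshot_interval must be < total_steps",
         call. = FALSE)
  invisible(p)
}

#' Elongation, shrinkage and contact-establishment probabilities
#'
#' `elongation_prob()` is the length-dependent elongation weight
#' `p_elong0 * exp(-alpha * length)`. `shrink_prob()` is the tip shrinkage
#' weight `p_shrink0 * exp(-tip_contacts * e_ii)`: every trans interaction at
#' the tip segment adds an energy barrier of `e_ii` to a shrinkage event.
#' `interaction_prob()` is the equilibrium occupancy of a single segment-pair
#' contact, `exp(e_ii) / (1 + exp(e_ii))`, computed in overflow-safe form.
#'
#' @param length non-negative integer segment count (vectorised).
#' @param tip_contacts non-negative number of neighboring cytonemes whose
#'   aligned segment interacts with the tip segment (vectorised).
#' @param e_ii non-negative interaction strength (vectorised in
#'   `interaction_prob()`).
#' @param params a [cytoneme_params()] object.
#' @return Numeric vector of weights (probabilities for
#'   `interaction_prob()`).
#' @examples
#' elongation_prob(0, cytoneme_params())   # 5
#' shrink_prob(0, cytoneme_params())       # 0.5
#' interaction_prob(0)                     # 0.5
#' @export
elongation_prob <- function(length, params) {
  if (any(length < 0)) stop("length must be non-negative", call. = FALSE)
  params$p_elong0 * exp(-params$alpha * length)
}

#' @rdname elongation_prob
#' @export
shrink_prob <- function(tip_contacts, params) {
  if (any(tip_contacts < 0))
    stop("tip_contacts must be non-negative", call. = FALSE)
  params$p_shrink0 * exp(-tip_contacts * params$e_ii)
}

#' @rdname elongation_prob
#' @export
interaction_prob <- function(e_ii) {
  if (any(e_ii < 0)) stop("e_ii must be non-negative", call. = FALSE)
  stats::plogis(e_ii)
}

#' Seeded random initial cytoneme placement
#'
#' Picks `floor(occupancy_fraction * surface_length)` distinct uniform-random
#' sites on the periodic surface; all initial lengths are zero.
#'
#' @param params a [cytoneme_params()] object.
#' @param seed optional seed overriding `params$seed`.
#' @return A tibble with columns `cytoneme`, `position` (0-based site) and
#'   `length`.
#' @export
make_initial_cytonemes <- function(params, seed = params$seed) {
  n <- floor(params$occupancy_fraction * params$surface_length)
  if (n < 1) stop("occupancy_fraction too small: no cytonemes", call. = FALSE)
  pos <- withr::with_seed(seed, sample.int(params$surface_length, n) - 1L)
  tibble::tibble(cytoneme = seq_len(n), position = pos, length = 0L)
}
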