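#' Run the cytoneme lattice simulation
#'
#' Evolves the cytoneme system for `params$total_steps` steps. Each step:
#' (1) a fresh binary contact assignment is drawn for every aligned segment
#' pair of neighboring cytonemes with probability [interaction_prob()];
#' (2) every cytoneme elongates or shrinks by one segment, shrinking with
#' probability `p_shrink / (p_elong + p_shrink)` (a zero-length cytoneme
#' always elongates); (3) one cytoneme, picked uniformly, attempts a
#' one-site translocation (left/right with equal probability), re-drawing the
#' contacts of its tentative neighborhood and accepting with the Metropolis
#' probability `min(1, exp(-dE / kbt))`, where the configuration energy is
#' lowered by `e_ii` per established contact. A proposal onto an occupied
#' site is rejected (excluded volume).
#'
#' @param params a [cytoneme_params()] object.
#' @param initial optional initial state tibble (columns `position`, `length`)
#'   as from [make_initial_cytonemes()]; defaults to the seeded random
#'   placement with zero lengths.
#' @return An object of class `cytoneme_sim`: a list with
#'   \describe{
#'     \item{snapshots}{tibble: `snapshot`, `step`, `cytoneme`, `position`,
#'       `length`, `contacts` (established pairwise interactions involving the
#'       cytoneme).}
#'     \item{pair_contacts}{tibble: `snapshot`, `i`, `j`, `contacts` for each
#'       neighboring pair with at least one established contact.}
#'     \item{params}{the parameter list.}
#'   }
#' @examples
#' p <- cytoneme_params(e_ii = 15, total_steps = 5000, burn_in_steps = 1000,
#'                      snapshot_interval = 40, snapshot_count = 101)
#' sim <- simulate_cytonemes(p)
#' dplyr::count(sim$snapshots, snapshot)
#' @export
simulate_cytonemes <- function(params, initial = NULL) {
  stopifnot(inherits(params, "cytoneme_params"))
  validate_cytoneme_params(params)
  if (is.null(initial)) initial <- make_initial_cytonemes(params)
  stopifnot(all(initial$position >= 0),
            all(initial$position < params$surface_length),
            !anyDuplicated(initial$position),
            all(initial$length >= 0))
  ov <- if (is.null(params$p_contact_override)) -1 else params$p_contact_override
  raw <- cyto_simulate_cpp(
    as.integer(initial$position), as.integer(initial$length),
    params$surface_length, params$p_elong0, params$p_shrink0, params$alpha,
    params$e_ii, params$kbt, params$neighbor_radius,
    params$total_steps, params$burn_in_steps,
    params$snapshot_interval, params$snapshot_count,
    ov, params$fixed_lengths, params$seed)
  snapshots <- tibble::tibble(
    snapshot = as.integer(raw$snapshot),
    step = params$burn_in_steps + (as.integer(raw$snapshot) - 1L) *
      params$snapshot_interval,
    cytoneme = as.integer(raw$cytoneme),
    position = as.integer(raw$position),
    length = as.integer(raw$length),
    contacts = as.integer(raw$contacts))
  pair_contacts <- tibble::tibble(
    snapshot = as.integer(raw$pair_snapshot),
    i = as.integer(raw$pair_i), j = as.integer(raw$pair_j),
    contacts = as.integer(raw$pair_contacts))
  structure(list(snapshots = snapshots, pair_contacts = pair_contacts,
                 params = params,
                 final = tibble::tibble(cytoneme = seq_along(raw$final_positions),
                                        position = raw$final_positions,
                                        length = raw$final_lengths)),
            class = "cytoneme_sim")
}

#' @export
print.cytoneme_sim <- function(x, ...) {
  n <- length(unique(x$snapshots$cytoneme))
  cat("<cytoneme_sim>: ", n, " cytonemes on ", x$params$surface_length,
      " sites, e_ii = ", x$params$e_ii, ", ",
      max(x$snapshots$snapshot), " snapshots\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.cytoneme_sim <- function(x, ...) x$snapshots

#' @rdname tidiers
#' @export
glance.cytoneme_sim <- function(x, ...) {
  per_snap <- dplyr::summarise(
    dplyr::group_by(x$snapshots, .data$snapshot),
    mean_length = mean(.data$length),
    interactions = sum(.data$contacts) / 2)
  tibble::tibble(
    e_ii = x$params$e_ii,
    n_cytonemes = length(unique(x$snapshots$cytoneme)),
    n_snapshots = nrow(per_snap),
    mean_length = mean(per_snap$mean_length),
    sd_length = stats::sd(per_snap$mean_length),
    mean_interactions = mean(per_snap$interactions),
    sd_interactions = stats::sd(per_snap$interactions))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Draw one simulated cytoneme configuration
#'
#' Renders cytonemes as vertical filaments on the periodic surface, one
#' segment per unit height, for a single snapshot.
#'
#' @param object a `cytoneme_sim` object.
#' @param snapshot which snapshot to draw (default: the last).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cytoneme_sim <- function(object, snapshot = NULL, ...) {
  snap <- if (is.null(snapshot)) max(object$snapshots$snapshot) else snapshot
  d <- dplyr::filter(object$snapshots, .data$snapshot == snap)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$position, xend = .data$position,
                                       y = 0, yend = .data$length),
                          linewidth = 1, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "surface position (site)", y = "length (segments)",
                  title = sprintf("cytoneme configuration, e_ii = %g, step %d",
                                  object$params$e_ii,
                                  as.integer(d$step[1]))) +
    ggplot2::theme_minimal()
}
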