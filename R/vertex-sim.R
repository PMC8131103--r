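#' Run the Voronoi/vertex Monte Carlo simulation
#'
#' Evolves the monolayer for `params$total_steps` Metropolis moves and
#' records `params$snapshot_count` snapshots after `params$burn_in` steps.
#' Each move displaces one uniformly chosen generator point (cellular or
#' environmental), re-tessellates the affected neighborhood, and accepts with
#' probability `min(1, exp(-dU / kbt))`. The maximum displacement is adapted
#' to keep the acceptance rate inside `params$accept_window`.
#'
#' @param params a [vertex_params()] object.
#' @param composition named integer vector of cellular labels (see
#'   [init_tissue()]); ignored when `initial` is given.
#' @param initial optional initial state tibble (`x`, `y`, `label`), e.g. from
#'   [init_tissue()] or a previous run's `final`.
#' @param trace_moves record per-move `dU` and acceptance for the first this
#'   many moves (diagnostic; 0 disables).
#' @return An object of class `tissue_sim`:
#'   \describe{
#'     \item{cells}{tibble: `snapshot`, `cell`, `label`, `area`, `perimeter`
#'       for every non-environment cell.}
#'     \item{edges}{tibble: `snapshot`, `i`, `j`, `label_i`, `label_j`,
#'       `length` for every shared edge touching at least one cell.}
#'     \item{trace}{tibble: `step`, `energy`, `accept_rate`, `max_disp` per
#'       adaptation window.}
#'     \item{moves}{tibble of per-move `dU`/`accepted` when requested.}
#'     \item{final}{tibble of final point positions and labels.}
#'     \item{energy_cached, energy_recomputed}{incrementally tracked vs
#'       freshly recomputed total energy at the end of the run.}
#'     \item{accept_rate}{overall acceptance rate.}
#'   }
#' @examples
#' p <- vertex_params(n_cells = 20, box_size = 9, total_steps = 2000,
#'                    burn_in = 1000, snapshot_count = 5)
#' sim <- simulate_tissue(p, c(IHOG_RED = 10, IHOG_GREEN = 10))
#' glance(sim)
#' @export
simulate_tissue <- function(params, composition = NULL, initial = NULL,
                            trace_moves = 0L) {
  stopifnot(inherits(params, "vertex_params"))
  validate_vertex_params(params)
  if (is.null(initial)) {
    if (is.null(composition))
      stop("either `composition` or `initial` is required", call. = FALSE)
    initial <- init_tissue(params, composition)
  }
  codes <- label_codes(initial$label)
  raw <- vx_simulate_cpp(
    initial$x, initial$y, codes, params$box_size,
    params$area_coeff, params$contract_coeff, params$pref_area,
    params$gamma_ii, params$gamma_ih, params$gamma_hh,
    params$kbt, params$edge_eps,
    params$total_steps, params$burn_in,
    params$snapshot_interval, params$snapshot_count,
    params$max_disp, params$accept_window[1], params$accept_window[2],
    params$adapt_interval, 1e-4, params$box_size / 4,
    params$recompute_interval, as.integer(trace_moves), params$seed,
    if (isTRUE(params$mobile_env)) rep(TRUE, nrow(initial))
    else initial$label != "ENV",
    contract_code(params$contractility), params$hop_frac,
    params$swap_frac, params$anneal_factor)
  lab_fct <- function(code) factor(cell_labels[code], levels = cell_labels)
  cells <- tibble::tibble(snapshot = as.integer(raw$cell_snapshot),
                          cell = as.integer(raw$cell_id),
                          label = lab_fct(as.integer(raw$cell_label)),
                          area = raw$cell_area,
                          perimeter = raw$cell_perimeter)
  edges <- tibble::tibble(snapshot = as.integer(raw$edge_snapshot),
                          i = as.integer(raw$edge_i),
                          j = as.integer(raw$edge_j),
                          label_i = lab_fct(as.integer(raw$edge_label_i)),
                          label_j = lab_fct(as.integer(raw$edge_label_j)),
                          length = raw$edge_length)
  structure(list(
    cells = cells, edges = edges,
    trace = tibble::tibble(step = raw$trace_step, energy = raw$trace_energy,
                           accept_rate = raw$trace_accept,
                           max_disp = raw$trace_max_disp),
    moves = tibble::tibble(dU = raw$move_dU,
                           accepted = as.logical(raw$move_accepted)),
    final = tibble::tibble(point = seq_along(raw$final_x),
                           x = raw$final_x, y = raw$final_y,
                           label = initial$label),
    energy_cached = raw$energy_cached,
    energy_recomputed = raw$energy_recomputed,
    accept_rate = raw$accept_rate,
    final_max_disp = raw$final_max_disp,
    params = params), class = "tissue_sim")
}

#' @export
print.tissue_sim <- function(x, ...) {
  cat("<tissue_sim>: ", sum(x$final$label != "ENV"), " cells + ",
      sum(x$final$label == "ENV"), " env points, box ", x$params$box_size,
      ", ", max(x$cells$snapshot), " snapshots, accept rate ",
      round(x$accept_rate, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.tissue_sim <- function(x, ...) x$cells

#' @rdname tidiers
#' @export
glance.tissue_sim <- function(x, ...) {
  ns <- neighbor_stats(x)
  tibble::tibble(n_cells = sum(x$final$label != "ENV"),
                 n_snapshots = max(x$cells$snapshot),
                 accept_rate = x$accept_rate,
                 energy = x$energy_recomputed,
                 n_center = ns$n_center,
                 mean_neighbors = ns$mean_neighbors,
                 mean_like = ns$mean_like,
                 pattern = classify_pattern(ns))
}

#' Draw the tessellated monolayer
#'
#' Renders the Voronoi polygons of the final configuration (or any stored
#' point set), colored by cell label; environmental polygons are unfilled.
#'
#' @param object a `tissue_sim` object.
#' @param points optional point tibble (`x`, `y`, `label`) to draw instead of
#'   the final state.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_sim <- function(object, points = NULL, ...) {
  pts <- if (is.null(points)) object$final else points
  raw <- vx_polygons_cpp(pts$x, pts$y, object$params$box_size)
  poly <- tibble::tibble(cell = as.integer(raw$cell), x = raw$x, y = raw$y,
                         label = pts$label[as.integer(raw$cell)])
  ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y, group = .data$cell,
                                     fill = .data$label)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(IHOG_RED = "#d73027",
                                          IHOG_GREEN = "#1a9850",
                                          HH = "#4575b4", ENV = "white")) +
    ggplot2::coord_fixed(xlim = c(0, object$params$box_size),
                         ylim = c(0, object$params$box_size)) +
    ggplot2::theme_void()
}

#' Invasion protocol: Hh cells invading a pre-formed Ihog aggregate
#'
#' Phase 1 relaxes an aggregate of `n_ihog` Ihog-expressing cells (plus their
#' environmental points) to steady state. Phase 2 inserts `n_hh` Hh-expressing
#' cells at uniform-random positions currently inside environmental polygons
#' and continues the simulation, so the invaders start outside the aggregate
#' and intercalate (or not) depending on the adhesion ratio.
#'
#' @param params a [vertex_params()] object for phase 1; `n_cells` must equal
#'   `n_ihog`. Phase 2 reuses every coefficient; by default
#'   `gamma_ih = 30 * gamma_ii`.
#' @param n_ihog,n_hh cell counts for the aggregate and the invaders.
#' @param gamma_ih heterotypic adhesion for phase 2.
#' @return A list of class `invasion_sim` with `phase1` and `phase2`
#'   (`tissue_sim` objects) and `inserted` (tibble of invader start points).
#' @export
invasion_protocol <- function(params = vertex_params(n_cells = 50L,
                                                     gamma_ih = 30 * 0.25),
                              n_ihog = 50L, n_hh = 50L,
                              gamma_ih = 30 * params$gamma_ii) {
  stopifnot(params$n_cells == n_ihog)
  phase1 <- simulate_tissue(params, composition = c(IHOG_RED = n_ihog))
  pts <- phase1$final
  new_pts <- withr::with_seed(params$seed + 77L, {
    got <- 0L; xs <- numeric(0); ys <- numeric(0)
    while (got < n_hh) {
      cx <- stats::runif(4 * n_hh, 0, params$box_size)
      cy <- stats::runif(4 * n_hh, 0, params$box_size)
      near <- nearest_generator(cx, cy, pts, params$box_size)
      ok <- which(pts$label[near] == "ENV")
      take <- utils::head(ok, n_hh - got)
      xs <- c(xs, cx[take]); ys <- c(ys, cy[take]); got <- length(xs)
    }
    tibble::tibble(x = xs, y = ys,
                   label = factor("HH", levels = cell_labels))
  })
  initial2 <- dplyr::bind_rows(pts[, c("x", "y", "label")], new_pts)
  params2 <- params
  params2$n_cells <- as.integer(n_ihog + n_hh)
  params2$gamma_ih <- gamma_ih
  params2$seed <- params$seed + 78L
  phase2 <- simulate_tissue(params2, initial = initial2)
  structure(list(phase1 = phase1, phase2 = phase2, inserted = new_pts),
            class = "invasion_sim")
}

nearest_generator <- function(qx, qy, pts, box) {
  vapply(seq_along(qx), function(k) {
    dx <- abs(pts$x - qx[k]); dx <- pmin(dx, box - dx)
    dy <- abs(pts$y - qy[k]); dy <- pmin(dy, box - dy)
    which.min(dx * dx + dy * dy)
  }, integer(1))
}
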