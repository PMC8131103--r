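edges_of <- function(x, min_edge = 0) {
  e <- if (inherits(x, "tissue_sim")) x$edges
  else if (is.data.frame(x)) x
  else stop("expected a tissue_sim or an edge tibble", call. = FALSE)
  if (min_edge > 0) e <- dplyr::filter(e, .data$length >= min_edge)
  e
}

# one row per (snapshot, cell, neighbor) over cell-cell and cell-ENV edges
neighbor_long <- function(edges) {
  dplyr::bind_rows(
    dplyr::transmute(edges, snapshot = .data$snapshot, cell = .data$i,
                     label = .data$label_i, nb = .data$j,
                     nb_label = .data$label_j),
    dplyr::transmute(edges, snapshot = .data$snapshot, cell = .data$j,
                     label = .data$label_j, nb = .data$i,
                     nb_label = .data$label_i))
}

#' Identify center cells
#'
#' A center cell is a non-environment cell all of whose tessellation
#' neighbors (shared edge at least `edge_eps`, applied upstream) are also
#' cells. These are the interior cells of an aggregate, the unit over which
#' neighbor counts are quantified.
#'
#' @param x a `tissue_sim` or its `edges` tibble.
#' @param min_edge minimum shared-edge length for a contact to count as a
#'   neighbor relation. The default 0.15 (roughly a quarter of the edge of a
#'   unit-area hexagonal cell) mirrors quantification on rendered
#'   tessellations, where only visually significant interfaces are counted;
#'   near-degenerate corner contacts and pinched slivers are ignored.
#' @return Tibble with columns `snapshot`, `cell`.
#' @export
center_cells <- function(x, min_edge = 0.15) {
  nb <- neighbor_long(edges_of(x, min_edge))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(nb, .data$label != "ENV"),
                    .data$snapshot, .data$cell),
    center = all(.data$nb_label != "ENV"), .groups = "drop")
  dplyr::select(dplyr::filter(out, .data$center), "snapshot", "cell")
}

#' Per-center-cell neighbor counts
#'
#' For every center cell in every snapshot, counts its neighbors and the
#' neighbors carrying the same label ("like" neighbors).
#'
#' @param x a `tissue_sim` or its `edges` tibble.
#' @inheritParams center_cells
#' @return Tibble: `snapshot`, `cell`, `label`, `n_neighbors`, `n_like`.
#' @export
neighbor_counts <- function(x, min_edge = 0.15) {
  edges <- edges_of(x, min_edge)
  nb <- neighbor_long(edges)
  centers <- center_cells(edges, min_edge = 0)
  d <- dplyr::inner_join(nb, centers, by = c("snapshot", "cell"))
  dplyr::summarise(dplyr::group_by(d, .data$snapshot, .data$cell, .data$label),
                   n_neighbors = dplyr::n(),
                   n_like = sum(.data$nb_label == .data$label[1]),
                   .groups = "drop")
}

#' Pooled neighbor statistics over snapshots
#'
#' Pools the per-center-cell observations of [neighbor_counts()] across all
#' snapshots and reports mean and SD of the total and like-neighbor counts.
#'
#' @param x a `tissue_sim` or its `edges` tibble.
#' @inheritParams center_cells
#' @return One-row tibble of class `neighbor_stats`: `n_center`,
#'   `mean_neighbors`, `sd_neighbors`, `mean_like`, `sd_like`. When no center
#'   cell exists the counts are `NA` and `n_center` is 0.
#' @export
neighbor_stats <- function(x, min_edge = 0.15) {
  d <- neighbor_counts(x, min_edge)
  out <- if (nrow(d) == 0) {
    tibble::tibble(n_center = 0L, mean_neighbors = NA_real_,
                   sd_neighbors = NA_real_, mean_like = NA_real_,
                   sd_like = NA_real_)
  } else {
    tibble::tibble(n_center = nrow(d),
                   mean_neighbors = mean(d$n_neighbors),
                   sd_neighbors = stats::sd(d$n_neighbors),
                   mean_like = mean(d$n_like),
                   sd_like = stats::sd(d$n_like))
  }
  structure(out, class = c("neighbor_stats", class(out)))
}

#' Classify a steady-state pattern from like-neighbor statistics
#'
#' Checkerboard patterns (heterotypic adhesion dominant) have almost no like
#' neighbors; honeycomb patterns (random mixing of same-type cells) have
#' roughly half like neighbors. The default thresholds sit midway between the
#' two observed regimes (about 0.3 vs about 2.4 like neighbors).
#'
#' @param stats a `neighbor_stats` row (or anything with `mean_like`), or a
#'   bare numeric mean like-neighbor count.
#' @param checkerboard_max classify checkerboard when `mean_like` is below
#'   this.
#' @param honeycomb_min classify honeycomb when `mean_like` is above this.
#' @return One of `"checkerboard"`, `"honeycomb"`, `"transitional"` (or `NA`
#'   when the statistics are empty).
#' @examples
#' classify_pattern(2.4)  # honeycomb
#' classify_pattern(0.3)  # checkerboard
#' classify_pattern(1.2)  # transitional
#' @export
classify_pattern <- function(stats, checkerboard_max = 1.0,
                             honeycomb_min = 1.5) {
  ml <- if (is.numeric(stats)) stats else stats$mean_like
  if (is.na(ml)) return(NA_character_)
  if (ml < checkerboard_max) "checkerboard"
  else if (ml > honeycomb_min) "honeycomb"
  else "transitional"
}

#' Sweep the heterotypic:homotypic adhesion ratio
#'
#' Runs one mixed Ihog/Hh simulation per ratio `gamma_ih / gamma_ii`,
#' computes pooled neighbor statistics and classifies each steady state.
#'
#' @param ratios strictly increasing numeric vector of adhesion ratios.
#' @param params base [vertex_params()]; `gamma_ih` and `seed` are overridden
#'   per run.
#' @param composition cellular composition for the mixed system; defaults to
#'   an even Ihog/Hh split of `params$n_cells`.
#' @param n_rep replicate simulations per ratio; per-center-cell observations
#'   are pooled across replicates before summarising (steady states of single
#'   runs end in a handful of aggregates whose particular layout dominates
#'   the statistics, so replicate pooling stabilises the classification).
#' @param min_edge contact threshold passed to [neighbor_counts()].
#' @return An object of class `gamma_sweep`: tibble with one row per ratio
#'   (`ratio`, `gamma_ih`, `n_center`, `mean_neighbors`, `sd_neighbors`,
#'   `mean_like`, `sd_like`, `pattern`).
#' @export
gamma_sweep <- function(ratios, params = vertex_params(),
                        composition = NULL, n_rep = 1L, min_edge = 0.15) {
  stopifnot(!is.unsorted(ratios, strictly = TRUE))
  if (is.null(composition)) {
    h <- params$n_cells %/% 2L
    composition <- c(IHOG_RED = params$n_cells - h, HH = h)
  }
  rows <- purrr::map_dfr(seq_along(ratios), function(k) {
    d <- purrr::map_dfr(seq_len(n_rep), function(rep) {
      pk <- params
      pk$gamma_ih <- ratios[k] * params$gamma_ii
      pk$seed <- params$seed + 1000L * k + rep - 1L
      neighbor_counts(simulate_tissue(pk, composition = composition),
                      min_edge = min_edge)
    })
    if (nrow(d) == 0) {
      return(tibble::tibble(ratio = ratios[k],
                            gamma_ih = ratios[k] * params$gamma_ii,
                            n_center = 0L, mean_neighbors = NA_real_,
                            sd_neighbors = NA_real_, mean_like = NA_real_,
                            sd_like = NA_real_, pattern = NA_character_))
    }
    tibble::tibble(ratio = ratios[k], gamma_ih = ratios[k] * params$gamma_ii,
                   n_center = nrow(d),
                   mean_neighbors = mean(d$n_neighbors),
                   sd_neighbors = stats::sd(d$n_neighbors),
                   mean_like = mean(d$n_like),
                   sd_like = stats::sd(d$n_like),
                   pattern = classify_pattern(mean(d$n_like)))
  })
  structure(rows, class = c("gamma_sweep", class(rows)))
}

#' Locate the honeycomb-to-checkerboard transition in a sweep
#'
#' The transition interval is bracketed by the largest ratio still classified
#' honeycomb and the smallest ratio classified checkerboard. A
#' non-monotone classification sequence along the grid is reported as
#' ambiguous rather than silently bracketed.
#'
#' @param sweep a `gamma_sweep` tibble.
#' @return A list with `lower` (largest honeycomb ratio), `upper` (smallest
#'   checkerboard ratio), `leaves_honeycomb` (smallest ratio no longer
#'   classified honeycomb) and `ambiguous` (logical); entries are `NA` when
#'   the regime is absent from the grid.
#' @export
estimate_transition <- function(sweep) {
  ord <- c(honeycomb = 1L, transitional = 2L, checkerboard = 3L)
  stage <- ord[sweep$pattern]
  ambiguous <- anyNA(stage) || is.unsorted(stage)
  hc <- sweep$ratio[sweep$pattern == "honeycomb"]
  cb <- sweep$ratio[sweep$pattern == "checkerboard"]
  nhc <- sweep$ratio[is.na(stage) | sweep$pattern != "honeycomb"]
  list(lower = if (length(hc)) max(hc) else NA_real_,
       upper = if (length(cb)) min(cb) else NA_real_,
       leaves_honeycomb = if (length(nhc)) min(nhc) else NA_real_,
       ambiguous = ambiguous)
}

#' Shuffle-null for like-neighbor statistics
#'
#' Randomly permutes the cell labels within each snapshot and recomputes the
#' pooled neighbor statistics. Under the null of no sorting, the expected
#' like fraction equals the label frequency, so a checkerboard's like-neighbor
#' deficit disappears.
#'
#' @param x a `tissue_sim` or its `edges` tibble.
#' @param seed seed for the permutation.
#' @return A `neighbor_stats` row for the shuffled labels.
#' @export
shuffle_null_stats <- function(x, seed = 1L) {
  edges <- edges_of(x)
  long <- dplyr::bind_rows(
    dplyr::transmute(edges, snapshot = .data$snapshot, cell = .data$i,
                     label = .data$label_i),
    dplyr::transmute(edges, snapshot = .data$snapshot, cell = .data$j,
                     label = .data$label_j))
  labs <- dplyr::distinct(long, .data$snapshot, .data$cell, .data$label)
  shuffled <- withr::with_seed(seed, {
    dplyr::mutate(
      dplyr::group_by(labs, .data$snapshot),
      new_label = {
        cellmask <- .data$label != "ENV"
        nl <- .data$label
        nl[cellmask] <- sample(as.character(.data$label[cellmask]))
        nl
      }) |> dplyr::ungroup()
  })
  relabeled <- edges |>
    dplyr::left_join(dplyr::select(shuffled, "snapshot", "cell",
                                   li = "new_label"),
                     by = c("snapshot", i = "cell")) |>
    dplyr::left_join(dplyr::select(shuffled, "snapshot", "cell",
                                   lj = "new_label"),
                     by = c("snapshot", j = "cell")) |>
    dplyr::mutate(label_i = factor(.data$li, levels = cell_labels),
                  label_j = factor(.data$lj, levels = cell_labels)) |>
    dplyr::select(-"li", -"lj")
  neighbor_stats(relabeled)
}

#' Plot an adhesion-ratio sweep
#'
#' @param object a `gamma_sweep` tibble.
#' @param ... unused.
#' @return A ggplot: mean total and like neighbors vs ratio, with SD ribbons.
#' @export
autoplot.gamma_sweep <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::transmute(object, ratio = .data$ratio, metric = "total neighbors",
                     mean = .data$mean_neighbors, sd = .data$sd_neighbors),
    dplyr::transmute(object, ratio = .data$ratio, metric = "like neighbors",
                     mean = .data$mean_like, sd = .data$sd_like))
  ggplot2::ggplot(d, ggplot2::aes(.data$ratio, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "gamma_IH : gamma_II", y = "neighbors per center cell") +
    ggplot2::theme_minimal()
}
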