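#' Snapshot summary metrics for cytoneme simulations
#'
#' `mean_length()` averages the per-snapshot mean cytoneme length and reports
#' mean and SD over snapshots. `interaction_counts()` returns the total number
#' of established pairwise segment interactions per snapshot.
#' `length_contact_correlation()` is the Pearson correlation between length
#' and per-cytoneme established-interaction count, pooled over individual
#' cytonemes across all snapshots.
#'
#' @param sim a `cytoneme_sim` object (or, for `length_contact_correlation()`,
#'   any tibble with `length` and `contacts` columns).
#' @return `mean_length()`: one-row tibble `mean`, `sd`, `n`;
#'   `interaction_counts()`: tibble `snapshot`, `interactions`;
#'   `length_contact_correlation()`: a single numeric in `[-1, 1]`.
#' @export
mean_length <- function(sim) {
  snaps <- if (inherits(sim, "cytoneme_sim")) sim$snapshots else sim
  if (nrow(snaps) == 0) stop("no snapshots", call. = FALSE)
  per <- dplyr::summarise(dplyr::group_by(snaps, .data$snapshot),
                          m = mean(.data$length))
  tibble::tibble(mean = mean(per$m),
                 sd = if (nrow(per) > 1) stats::sd(per$m) else 0,
                 n = nrow(per))
}

#' @rdname mean_length
#' @export
interaction_counts <- function(sim) {
  stopifnot(inherits(sim, "cytoneme_sim"))
  snaps <- tibble::tibble(snapshot = sort(unique(sim$snapshots$snapshot)))
  counts <- dplyr::summarise(dplyr::group_by(sim$pair_contacts, .data$snapshot),
                             interactions = sum(.data$contacts))
  out <- dplyr::left_join(snaps, counts, by = "snapshot")
  out$interactions[is.na(out$interactions)] <- 0L
  out
}

#' @rdname mean_length
#' @export
length_contact_correlation <- function(sim) {
  d <- if (inherits(sim, "cytoneme_sim")) sim$snapshots else sim
  if (nrow(d) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(d$length) == 0 || stats::sd(d$contacts) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(d$length, d$contacts)
}

#' Identify cytoneme bundles in one snapshot
#'
#' A bundle is a maximal group of cytonemes connected by pairwise links, where
#' two cytonemes are linked when they share more than three established
#' segment contacts (i.e. at least `min_contacts = 4`). Since contacts only
#' exist between neighboring cytonemes, members of a bundle are necessarily
#' close together on the surface. The bundling index of a bundle is the
#' minimum cytoneme length within it times the number of member cytonemes.
#'
#' @param lengths tibble with columns `cytoneme` and `length` for one snapshot.
#' @param pairs tibble with columns `i`, `j`, `contacts` for the same snapshot.
#' @param min_contacts minimum established contacts for a pairwise link
#'   (default 4, a literal "more than three").
#' @return Tibble with one row per bundle: `bundle`, `size`, `min_length`,
#'   `bundling_index`, and a list-column `members`.
#' @examples
#' lengths <- tibble::tibble(cytoneme = 1:3, length = c(5L, 7L, 9L))
#' pairs <- tibble::tibble(i = c(1, 2), j = c(2, 3), contacts = c(5L, 4L))
#' find_bundles(lengths, pairs)  # one bundle of 3, index 15
#' @export
find_bundles <- function(lengths, pairs, min_contacts = 4L) {
  linked <- dplyr::filter(pairs, .data$contacts >= min_contacts)
  if (nrow(linked) == 0) {
    return(tibble::tibble(bundle = integer(), size = integer(),
                          min_length = integer(), bundling_index = numeric(),
                          members = list()))
  }
  g <- igraph::graph_from_data_frame(
    linked[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = lengths$cytoneme))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2)
  purrr::map_dfr(seq_along(keep), function(b) {
    ids <- as.integer(names(comp$membership)[comp$membership == keep[b]])
    len <- lengths$length[match(ids, lengths$cytoneme)]
    tibble::tibble(bundle = b, size = length(ids),
                   min_length = min(len),
                   bundling_index = as.numeric(min(len) * length(ids)),
                   members = list(ids))
  })
}

#' Bundle report over all snapshots of a simulation
#'
#' Applies [find_bundles()] to every snapshot and summarises the composition:
#' how many cytonemes are singular (in no bundle) and how many sit in bundles
#' of each size.
#'
#' @param sim a `cytoneme_sim` object.
#' @param min_contacts see [find_bundles()].
#' @return A list with `bundles` (tibble: `snapshot` + [find_bundles()]
#'   columns) and `proportions` (tibble: `snapshot`, `n_cytonemes`,
#'   `n_singular`, `prop_singular`, `prop_bundled`).
#' @export
bundle_report <- function(sim, min_contacts = 4L) {
  stopifnot(inherits(sim, "cytoneme_sim"))
  n_cyto <- length(unique(sim$snapshots$cytoneme))
  snaps <- split(sim$snapshots, sim$snapshots$snapshot)
  pairs <- split(sim$pair_contacts, sim$pair_contacts$snapshot)
  bundles <- purrr::map_dfr(names(snaps), function(s) {
    pr <- pairs[[s]]
    if (is.null(pr)) return(NULL)
    b <- find_bundles(snaps[[s]], pr, min_contacts)
    if (nrow(b) == 0) return(NULL)
    dplyr::mutate(b, snapshot = as.integer(s), .before = 1)
  })
  per_snap <- tibble::tibble(snapshot = as.integer(names(snaps)),
                             n_cytonemes = n_cyto)
  in_bundle <- if (nrow(bundles) > 0) {
    dplyr::summarise(dplyr::group_by(bundles, .data$snapshot),
                     n_bundled = sum(.data$size))
  } else {
    tibble::tibble(snapshot = integer(), n_bundled = integer())
  }
  proportions <- dplyr::left_join(per_snap, in_bundle, by = "snapshot")
  proportions$n_bundled[is.na(proportions$n_bundled)] <- 0L
  proportions <- dplyr::mutate(proportions,
                               n_singular = .data$n_cytonemes - .data$n_bundled,
                               prop_singular = .data$n_singular / .data$n_cytonemes,
                               prop_bundled = .data$n_bundled / .data$n_cytonemes)
  list(bundles = bundles, proportions = proportions)
}

#' Sweep the trans-interaction strength
#'
#' Runs one full simulation per value of `e_ii` and summarises mean length,
#' interaction counts, bundling index and singular/bundled proportions.
#' Seeds are derived from `params$seed` plus the sweep position so runs are
#' independent but reproducible.
#'
#' @param e_values increasing numeric vector of interaction strengths.
#' @param params base [cytoneme_params()]; `e_ii` and `seed` are overridden
#'   per run.
#' @return An object of class `eii_sweep`: tibble with one row per `e_ii`
#'   (`mean_length`, `sd_length`, `mean_interactions`, `mean_bundling_index`,
#'   `sd_bundling_index`, `n_bundles`, `prop_singular`, `prop_bundled`), with
#'   the per-run simulations in attribute `"sims"`.
#' @export
sweep_eii <- function(e_values, params = cytoneme_params()) {
  stopifnot(!is.unsorted(e_values))
  sims <- purrr::map(seq_along(e_values), function(k) {
    pk <- params
    pk$e_ii <- e_values[k]
    pk$seed <- params$seed + 1000L * k
    simulate_cytonemes(pk)
  })
  rows <- purrr::map2_dfr(sims, e_values, function(sim, e) {
    g <- glance(sim)
    br <- bundle_report(sim)
    idx <- br$bundles$bundling_index
    tibble::tibble(e_ii = e,
                   mean_length = g$mean_length, sd_length = g$sd_length,
                   mean_interactions = g$mean_interactions,
                   sd_interactions = g$sd_interactions,
                   n_bundles = length(idx),
                   mean_bundling_index = if (length(idx)) mean(idx) else 0,
                   sd_bundling_index = if (length(idx) > 1) stats::sd(idx) else 0,
                   prop_singular = mean(br$proportions$prop_singular),
                   prop_bundled = mean(br$proportions$prop_bundled))
  })
  structure(rows, class = c("eii_sweep", class(rows)), sims = sims)
}

#' Plot an interaction-strength sweep
#'
#' @param object an `eii_sweep` object from [sweep_eii()].
#' @param ... unused.
#' @return A ggplot object: mean length and mean bundling index vs `e_ii`.
#' @export
autoplot.eii_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "e_ii",
                  length = "mean_length", `bundling index` = "mean_bundling_index"),
    -"e_ii", names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$e_ii, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "trans interaction strength e_ii (kT)", y = NULL) +
    ggplot2::theme_minimal()
}
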