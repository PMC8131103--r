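experiment_names <- c("cytoneme-baseline", "eii-sweep", "vertex-homogeneous",
                      "vertex-mixed", "gamma-sweep", "invasion")

#' Run a named, fully configured experiment
#'
#' Reproduces the package's headline in silico experiments end to end and
#' persists snapshot tables, metrics tables, a JSON metadata record and
#' figure-style plots under `out_dir`. Every run is deterministic given
#' `(name, seed, fast, overrides)`.
#'
#' \describe{
#'   \item{cytoneme-baseline}{cytoneme runs at `e_ii = 0` and `15`; reports
#'     mean lengths, interaction counts and the pooled length-interaction
#'     Pearson correlation at `e_ii = 15`.}
#'   \item{eii-sweep}{cytoneme sweep over `e_ii` in `{0, 5, 15, 30, 50}`:
#'     mean length, bundling index, singular/bundled proportions.}
#'   \item{vertex-homogeneous}{two-color Ihog monolayer (50 red + 50 green);
#'     neighbor statistics per center cell.}
#'   \item{vertex-mixed}{mixed 50 Ihog + 50 Hh monolayer at
#'     `gamma_ih = 30 * gamma_ii`; neighbor statistics.}
#'   \item{gamma-sweep}{adhesion-ratio sweep over `{5, 10, 15, 20, 25, 30,
#'     35}` with transition bracketing.}
#'   \item{invasion}{50 Hh cells added to a relaxed 50-cell Ihog aggregate at
#'     ratio 30; classifies the final pattern.}
#' }
#'
#' @param name experiment name (see above).
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param seed master seed.
#' @param fast logical; divide step and snapshot counts by 10 for quick runs.
#' @param overrides named list of parameter overrides applied to the
#'   experiment's base [cytoneme_params()] / [vertex_params()].
#' @return A report list (class `adhesim_report`) with elements `name`,
#'   `metrics` (named list of scalar summaries), `tables` (named list of
#'   tibbles) and `config`.
#' @export
run_experiment <- function(name, out_dir = NULL, seed = 1L, fast = FALSE,
                           overrides = list()) {
  if (!name %in% experiment_names)
    stop("unknown experiment '", name, "'; available: ",
         paste(experiment_names, collapse = ", "), call. = FALSE)
  scale <- if (fast) 10 else 1
  cyto_base <- function(...) {
    args <- list(total_steps = 5e6 / scale, burn_in_steps = 1e6 / scale,
                 snapshot_interval = 4000 / scale, snapshot_count = 1001L,
                 seed = seed)
    args <- modifyList(args, list(...))
    args <- modifyList(args, overrides)
    do.call(cytoneme_params, args)
  }
  vx_base <- function(...) {
    args <- list(total_steps = 2.5e6 / scale, burn_in = 2.05e6 / scale,
                 snapshot_count = 50L, seed = seed)
    args <- modifyList(args, list(...))
    args <- modifyList(args, overrides)
    do.call(vertex_params, args)
  }
  # replicate-pooled neighbor statistics: one simulation per seed offset,
  # per-center-cell observations pooled before summarising
  pooled_vertex <- function(n_rep, composition, ...) {
    sims <- purrr::map(seq_len(n_rep), function(k) {
      simulate_tissue(vx_base(seed = seed + 101L * k, ...), composition)
    })
    d <- purrr::map_dfr(sims, neighbor_counts)
    stats <- structure(tibble::tibble(
      n_center = nrow(d),
      mean_neighbors = mean(d$n_neighbors), sd_neighbors = stats::sd(d$n_neighbors),
      mean_like = mean(d$n_like), sd_like = stats::sd(d$n_like)),
      class = c("neighbor_stats", "tbl_df", "tbl", "data.frame"))
    list(sims = sims, stats = stats)
  }
  metrics <- list(); tables <- list(); plots <- list()

  if (name == "cytoneme-baseline") {
    sim0 <- simulate_cytonemes(cyto_base(e_ii = 0))
    sim15 <- simulate_cytonemes(cyto_base(e_ii = 15, seed = seed + 1L))
    g <- dplyr::bind_rows(glance(sim0), glance(sim15))
    metrics <- list(mean_length_e0 = g$mean_length[1],
                    mean_length_e15 = g$mean_length[2],
                    interactions_e0 = g$mean_interactions[1],
                    interactions_e15 = g$mean_interactions[2],
                    pearson_r_e15 = length_contact_correlation(sim15))
    tables <- list(summary = g, snapshots_e0 = sim0$snapshots,
                   snapshots_e15 = sim15$snapshots)
    plots <- list(configuration = autoplot(sim15))
  } else if (name == "eii-sweep") {
    sw <- sweep_eii(c(0, 5, 15, 30, 50), cyto_base())
    metrics <- as.list(setNames(sw$mean_length,
                                paste0("mean_length_e", sw$e_ii)))
    metrics <- c(metrics, as.list(setNames(sw$mean_bundling_index,
                                           paste0("bundling_index_e", sw$e_ii))))
    tables <- list(sweep = tibble::as_tibble(sw))
    plots <- list(sweep = autoplot(sw))
  } else if (name == "vertex-homogeneous") {
    pv <- pooled_vertex(6L, c(IHOG_RED = 50, IHOG_GREEN = 50))
    ns <- pv$stats
    metrics <- list(mean_neighbors = ns$mean_neighbors,
                    sd_neighbors = ns$sd_neighbors,
                    mean_like = ns$mean_like, sd_like = ns$sd_like,
                    n_center = ns$n_center)
    tables <- list(neighbor_stats = tibble::as_tibble(ns),
                   cells = pv$sims[[1]]$cells, trace = pv$sims[[1]]$trace)
    plots <- list(tessellation = autoplot(pv$sims[[1]]))
  } else if (name == "vertex-mixed") {
    pv <- pooled_vertex(6L, c(IHOG_RED = 50, HH = 50), gamma_ih = 30 * 0.25)
    ns <- pv$stats
    metrics <- list(mean_neighbors = ns$mean_neighbors,
                    sd_neighbors = ns$sd_neighbors,
                    mean_like = ns$mean_like, sd_like = ns$sd_like,
                    n_center = ns$n_center, pattern = classify_pattern(ns))
    tables <- list(neighbor_stats = tibble::as_tibble(ns),
                   cells = pv$sims[[1]]$cells, trace = pv$sims[[1]]$trace)
    plots <- list(tessellation = autoplot(pv$sims[[1]]))
  } else if (name == "gamma-sweep") {
    sw <- gamma_sweep(c(5, 10, 15, 20, 25, 30, 35), vx_base())
    tr <- estimate_transition(sw)
    metrics <- list(transition_lower = tr$lower, transition_upper = tr$upper,
                    ambiguous = tr$ambiguous)
    tables <- list(sweep = tibble::as_tibble(sw))
    plots <- list(sweep = autoplot(sw))
  } else if (name == "invasion") {
    inv <- invasion_protocol(vx_base(n_cells = 50L, gamma_ih = 30 * 0.25))
    ns <- neighbor_stats(inv$phase2)
    metrics <- list(final_pattern = classify_pattern(ns),
                    mean_like = ns$mean_like,
                    mean_neighbors = ns$mean_neighbors)
    tables <- list(neighbor_stats = tibble::as_tibble(ns),
                   inserted = inv$inserted)
    plots <- list(final = autoplot(inv$phase2))
  }

  report <- structure(list(name = name, metrics = metrics, tables = tables,
                           config = list(seed = seed, fast = fast,
                                         overrides = overrides)),
                      class = "adhesim_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tn in names(tables))
      readr::write_csv(tables[[tn]], file.path(out_dir,
                                               paste0(name, "-", tn, ".csv")))
    jsonlite::write_json(
      list(experiment = name, seed = seed, fast = fast,
           metrics = metrics[!vapply(metrics, is.character, logical(1))],
           timestamp = format(Sys.time())),
      file.path(out_dir, paste0(name, "-metadata.json")),
      auto_unbox = TRUE, digits = NA)
    for (pn in names(plots))
      suppressMessages(ggplot2::ggsave(
        file.path(out_dir, paste0(name, "-", pn, ".png")),
        plots[[pn]], width = 6, height = 4, dpi = 150))
  }
  report
}

#' Compare an experiment report against reference targets
#'
#' @param report an `adhesim_report` from [run_experiment()].
#' @param targets tibble with columns `id`, `metric` (name in
#'   `report$metrics`), `value`, `tol` and `cmp` (`"eq"` within `tol`,
#'   `"le"`, `"ge"`).
#' @return Tibble: `id`, `metric`, `observed`, `value`, `status`
#'   (`"pass"`, `"fail"` or `"not evaluated"` when the metric is absent).
#' @export
compare_to_reference <- function(report, targets) {
  purrr::pmap_dfr(targets, function(id, metric, value, tol, cmp, ...) {
    obs <- report$metrics[[metric]]
    status <- if (is.null(obs) || is.na(obs)) "not evaluated"
    else if (cmp == "eq") ifelse(abs(obs - value) <= tol, "pass", "fail")
    else if (cmp == "le") ifelse(obs <= value + tol, "pass", "fail")
    else if (cmp == "ge") ifelse(obs >= value - tol, "pass", "fail")
    else stop("unknown cmp: ", cmp, call. = FALSE)
    tibble::tibble(id = id, metric = metric,
                   observed = if (is.null(obs)) NA_real_ else as.numeric(obs),
                   value = value, status = status)
  })
}
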