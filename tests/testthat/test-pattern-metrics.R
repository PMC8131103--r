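# hand-built edge tables: a 3x3 block of cells inside an ENV sea, and a
# periodic 4x4 two-color checkerboard with no ENV at all
lv <- c("IHOG_RED", "IHOG_GREEN", "HH", "ENV")
fct <- function(x) factor(x, levels = lv)

block3x3_edges <- function() {
  # cells 1..9 on a 3x3 grid (cell 5 in the middle), ENV ids 100+
  grid <- expand.grid(cx = 1:3, cy = 1:3)
  id <- function(cx, cy) (cy - 1) * 3 + cx
  rows <- list()
  for (k in seq_len(9)) {
    cx <- grid$cx[k]; cy <- grid$cy[k]
    nbs <- list(c(cx + 1, cy), c(cx, cy + 1))
    for (nb in nbs) {
      if (nb[1] <= 3 && nb[2] <= 3)
        rows[[length(rows) + 1]] <- data.frame(i = id(cx, cy),
                                               j = id(nb[1], nb[2]))
    }
    # boundary cells touch the surrounding ENV polygon(s)
    if (cx %in% c(1, 3) || cy %in% c(1, 3))
      rows[[length(rows) + 1]] <- data.frame(i = id(cx, cy), j = 100 + k)
  }
  e <- do.call(rbind, rows)
  tibble::tibble(snapshot = 1L, i = e$i, j = e$j,
                 label_i = fct(ifelse(e$i <= 9, "IHOG_RED", "ENV")),
                 label_j = fct(ifelse(e$j <= 9, "IHOG_RED", "ENV")),
                 length = 1)
}

checkerboard4x4_edges <- function() {
  # periodic square lattice, labels alternating RED / HH
  id <- function(cx, cy) (cy %% 4) * 4 + (cx %% 4) + 1
  lab <- function(k) ifelse(((k - 1) %% 4 + (k - 1) %/% 4) %% 2 == 0,
                            "IHOG_RED", "HH")
  rows <- list()
  for (cx in 0:3) for (cy in 0:3) {
    a <- id(cx, cy)
    for (nb in list(id(cx + 1, cy), id(cx, cy + 1))) {
      rows[[length(rows) + 1]] <- data.frame(i = min(a, nb), j = max(a, nb))
    }
  }
  e <- unique(do.call(rbind, rows))
  tibble::tibble(snapshot = 1L, i = e$i, j = e$j,
                 label_i = fct(lab(e$i)), label_j = fct(lab(e$j)), length = 1)
}

test_that("center cells are exactly the cells without ENV neighbors", {
  ctr <- center_cells(block3x3_edges())
  expect_equal(ctr$cell, 5L)            # only the middle of the 3x3 block
  cb <- checkerboard4x4_edges()
  expect_equal(sort(center_cells(cb)$cell), 1:16)  # no ENV anywhere
  # a lone cell fully surrounded by ENV
  lone <- tibble::tibble(snapshot = 1L, i = 1L, j = 101:104,
                         label_i = fct("HH"), label_j = fct("ENV"), length = 1)
  expect_equal(nrow(center_cells(lone)), 0)
})

test_that("neighbor counts separate total and like neighbors", {
  nc <- neighbor_counts(block3x3_edges())
  expect_equal(nc$n_neighbors, 4L)      # the middle cell has 4 edge neighbors
  expect_equal(nc$n_like, 4L)           # monotypic: all like
  cb <- neighbor_counts(checkerboard4x4_edges())
  expect_equal(nrow(cb), 16)
  expect_true(all(cb$n_neighbors == 4L))
  expect_true(all(cb$n_like == 0L))     # perfect checkerboard
})

test_that("pooled neighbor statistics and empty-stats flag behave", {
  ns <- neighbor_stats(checkerboard4x4_edges())
  expect_equal(ns$n_center, 16L)
  expect_equal(ns$mean_neighbors, 4)
  expect_equal(ns$mean_like, 0)
  expect_equal(ns$sd_like, 0)
  lone <- tibble::tibble(snapshot = 1L, i = 1L, j = 101:104,
                         label_i = fct("HH"), label_j = fct("ENV"), length = 1)
  empty <- neighbor_stats(lone)
  expect_equal(empty$n_center, 0L)
  expect_true(is.na(empty$mean_like))
})

test_that("mean_like never exceeds mean_neighbors on simulated tissue", {
  sim <- cached("vx_short", simulate_tissue(
    short_vertex(seed = 5, recompute_interval = 0),
    c(IHOG_RED = 10, IHOG_GREEN = 10), trace_moves = 30000L))
  nc <- neighbor_counts(sim)
  if (nrow(nc) > 0) expect_true(all(nc$n_like <= nc$n_neighbors))
  ns <- neighbor_stats(sim)
  if (ns$n_center > 0) expect_lte(ns$mean_like, ns$mean_neighbors)
})

test_that("pattern classification thresholds follow the two observed regimes", {
  expect_equal(classify_pattern(2.4), "honeycomb")
  expect_equal(classify_pattern(0.3), "checkerboard")
  expect_equal(classify_pattern(1.2), "transitional")
  expect_equal(classify_pattern(1.2, checkerboard_max = 1.3), "checkerboard")
  expect_true(is.na(classify_pattern(NA_real_)))
  # monotone: higher mean_like never moves the class toward checkerboard
  cls <- vapply(c(0.2, 0.9, 1.1, 1.6, 3), classify_pattern, character(1))
  expect_equal(cls, c("checkerboard", "checkerboard", "transitional",
                      "honeycomb", "honeycomb"))
})

test_that("transition bracketing reports interval ends and flags ambiguity", {
  sw <- tibble::tibble(ratio = c(5, 10, 15, 20, 25, 30, 35),
                       pattern = c("honeycomb", "honeycomb", "honeycomb",
                                   "honeycomb", "transitional",
                                   "checkerboard", "checkerboard"))
  tr <- estimate_transition(sw)
  expect_equal(tr$lower, 20)
  expect_equal(tr$upper, 30)
  expect_false(tr$ambiguous)
  sw2 <- dplyr::mutate(sw, pattern = replace(pattern, 2, "checkerboard"))
  expect_true(estimate_transition(sw2)$ambiguous)
})

test_that("label shuffling restores the random-mixing like fraction", {
  cb <- checkerboard4x4_edges()
  base <- neighbor_stats(cb)
  expect_equal(base$mean_like, 0)
  sh <- purrr::map_dbl(1:20, ~shuffle_null_stats(cb, seed = .x)$mean_like)
  # random half/half labels on 4 neighbors: expected like about 4 * 7/15
  expect_gt(mean(sh), 1.4)
  expect_lt(mean(sh), 2.4)
})
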