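test_that("elongation weight decays exponentially with length", {
  p <- cytoneme_params()
  expect_equal(elongation_prob(0, p), 5)
  expect_equal(elongation_prob(10, p), 5 * exp(-2), tolerance = 1e-12)
  p0 <- cytoneme_params(alpha = 0)
  expect_equal(elongation_prob(c(0, 3, 17), p0), rep(5, 3))
  lens <- 0:40
  expect_true(all(diff(elongation_prob(lens, p)) < 0))
  expect_error(elongation_prob(-1, p), "non-negative")
})

test_that("shrinkage weight drops by one trans-interaction barrier per tip contact", {
  p <- cytoneme_params(e_ii = 15)
  expect_equal(shrink_prob(0, p), 0.5)
  expect_equal(shrink_prob(1, p), 0.5 * exp(-15), tolerance = 1e-12)
  expect_equal(shrink_prob(3, cytoneme_params(e_ii = 0)), 0.5)
  expect_true(all(diff(shrink_prob(0:5, p)) < 0))
  expect_error(shrink_prob(-2, p), "non-negative")
})

test_that("contact-establishment probability is a safe logistic", {
  expect_equal(interaction_prob(0), 0.5)
  expect_equal(interaction_prob(15), exp(15) / (1 + exp(15)), tolerance = 1e-12)
  expect_equal(interaction_prob(1000), 1)   # no overflow
  e <- seq(0, 50, by = 5)
  expect_true(all(diff(interaction_prob(e)) >= 0))
  expect_true(all(interaction_prob(e) >= 0.5 & interaction_prob(e) <= 1))
  expect_error(interaction_prob(-1), "non-negative")
})

test_that("initial placement is seeded, distinct, zero-length", {
  p <- cytoneme_params()
  s1 <- make_initial_cytonemes(p)
  s2 <- make_initial_cytonemes(p)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 30)
  expect_false(anyDuplicated(s1$position) > 0)
  expect_true(all(s1$length == 0L))
  expect_true(all(s1$position >= 0 & s1$position < 100))
  full <- make_initial_cytonemes(cytoneme_params(surface_length = 10L,
                                                 occupancy_fraction = 1))
  expect_setequal(full$position, 0:9)
})

test_that("per-pair contact counts match Binomial(levels, p) moments", {
  # m aligned levels, each established independently with the logistic prob
  draws0 <- adhesim:::cyto_sample_contacts_cpp(4L, 0.5, 40000L, 7L)
  expect_equal(mean(draws0), 2.0, tolerance = 0.03)
  expect_equal(var(draws0), 1.0, tolerance = 0.05)
  p50 <- interaction_prob(50)
  draws50 <- adhesim:::cyto_sample_contacts_cpp(6L, p50, 20000L, 8L)
  expect_true(mean(draws50 == 6L) >= 1 - 1e-6)
})

test_that("simulation conserves cytoneme count and position distinctness", {
  sim <- cached("cyto_short_e5", simulate_cytonemes(short_cyto(e_ii = 5, seed = 3)))
  per_snap <- dplyr::count(sim$snapshots, snapshot)
  expect_true(all(per_snap$n == 30))
  dup <- dplyr::summarise(dplyr::group_by(sim$snapshots, snapshot),
                          dup = anyDuplicated(position) > 0)
  expect_false(any(dup$dup))
  expect_true(all(sim$snapshots$length >= 0))
  expect_true(all(sim$snapshots$contacts >= 0))
})

test_that("fixed seed reproduces the snapshot sequence bit-for-bit", {
  a <- simulate_cytonemes(short_cyto(e_ii = 5, seed = 11))
  b <- simulate_cytonemes(short_cyto(e_ii = 5, seed = 11))
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$pair_contacts, b$pair_contacts)
  c <- simulate_cytonemes(short_cyto(e_ii = 5, seed = 12))
  expect_false(identical(a$snapshots, c$snapshots))
})

test_that("schedule inconsistency is a configuration error", {
  expect_error(cytoneme_params(total_steps = 1000, burn_in_steps = 500,
                               snapshot_interval = 100, snapshot_count = 20),
               "schedule")
})

test_that("isolated cytoneme length matches the enumerated birth-death chain", {
  # odd snapshot interval so both parity classes of the +-1 chain are sampled
  p <- cytoneme_params(surface_length = 10L, occupancy_fraction = 0.1,
                       total_steps = 3.2e5, burn_in_steps = 2e4,
                       snapshot_interval = 3, snapshot_count = 1e5, seed = 2)
  sim <- cached("cyto_birthdeath", simulate_cytonemes(p))
  expect_equal(nrow(sim$snapshots), 1e5)  # a single cytoneme
  emp <- tabulate(sim$snapshots$length + 1L, nbins = 201) / nrow(sim$snapshots)
  ref <- birth_death_stationary(p, max_length = 200L)
  tv <- 0.5 * sum(abs(emp - ref$prob))
  expect_lt(tv, 0.02)
  expect_equal(mean(sim$snapshots$length), sum(ref$length * ref$prob),
               tolerance = 0.02)
})

test_that("translocation-only toy system samples the enumerated Boltzmann law", {
  toy <- toy_cytoneme_system(surface_length = 6L, lengths = c(2L, 2L))
  e_ii <- 1.5
  ref <- enumerate_toy_boltzmann(toy, e_ii)
  # adjacency probability: marginal of the enumerated distribution
  p_adj_ref <- sum(ref$prob[ref$pairs > 0])
  p <- cytoneme_params(surface_length = 6L, occupancy_fraction = 0.34,
                       e_ii = e_ii, fixed_lengths = TRUE,
                       p_contact_override = 1,
                       total_steps = 2.2e5, burn_in_steps = 2e4,
                       snapshot_interval = 2, snapshot_count = 1e5, seed = 9)
  init <- tibble::tibble(cytoneme = 1:2, position = c(0L, 3L),
                         length = c(2L, 2L))
  sim <- simulate_cytonemes(p, initial = init)
  pos <- tidyr::pivot_wider(sim$snapshots[, c("snapshot", "cytoneme", "position")],
                            names_from = "cytoneme", values_from = "position")
  d <- abs(pos$`1` - pos$`2`)
  adj <- pmin(d, 6 - d) <= 1
  p_adj <- mean(adj)
  # 3-sigma band using an effective sample size from the lag-1 autocorrelation
  rho <- stats::cor(adj[-1], adj[-length(adj)])
  n_eff <- length(adj) * (1 - rho) / (1 + rho)
  se <- sqrt(p_adj_ref * (1 - p_adj_ref) / n_eff)
  expect_lt(abs(p_adj - p_adj_ref), 3 * se + 1e-3)
})

test_that("toy Boltzmann enumeration has exact limiting behavior", {
  toy <- toy_cytoneme_system(surface_length = 6L, lengths = c(2L, 2L))
  u <- enumerate_toy_boltzmann(toy, 0)
  expect_equal(sum(u$prob), 1)
  expect_true(all(abs(u$prob - 1 / nrow(u)) < 1e-12))  # uniform at zero coupling
  b <- enumerate_toy_boltzmann(toy, 1)
  expect_equal(sum(b$prob), 1)
  # two-configuration check: weights in ratio exp(pairs difference)
  w01 <- b$prob[b$pairs == 2][1] / b$prob[b$pairs == 0][1]
  expect_equal(w01, exp(2), tolerance = 1e-12)
  expect_error(enumerate_toy_boltzmann(
    toy_cytoneme_system(8L, c(1L, 1L, 1L)), 0), NA)
})
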