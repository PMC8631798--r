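test_that("certain transmission labels everything and doubles every divergent neuron", {
  cohort <- generate_cohort(lumbar_config(n = 2000, d = 0.3), seed = 1)
  cells <- simulate_infection(cohort, virus_params(efficiency = 1), seed = 2)
  expect_equal(nrow(cells), nrow(cohort))
  both <- cells$connectivity == "both"
  expect_true(all(cells$label_a[both] & cells$label_b[both]))
  expect_true(all(xor(cells$label_a[!both], cells$label_b[!both])))
})

test_that("no cell ever carries the colour of a pool its neuron does not contact", {
  for (seed in 1:5) {
    cells <- labelled_lumbar(n = 5000, d = 0.2, e = 0.4, seed = seed)
    expect_false(any(cells$label_a & cells$connectivity == "B_only"))
    expect_false(any(cells$label_b & cells$connectivity == "A_only"))
    expect_true(all(cells$label_a | cells$label_b))
  }
})

test_that("empty input returns an empty labelled table, not an error", {
  cohort <- generate_cohort(lumbar_config(n = 10, d = 0), seed = 1)[0, ]
  cells <- simulate_infection(cohort, virus_params(0.25), seed = 1)
  expect_equal(nrow(cells), 0)
  expect_true(all(c("label_a", "label_b") %in% names(cells)))
})

test_that("fully divergent cohort shows the e/(2-e) double fraction", {
  # brute-force expectation: outcomes {both, A, B, none} have probabilities
  # {e^2, e(1-e), (1-e)e, (1-e)^2}; among labelled, both = e^2/(2e - e^2)
  n <- 100000; e <- 0.25
  cohort <- all_divergent_cohort(n, seed = 3)
  cells <- simulate_infection(cohort, virus_params(e), seed = 4)
  frac_double <- mean(cells$label_a & cells$label_b)
  p <- e / (2 - e)
  se <- sqrt(p * (1 - p) / nrow(cells))
  expect_lt(abs(frac_double - p), 3 * se)

  # the full outcome distribution matches the enumeration, counting 'none'
  n_both <- sum(cells$label_a & cells$label_b)
  n_a <- sum(cells$label_a & !cells$label_b)
  n_b <- sum(cells$label_b & !cells$label_a)
  n_none <- n - nrow(cells)
  probs <- c(e^2, e * (1 - e), (1 - e) * e, (1 - e)^2)
  obs <- c(n_both, n_a, n_b, n_none)
  for (i in 1:4) {
    expect_lt(abs(obs[i] - n * probs[i]), 3 * sqrt(n * probs[i] * (1 - probs[i])))
  }
})

test_that("observed double fraction converges to the closed form", {
  d <- 0.18; e <- 0.25
  cells <- labelled_lumbar(n = 1e5, d = d, e = e, seed = 8)
  r_hat <- mean(cells$label_a & cells$label_b)
  r <- observed_rate(d, e)
  expect_lt(abs(r_hat - r), 3 * sqrt(r * (1 - r) / nrow(cells)))
})

test_that("interference strictly depresses double labelling", {
  n <- 1e5
  cohort <- generate_cohort(lumbar_config(n = n, d = 0.3), seed = 10)
  mean_doubles <- vapply(c(0, 0.5, 0.9), function(rho) {
    counts <- vapply(1:20, function(s) {
      cells <- simulate_infection(cohort, virus_params(0.25, rho), seed = s)
      sum(cells$label_a & cells$label_b)
    }, numeric(1))
    mean(counts)
  }, numeric(1))
  expect_true(all(diff(mean_doubles) < 0))
})

test_that("identical seed and inputs give byte-identical labelled tables", {
  cohort <- generate_cohort(lumbar_config(n = 1000, d = 0.2), seed = 1)
  a <- simulate_infection(cohort, virus_params(0.25), seed = 99)
  b <- simulate_infection(cohort, virus_params(0.25), seed = 99)
  expect_identical(a, b)
})

test_that("section spillover duplicates cells onto the adjacent section", {
  cohort <- generate_cohort(lumbar_config(n = 5000, d = 0.2), seed = 2)
  base <- simulate_infection(cohort, virus_params(0.5), seed = 3)
  spill <- simulate_infection(cohort, virus_params(0.5), seed = 3,
                              spillover_prob = 0.3)
  expect_gt(nrow(spill), nrow(base))
  dups <- spill[duplicated(spill$neuron_id) | duplicated(spill$neuron_id, fromLast = TRUE), ]
  per <- split(dups$section_index, dups$neuron_id)
  expect_true(all(vapply(per, function(s) diff(sort(s)) == 1L, logical(1))))
  # duplicated rows inflate a naive every-section count but a one-in-three
  # subsample never keeps both copies of the same neuron
  kept <- subsample_sections(spill, "lumbar", k = 3, offset = 0)
  expect_false(any(duplicated(kept$neuron_id)))
})

test_that("motoneurons are always labelled by their own pool's virus", {
  cfg <- cord_config(
    regions = list(lumbar = region_spec(100, 0.2, n_motoneurons = 30)),
    n_animals = 1
  )
  cohort <- generate_cohort(cfg, seed = 4)
  cells <- simulate_infection(cohort, virus_params(0.1), seed = 5)
  mn <- dplyr::filter(cells, is_motoneuron)
  expect_equal(nrow(mn), 30)
  expect_true(all(xor(mn$label_a, mn$label_b)))
})
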