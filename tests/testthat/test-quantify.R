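bounds1 <- data.frame(canal_x = 100, canal_y = -50,
                      x_min = -700, x_max = 900, y_min = -650, y_max = 850)

test_that("coordinate normalisation maps canal and borders to the unit frame", {
  pts <- data.frame(
    x = c(100, 900, -700, 100, 100, 500),
    y = c(-50, -50, -50, 850, -650, 400)
  )
  out <- normalize_coordinates(pts, bounds1, injection_side = "right")
  expect_equal(out$x_norm, c(0, 1, -1, 0, 0, 0.5))
  expect_equal(out$y_norm, c(0, 0, 0, 1, -1, 0.5))
  expect_false(any(out$out_of_bounds))
  # a dorsal point on the injection side is (+, +)
  dorsal_ipsi <- normalize_coordinates(data.frame(x = 300, y = 200), bounds1,
                                       injection_side = "right")
  expect_gt(dorsal_ipsi$x_norm, 0)
  expect_gt(dorsal_ipsi$y_norm, 0)
  # left-side injection flips ipsilaterality, not dorsality
  left <- normalize_coordinates(pts, bounds1, injection_side = "left")
  expect_equal(left$x_norm, -out$x_norm)
  expect_equal(left$y_norm, out$y_norm)
})

test_that("points outside the stated bounds are flagged, not dropped silently", {
  pts <- data.frame(x = c(100, 1500), y = c(-50, 0))
  out <- normalize_coordinates(pts, bounds1, "right")
  expect_equal(out$out_of_bounds, c(FALSE, TRUE))
  expect_true(is.na(out$x_norm[2]))
  expect_error(
    normalize_coordinates(pts, transform(bounds1, canal_x = 1000), "right"),
    regexp = "enclose"
  )
})

test_that("region-wise bounds are joined by region", {
  pts <- data.frame(region = c("lumbar", "cervical"), x = c(200, 200), y = c(0, 0))
  b <- rbind(cbind(region = "lumbar", bounds1),
             cbind(region = "cervical", transform(bounds1, x_max = 300)))
  out <- normalize_coordinates(pts, b, "right")
  expect_equal(out$x_norm, c((200 - 100) / 800, (200 - 100) / 200))
  expect_error(normalize_coordinates(data.frame(region = "sacral", x = 1, y = 1), b, "right"),
               regexp = "sacral")
})

test_that("quadrant assignment follows the sign convention with a deterministic tie rule", {
  expect_equal(as.character(assign_quadrant(0.3, 0.5)), "DI")
  expect_equal(as.character(assign_quadrant(-0.2, -0.7)), "VC")
  expect_equal(as.character(assign_quadrant(-0.2, 0.7)), "DC")
  expect_equal(as.character(assign_quadrant(0.2, -0.7)), "VI")
  # ties go ipsilateral/dorsal
  expect_equal(as.character(assign_quadrant(0, 0)), "DI")
  expect_equal(as.character(assign_quadrant(0, -0.1)), "VI")
  expect_true(is.na(assign_quadrant(NaN, 0.5)))
})

test_that("quadrant counts conserve the total cell count", {
  cells <- add_quadrant(labelled_lumbar(n = 5000, d = 0.2, e = 0.3, seed = 21))
  expect_false(any(is.na(cells$quadrant)))
  expect_equal(sum(table(cells$quadrant)), nrow(cells))
  summ <- divergence_summary(cells, group_by = c("region", "quadrant"))
  expect_equal(sum(summ$n_total), nrow(cells))
})

test_that("one-in-k section subsampling keeps one residue class in one region", {
  cells <- tibble::tibble(
    region = rep(c("lumbar", "thoracic"), each = 9),
    section_index = rep(0:8, 2),
    label_a = TRUE, label_b = FALSE, animal_id = "a1"
  )
  kept <- subsample_sections(cells, "lumbar", k = 3, offset = 0)
  expect_equal(kept$section_index[kept$region == "lumbar"], c(0, 3, 6))
  # other regions pass through untouched
  expect_equal(sum(kept$region == "thoracic"), 9)
  # k = 1 is the identity
  expect_identical(subsample_sections(cells, "lumbar", k = 1), cells)
  expect_error(subsample_sections(cells, "lumbar", k = 3, offset = 3),
               class = "divtrace_config_error")
})

test_that("the three offsets at k = 3 partition the region's cells", {
  cells <- labelled_lumbar(n = 3000, d = 0.2, e = 0.3, seed = 31)
  parts <- lapply(0:2, function(o) subsample_sections(cells, "lumbar", 3, o))
  ids <- lapply(parts, function(p) p$neuron_id)
  expect_equal(sort(unlist(ids)), sort(cells$neuron_id))
  expect_equal(sum(lengths(ids)), nrow(cells))
})

test_that("uniform sections give a binomial one-third retention", {
  n <- 30000
  cells <- tibble::tibble(
    region = "lumbar",
    section_index = withr::with_seed(5L, sample.int(90, n, replace = TRUE) - 1L),
    label_a = TRUE, label_b = FALSE, animal_id = "a1"
  )
  kept <- subsample_sections(cells, "lumbar", k = 3, offset = 0)
  expect_lt(abs(nrow(kept) - n / 3), 3 * sqrt(n * (1 / 3) * (2 / 3)))
})

test_that("divergence summaries reproduce printed pooled percentages", {
  # build a table with the published counts: doubles then singles split A/B
  make_cells <- function(n_double, n_total, region, quadrant) {
    n_single <- n_total - n_double
    tibble::tibble(
      region = region, quadrant = quadrant,
      animal_id = "a1", section_index = 0L,
      label_a = c(rep(TRUE, n_double), rep(TRUE, ceiling(n_single / 2)),
                  rep(FALSE, floor(n_single / 2))),
      label_b = c(rep(TRUE, n_double), rep(FALSE, ceiling(n_single / 2)),
                  rep(TRUE, floor(n_single / 2)))
    )
  }
  tbl <- dplyr::bind_rows(
    make_cells(206, 4341, "lumbar", "all"),
    make_cells(74, 1913, "lumbar_vi_syn", "VI"),
    make_cells(134, 2651, "lumbar_di_ant", "DI"),
    make_cells(5, 142, "lumbar_dc_ant", "DC"),
    make_cells(46 + 42, 188 + 211, "thoracic_di", "DI")
  )
  summ <- divergence_summary(tbl, group_by = "region")
  got <- setNames(summ$rate_percent, summ$region)
  expect_equal(got[["lumbar"]], 4.7)
  expect_equal(got[["lumbar_vi_syn"]], 3.9)
  expect_equal(got[["lumbar_di_ant"]], 5.1)
  expect_equal(got[["lumbar_dc_ant"]], 3.5)
  expect_equal(got[["thoracic_di"]], 22.1)
  expect_equal(summ$n_total,
               summ$n_single_a + summ$n_single_b + summ$n_double)
})

test_that("pooled rate is invariant to row order and colour swap", {
  cells <- labelled_lumbar(n = 4000, d = 0.2, e = 0.3, seed = 41, n_animals = 2)
  base <- divergence_summary(cells, group_by = "region")
  shuffled <- cells[withr::with_seed(1L, sample(nrow(cells))), ]
  expect_equal(divergence_summary(shuffled, "region")$rate_pooled,
               base$rate_pooled)
  swapped <- dplyr::rename(cells, label_a = label_b, label_b = label_a)
  sw <- divergence_summary(swapped, "region")
  expect_equal(sw$rate_pooled, base$rate_pooled)
  expect_equal(sw$n_double, base$n_double)
  expect_equal(sw$n_single_a, base$n_single_b)
})

test_that("cells counted as double are exactly the divergent neurons labelled twice", {
  cells <- labelled_lumbar(n = 20000, d = 0.18, e = 0.25, seed = 51)
  counted_double <- cells$neuron_id[cells$label_a & cells$label_b]
  truth <- cells$neuron_id[cells$connectivity == "both" &
                             cells$label_a & cells$label_b]
  expect_setequal(counted_double, truth)
  expect_true(all(cells$connectivity[cells$label_a & cells$label_b] == "both"))
})

test_that("motoneuron rows never enter premotor denominators", {
  cfg <- cord_config(
    regions = list(lumbar = region_spec(500, 0.2, n_motoneurons = 50)),
    n_animals = 1
  )
  cells <- simulate_infection(generate_cohort(cfg, 1), virus_params(0.5), 2)
  summ <- divergence_summary(cells, group_by = "region")
  expect_equal(summ$n_total, sum(!cells$is_motoneuron))
})

test_that("a table with no doubles reports 0.0%, an empty group is absent", {
  cells <- tibble::tibble(
    region = "lumbar", animal_id = "a1", section_index = 0L,
    label_a = rep(c(TRUE, FALSE), 10), label_b = rep(c(FALSE, TRUE), 10)
  )
  summ <- divergence_summary(cells, "region")
  expect_equal(summ$rate_pooled, 0)
  expect_equal(percent_label(summ$rate_pooled), "0.0%")
  expect_equal(nrow(summ), 1)
})

test_that("percent rendering rounds half away from zero at one decimal", {
  expect_equal(round_half_away(c(4.45, 4.44, -4.45, 0.05), 1),
               c(4.5, 4.4, -4.5, 0.1))
  # property over a grid of count-derived rates
  nd <- 0:50; nt <- 407
  rendered <- round_half_away(100 * nd / nt, 1)
  manual <- floor(abs(100 * nd / nt) * 10 + 0.5) / 10
  expect_equal(rendered, manual)
  expect_equal(percent_label(46 / 1020), "4.5%")
})

test_that("pooled and per-animal mean agree for homogeneous animals and the diagnostic flags heterogeneity", {
  # homogeneous: same size and true rate per animal
  cells <- labelled_lumbar(n = 7000, d = 0.18, e = 0.25, seed = 61, n_animals = 4)
  cons <- rate_consistency(cells, group_by = "region")
  expect_lt(cons$abs_diff, 0.01)
  expect_false(cons$heterogeneous)

  # heterogeneous: animals differ in rate and in size, mean != pooled
  big <- labelled_lumbar(n = 9000, d = 0.02, e = 0.25, seed = 62)
  small <- labelled_lumbar(n = 900, d = 0.6, e = 0.25, seed = 63)
  small$animal_id <- "animal_02"
  mix <- dplyr::bind_rows(big, small)
  cons2 <- rate_consistency(mix, group_by = "region")
  expect_true(cons2$heterogeneous)
  expect_lt(cons2$p_heterogeneity, 0.001)
  expect_gt(cons2$abs_diff, 0.02)
})
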