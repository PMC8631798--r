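#' Round half away from zero
#'
#' Reporting convention for percentages: `round_half_away(4.45, 1)` is 4.5,
#' unlike [round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a fraction as a percentage string
#'
#' @param r Fraction(s) in `[0, 1]`.
#' @param digits Decimal places (default 1, the usual reporting precision).
#' @return Character vector like `"4.7%"`.
#' @export
percent_label <- function(r, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_away(100 * r, digits))
}

#' Summarise divergence rates from a labelled-cell table
#'
#' The core counting stage. After excluding motoneuron and out-of-bounds rows
#' and applying the per-region section-sampling plan, cells are classed as
#' single-A, single-B, or double-labelled (divergent) and counted per group.
#' Two rate estimators are always reported because they answer different
#' questions: the pooled rate `sum(double) / sum(total)` and the unweighted
#' mean +/- SD of per-animal rates. They agree for homogeneous animals and
#' diverge when animals differ in rate or size (see [rate_consistency()]).
#'
#' @param cells Labelled-cell tibble (from [simulate_infection()] or
#'   [read_cell_table()]); needs `label_a`, `label_b`, `animal_id`, plus any
#'   grouping columns.
#' @param group_by Character vector of grouping columns, e.g.
#'   `c("region", "quadrant")`. A `quadrant` key is derived from the
#'   normalised coordinates when not already present.
#' @param sampling Per-region sampling plan as in [default_sampling()];
#'   `NULL` keeps every section.
#'
#' @return A tibble with one row per group: the keys, `n_single_a`,
#'   `n_single_b`, `n_double`, `n_total`, `rate_pooled`, `rate_percent`
#'   (pooled, one decimal, half away from zero), `rate_mean`, `rate_sd`
#'   (per-animal), `n_animals`. Groups without labelled cells are absent, not
#'   zero.
#' @export
#' @examples
#' cfg <- cord_config(list(lumbar = region_spec(2000, 0.18)), n_animals = 3)
#' cells <- simulate_infection(generate_cohort(cfg, 1), virus_params(0.25), 2)
#' divergence_summary(cells, group_by = "region", sampling = default_sampling())
divergence_summary <- function(cells, group_by = "region", sampling = NULL) {
  cells <- premotor_cells(cells)
  if (!is.null(sampling)) cells <- apply_sampling(cells, sampling)
  if ("quadrant" %in% group_by && !"quadrant" %in% names(cells)) {
    cells <- add_quadrant(cells)
  }
  missing_keys <- setdiff(group_by, names(cells))
  if (length(missing_keys) > 0) {
    abort(paste0("grouping column(s) not in table: ",
                 paste(missing_keys, collapse = ", ")),
          class = "divtrace_config_error")
  }

  classed <- dplyr::mutate(
    cells,
    .class = dplyr::case_when(
      .data$label_a & .data$label_b ~ "double",
      .data$label_a ~ "single_a",
      TRUE ~ "single_b"
    )
  )

  counts <- classed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_single_a = sum(.data$.class == "single_a"),
      n_single_b = sum(.data$.class == "single_b"),
      n_double = sum(.data$.class == "double"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate_pooled = .data$n_double / .data$n_total,
      rate_percent = round_half_away(100 * .data$rate_pooled, 1)
    )

  per_animal <- classed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "animal_id")))) |>
    dplyr::summarise(.rate = mean(.data$.class == "double"), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      rate_mean = mean(.data$.rate),
      rate_sd = sd(.data$.rate),
      n_animals = dplyr::n(),
      .groups = "drop"
    )

  if (length(group_by) > 0) {
    dplyr::left_join(counts, per_animal, by = group_by)
  } else {
    dplyr::bind_cols(counts, per_animal)
  }
}

# Premotor denominator: drop motoneurons and unmappable rows.
premotor_cells <- function(cells) {
  cells <- tibble::as_tibble(cells)
  if ("is_motoneuron" %in% names(cells)) {
    cells <- dplyr::filter(cells, !.data$is_motoneuron)
  }
  if ("out_of_bounds" %in% names(cells)) {
    cells <- dplyr::filter(cells, !.data$out_of_bounds)
  }
  cells
}

#' Diagnose disagreement between pooled and per-animal-mean rates
#'
#' The pooled rate weights animals by their cell counts; the per-animal mean
#' weights them equally. When animals are exchangeable the two agree (up to
#' sampling noise); when animals differ in divergence rate and in size the two
#' estimators drift apart. This diagnostic reports both, their difference, and
#' a chi-squared test of homogeneity of per-animal double-labelling
#' proportions, flagging groups where the animal-level rates are
#' statistically heterogeneous.
#'
#' @param cells Labelled-cell tibble.
#' @param group_by Grouping columns (default `"region"`).
#' @param sampling Optional sampling plan, as in [divergence_summary()].
#' @param alpha Significance level of the heterogeneity flag (default 0.05).
#'
#' @return A tibble per group: `rate_pooled`, `rate_mean`, `abs_diff`,
#'   `p_heterogeneity` (`NA` with fewer than two animals), `heterogeneous`.
#' @export
rate_consistency <- function(cells, group_by = "region", sampling = NULL,
                             alpha = 0.05) {
  cells <- premotor_cells(cells)
  if (!is.null(sampling)) cells <- apply_sampling(cells, sampling)
  summ <- divergence_summary(cells, group_by = group_by, sampling = NULL)

  het <- cells |>
    dplyr::mutate(.double = .data$label_a & .data$label_b) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "animal_id")))) |>
    dplyr::summarise(d = sum(.data$.double), n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      p_heterogeneity = homogeneity_p(.data$d, .data$n),
      .groups = "drop"
    )

  summ |>
    dplyr::left_join(het, by = group_by) |>
    dplyr::mutate(
      abs_diff = abs(.data$rate_mean - .data$rate_pooled),
      heterogeneous = !is.na(.data$p_heterogeneity) &
        .data$p_heterogeneity < alpha
    ) |>
    dplyr::select(dplyr::all_of(group_by), "rate_pooled", "rate_mean",
                  "abs_diff", "p_heterogeneity", "heterogeneous")
}

homogeneity_p <- function(d, n) {
  if (length(d) < 2 || sum(d) == 0 || sum(d) == sum(n)) return(NA_real_)
  suppressWarnings(stats::prop.test(d, n)$p.value)
}
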