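#' Binned density profile of labelled cells along a normalised axis
#'
#' Histogram density over a fixed grid on `[-1, 1]` of the medio-lateral (`x`)
#' or dorso-ventral (`y`) normalised coordinate — the tabular counterpart of
#' the violin profiles used to display labelled-cell distributions. Two
#' normalisation modes: `"unit"` scales every group's profile to integrate to
#' 1; `"count"` scales each group to its share of the total cell count, so
#' areas compare group sizes.
#'
#' @param cells Labelled-cell tibble with `x_norm`, `y_norm`.
#' @param axis `"x"` (medio-lateral) or `"y"` (dorso-ventral).
#' @param by Optional grouping column (tidy-select string), e.g. `"region"`.
#' @param n_bins Number of equal bins over `[-1, 1]` (default 40).
#' @param normalize `"unit"` or `"count"`.
#'
#' @return A tibble with `bin_left`, `bin_right`, `density` (plus the grouping
#'   column when `by` is given). Empty input gives an empty profile.
#' @export
#' @examples
#' cells <- data.frame(x_norm = runif(100, -1, 1), y_norm = runif(100, -1, 1),
#'                     label_a = TRUE, label_b = FALSE)
#' spatial_density(cells, axis = "x")
spatial_density <- function(cells, axis = c("x", "y"), by = NULL,
                            n_bins = 40L, normalize = c("unit", "count")) {
  axis <- match.arg(axis)
  normalize <- match.arg(normalize)
  cells <- premotor_cells(cells)
  col <- if (axis == "x") "x_norm" else "y_norm"
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  width <- 2 / n_bins
  grid <- tibble::tibble(bin_left = breaks[-length(breaks)],
                         bin_right = breaks[-1])
  if (nrow(cells) == 0) {
    out <- grid[0, ]
    out$density <- double(0)
    return(out)
  }
  v <- cells[[col]]
  if (any(!is.finite(v)) || any(abs(v) > 1)) {
    abort("coordinates must be finite and within [-1, 1]; normalise first.",
          class = "divtrace_config_error")
  }
  n_total <- nrow(cells)

  profile_one <- function(vals) {
    idx <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L),
                n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    dens <- counts / (length(vals) * width)
    if (normalize == "count") dens <- dens * length(vals) / n_total
    dplyr::mutate(grid, density = dens)
  }

  if (is.null(by)) {
    profile_one(v)
  } else {
    cells |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ profile_one(.x[[col]])) |>
      dplyr::ungroup()
  }
}

#' Plot a spatial density profile
#'
#' @param profile Output of [spatial_density()].
#' @param by Optional grouping column name used when computing the profile.
#' @return A ggplot.
#' @export
plot_spatial_density <- function(profile, by = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = (.data$bin_left + .data$bin_right) / 2, y = .data$density
  ))
  if (!is.null(by)) {
    p <- p + ggplot2::geom_step(ggplot2::aes(colour = .data[[by]]))
  } else {
    p <- p + ggplot2::geom_step()
  }
  p + ggplot2::labs(x = "normalised position", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot quadrant counts from a divergence summary
#'
#' @param summary Output of [divergence_summary()] grouped by `quadrant`
#'   (optionally among other keys).
#' @return A ggplot bar chart of totals with the double-labelled fraction
#'   annotated.
#' @export
plot_quadrant_counts <- function(summary) {
  stopifnot("quadrant" %in% names(summary))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$quadrant, y = .data$n_total)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = percent_label(.data$rate_pooled)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "quadrant", y = "labelled premotor cells",
                  subtitle = "label: double-labelled (divergent) fraction") +
    ggplot2::theme_minimal()
}
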