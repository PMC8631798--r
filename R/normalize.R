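#' Normalise raw section coordinates to the central-canal frame
#'
#' Maps raw micrometre coordinates of labelled cells to the dimensionless
#' transverse frame used throughout the package: the central canal becomes
#' `(0, 0)`, the lateral grey-matter border on the injection (ipsilateral)
#' side maps to `x_norm = +1` and the contralateral border to `-1`, the
#' dorsal-most border to `y_norm = +1` and the ventral-most to `-1`.
#' Normalisation is region-wise: each region carries its own fixed bounds, so
#' supply one row of `bounds` per region present in `points` (or a single
#' unkeyed row applied to everything).
#'
#' @param points Data frame with raw `x`, `y` in micrometres (x increasing to
#'   the animal's right, y increasing dorsally) and optionally a `region`
#'   column.
#' @param bounds Data frame with columns `canal_x`, `canal_y`, `x_min`,
#'   `x_max`, `y_min`, `y_max` (micrometres; the grey-matter extents enclosing
#'   the canal) and optionally `region`.
#' @param injection_side `"left"` or `"right"`: the side of the hindlimb
#'   injections; that side becomes ipsilateral (positive x).
#'
#' @return The input tibble with `x_norm`, `y_norm` and a logical
#'   `out_of_bounds` flag; flagged rows get `NA` coordinates and are excluded
#'   from downstream summaries.
#' @export
#' @examples
#' b <- data.frame(canal_x = 0, canal_y = 0,
#'                 x_min = -800, x_max = 800, y_min = -600, y_max = 900)
#' normalize_coordinates(data.frame(x = 400, y = -300), b, "right")
normalize_coordinates <- function(points, bounds, injection_side = c("right", "left")) {
  injection_side <- match.arg(injection_side)
  points <- tibble::as_tibble(points)
  bounds <- tibble::as_tibble(bounds)

  if ("region" %in% names(points) && "region" %in% names(bounds)) {
    missing_regions <- setdiff(unique(points$region), bounds$region)
    if (length(missing_regions) > 0) {
      abort(paste0("no bounds supplied for region(s): ",
                   paste(missing_regions, collapse = ", ")),
            class = "divtrace_config_error")
    }
    joined <- dplyr::left_join(points, bounds, by = "region")
  } else {
    if (nrow(bounds) != 1L) {
      abort("`bounds` must have a `region` key or a single row.",
            class = "divtrace_config_error")
    }
    joined <- dplyr::bind_cols(points, bounds[rep(1L, nrow(points)), ])
  }

  bad_bounds <- with(joined, canal_x <= x_min | canal_x >= x_max |
                       canal_y <= y_min | canal_y >= y_max)
  if (any(bad_bounds, na.rm = TRUE)) {
    abort("grey-matter bounds must strictly enclose the central canal.",
          class = "divtrace_config_error")
  }

  # Asymmetric scaling about the canal: each half-width maps to unit length.
  u <- with(joined, ifelse(x >= canal_x,
                           (x - canal_x) / (x_max - canal_x),
                           (x - canal_x) / (canal_x - x_min)))
  v <- with(joined, ifelse(y >= canal_y,
                           (y - canal_y) / (y_max - canal_y),
                           (y - canal_y) / (canal_y - y_min)))
  if (injection_side == "left") u <- -u

  oob <- !is.finite(u) | !is.finite(v) | abs(u) > 1 | abs(v) > 1
  points$x_norm <- ifelse(oob, NA_real_, u)
  points$y_norm <- ifelse(oob, NA_real_, v)
  points$out_of_bounds <- oob
  points
}

#' Assign transverse quadrants from normalised coordinates
#'
#' Quadrants split the transverse plane by the central canal: dorsal (`y >= 0`)
#' vs ventral, ipsilateral (`x >= 0`) vs contralateral, giving `DI`, `DC`,
#' `VI`, `VC`. Coordinates exactly on an axis are assigned to the
#' ipsilateral/dorsal side — a deterministic tie rule of measure zero under
#' continuous positions.
#'
#' @param x_norm,y_norm Normalised coordinates (vectors).
#' @return Factor with levels `DI`, `DC`, `VI`, `VC`; `NA` for non-finite
#'   coordinates.
#' @export
#' @examples
#' assign_quadrant(c(0.3, -0.2, 0), c(0.5, -0.7, 0))
assign_quadrant <- function(x_norm, y_norm) {
  ipsi <- x_norm >= 0
  dorsal <- y_norm >= 0
  q <- ifelse(dorsal, ifelse(ipsi, "DI", "DC"), ifelse(ipsi, "VI", "VC"))
  q[!is.finite(x_norm) | !is.finite(y_norm)] <- NA
  factor(q, levels = QUADRANTS)
}

#' Add a `quadrant` column to a cell table
#'
#' @param cells Data frame with `x_norm`, `y_norm`.
#' @return The tibble with a `quadrant` factor column.
#' @export
add_quadrant <- function(cells) {
  dplyr::mutate(tibble::as_tibble(cells),
                quadrant = assign_quadrant(.data$x_norm, .data$y_norm))
}
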