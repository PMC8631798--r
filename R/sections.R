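#' Subsample a region's sections one-in-k
#'
#' Counting every section risks counting the same soma twice where it spans
#' consecutive sections; quantifying one of every `k` sections removes that
#' artefact. Retains, within the named region, exactly the cells whose
#' `section_index` is congruent to `offset` modulo `k`; cells in other regions
#' pass through unchanged.
#'
#' @param cells Cell table with `region` and 0-based `section_index`.
#' @param region Region whose sections are subsampled.
#' @param k Keep one section in every `k` (`k = 1` is the identity).
#' @param offset Which residue class to keep, `0 <= offset < k`.
#'
#' @return The filtered tibble. The three possible offsets at `k = 3`
#'   partition the region's cells.
#' @export
#' @examples
#' cfg <- cord_config(list(lumbar = region_spec(100, 0.1)), n_animals = 1)
#' cells <- simulate_infection(generate_cohort(cfg, 1), virus_params(), 2)
#' subsample_sections(cells, "lumbar", k = 3)
subsample_sections <- function(cells, region, k = 3L, offset = 0L) {
  if (k < 1) abort("`k` must be >= 1.", class = "divtrace_config_error")
  if (offset < 0 || offset >= k) {
    abort("`offset` must satisfy 0 <= offset < k.", class = "divtrace_config_error")
  }
  if (k == 1L) return(tibble::as_tibble(cells))
  dplyr::filter(tibble::as_tibble(cells),
                .data$region != !!region |
                  .data$section_index %% !!as.integer(k) == !!as.integer(offset))
}

# Apply a per-region sampling plan, e.g. list(lumbar = c(k = 3, offset = 0)).
apply_sampling <- function(cells, sampling) {
  for (r in names(sampling)) {
    s <- sampling[[r]]
    k <- if (!is.null(names(s))) s[["k"]] else s[[1]]
    offset <- if ("offset" %in% names(s)) s[["offset"]] else 0L
    cells <- subsample_sections(cells, r, k = k, offset = offset)
  }
  cells
}

#' Default per-region section-sampling plan
#'
#' One-in-three sections for the dense lumbar premotor population, every
#' section elsewhere (sparse populations allow manual exclusion of doubly cut
#' somata). Motoneuron counts conventionally use every other section; pass a
#' custom plan where needed.
#'
#' @return Named list of `c(k, offset)` pairs keyed by region.
#' @export
default_sampling <- function() {
  list(lumbar = c(k = 3L, offset = 0L))
}
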