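#' Read and write labelled-cell tables
#'
#' Cell tables are plain comma-separated text with a header row; logical
#' columns are stored as `TRUE`/`FALSE` (empty = unknown for tri-state marker
#' columns). Colour identifiers travel in a `# colour_a=...` comment pair on
#' the first lines and are restored as attributes.
#'
#' @param path File path.
#' @param cells Labelled-cell tibble.
#' @return `read_cell_table()` returns the tibble; `write_cell_table()`
#'   returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  first <- readLines(path, n = 2L)
  meta <- grep("^# ", first, value = TRUE)
  cells <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  for (m in meta) {
    kv <- strsplit(sub("^# ", "", m), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) attr(cells, kv[1]) <- kv[2]
  }
  cells
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  header <- character(0)
  for (a in c("colour_a", "colour_b")) {
    if (!is.null(attr(cells, a))) {
      header <- c(header, sprintf("# %s=%s", a, attr(cells, a)))
    }
  }
  writeLines(c(if (length(header)) paste0(header, "\n"),
               readr::format_csv(cells)), path, sep = "")
  invisible(path)
}

# Flatten a cord_config (+ virus/pipeline settings) for YAML round-tripping.
config_to_list <- function(config) {
  list(
    n_animals = config$n_animals,
    regions = lapply(config$regions, function(s) {
      s <- unclass(s)
      s$quadrant_probs <- as.list(s$quadrant_probs)
      s
    })
  )
}

list_to_config <- function(x) {
  regions <- lapply(x$regions, function(s) {
    region_spec(
      n_premotor = s$n_premotor,
      divergent_fraction = s$divergent_fraction,
      quadrant_probs = unlist(s$quadrant_probs),
      segment_range = s$segment_range,
      n_sections = s$n_sections,
      soma_logmean = s$soma_logmean,
      soma_logsd = s$soma_logsd,
      inhibitory_fraction = s$inhibitory_fraction,
      cholinergic_fraction = s$cholinergic_fraction,
      a_fraction = s$a_fraction %||% 0.5,
      n_motoneurons = s$n_motoneurons %||% 0L
    )
  })
  cord_config(regions = regions, n_animals = x$n_animals)
}

#' Write / read a cohort configuration as YAML
#'
#' @param config A [cord_config()].
#' @param path File path.
#' @return `write_cord_config()` returns `path` invisibly;
#'   `read_cord_config()` returns the `cord_config`.
#' @export
write_cord_config <- function(config, path) {
  # full float precision so a round-tripped config regenerates identical cohorts
  yaml::write_yaml(config_to_list(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_cord_config
#' @export
read_cord_config <- function(path) {
  list_to_config(yaml::read_yaml(path))
}
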