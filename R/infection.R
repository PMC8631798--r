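#' Simulate dual-virus trans-synaptic labelling of a cohort
#'
#' Each neuron-to-pool connection transmits that pool's colour with the
#' per-jump probability `e`, independently across connections. For divergent
#' neurons, the infection order of the two viruses is randomised per neuron
#' and, if the first-transmitting virus succeeds, the second virus's transfer
#' probability is reduced to `e * (1 - rho)` (viral interference; `rho = 0`
#' restores full independence). Motoneuron rows model primary infection and
#' are labelled with their pool's colour with probability 1. Only neurons
#' receiving at least one label appear in the output.
#'
#' @param neurons Cohort tibble from [generate_cohort()].
#' @param virus A [virus_params()].
#' @param seed Integer seed.
#' @param spillover_prob Probability that a labelled cell is spuriously
#'   counted again on the adjacent section (the artefact that one-in-k section
#'   subsampling guards against). Default 0: each cell appears on exactly one
#'   section.
#'
#' @return A tibble of labelled cells: the cohort columns plus logical
#'   `label_a`, `label_b` (at least one `TRUE` per row), `lhx1_positive`
#'   (`NA`: not modelled), and ground-truth `neuron_id`, `connectivity`
#'   retained for validation. Colour identifiers are attached as attributes
#'   `colour_a`, `colour_b`.
#' @export
#' @examples
#' cfg <- cord_config(list(lumbar = region_spec(500, 0.18)), n_animals = 1)
#' cells <- generate_cohort(cfg, seed = 1) |>
#'   simulate_infection(virus_params(0.25), seed = 2)
simulate_infection <- function(neurons, virus = virus_params(), seed,
                               spillover_prob = 0) {
  stopifnot(inherits(virus, "virus_params"))
  e <- virus$efficiency
  rho <- virus$interference
  n <- nrow(neurons)
  if (n == 0L) {
    out <- dplyr::mutate(neurons, label_a = logical(0), label_b = logical(0),
                         lhx1_positive = NA)
    return(label_attrs(out, virus))
  }

  withr::with_seed(as.integer(seed), {
    to_a <- neurons$connectivity %in% c("A_only", "both")
    to_b <- neurons$connectivity %in% c("B_only", "both")
    label_a <- logical(n)
    label_b <- logical(n)

    single <- xor(to_a, to_b)
    label_a[single & to_a] <- runif(sum(single & to_a)) < e
    label_b[single & to_b] <- runif(sum(single & to_b)) < e

    both <- to_a & to_b
    nb <- sum(both)
    if (nb > 0) {
      a_first <- runif(nb) < 0.5
      first_ok <- runif(nb) < e
      second_ok <- runif(nb) < ifelse(first_ok, e * (1 - rho), e)
      label_a[both] <- ifelse(a_first, first_ok, second_ok)
      label_b[both] <- ifelse(a_first, second_ok, first_ok)
    }

    # primary infection of motoneurons is certain
    mn <- neurons$is_motoneuron
    label_a[mn & to_a] <- TRUE
    label_b[mn & to_b] <- TRUE

    out <- neurons
    out$label_a <- label_a
    out$label_b <- label_b
    out$lhx1_positive <- NA
    out <- out[label_a | label_b, , drop = FALSE]

    if (spillover_prob > 0 && nrow(out) > 0) {
      dup <- out[runif(nrow(out)) < spillover_prob, , drop = FALSE]
      if (nrow(dup) > 0) {
        dup$section_index <- dup$section_index + 1L
        out <- dplyr::bind_rows(out, dup)
      }
    }
  })
  label_attrs(tibble::as_tibble(out), virus)
}

label_attrs <- function(x, virus) {
  attr(x, "colour_a") <- virus$colour_a
  attr(x, "colour_b") <- virus$colour_b
  x
}
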