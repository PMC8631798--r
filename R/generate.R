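#' Generate a virtual premotor cohort with known ground truth
#'
#' Draws, for every region and animal in `config`, a population of premotor
#' neurons with known connectivity to the two injected motor pools. Each
#' neuron is divergent (contacts both pools) with probability
#' `divergent_fraction`; non-divergent neurons split between pool A and pool B
#' according to `a_fraction`. Positions are drawn by first sampling a quadrant
#' from `quadrant_probs`, then placing the neuron uniformly within that
#' quadrant of the normalised transverse plane (central canal at the origin,
#' grey-matter borders at +/-1). Soma areas are log-normal; marker flags are
#' Bernoulli.
#'
#' @param config A [cord_config()].
#' @param seed Integer seed; identical `config` + `seed` give byte-identical
#'   tables.
#'
#' @return A tibble with one row per neuron: `neuron_id`, `animal_id`,
#'   `region`, `segment`, `section_index` (0-based), `x_norm`, `y_norm`
#'   (ipsilateral-positive / dorsal-positive), `connectivity`
#'   (`"A_only"`, `"B_only"` or `"both"`), `soma_area` (um^2),
#'   `glyt2_positive`, `chat_positive`, `is_motoneuron`.
#' @seealso [simulate_infection()]
#' @export
#' @examples
#' cfg <- cord_config(list(lumbar = region_spec(100, 0.18)), n_animals = 2)
#' generate_cohort(cfg, seed = 1)
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cord_config"))
  withr::with_seed(as.integer(seed), {
    out <- purrr::imap(config$regions, function(spec, region) {
      purrr::map(seq_len(config$n_animals), function(a) {
        generate_block(spec, region, a)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  out$neuron_id <- sprintf("n%07d", seq_len(nrow(out)))
  dplyr::relocate(out, "neuron_id")
}

generate_block <- function(spec, region, animal) {
  n <- spec$n_premotor
  nm <- spec$n_motoneurons
  total <- n + nm
  if (total == 0L) {
    return(empty_cohort())
  }
  is_mn <- rep(c(FALSE, TRUE), c(n, nm))

  connectivity <- character(total)
  if (n > 0) {
    div <- runif(n) < spec$divergent_fraction
    conn <- ifelse(runif(n) < spec$a_fraction, "A_only", "B_only")
    connectivity[!is_mn] <- ifelse(div, "both", conn)
  }
  if (nm > 0) {
    # Motoneurons are primary infection targets of a single pool each.
    connectivity[is_mn] <- ifelse(runif(nm) < 0.5, "A_only", "B_only")
  }

  quadrant <- sample(QUADRANTS, total, replace = TRUE, prob = spec$quadrant_probs)
  # Uniform within the assigned quadrant; strictly inside (0, 1) so the sign
  # convention is unambiguous.
  xs <- runif(total)
  ys <- runif(total)
  x_norm <- ifelse(quadrant %in% c("DI", "VI"), xs, -xs)
  y_norm <- ifelse(quadrant %in% c("DI", "DC"), ys, -ys)
  # Motoneurons sit in the ventral ipsilateral grey matter.
  if (nm > 0) {
    x_norm[is_mn] <- abs(x_norm[is_mn])
    y_norm[is_mn] <- -abs(y_norm[is_mn])
  }

  soma <- rlnorm(total, spec$soma_logmean, spec$soma_logsd)
  if (nm > 0) soma[is_mn] <- rlnorm(nm, log(660), 0.15)

  tibble::tibble(
    animal_id = sprintf("animal_%02d", animal),
    region = region,
    segment = sample(spec$segment_range, total, replace = TRUE),
    section_index = sample.int(spec$n_sections, total, replace = TRUE) - 1L,
    x_norm = x_norm,
    y_norm = y_norm,
    connectivity = connectivity,
    soma_area = soma,
    glyt2_positive = runif(total) < spec$inhibitory_fraction & !is_mn,
    chat_positive = (runif(total) < spec$cholinergic_fraction & !is_mn) | is_mn,
    is_motoneuron = is_mn
  )
}

empty_cohort <- function() {
  tibble::tibble(
    animal_id = character(), region = character(), segment = character(),
    section_index = integer(), x_norm = double(), y_norm = double(),
    connectivity = character(), soma_area = double(),
    glyt2_positive = logical(), chat_positive = logical(),
    is_motoneuron = logical()
  )
}
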