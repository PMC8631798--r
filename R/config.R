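#' Specify one spinal-cord region of a virtual premotor cohort
#'
#' A region spec fixes, for one of the four longitudinal divisions of the
#' cord, how many premotor neurons each animal carries, what fraction of them
#' genuinely contact both injected motor pools ("divergent"), and the spatial
#' and cytological structure of the population.
#'
#' @param n_premotor Number of premotor neurons per animal (non-negative
#'   integer).
#' @param divergent_fraction Fraction of premotor neurons contacting both
#'   motor pools, in `[0, 1]`. This is the ground-truth divergence rate the
#'   labelling experiment tries to estimate.
#' @param quadrant_probs Named numeric 4-vector of probabilities over the
#'   quadrants `DI`, `DC`, `VI`, `VC` (dorsal/ventral x ipsi/contralateral);
#'   must sum to 1 within `1e-9`.
#' @param segment_range Character vector of ordered segment labels, e.g.
#'   `c("L1", ..., "L6")`; neurons are placed uniformly across segments.
#' @param n_sections Number of transverse sections spanning the region
#'   (>= 1); each neuron sits on exactly one section.
#' @param soma_logmean,soma_logsd Log-scale mean and SD of the log-normal
#'   soma cross-sectional area distribution (area in um^2).
#' @param inhibitory_fraction,cholinergic_fraction Fractions of neurons
#'   carrying the glycinergic (GlyT2) and cholinergic (ChAT) markers.
#' @param a_fraction Among non-divergent neurons, the fraction connected to
#'   pool A (the rest connect to pool B). Defaults to an even split.
#' @param n_motoneurons Number of primary-infected motoneuron rows emitted per
#'   animal for table realism; they never enter premotor denominators.
#'   Default 0.
#'
#' @return A list of class `region_spec`.
#' @seealso [cord_config()], [generate_cohort()]
#' @export
#' @examples
#' region_spec(n_premotor = 1000, divergent_fraction = 0.18)
region_spec <- function(n_premotor,
                        divergent_fraction,
                        quadrant_probs = c(DI = 0.25, DC = 0.25, VI = 0.25, VC = 0.25),
                        segment_range = c("S1", "S2", "S3"),
                        n_sections = 30L,
                        soma_logmean = log(320) - 0.5 * log(1 + (114 / 320)^2),
                        soma_logsd = sqrt(log(1 + (114 / 320)^2)),
                        inhibitory_fraction = 0.4,
                        cholinergic_fraction = 0.05,
                        a_fraction = 0.5,
                        n_motoneurons = 0L) {
  if (length(n_premotor) != 1L || is.na(n_premotor) || n_premotor < 0) {
    abort("`n_premotor` must be a single non-negative count.",
          class = "divtrace_config_error")
  }
  check_fraction(divergent_fraction, "divergent_fraction")
  check_fraction(inhibitory_fraction, "inhibitory_fraction")
  check_fraction(cholinergic_fraction, "cholinergic_fraction")
  check_fraction(a_fraction, "a_fraction")
  if (length(quadrant_probs) != 4L || any(is.na(quadrant_probs)) ||
      any(quadrant_probs < 0) || abs(sum(quadrant_probs) - 1) > 1e-9) {
    abort("`quadrant_probs` must be 4 non-negative probabilities summing to 1.",
          class = "divtrace_config_error")
  }
  if (is.null(names(quadrant_probs))) {
    names(quadrant_probs) <- QUADRANTS
  } else if (!setequal(names(quadrant_probs), QUADRANTS)) {
    abort("`quadrant_probs` names must be DI, DC, VI, VC.",
          class = "divtrace_config_error")
  }
  if (length(n_sections) != 1L || is.na(n_sections) || n_sections < 1) {
    abort("`n_sections` must be a single count >= 1.",
          class = "divtrace_config_error")
  }
  structure(
    list(
      n_premotor = as.integer(n_premotor),
      divergent_fraction = divergent_fraction,
      quadrant_probs = quadrant_probs[QUADRANTS],
      segment_range = as.character(segment_range),
      n_sections = as.integer(n_sections),
      soma_logmean = soma_logmean,
      soma_logsd = soma_logsd,
      inhibitory_fraction = inhibitory_fraction,
      cholinergic_fraction = cholinergic_fraction,
      a_fraction = a_fraction,
      n_motoneurons = as.integer(n_motoneurons)
    ),
    class = "region_spec"
  )
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name),
          class = "divtrace_config_error")
  }
  invisible(x)
}

# Log-normal parameters matching a target arithmetic mean and SD.
lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(logmean = log(mean) - s2 / 2, logsd = sqrt(s2))
}

#' Configure a virtual spinal-cord premotor cohort
#'
#' Bundles per-region [region_spec()]s with the number of animals. The
#' defaults emulate a dual hindlimb-injection experiment: a dense lumbar
#' premotor population with true divergence 0.18, sparser thoracic and
#' cervical (long descending propriospinal) populations, quadrant occupancies
#' and soma-size moments shaped like the traced populations (lumbar 320 +/- 114
#' um^2, thoracic 359 +/- 144, cervical 774 +/- 231).
#'
#' @param regions Named list of [region_spec()] objects; names drawn from
#'   `cervical`, `thoracic`, `lumbar`, `sacral`.
#' @param n_animals Number of animals; each animal receives `n_premotor`
#'   neurons per region.
#'
#' @return A list of class `cord_config`.
#' @export
#' @examples
#' cfg <- cord_config(
#'   regions = list(lumbar = region_spec(7000, 0.18)),
#'   n_animals = 3
#' )
cord_config <- function(regions = default_regions(), n_animals = 3L) {
  if (!is.list(regions) || length(regions) == 0 ||
      is.null(names(regions)) || !all(names(regions) %in% REGIONS)) {
    abort("`regions` must be a named list keyed by cervical/thoracic/lumbar/sacral.",
          class = "divtrace_config_error")
  }
  ok <- vapply(regions, inherits, logical(1), what = "region_spec")
  if (!all(ok)) {
    abort("every element of `regions` must be a `region_spec`.",
          class = "divtrace_config_error")
  }
  if (length(n_animals) != 1L || is.na(n_animals) || n_animals < 1) {
    abort("`n_animals` must be a single count >= 1.",
          class = "divtrace_config_error")
  }
  structure(
    list(regions = regions, n_animals = as.integer(n_animals)),
    class = "cord_config"
  )
}

default_regions <- function() {
  lum <- lnorm_params(320, 114)
  tho <- lnorm_params(359, 144)
  cer <- lnorm_params(774, 231)
  list(
    cervical = region_spec(
      n_premotor = 15, divergent_fraction = 0.8,
      quadrant_probs = c(DI = 0.02, DC = 0.02, VI = 0.22, VC = 0.74),
      segment_range = paste0("C", 1:8), n_sections = 60L,
      soma_logmean = cer[["logmean"]], soma_logsd = cer[["logsd"]],
      inhibitory_fraction = 0.1
    ),
    thoracic = region_spec(
      n_premotor = 120, divergent_fraction = 0.5,
      quadrant_probs = c(DI = 0.55, DC = 0.05, VI = 0.16, VC = 0.24),
      segment_range = paste0("T", 1:13), n_sections = 80L,
      soma_logmean = tho[["logmean"]], soma_logsd = tho[["logsd"]],
      inhibitory_fraction = 0.5
    ),
    lumbar = region_spec(
      n_premotor = 7000, divergent_fraction = 0.18,
      quadrant_probs = c(DI = 0.55, DC = 0.04, VI = 0.27, VC = 0.14),
      segment_range = paste0("L", 1:6), n_sections = 90L,
      soma_logmean = lum[["logmean"]], soma_logsd = lum[["logsd"]],
      inhibitory_fraction = 0.5
    ),
    sacral = region_spec(
      n_premotor = 150, divergent_fraction = 0.1,
      quadrant_probs = c(DI = 0.4, DC = 0.1, VI = 0.3, VC = 0.2),
      segment_range = paste0("S", 1:4), n_sections = 30L,
      soma_logmean = lum[["logmean"]], soma_logsd = lum[["logsd"]],
      inhibitory_fraction = 0.5
    )
  )
}

#' Parameters of the two trans-synaptic viruses
#'
#' @param efficiency Per-jump transfer probability `e`, in `(0, 1]`: the
#'   chance that a virus crosses a given premotor-to-motoneuron synapse and
#'   labels the presynaptic neuron. The glycoprotein-deleted SADB19 strain is
#'   thought to be no more efficient than 0.25.
#' @param interference Viral interference `rho`, in `[0, 1)`: multiplicative
#'   reduction of the second virus's transfer probability once the
#'   first-transmitting virus has succeeded in the same cell (infection order
#'   randomised per neuron). Default 0 (independent transfers).
#' @param colour_a,colour_b Colour identifiers of the two viruses.
#'
#' @return A list of class `virus_params`.
#' @export
#' @examples
#' virus_params(efficiency = 0.25)
virus_params <- function(efficiency = 0.25, interference = 0,
                         colour_a = "eGFP", colour_b = "mCherry") {
  if (length(efficiency) != 1L || is.na(efficiency) ||
      efficiency <= 0 || efficiency > 1) {
    abort("`efficiency` must be a single value in (0, 1].",
          class = "divtrace_config_error")
  }
  if (length(interference) != 1L || is.na(interference) ||
      interference < 0 || interference >= 1) {
    abort("`interference` must be a single value in [0, 1).",
          class = "divtrace_config_error")
  }
  structure(
    list(
      efficiency = efficiency,
      interference = interference,
      colour_a = as.character(colour_a),
      colour_b = as.character(colour_b)
    ),
    class = "virus_params"
  )
}

#' @export
print.cord_config <- function(x, ...) {
  cat("<cord_config> ", x$n_animals, " animal(s)\n", sep = "")
  for (r in names(x$regions)) {
    s <- x$regions[[r]]
    cat(sprintf("  %-9s n_premotor=%d  d=%.3f  sections=%d\n",
                r, s$n_premotor, s$divergent_fraction, s$n_sections))
  }
  invisible(x)
}

#' @export
print.virus_params <- function(x, ...) {
  cat(sprintf("<virus_params> e=%.3f rho=%.3f colours=%s/%s\n",
              x$efficiency, x$interference, x$colour_a, x$colour_b))
  invisible(x)
}
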