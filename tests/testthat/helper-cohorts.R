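# Small cohort builders shared across tests.

lumbar_config <- function(n = 2000, d = 0.18, n_animals = 1L, ...) {
  cord_config(
    regions = list(lumbar = region_spec(n_premotor = n, divergent_fraction = d,
                                        n_sections = 90L,
                                        segment_range = paste0("L", 1:6), ...)),
    n_animals = n_animals
  )
}

# A cohort of pure divergent neurons, for enumeration-style checks.
all_divergent_cohort <- function(n, seed = 1) {
  cfg <- lumbar_config(n = n, d = 1)
  generate_cohort(cfg, seed = seed)
}

labelled_lumbar <- function(n = 2000, d = 0.18, e = 0.25, seed = 1,
                            n_animals = 1L, rho = 0) {
  cohort <- generate_cohort(lumbar_config(n, d, n_animals), seed = seed)
  simulate_infection(cohort, virus_params(e, rho), seed = seed + 1000L)
}
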