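# Scenario builders for tests. tweak_scenario() rebuilds the default
# two-ladybird scenario with selected fields overridden.
tweak_scenario <- function(seed = 1L, unit_sd = NULL, detection_probs = NULL,
                           larvae_per_unit = NULL, n_units = NULL,
                           instar_probs = NULL) {
  sc <- igpsim::default_scenario(seed = seed)
  if (!is.null(unit_sd)) sc$field$unit_sd <- unit_sd
  if (!is.null(detection_probs)) sc$field$detection_probs <- detection_probs
  if (!is.null(larvae_per_unit)) sc$field$larvae_per_unit <- larvae_per_unit
  if (!is.null(n_units)) sc$field$n_units <- n_units
  if (!is.null(instar_probs)) sc$field$instar_probs <- instar_probs
  sc
}

# Scenario with a single decay pair, for feeding-trial generation.
one_pair_scenario <- function(beta0, beta1, seed = 1L,
                              predator = "P", prey = "Q") {
  sc <- igpsim::default_scenario(seed = seed)
  igpsim::synthetic_scenario(
    decay = tibble::tibble(
      predator_species = predator, prey_species = prey,
      beta0 = beta0, beta1 = beta1
    ),
    field = sc$field, lab = sc$lab, seed = seed
  )
}

# Detection-probability table helper for the two default species.
detect_probs <- function(cs_aphid, hv_aphid, cs_het = 0.252, hv_het = 0.283) {
  tibble::tibble(
    predator_species = rep(c("C. septempunctata", "H. variegata"), 2),
    prey_kind = rep(c("aphid", "heterospecific"), each = 2),
    prob = c(cs_aphid, hv_aphid, cs_het, hv_het)
  )
}
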