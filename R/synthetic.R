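#' Define a synthetic study scenario
#'
#' A scenario bundles the generative parameters for all three dataset
#' kinds the pipeline consumes: logistic decay of prey-DNA detectability
#' for each predator-prey pair, a clustered field survey with
#' unit-level aphid densities and random effects, and density-dependent
#' stage-specific laboratory predation. All randomness in the generators
#' derives deterministically from `seed` (each generator uses a fixed
#' offset from it), so a scenario fully reproduces its datasets.
#'
#' @param decay Tibble with columns `predator_species`, `prey_species`,
#'   `beta0` (logit-scale intercept) and `beta1` (slope per hour,
#'   strictly negative: detectability must decay).
#' @param field List with `n_units` (>= 1), `larvae_per_unit` (named
#'   numeric, mean Poisson count per unit per predator species, > 0),
#'   `density_mean` and `density_dispersion` (negative-binomial law of
#'   aphids per 10 leaves), `unit_sd` (SD of unit-level logit intercepts,
#'   >= 0), `detection_probs` (tibble `predator_species`, `prey_kind`,
#'   `prob` in \[0,1\]) and `instar_probs` (length-4 simplex).
#' @param lab Tibble with columns `ig_predator_species`,
#'   `prey_stage_class` (one of `immobile`, `small_larvae`,
#'   `similar_larvae`), `alpha` (logit intercept) and `gamma` (slope per
#'   unit aphid density).
#' @param seed Integer seed; required.
#' @return A `synthetic_scenario` list.
#' @seealso [default_scenario()], [read_scenario()],
#'   [gen_feeding_trials()], [gen_field_survey()], [gen_lab_bioassays()]
#' @export
synthetic_scenario <- function(decay, field, lab, seed) {
  decay <- tibble::as_tibble(decay)
  stopifnot(
    all(c("predator_species", "prey_species", "beta0", "beta1") %in% names(decay))
  )
  if (any(decay$beta1 >= 0)) {
    abort("all decay slopes (beta1) must be negative: detectability must decay")
  }
  if (!is.list(field)) abort("`field` must be a list")
  needed <- c(
    "n_units", "larvae_per_unit", "density_mean", "density_dispersion",
    "unit_sd", "detection_probs", "instar_probs"
  )
  missing <- setdiff(needed, names(field))
  if (length(missing) > 0) {
    abort(paste0("`field` lacks: ", paste(missing, collapse = ", ")))
  }
  if (field$n_units < 1) abort("n_units must be >= 1")
  if (field$unit_sd < 0) abort("unit_sd must be >= 0")
  field$detection_probs <- tibble::as_tibble(field$detection_probs)
  stopifnot(
    all(c("predator_species", "prey_kind", "prob") %in%
          names(field$detection_probs)),
    all(field$detection_probs$prey_kind %in% prey_kinds())
  )
  if (any(field$detection_probs$prob < 0 | field$detection_probs$prob > 1)) {
    abort("detection probabilities must lie in [0, 1]")
  }
  if (length(field$instar_probs) != 4 ||
      abs(sum(field$instar_probs) - 1) > 1e-8) {
    abort("instar_probs must be 4 probabilities summing to 1")
  }
  lab <- tibble::as_tibble(lab)
  stopifnot(
    all(c("ig_predator_species", "prey_stage_class", "alpha", "gamma") %in%
          names(lab)),
    all(lab$prey_stage_class %in% stage_classes())
  )
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  structure(
    list(decay = decay, field = field, lab = lab, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario (seed ", x$seed, ")\n", sep = "")
  cat("  decay pairs: ", nrow(x$decay),
      " (T50 ", paste(round(-x$decay$beta0 / x$decay$beta1, 2), collapse = ", "),
      " h)\n", sep = "")
  cat("  field: ", x$field$n_units, " units, unit_sd ", x$field$unit_sd,
      "\n", sep = "")
  cat("  lab cells: ", nrow(x$lab), "\n", sep = "")
  invisible(x)
}

#' Default two-ladybird study scenario
#'
#' Parameter set emulating a melon-field study of two aphidophagous
#' ladybirds, *Coccinella septempunctata* (Cs) and *Hippodamia variegata*
#' (Hv), sharing the aphid *Aphis gossypii* (Ag). Decay intercepts are
#' chosen so the half-detectability times are 11.40 h (Cs detecting Hv),
#' 2.27 h (Cs-Ag), 14.64 h (Hv-Cs) and 2.81 h (Hv-Ag); field detection
#' probabilities are 70.9%/90.6% for the aphid and 25.2%/28.3% for the
#' heterospecific ladybird; 28 sampling units yield on average 151 Cs and
#' 53 Hv larvae. Laboratory predation is anchored at stage-class
#' probabilities 0.22 (similarly aged larvae) and 0.74 (immobile stages
#' and small larvae) for Cs at the reference density of 50 aphids, scaled
#' by 43/70 for the weaker IG-predator Hv, with predation declining in
#' aphid density (slope -0.02 per aphid on the logit scale).
#'
#' @param seed Integer seed.
#' @return A [synthetic_scenario()].
#' @export
default_scenario <- function(seed = 1L) {
  cs <- "C. septempunctata"
  hv <- "H. variegata"
  ag <- "A. gossypii"
  slope_ladybird <- -0.21841
  slope_aphid <- -0.9
  decay <- tibble::tibble(
    predator_species = c(cs, cs, hv, hv),
    prey_species = c(hv, ag, cs, ag),
    beta1 = c(slope_ladybird, slope_aphid, slope_ladybird, slope_aphid),
    beta0 = -beta1 * c(11.40, 2.27, 14.64, 2.81)
  )[, c("predator_species", "prey_species", "beta0", "beta1")]

  gamma <- -0.02
  d_mid <- 50
  p_cs <- c(immobile = 0.74, small_larvae = 0.74, similar_larvae = 0.22)
  p_hv <- p_cs * 43 / 70
  lab <- tibble::tibble(
    ig_predator_species = rep(c(cs, hv), each = 3),
    prey_stage_class = rep(stage_classes(), 2),
    alpha = unname(qlogis(c(p_cs, p_hv))) - gamma * d_mid,
    gamma = gamma
  )

  field <- list(
    n_units = 28L,
    larvae_per_unit = stats::setNames(c(151, 53) / 28, c(cs, hv)),
    density_mean = 40,
    density_dispersion = 1.5,
    unit_sd = 0.5,
    detection_probs = tibble::tibble(
      predator_species = c(cs, hv, cs, hv),
      prey_kind = c("aphid", "aphid", "heterospecific", "heterospecific"),
      prob = c(0.709, 0.906, 0.252, 0.283)
    ),
    instar_probs = c(0.05, 0.05, 0.40, 0.50)
  )
  synthetic_scenario(decay, field, lab, seed = seed)
}

#' Read a scenario from a YAML configuration file
#'
#' The file must carry a top-level `seed` plus `decay` (list of
#' `predator`/`prey`/`beta0`/`beta1` entries), `field` (keys as in
#' [synthetic_scenario()], with `detection_probs` a list of
#' `predator`/`prey_kind`/`prob` entries and `larvae_per_unit` a map from
#' species to mean count) and `lab` (list of
#' `predator`/`stage`/`alpha`/`gamma` entries).
#'
#' @param path Path to a YAML file.
#' @return A [synthetic_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  for (key in c("seed", "decay", "field", "lab")) {
    if (is.null(y[[key]])) abort(paste0("scenario file lacks key '", key, "'"))
  }
  decay <- purrr::map_dfr(y$decay, function(e) {
    tibble::tibble(
      predator_species = e$predator, prey_species = e$prey,
      beta0 = e$beta0, beta1 = e$beta1
    )
  })
  field <- y$field
  field$larvae_per_unit <- unlist(field$larvae_per_unit)
  field$instar_probs <- as.numeric(unlist(field$instar_probs))
  field$detection_probs <- purrr::map_dfr(field$detection_probs, function(e) {
    tibble::tibble(
      predator_species = e$predator, prey_kind = e$prey_kind, prob = e$prob
    )
  })
  lab <- purrr::map_dfr(y$lab, function(e) {
    tibble::tibble(
      ig_predator_species = e$predator, prey_stage_class = e$stage,
      alpha = e$alpha, gamma = e$gamma
    )
  })
  synthetic_scenario(decay, field, lab, seed = y$seed)
}

#' Write a scenario to YAML
#'
#' @param scenario A [synthetic_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  y <- list(
    seed = scenario$seed,
    decay = purrr::pmap(scenario$decay, function(predator_species, prey_species,
                                                 beta0, beta1) {
      list(predator = predator_species, prey = prey_species,
           beta0 = beta0, beta1 = beta1)
    }),
    field = list(
      n_units = scenario$field$n_units,
      larvae_per_unit = as.list(scenario$field$larvae_per_unit),
      density_mean = scenario$field$density_mean,
      density_dispersion = scenario$field$density_dispersion,
      unit_sd = scenario$field$unit_sd,
      detection_probs = purrr::pmap(
        scenario$field$detection_probs,
        function(predator_species, prey_kind, prob) {
          list(predator = predator_species, prey_kind = prey_kind, prob = prob)
        }
      ),
      instar_probs = as.list(scenario$field$instar_probs)
    ),
    lab = purrr::pmap(scenario$lab, function(ig_predator_species,
                                             prey_stage_class, alpha, gamma) {
      list(predator = ig_predator_species, stage = prey_stage_class,
           alpha = alpha, gamma = gamma)
    })
  )
  yaml::write_yaml(y, path, precision = 17)
  invisible(path)
}

# Stage-specific seed offsets keep the three generators independent while
# everything derives from the one scenario seed.
stage_seed <- function(scenario, stage) {
  offset <- c(feeding = 1L, field = 2L, lab = 3L)[[stage]]
  (scenario$seed + offset) %% .Machine$integer.max
}

#' Generate feeding-trial data
#'
#' For each predator-prey pair in the scenario and each post-feeding time
#' point `t`, draws `n_per_point` detection outcomes from
#' `Bernoulli(plogis(beta0 + beta1 * t))` - the same logistic decay law
#' the fitting stage assumes.
#'
#' @param scenario A [synthetic_scenario()].
#' @param time_points Hours post feeding (non-negative, non-empty).
#'   The default is the 9-point design 0-24 h used for ladybird prey;
#'   aphid-prey trials typically append 36 h.
#' @param n_per_point Larvae analysed per time point (default 6).
#' @param prey Optional character vector restricting to prey species.
#' @return Tibble in the `feeding_trial` schema.
#' @export
gen_feeding_trials <- function(scenario,
                               time_points = c(0, 1, 2, 3, 4, 8, 12, 18, 24),
                               n_per_point = 6,
                               prey = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (length(time_points) == 0 || any(time_points < 0)) {
    abort("time_points must be non-empty and non-negative")
  }
  specs <- scenario$decay
  if (!is.null(prey)) {
    specs <- dplyr::filter(specs, .data$prey_species %in% prey)
    if (nrow(specs) == 0) abort("no decay spec matches the requested prey")
  }
  if (any(specs$beta1 >= 0)) abort("decay slopes must be negative")
  withr::with_seed(stage_seed(scenario, "feeding"), {
    out <- tidyr::crossing(
      specs,
      tibble::tibble(hours_post_feeding = sort(unique(time_points)))
    )
    out <- tidyr::uncount(out, n_per_point)
    out$detected <- runif(nrow(out)) <
      plogis(out$beta0 + out$beta1 * out$hours_post_feeding)
    out <- dplyr::select(
      out, "predator_species", "prey_species", "hours_post_feeding", "detected"
    )
    attr(out, "igp_schema") <- "feeding_trial"
    out
  })
}

#' Generate a clustered field survey
#'
#' Draws `n_units` sampling units with negative-binomial aphid densities,
#' a Poisson number of larvae per unit per predator species, instars from
#' the scenario's instar distribution, and per-larva detection flags with
#' `logit p = qlogis(true_prob) + u_j`, where the unit effect
#' `u_j ~ Normal(0, unit_sd^2)` is shared by both prey kinds within a
#' unit. This is exactly the random-intercept structure the mixed-model
#' comparison assumes.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with elements `units` (schema `field_survey_units`) and
#'   `larvae` (schema `field_survey_larvae`).
#' @export
gen_field_survey <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  fs <- scenario$field
  if (any(fs$larvae_per_unit <= 0)) {
    abort("larvae_per_unit means must be > 0")
  }
  species <- names(fs$larvae_per_unit)
  probs <- fs$detection_probs
  get_prob <- function(sp, kind) {
    hit <- probs$prob[probs$predator_species == sp & probs$prey_kind == kind]
    if (length(hit) != 1) {
      abort(paste0("no detection probability for (", sp, ", ", kind, ")"))
    }
    hit
  }
  withr::with_seed(stage_seed(scenario, "field"), {
    units <- tibble::tibble(
      unit_id = sprintf("U%02d", seq_len(fs$n_units)),
      aphid_density = as.numeric(rnbinom(
        fs$n_units, size = fs$density_dispersion, mu = fs$density_mean
      ))
    )
    unit_effect <- rnorm(fs$n_units, 0, fs$unit_sd)

    larvae <- purrr::map_dfr(seq_len(fs$n_units), function(j) {
      purrr::map_dfr(species, function(sp) {
        n <- rpois(1, fs$larvae_per_unit[[sp]])
        if (n == 0) return(NULL)
        p_aphid <- plogis(qlogis(get_prob(sp, "aphid")) + unit_effect[j])
        p_het <- plogis(qlogis(get_prob(sp, "heterospecific")) + unit_effect[j])
        tibble::tibble(
          unit_id = units$unit_id[j],
          predator_species = sp,
          instar = sample.int(4L, n, replace = TRUE, prob = fs$instar_probs),
          detected_aphid = runif(n) < p_aphid,
          detected_heterospecific = runif(n) < p_het
        )
      })
    })
    larvae <- dplyr::mutate(
      larvae,
      larva_id = sprintf("L%04d", dplyr::row_number()),
      .before = 1
    )
    attr(units, "igp_schema") <- "field_survey_units"
    attr(larvae, "igp_schema") <- "field_survey_larvae"
    list(units = units, larvae = larvae)
  })
}

#' Generate laboratory bioassay data
#'
#' For each (IG-predator, prey stage class) cell and each arena aphid
#' density `d`, draws `n_per_cell` predation outcomes from
#' `Bernoulli(plogis(alpha + gamma * d))`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param density_grid Arena aphid densities (non-empty).
#' @param n_per_cell Trials per (cell, density) combination.
#' @return Tibble in the `lab_bioassay` schema.
#' @export
gen_lab_bioassays <- function(scenario,
                              density_grid = seq(0, 100, by = 20),
                              n_per_cell = 10) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (length(density_grid) == 0) abort("density_grid must be non-empty")
  withr::with_seed(stage_seed(scenario, "lab"), {
    out <- tidyr::crossing(
      scenario$lab,
      tibble::tibble(aphid_density = as.numeric(sort(unique(density_grid))))
    )
    out <- tidyr::uncount(out, n_per_cell)
    out$predation <- runif(nrow(out)) <
      plogis(out$alpha + out$gamma * out$aphid_density)
    out <- dplyr::select(
      out, "ig_predator_species", "prey_stage_class", "aphid_density",
      "predation"
    )
    attr(out, "igp_schema") <- "lab_bioassay"
    out
  })
}
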