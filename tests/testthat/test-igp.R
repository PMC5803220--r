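flat_units <- function(n_units = 3, density = 50) {
  tibble::tibble(unit_id = sprintf("U%02d", 1:n_units),
                 aphid_density = density)
}

flat_larvae <- function(n, species = "X", n_units = 3) {
  tibble::tibble(
    larva_id = sprintf("L%03d", 1:n),
    unit_id = sprintf("U%02d", rep_len(1:n_units, n)),
    predator_species = species,
    instar = 4L,
    detected_aphid = FALSE,
    detected_heterospecific = FALSE
  )
}

test_that("stage models recover generative parameters and flag separation", {
  sc <- default_scenario(seed = 3)
  sc$lab <- tibble::tibble(
    ig_predator_species = "X", prey_stage_class = "similar_larvae",
    alpha = 1.04, gamma = -0.02
  )
  lab <- gen_lab_bioassays(sc, density_grid = seq(0, 100, 10), n_per_cell = 1000)
  sm <- fit_stage_models(lab)
  expect_true(sm$converged)
  expect_equal(sm$alpha, 1.04, tolerance = 0.10)
  expect_equal(sm$gamma, -0.02, tolerance = 0.10)

  # constant 50% predation: slope ~ 0
  flat <- tibble::tibble(
    ig_predator_species = "X", prey_stage_class = "immobile",
    aphid_density = rep(c(0, 50, 100), each = 40),
    predation = rep(c(TRUE, FALSE), 60)
  )
  sm_flat <- fit_stage_models(flat)
  expect_equal(sm_flat$gamma, 0, tolerance = 0.02)

  # all-predation cell: non-converged
  all_pred <- dplyr::mutate(flat, predation = TRUE)
  sm_sep <- fit_stage_models(all_pred)
  expect_false(sm_sep$converged)
  expect_true(is.na(sm_sep$alpha))
})

test_that("certainty and impossibility propagate through the two-part draw", {
  larvae <- flat_larvae(15)
  units <- flat_units()
  decay_sure <- make_decay(700, -1e-3)
  cfg <- sim_config(seed = 5, n_iterations = 300)

  sure <- simulate_igp_counts(
    larvae, units, make_stage_models("X", alpha = 700, gamma = 0),
    decay_sure, cfg
  )
  expect_true(all(sure$draws == 15))

  never <- simulate_igp_counts(
    larvae, units, make_stage_models("X", alpha = -700, gamma = 0),
    decay_sure, cfg
  )
  expect_true(all(never$draws == 0))
})

test_that("draws are conserved, integer and seed-deterministic", {
  larvae <- flat_larvae(20)
  units <- flat_units()
  sm <- make_stage_models("X", alpha = 0.5, gamma = -0.01)
  dm <- make_decay(2.4899, -0.21841)
  cfg <- sim_config(seed = 11, n_iterations = 500)
  a <- simulate_igp_counts(larvae, units, sm, dm, cfg)
  b <- simulate_igp_counts(larvae, units, sm, dm, cfg)
  expect_identical(a$draws, b$draws)
  expect_true(all(a$draws >= 0 & a$draws <= 20))
  expect_type(a$draws, "integer")
  cfg2 <- sim_config(seed = 12, n_iterations = 500)
  expect_false(identical(
    a$draws, simulate_igp_counts(larvae, units, sm, dm, cfg2)$draws
  ))
})

test_that("Monte Carlo means match the quadrature oracle", {
  units <- flat_units(1, density = 60)
  larvae <- flat_larvae(20, n_units = 1)
  sm <- make_stage_models("X", alpha = c(2, 1, -0.5), gamma = c(-0.02, -0.01, -0.03))
  dm <- make_decay(2.4899, -0.21841)
  cfg <- sim_config(seed = 21, n_iterations = 5000)
  sim <- simulate_igp_counts(larvae, units, sm, dm, cfg)
  oracle <- quad_expected_count(
    alpha = sm$alpha, gamma = sm$gamma,
    weights = cfg$stage_class_weights,
    densities = rep(60, 20), b0 = 2.4899, b1 = -0.21841, W = 6
  )
  mc_se <- sd(sim$draws) / sqrt(length(sim$draws))
  expect_lt(abs(mean(sim$draws) - oracle), 3 * mc_se)
})

test_that("degenerate stage weights reduce to the single-model expectation", {
  units <- flat_units(1, density = 40)
  larvae <- flat_larvae(25, n_units = 1)
  sm <- make_stage_models("X", alpha = c(1.2, -5, -5), gamma = c(-0.015, 0, 0))
  dm <- make_decay(3.1975, -0.21841)
  cfg <- sim_config(
    seed = 31, n_iterations = 5000,
    stage_class_weights = c(immobile = 1, small_larvae = 0, similar_larvae = 0)
  )
  sim <- simulate_igp_counts(larvae, units, sm, dm, cfg)
  oracle <- quad_expected_count(
    alpha = 1.2, gamma = -0.015, weights = 1,
    densities = rep(40, 25), b0 = 3.1975, b1 = -0.21841, W = 6
  )
  mc_se <- sd(sim$draws) / sqrt(length(sim$draws))
  expect_lt(abs(mean(sim$draws) - oracle), 3 * mc_se)
})

test_that("a missing stage model with positive weight aborts the simulation", {
  larvae <- flat_larvae(10)
  units <- flat_units()
  sm <- make_stage_models("X", alpha = 1, gamma = -0.01)
  sm$converged[sm$prey_stage_class == "immobile"] <- FALSE
  dm <- make_decay(2, -0.2)
  cfg <- sim_config(seed = 41, n_iterations = 10)
  expect_error(simulate_igp_counts(larvae, units, sm, dm, cfg), "immobile")

  # zero weight on the missing class: simulation proceeds
  cfg0 <- sim_config(
    seed = 41, n_iterations = 10,
    stage_class_weights = c(immobile = 0, small_larvae = 0.5,
                            similar_larvae = 0.5)
  )
  expect_s3_class(simulate_igp_counts(larvae, units, sm, dm, cfg0),
                  "igp_simulation")
})

test_that("summary statistics follow their definitions on known draws", {
  base <- structure(
    list(species = "X", n_larvae = 100L, draws = 0:100,
         observed_positive = NA_integer_, expected_count = NA_real_,
         expected_proportion = NA_real_, ci_low = NA_real_,
         ci_high = NA_real_, p_value = NA_real_,
         config = sim_config(seed = 1, n_iterations = 101)),
    class = "igp_simulation"
  )
  out <- summarize_simulation(base, observed_positive = 50)
  expect_equal(out$expected_count, mean(0:100))
  expect_equal(out$expected_proportion, 0.5)
  expect_equal(out$ci_low, quantile(0:100, 0.025, names = FALSE))
  expect_equal(out$ci_high, quantile(0:100, 0.975, names = FALSE))
  expect_equal(out$ci_low, 2.5)
  expect_equal(out$ci_high, 97.5)

  # all draws equal to the observation: p capped at 1
  same <- base
  same$draws <- rep(7L, 500)
  same$config <- sim_config(seed = 1, n_iterations = 500)
  expect_equal(summarize_simulation(same, 7)$p_value, 1)

  # observation far below all draws: continuity-corrected minimum
  extreme <- base
  extreme$draws <- rep(5:30, length.out = 5000)
  extreme$config <- sim_config(seed = 1, n_iterations = 5000)
  out2 <- summarize_simulation(extreme, 0)
  expect_equal(out2$p_value, 2 / 5001, tolerance = 1e-12)
  expect_lt(out2$p_value, 0.001)

  one_sided <- extreme
  one_sided$config <- sim_config(seed = 1, n_iterations = 5000,
                                 alternative = "less")
  expect_equal(summarize_simulation(one_sided, 0)$p_value, 1 / 5001)
})

test_that("the orchestrated observed-vs-expected analysis is complete", {
  sc <- default_scenario(seed = 47)
  trials <- gen_feeding_trials(sc, n_per_point = 12)
  survey <- gen_field_survey(sc)
  lab <- gen_lab_bioassays(sc, n_per_cell = 30)
  cfg <- sim_config(seed = 53, n_iterations = 400)
  res <- run_observed_vs_expected(survey$larvae, survey$units, lab, trials, cfg)
  tbl <- tidy(res)
  expect_equal(nrow(tbl), 2)
  expect_setequal(tbl$species, c("C. septempunctata", "H. variegata"))
  expect_true(all(tbl$p_value > 0 & tbl$p_value <= 1))
  expect_true(all(tbl$ci_low <= tbl$expected_count))
  expect_true(all(tbl$expected_count <= tbl$ci_high))
  expect_true(all(tbl$observed_positive <= tbl$n_larvae))
  expect_equal(tbl$expected_proportion, tbl$expected_count / tbl$n_larvae)
  # larvae restricted to instars 3-4
  n34 <- dplyr::count(
    dplyr::filter(survey$larvae, instar %in% c(3, 4)),
    predator_species
  )
  expect_equal(sort(tbl$n_larvae), sort(n34$n))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("simulation aborts with the failing stage named", {
  sc <- default_scenario(seed = 59)
  survey <- gen_field_survey(sc)
  lab <- gen_lab_bioassays(sc, n_per_cell = 20)
  cfg <- sim_config(seed = 1, n_iterations = 10)
  no_trials <- gen_feeding_trials(sc, n_per_point = 4, prey = "A. gossypii")
  expect_error(
    run_observed_vs_expected(survey$larvae, survey$units, lab, no_trials, cfg),
    "fit_decay"
  )
})
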