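random_larvae <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    larva_id = sprintf("L%03d", 1:n),
    unit_id = sample(sprintf("U%02d", 1:5), n, replace = TRUE),
    predator_species = sample(c("A", "B"), n, replace = TRUE),
    instar = sample(1:4, n, replace = TRUE),
    detected_aphid = runif(n) < 0.6,
    detected_heterospecific = runif(n) < 0.3
  ))
}

test_that("summarize_detection matches brute-force recounts", {
  larvae <- random_larvae(200, seed = 1)
  summ <- summarize_detection(larvae, "heterospecific", instars = c(3, 4))
  for (sp in c("A", "B")) {
    sub <- larvae[larvae$predator_species == sp & larvae$instar %in% c(3, 4), ]
    row <- summ[summ$predator_species == sp, ]
    expect_equal(row$n_screened, nrow(sub))
    expect_equal(row$n_positive, sum(sub$detected_heterospecific))
    expect_equal(row$proportion, mean(sub$detected_heterospecific))
  }
})

test_that("a 38/151 split prints as the familiar 25.2%", {
  larvae <- tibble::tibble(
    larva_id = sprintf("L%03d", 1:151),
    unit_id = "U1", predator_species = "X", instar = 4L,
    detected_aphid = FALSE,
    detected_heterospecific = c(rep(TRUE, 38), rep(FALSE, 113))
  )
  summ <- summarize_detection(larvae, "heterospecific")
  expect_equal(summ$proportion, 38 / 151)
  expect_equal(round(100 * summ$proportion, 1), 25.2)

  all_true <- dplyr::mutate(larvae, detected_heterospecific = TRUE)
  expect_equal(summarize_detection(all_true, "heterospecific")$proportion, 1)
})

test_that("species emptied by the instar filter are omitted with a warning", {
  larvae <- random_larvae(50, seed = 2)
  larvae$instar[larvae$predator_species == "B"] <- 1L
  expect_warning(
    summ <- summarize_detection(larvae, "aphid", instars = c(3, 4)),
    "omitted"
  )
  expect_false("B" %in% summ$predator_species)
})

test_that("correction is the identity under a shared decay model", {
  m <- make_decay(2.4899, -0.21841)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(correct_proportion(p, m, m), p, tolerance = 1e-10)
})

test_that("correction follows the closed form and is monotone", {
  own <- make_decay(3, -1)
  ref <- make_decay(2, -1)
  # p = 0.5 -> t* = 3 -> plogis(2 - 3) = plogis(-1)
  expect_equal(correct_proportion(0.5, own, ref), plogis(-1), tolerance = 1e-12)
  expect_equal(correct_proportion(0.5, own, ref), 0.2689, tolerance = 1e-3)

  grid <- seq(0.05, 0.95, by = 0.01)
  out <- correct_proportion(grid, own, ref)
  expect_true(all(diff(out) > 0))
  expect_true(all(out > 0 & out < 1))
})

test_that("A->B->A correction round trip returns the original proportion", {
  a <- make_decay(2.4899, -0.21841)
  b <- make_decay(3.1975, -0.31)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(correct_proportion(correct_proportion(p, a, b), b, a), p,
               tolerance = 1e-8)
})

test_that("correcting a slower-digesting species onto a faster reference lowers it", {
  # reference T50 2.27 h vs corrected species T50 2.81 h (aphid regime),
  # and 11.40 vs 14.64 (ladybird regime)
  regimes <- list(
    list(ref = make_decay(2.27 * 0.9, -0.9), own = make_decay(2.81 * 0.9, -0.9)),
    list(ref = make_decay(2.4899, -0.21841), own = make_decay(3.1975, -0.21841))
  )
  for (r in regimes) {
    p <- seq(0.05, 0.95, by = 0.05)
    expect_true(all(correct_proportion(p, r$own, r$ref) < p))
  }
})

test_that("rank_predators keeps the reference raw and can flip rankings", {
  summ <- tibble::tibble(
    predator_species = c("A", "B"),
    prey_kind = "heterospecific",
    n_screened = c(151L, 53L),
    n_positive = c(38L, 15L),
    proportion = c(38 / 151, 15 / 53)
  )
  # equal decay models: corrected == raw, same ranking
  same <- list(make_decay(2, -0.3, predator = "A"),
               make_decay(2, -0.3, predator = "B"))
  rk <- rank_predators(summ, same, reference_species = "A")
  expect_equal(rk$table$proportion_corrected, rk$table$proportion_raw,
               tolerance = 1e-12)
  expect_identical(rk$ranking_raw, rk$ranking_corrected)

  # B digests much slower (longer T50): its corrected value drops below
  # its raw value and below A, flipping the ranking
  slow_b <- list(make_decay(2.4899, -0.21841, predator = "A"),
                 make_decay(3.1975, -0.21841, predator = "B"))
  rk2 <- rank_predators(summ, slow_b, reference_species = "A")
  b_row <- rk2$table[rk2$table$predator_species == "B", ]
  expect_lt(b_row$proportion_corrected, b_row$proportion_raw)
  expect_identical(rk2$ranking_raw, c("B", "A"))
  expect_identical(rk2$ranking_corrected, c("A", "B"))
  # reference untouched
  a_row <- rk2$table[rk2$table$predator_species == "A", ]
  expect_equal(a_row$proportion_corrected, a_row$proportion_raw)
})

test_that("boundary proportions get a continuity adjustment with warning", {
  summ <- tibble::tibble(
    predator_species = c("A", "B"), prey_kind = "aphid",
    n_screened = c(100L, 40L), n_positive = c(70L, 40L),
    proportion = c(0.7, 1.0)
  )
  models <- list(make_decay(2, -0.3, predator = "A"),
                 make_decay(2, -0.3, predator = "B"))
  expect_warning(rk <- rank_predators(summ, models, "A"), "continuity")
  b_corr <- rk$table$proportion_corrected[rk$table$predator_species == "B"]
  expect_equal(b_corr, (40 + 0.5) / (40 + 1), tolerance = 1e-10)
})

test_that("rank_predators names the species missing a decay model", {
  summ <- tibble::tibble(
    predator_species = c("A", "B"), prey_kind = "aphid",
    n_screened = c(10L, 10L), n_positive = c(5L, 5L), proportion = 0.5
  )
  expect_error(
    rank_predators(summ, list(make_decay(2, -0.3, predator = "A")), "A"),
    "B"
  )
})

test_that("the GLMM recovers a strong species contrast on clustered data", {
  sc <- tweak_scenario(
    seed = 61, unit_sd = 0.5,
    detection_probs = detect_probs(0.709, 0.906)
  )
  survey <- gen_field_survey(sc)
  cmp <- compare_predators_glmm(survey$larvae, survey$units, "aphid")
  expect_true(cmp$converged)
  expect_gt(cmp$fixed_effect_estimate, 0) # H. variegata higher than Cs
  expect_gte(cmp$unit_sd_estimate, 0)
  expect_equal(cmp$n_units, dplyr::n_distinct(survey$larvae$unit_id))
  td <- tidy(cmp)
  expect_equal(td$estimate, cmp$fixed_effect_estimate)
  gl <- glance(cmp)
  expect_false(gl$fallback)

  lrt <- compare_predators_glmm(survey$larvae, survey$units, "aphid",
                                test = "lrt")
  expect_true(is.finite(lrt$p_value))
})

test_that("unit SD estimates are near zero when units carry no signal", {
  ests <- purrr::map_dbl(1:30, function(i) {
    sc <- tweak_scenario(seed = 7000 + i, unit_sd = 0,
                         detection_probs = detect_probs(0.6, 0.6))
    survey <- gen_field_survey(sc)
    compare_predators_glmm(survey$larvae, survey$units, "aphid")$unit_sd_estimate
  })
  expect_lt(median(ests), 0.15)
})

test_that("GLMM input validation catches structural errors", {
  larvae <- random_larvae(60, seed = 3)
  units <- tibble::tibble(unit_id = sprintf("U%02d", 1:5), aphid_density = 10)
  one_species <- dplyr::mutate(larvae, predator_species = "A")
  expect_error(compare_predators_glmm(one_species, units, "aphid"),
               "two predator species")
  expect_error(
    compare_predators_glmm(larvae, units[1:2, ], "aphid"),
    "unknown unit_id"
  )
})
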