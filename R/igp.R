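#' Fit stage-specific laboratory predation models
#'
#' For each (IG-predator species, prey stage class) cell, fits a
#' logistic regression of the predation outcome on arena aphid density:
#' `logit P(predation) = alpha + gamma * d`. These are the "first part"
#' models of the observed-vs-expected simulation: one is drawn per larva
#' per iteration according to the stage-class weights.
#'
#' Cells with a single outcome value, fewer than two distinct densities,
#' or quasi-separated fits (|coefficient| > 15) are flagged
#' `converged = FALSE` and excluded from simulation use.
#'
#' @param records Tibble in the `lab_bioassay` schema.
#' @return A `stage_models` tibble: `ig_predator_species`,
#'   `prey_stage_class`, `alpha`, `gamma`, `alpha_se`, `gamma_se`,
#'   `n_obs`, `converged`.
#' @export
fit_stage_models <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("ig_predator_species", "prey_stage_class", "aphid_density",
              "predation")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("records lack column(s): ", paste(missing, collapse = ", ")))
  }
  cells <- dplyr::group_split(
    records, .data$ig_predator_species, .data$prey_stage_class
  )
  out <- purrr::map_dfr(cells, function(cell) {
    base <- tibble::tibble(
      ig_predator_species = cell$ig_predator_species[1],
      prey_stage_class = cell$prey_stage_class[1],
      n_obs = nrow(cell)
    )
    y <- as.logical(cell$predation)
    degenerate <- dplyr::n_distinct(y) < 2 ||
      dplyr::n_distinct(cell$aphid_density) < 2
    if (degenerate) {
      return(dplyr::mutate(base, alpha = NA_real_, gamma = NA_real_,
                           alpha_se = NA_real_, gamma_se = NA_real_,
                           converged = FALSE))
    }
    fit <- suppressWarnings(glm(y ~ aphid_density, family = binomial(),
                                data = cell))
    co <- unname(coef(fit))
    se <- sqrt(diag(vcov(fit)))
    ok <- fit$converged && all(abs(co) <= 15)
    dplyr::mutate(
      base,
      alpha = if (ok) co[1] else NA_real_,
      gamma = if (ok) co[2] else NA_real_,
      alpha_se = if (ok) se[1] else NA_real_,
      gamma_se = if (ok) se[2] else NA_real_,
      converged = ok
    )
  })
  out <- dplyr::select(
    out, "ig_predator_species", "prey_stage_class", "alpha", "gamma",
    "alpha_se", "gamma_se", "n_obs", "converged"
  )
  class(out) <- c("stage_models", class(out))
  out
}

#' Configuration of the observed-vs-expected simulation
#'
#' @param seed Integer seed for the simulation's randomness; required.
#' @param n_iterations Simulated datasets (default 5000).
#' @param encounter_window_hours Length of the window before collection
#'   within which an IG-prey encounter is assumed (default 6 h); the
#'   feeding time is drawn uniformly on it.
#' @param stage_class_weights Probabilities of encountering each prey
#'   stage class, named `immobile`, `small_larvae`, `similar_larvae`;
#'   must sum to 1. Default: equal weights (encounters "randomly
#'   assigned" with no further information).
#' @param ci_level Confidence level for the empirical interval (default
#'   0.95).
#' @param density_scale Linear factor converting field aphid density
#'   (aphids per 10 leaves) to the laboratory arena density scale;
#'   defaults to 1 (identity) and should be calibrated when the two
#'   scales differ.
#' @param alternative Sidedness of the p-value: `"two.sided"` (default,
#'   with +1 continuity correction), `"less"` or `"greater"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_iterations = 5000,
                       encounter_window_hours = 6,
                       stage_class_weights = c(
                         immobile = 1, small_larvae = 1, similar_larvae = 1
                       ) / 3,
                       ci_level = 0.95,
                       density_scale = 1,
                       alternative = c("two.sided", "less", "greater")) {
  alternative <- rlang::arg_match(alternative)
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (encounter_window_hours <= 0) abort("encounter_window_hours must be > 0")
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must lie in (0, 1)")
  w <- stage_class_weights
  if (is.null(names(w))) names(w) <- stage_classes()
  if (!setequal(names(w), stage_classes())) {
    abort(paste0("stage_class_weights must be named ",
                 paste(stage_classes(), collapse = ", ")))
  }
  w <- w[stage_classes()]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    abort("stage_class_weights must be non-negative and sum to 1")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_iterations = as.integer(n_iterations),
      encounter_window_hours = encounter_window_hours,
      stage_class_weights = w,
      ci_level = ci_level,
      density_scale = density_scale,
      alternative = alternative
    ),
    class = "sim_config"
  )
}

#' Simulate expected IGP detection counts (two-part model)
#'
#' For each of `n_iterations` simulated datasets and each field larva
#' `i` (one IG-predator species): a prey stage class is drawn with the
#' configured weights; predation is drawn as
#' `Bernoulli(plogis(alpha_c + gamma_c * density_scale * d_i))` from the
#' class's laboratory model at the larva's unit aphid density; if
#' predation occurred, a feeding time `tau ~ Uniform(0, window)` is
#' drawn and detection as `Bernoulli(detect_prob(decay_model, tau))`.
#' The two Bernoulli draws are dependent events: detection is drawn only
#' when predation occurred. The iteration's value is the count of
#' positive larvae.
#'
#' The stage class is re-drawn for every larva in every iteration, and
#' each larva's density is fixed at its unit's measured value (no
#' density resampling across iterations).
#'
#' @param larvae Field larvae of a single predator species (the caller
#'   applies any instar restriction).
#' @param units Sampling-unit tibble providing each larva's aphid
#'   density.
#' @param stage_models [fit_stage_models()] output; must contain a
#'   converged model for this species and every stage class with
#'   non-zero weight.
#' @param decay_model Converged `decay_model` of this species detecting
#'   the heterospecific prey.
#' @param config A [sim_config()].
#' @return An `igp_simulation` object with the `draws` vector filled and
#'   summary fields empty; pass to [summarize_simulation()].
#' @export
simulate_igp_counts <- function(larvae, units, stage_models, decay_model,
                                config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(decay_model, "decay_model"))
  larvae <- tibble::as_tibble(larvae)
  species <- unique(larvae$predator_species)
  if (length(species) != 1) {
    abort("larvae must belong to a single IG-predator species")
  }
  if (!decay_model$converged) abort("decay model did not converge")

  dat <- dplyr::left_join(larvae, tibble::as_tibble(units), by = "unit_id")
  if (any(is.na(dat$aphid_density))) {
    abort("some larvae reference units with no aphid density")
  }

  sm <- dplyr::filter(
    tibble::as_tibble(stage_models), .data$ig_predator_species == species
  )
  w <- config$stage_class_weights
  needed_classes <- names(w)[w > 0]
  alpha <- gamma <- stats::setNames(rep(NA_real_, 3), stage_classes())
  for (cl in stage_classes()) {
    row <- dplyr::filter(sm, .data$prey_stage_class == cl)
    if (nrow(row) == 1 && isTRUE(row$converged)) {
      alpha[cl] <- row$alpha
      gamma[cl] <- row$gamma
    }
  }
  absent <- needed_classes[is.na(alpha[needed_classes])]
  if (length(absent) > 0) {
    abort(paste0(
      "no converged stage model for species '", species, "', class(es) ",
      paste(absent, collapse = ", "), "; simulation cannot proceed"
    ))
  }

  n <- nrow(dat)
  B <- config$n_iterations
  d_lab <- config$density_scale * dat$aphid_density
  W <- config$encounter_window_hours

  draws <- withr::with_seed(config$seed, {
    # n x B layout: larvae vary fastest, iterations are columns
    cls <- sample.int(3L, n * B, replace = TRUE, prob = w)
    p_pred <- plogis(alpha[cls] + gamma[cls] * rep(d_lab, times = B))
    predated <- runif(n * B) < p_pred
    tau <- runif(n * B, 0, W)
    positive <- predated & (runif(n * B) < detect_prob(decay_model, tau))
    as.integer(colSums(matrix(positive, nrow = n, ncol = B)))
  })

  structure(
    list(
      species = species,
      n_larvae = n,
      draws = draws,
      observed_positive = NA_integer_,
      expected_count = NA_real_,
      expected_proportion = NA_real_,
      ci_low = NA_real_,
      ci_high = NA_real_,
      p_value = NA_real_,
      config = config
    ),
    class = "igp_simulation"
  )
}

#' Summarize a simulated IGP count distribution against the observation
#'
#' Fills the summary fields of an [simulate_igp_counts()] result:
#' `expected_count` is the mean of the draws, the confidence interval is
#' the pair of empirical quantiles at `(1 - ci_level)/2` and
#' `1 - (1 - ci_level)/2`, and the p-value is the probability of a value
#' at least as extreme as the observation under the simulated
#' distribution, with a +1 continuity correction so it is never zero:
#' `p = min(1, 2 * min(r_le, r_ge))` with
#' `r_le = (#draws <= obs + 1) / (B + 1)` (two-sided default; one-sided
#' via the config's `alternative`).
#'
#' @param result An `igp_simulation` with draws.
#' @param observed_positive Observed count of field-positive larvae
#'   (0 to `n_larvae`).
#' @param config A [sim_config()]; defaults to the one stored in
#'   `result`.
#' @return The `igp_simulation` with summary fields filled.
#' @export
summarize_simulation <- function(result, observed_positive,
                                 config = result$config) {
  stopifnot(inherits(result, "igp_simulation"))
  if (length(result$draws) == 0) abort("draws are empty")
  obs <- observed_positive
  if (obs < 0 || obs > result$n_larvae) {
    abort("observed_positive must lie in [0, n_larvae]")
  }
  draws <- result$draws
  B <- length(draws)
  qs <- quantile(
    draws,
    probs = c((1 - config$ci_level) / 2, 1 - (1 - config$ci_level) / 2),
    names = FALSE
  )
  r_le <- (sum(draws <= obs) + 1) / (B + 1)
  r_ge <- (sum(draws >= obs) + 1) / (B + 1)
  p <- switch(config$alternative,
    two.sided = min(1, 2 * min(r_le, r_ge)),
    less = r_le,
    greater = r_ge
  )
  result$observed_positive <- as.integer(obs)
  result$expected_count <- mean(draws)
  result$expected_proportion <- mean(draws) / result$n_larvae
  result$ci_low <- qs[1]
  result$ci_high <- qs[2]
  result$p_value <- p
  result
}

#' @export
print.igp_simulation <- function(x, ...) {
  cat("Two-part IGP simulation: ", x$species, " (", x$n_larvae,
      " larvae, ", length(x$draws), " iterations)\n", sep = "")
  if (is.na(x$expected_count)) {
    cat("  draws only; call summarize_simulation() with the observed count\n")
    return(invisible(x))
  }
  cat(sprintf(
    "  observed %d (%.1f%%)  expected %.1f (%.1f%%)  %g%% CI [%.1f, %.1f]\n",
    x$observed_positive, 100 * x$observed_positive / x$n_larvae,
    x$expected_count, 100 * x$expected_proportion,
    100 * x$config$ci_level, x$ci_low, x$ci_high
  ))
  cat(sprintf("  P = %.4g (%s)\n", x$p_value, x$config$alternative))
  invisible(x)
}

#' @rdname summarize_simulation
#' @param x An `igp_simulation`.
#' @param ... Unused.
#' @method tidy igp_simulation
#' @export
tidy.igp_simulation <- function(x, ...) {
  tibble::tibble(
    species = x$species,
    n_larvae = x$n_larvae,
    observed_positive = x$observed_positive,
    observed_proportion = x$observed_positive / x$n_larvae,
    expected_count = x$expected_count,
    expected_proportion = x$expected_proportion,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    p_value = x$p_value
  )
}

#' Observed-vs-expected IGP analysis, end to end
#'
#' Orchestrates the full comparison for both IG-predator species: fits
#' the stage-specific laboratory predation models, fits each species'
#' decay model for detecting the heterospecific ladybird, counts
#' observed field IGP positives among the requested instars, simulates
#' the expected count distribution with the two-part model, and
#' summarizes expectation, confidence interval and significance.
#'
#' Per-species simulations use `config$seed` and `config$seed + 1` (in
#' alphabetical species order) so the pair is reproducible from one
#' seed.
#'
#' @param larvae,units Field-survey tibbles.
#' @param lab_records Laboratory bioassay tibble.
#' @param feeding_records Feeding-trial tibble containing, for each
#'   species, its trials detecting the other species.
#' @param config A [sim_config()].
#' @param instars Instars analysed (default `c(3, 4)`, the stages
#'   comparable to the laboratory IG-prey bioassays).
#' @return An `igp_comparison`: `results` (named list of
#'   `igp_simulation`s) and `table` (two-row tidy summary).
#' @export
run_observed_vs_expected <- function(larvae, units, lab_records,
                                     feeding_records, config,
                                     instars = c(3, 4)) {
  stopifnot(inherits(config, "sim_config"))
  larvae <- tibble::as_tibble(larvae)
  species <- sort(unique(larvae$predator_species))
  if (length(species) != 2) {
    abort("exactly two predator species are required")
  }
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }
  stage_models <- in_stage("fit_stage_models", fit_stage_models(lab_records))
  observed <- in_stage(
    "summarize_detection",
    summarize_detection(larvae, "heterospecific", instars = instars)
  )
  results <- purrr::map(seq_along(species), function(i) {
    sp <- species[i]
    other <- setdiff(species, sp)
    trials <- dplyr::filter(
      tibble::as_tibble(feeding_records),
      .data$predator_species == sp, .data$prey_species == other
    )
    if (nrow(trials) == 0) {
      abort(paste0("stage 'fit_decay' failed: no feeding trials for ",
                   sp, " detecting ", other))
    }
    dm <- in_stage("fit_decay", fit_decay(trials))
    if (!dm$converged) {
      abort(paste0("stage 'fit_decay' failed: decay model for ", sp,
                   " did not converge (", dm$diagnostic, ")"))
    }
    sub <- dplyr::filter(larvae, .data$predator_species == sp,
                         .data$instar %in% instars)
    cfg <- config
    cfg$seed <- config$seed + (i - 1L)
    sim <- in_stage(
      "simulate_igp_counts",
      simulate_igp_counts(sub, units, stage_models, dm, cfg)
    )
    obs_n <- observed$n_positive[observed$predator_species == sp]
    summarize_simulation(sim, obs_n, cfg)
  })
  names(results) <- species
  structure(
    list(
      results = results,
      table = purrr::map_dfr(results, tidy),
      instars = instars
    ),
    class = "igp_comparison"
  )
}

#' @export
print.igp_comparison <- function(x, ...) {
  cat("Observed vs expected IGP (instars ",
      paste(x$instars, collapse = ", "), ")\n", sep = "")
  for (r in x$results) print(r)
  invisible(x)
}

#' @rdname run_observed_vs_expected
#' @param x An `igp_comparison`.
#' @param ... Unused.
#' @method tidy igp_comparison
#' @export
tidy.igp_comparison <- function(x, ...) {
  x$table
}

#' Plot observed versus expected IGP levels
#'
#' Bars show the observed percentage of field larvae positive for the
#' heterospecific ladybird; dots and whiskers show the simulated
#' expectation and its confidence interval.
#'
#' @param object An `igp_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot igp_comparison
#' @export
autoplot.igp_comparison <- function(object, ...) {
  tbl <- object$table
  tbl <- dplyr::mutate(
    tbl,
    observed_pct = 100 * .data$observed_proportion,
    expected_pct = 100 * .data$expected_proportion,
    lo_pct = 100 * .data$ci_low / .data$n_larvae,
    hi_pct = 100 * .data$ci_high / .data$n_larvae
  )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$species)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_pct),
                      fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lo_pct, ymax = .data$hi_pct), width = 0.15
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_pct), size = 3) +
    ggplot2::labs(
      x = NULL, y = "Larvae positive for IGP (%)",
      title = "Observed (bars) vs expected (dots) intraguild predation"
    ) +
    ggplot2::theme_minimal()
}
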