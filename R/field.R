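#' Summarize field detection proportions per predator species
#'
#' Counts screened larvae and positive detections of the requested prey
#' kind for each predator species, optionally restricted to an instar
#' subset (e.g. `c(3, 4)` for the IGP analysis of late instars).
#'
#' @param larvae Tibble in the `field_survey_larvae` schema.
#' @param prey_kind `"aphid"` (extraguild prey) or `"heterospecific"`
#'   (the other ladybird, i.e. IGP).
#' @param instars Optional integer subset of 1-4.
#' @return Tibble with `predator_species`, `prey_kind`, `n_screened`,
#'   `n_positive`, `proportion`.
#' @export
summarize_detection <- function(larvae, prey_kind, instars = NULL) {
  prey_kind <- rlang::arg_match(prey_kind, prey_kinds())
  larvae <- tibble::as_tibble(larvae)
  species_before <- unique(larvae$predator_species)
  if (!is.null(instars)) {
    larvae <- dplyr::filter(larvae, .data$instar %in% instars)
  }
  if (nrow(larvae) == 0) {
    abort("no larvae left after the instar filter")
  }
  lost <- setdiff(species_before, unique(larvae$predator_species))
  if (length(lost) > 0) {
    warn(paste0(
      "species omitted (no larvae after filtering): ",
      paste(lost, collapse = ", ")
    ))
  }
  flag <- paste0("detected_", if (prey_kind == "aphid") "aphid" else "heterospecific")
  dplyr::summarise(
    dplyr::group_by(larvae, .data$predator_species),
    prey_kind = prey_kind,
    n_screened = dplyr::n(),
    n_positive = sum(as.logical(.data[[flag]])),
    proportion = .data$n_positive / .data$n_screened,
    .groups = "drop"
  )
}

#' Compare predator species with a binomial mixed model
#'
#' Fits a binomial GLMM of the detection flag on predator species with a
#' random intercept per sampling unit (Laplace approximation via
#' [lme4::glmer()]), the identifiable reading of larvae nested within
#' units for a single Bernoulli response per larva. Returns the
#' logit-scale species contrast, its test, and the unit-level SD.
#'
#' If the mixed model fails, a documented fallback is returned instead:
#' a fixed-effects GLM with cluster-robust (sampling-unit) variance, with
#' `converged = FALSE` and `fallback = TRUE`.
#'
#' @param larvae Tibble in the `field_survey_larvae` schema with exactly
#'   two predator species.
#' @param units Tibble in the `field_survey_units` schema; every larva's
#'   `unit_id` must appear here.
#' @param prey_kind `"aphid"` or `"heterospecific"`.
#' @param test `"wald"` (default) or `"lrt"` for the species-effect
#'   p-value.
#' @return A `glmm_comparison` object.
#' @export
compare_predators_glmm <- function(larvae, units, prey_kind,
                                   test = c("wald", "lrt")) {
  test <- rlang::arg_match(test)
  prey_kind <- rlang::arg_match(prey_kind, prey_kinds())
  larvae <- tibble::as_tibble(larvae)
  if (dplyr::n_distinct(larvae$predator_species) != 2) {
    abort("exactly two predator species are required for the contrast")
  }
  if (dplyr::n_distinct(larvae$unit_id) < 2) {
    abort("at least two sampling units are required")
  }
  orphan <- setdiff(larvae$unit_id, units$unit_id)
  if (length(orphan) > 0) {
    abort(paste0("larvae reference unknown unit_id: ",
                 paste(head(orphan, 3), collapse = ", ")))
  }
  flag <- paste0("detected_", if (prey_kind == "aphid") "aphid" else "heterospecific")
  dat <- tibble::tibble(
    y = as.logical(larvae[[flag]]),
    species = factor(larvae$predator_species),
    unit = factor(larvae$unit_id)
  )
  ref <- levels(dat$species)[1]
  contrast_species <- levels(dat$species)[2]

  fit <- tryCatch(
    suppressMessages(lme4::glmer(
      y ~ species + (1 | unit),
      data = dat, family = binomial(),
      control = lme4::glmerControl(calc.derivs = FALSE)
    )),
    error = function(e) NULL
  )

  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    est <- co[2, "Estimate"]
    se <- co[2, "Std. Error"]
    p <- if (test == "wald") {
      co[2, "Pr(>|z|)"]
    } else {
      reduced <- suppressMessages(lme4::glmer(
        y ~ 1 + (1 | unit),
        data = dat, family = binomial(),
        control = lme4::glmerControl(calc.derivs = FALSE)
      ))
      a <- stats::anova(fit, reduced)
      a[["Pr(>Chisq)"]][2]
    }
    unit_sd <- sqrt(unlist(lme4::VarCorr(fit))[["unit"]])
    out <- list(
      fixed_effect_estimate = unname(est),
      std_error = unname(se),
      statistic = unname(est / se),
      p_value = unname(p),
      unit_sd_estimate = unname(unit_sd),
      converged = TRUE,
      fallback = FALSE
    )
  } else {
    gfit <- suppressWarnings(glm(y ~ species, data = dat, family = binomial()))
    vc <- sandwich::vcovCL(gfit, cluster = dat$unit)
    est <- coef(gfit)[2]
    se <- sqrt(diag(vc))[2]
    out <- list(
      fixed_effect_estimate = unname(est),
      std_error = unname(se),
      statistic = unname(est / se),
      p_value = unname(2 * pnorm(-abs(est / se))),
      unit_sd_estimate = NA_real_,
      converged = FALSE,
      fallback = TRUE
    )
  }
  structure(
    c(out, list(
      reference_species = ref,
      contrast_species = contrast_species,
      prey_kind = prey_kind,
      n_units = dplyr::n_distinct(dat$unit),
      n_obs = nrow(dat),
      test = test
    )),
    class = "glmm_comparison"
  )
}

#' @export
print.glmm_comparison <- function(x, ...) {
  cat("Binomial GLMM comparison (", x$prey_kind, " detection)\n", sep = "")
  cat("  ", x$contrast_species, " vs ", x$reference_species,
      sprintf(": %+.3f (SE %.3f) on the logit scale, P = %.3g (%s)\n",
              x$fixed_effect_estimate, x$std_error, x$p_value, x$test),
      sep = "")
  cat(sprintf("  unit SD = %s over %d units (%d larvae)\n",
              if (is.na(x$unit_sd_estimate)) "NA" else
                sprintf("%.3f", x$unit_sd_estimate),
              x$n_units, x$n_obs))
  if (x$fallback) {
    cat("  FALLBACK: mixed model failed; cluster-robust GLM reported\n")
  }
  invisible(x)
}

#' @rdname compare_predators_glmm
#' @param x A `glmm_comparison`.
#' @param ... Unused.
#' @method tidy glmm_comparison
#' @export
tidy.glmm_comparison <- function(x, ...) {
  tibble::tibble(
    term = paste0("species", x$contrast_species),
    estimate = x$fixed_effect_estimate,
    std.error = x$std_error,
    statistic = x$statistic,
    p.value = x$p_value
  )
}

#' @rdname compare_predators_glmm
#' @method glance glmm_comparison
#' @export
glance.glmm_comparison <- function(x, ...) {
  tibble::tibble(
    prey_kind = x$prey_kind,
    unit_sd_estimate = x$unit_sd_estimate,
    n_units = x$n_units,
    nobs = x$n_obs,
    converged = x$converged,
    fallback = x$fallback
  )
}

#' Digestion-rate correction of an observed detection proportion
#'
#' Greenstone-style detectability correction: the observed proportion is
#' mapped through the focal species' own decay model to the time since
#' feeding at which that proportion is reached
#' (`t* = invert_detect(model_own, p_obs)`), then through the reference
#' species' decay model (`detect_prob(model_ref, t*)`). The result is
#' the proportion the focal species would show if it digested prey DNA
#' at the reference's rate.
#'
#' @param p_obs Observed proportion strictly inside (0, 1) (vectorized).
#' @param model_own Converged `decay_model` of the focal species
#'   detecting the prey.
#' @param model_ref Converged `decay_model` of the reference species.
#' @return Corrected proportion(s) in (0, 1).
#' @export
correct_proportion <- function(p_obs, model_own, model_ref) {
  stopifnot(inherits(model_own, "decay_model"), inherits(model_ref, "decay_model"))
  for (m in list(model_own, model_ref)) {
    if (!m$converged) abort("both decay models must be converged")
    if (is.na(m$beta1) || m$beta1 >= 0) {
      abort("both decay models must have negative slope (beta1 < 0)")
    }
  }
  detect_prob(model_ref, invert_detect(model_own, p_obs))
}

#' Rank predators on raw and detectability-corrected proportions
#'
#' Applies [correct_proportion()] to every non-reference species, mapping
#' its observed proportion onto the reference species' decay model; the
#' reference keeps its raw value. Corrected proportions carry no test
#' statistics by design: they are used only to rank the predators net of
#' digestion-rate differences.
#'
#' Boundary proportions (0 or 1, possible in small synthetic surveys)
#' receive a continuity adjustment of 0.5 successes and 0.5 failures
#' before correction, with a warning.
#'
#' @param summaries Output of [summarize_detection()] for one prey kind.
#' @param decay_models List of converged `decay_model`s (or a
#'   [fit_decay_table()] result) containing, for every species in
#'   `summaries`, that species' model for detecting the relevant prey.
#' @param reference_species Species whose digestion rate is the yardstick.
#' @return A `corrected_ranking` object: a table of raw and corrected
#'   proportions plus `ranking_raw` and `ranking_corrected` (species
#'   ordered by decreasing proportion; ties broken alphabetically).
#' @export
rank_predators <- function(summaries, decay_models, reference_species) {
  summaries <- tibble::as_tibble(summaries)
  stopifnot(all(
    c("predator_species", "prey_kind", "n_screened", "n_positive",
      "proportion") %in% names(summaries)
  ))
  if (dplyr::n_distinct(summaries$prey_kind) != 1) {
    abort("summaries must cover a single prey kind")
  }
  if (is.data.frame(decay_models) && "model" %in% names(decay_models)) {
    decay_models <- decay_models$model
  }
  models <- stats::setNames(
    decay_models,
    purrr::map_chr(decay_models, "predator_species")
  )
  species <- summaries$predator_species
  if (!reference_species %in% species) {
    abort(paste0("reference species '", reference_species,
                 "' not present in summaries"))
  }
  need <- species
  absent <- setdiff(need, names(models))
  if (length(absent) > 0) {
    abort(paste0("missing decay model for species: ",
                 paste(absent, collapse = ", ")))
  }

  corrected <- purrr::pmap_dbl(
    summaries[, c("predator_species", "prey_kind", "n_screened",
                  "n_positive", "proportion")],
    function(predator_species, prey_kind, n_screened, n_positive, proportion) {
      if (predator_species == reference_species) return(proportion)
      p <- proportion
      if (p <= 0 || p >= 1) {
        warn(paste0(
          "boundary proportion for ", predator_species,
          "; continuity adjustment (x + 0.5) / (n + 1) applied"
        ))
        p <- (n_positive + 0.5) / (n_screened + 1)
      }
      correct_proportion(p, models[[predator_species]],
                         models[[reference_species]])
    }
  )

  tbl <- dplyr::mutate(
    dplyr::rename(summaries, proportion_raw = "proportion"),
    proportion_corrected = corrected
  )
  rank_by <- function(p) {
    tbl$predator_species[order(-p, tbl$predator_species)]
  }
  structure(
    list(
      table = tbl,
      reference_species = reference_species,
      prey_kind = summaries$prey_kind[1],
      ranking_raw = rank_by(tbl$proportion_raw),
      ranking_corrected = rank_by(tbl$proportion_corrected)
    ),
    class = "corrected_ranking"
  )
}

#' @export
print.corrected_ranking <- function(x, ...) {
  cat("Detectability-corrected ranking (", x$prey_kind,
      " detection; reference: ", x$reference_species, ")\n", sep = "")
  tbl <- x$table
  for (i in seq_len(nrow(tbl))) {
    cat(sprintf("  %-22s raw %5.1f%%  corrected %5.1f%%\n",
                tbl$predator_species[i],
                100 * tbl$proportion_raw[i],
                100 * tbl$proportion_corrected[i]))
  }
  cat("  ranking (raw):      ", paste(x$ranking_raw, collapse = " > "), "\n")
  cat("  ranking (corrected):", paste(x$ranking_corrected, collapse = " > "), "\n")
  invisible(x)
}

#' @rdname rank_predators
#' @param x A `corrected_ranking`.
#' @param ... Unused.
#' @method tidy corrected_ranking
#' @export
tidy.corrected_ranking <- function(x, ...) {
  x$table
}

#' Plot raw versus corrected detection proportions
#'
#' @param object A `corrected_ranking`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot corrected_ranking
#' @export
autoplot.corrected_ranking <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$table,
    cols = c("proportion_raw", "proportion_corrected"),
    names_to = "kind", values_to = "proportion"
  )
  long$kind <- factor(long$kind, levels = c("proportion_raw", "proportion_corrected"),
                      labels = c("raw", "corrected"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$predator_species, y = .data$proportion, fill = .data$kind
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Detection proportion", fill = NULL,
      title = paste0("Detection of ", object$prey_kind, " prey"),
      subtitle = paste0("corrected onto ", object$reference_species,
                        "'s digestion rate")
    ) +
    ggplot2::theme_minimal()
}
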