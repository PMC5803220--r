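#' Fit a prey-DNA detectability decay model
#'
#' Maximum-likelihood logistic regression of detection (positive PCR) on
#' hours post feeding for a single predator-prey pair:
#' `logit P(detected) = beta0 + beta1 * t`. The half-detectability time
#' is `T50 = -beta0 / beta1`, the time at which prey DNA is detectable in
#' half of the fed predators.
#'
#' Fits with any coefficient exceeding 15 in absolute value on the logit
#' scale, a single outcome value in the data, or an IRLS failure are
#' flagged as non-converged (a practical detector of complete separation
#' in small feeding trials); such fits carry `NA` coefficients and a
#' diagnostic rather than silently unstable estimates.
#'
#' @param records Feeding-trial tibble (schema `feeding_trial`) for one
#'   predator-prey pair with at least two distinct time points.
#' @return A `decay_model` object with fields `predator_species`,
#'   `prey_species`, `beta0`, `beta1`, `vcov`, `n_obs`, `loglik`, `t50`,
#'   `converged`, `t50_defined` and an observed-proportion summary used
#'   by [autoplot.decay_model()].
#' @seealso [detect_prob()], [invert_detect()], [compare_decay_lrt()]
#' @export
fit_decay <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("predator_species", "prey_species", "hours_post_feeding", "detected")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("records lack column(s): ", paste(missing, collapse = ", ")))
  }
  pair <- dplyr::distinct(records, .data$predator_species, .data$prey_species)
  if (nrow(pair) != 1) {
    abort("records must cover exactly one predator-prey pair; got several")
  }
  if (any(records$hours_post_feeding < 0)) {
    abort("hours_post_feeding must be >= 0")
  }
  if (dplyr::n_distinct(records$hours_post_feeding) < 2) {
    abort("need at least two distinct time points to fit a decay model")
  }
  det <- as.logical(records$detected)
  one_outcome <- dplyr::n_distinct(det) < 2

  fit <- suppressWarnings(glm(
    det ~ hours_post_feeding,
    family = binomial(), data = records
  ))
  co <- unname(coef(fit))
  separated <- one_outcome || !fit$converged || any(abs(co) > 15)
  converged <- !separated
  diagnostic <- NULL
  if (one_outcome) {
    diagnostic <- "all outcomes identical (complete separation)"
  } else if (!fit$converged) {
    diagnostic <- "IRLS did not converge"
  } else if (any(abs(co) > 15)) {
    diagnostic <- "coefficient beyond 15 on the logit scale (quasi-separation)"
  }

  beta0 <- if (converged) co[1] else NA_real_
  beta1 <- if (converged) co[2] else NA_real_
  t50_defined <- converged && !is.na(beta1) && beta1 < 0 && abs(beta1) > 1e-6
  t50 <- if (t50_defined) -beta0 / beta1 else NA_real_
  if (t50_defined && t50 > max(records$hours_post_feeding)) {
    warn(paste0(
      "T50 (", round(t50, 2), " h) lies beyond the observed time range (",
      max(records$hours_post_feeding), " h); extrapolated"
    ))
  }
  if (converged && beta1 >= 0) {
    warn("fitted slope is non-negative; detectability does not decay, T50 undefined")
  }

  obs <- dplyr::summarise(
    dplyr::group_by(records, hours = .data$hours_post_feeding),
    n = dplyr::n(), n_pos = sum(as.logical(.data$detected)), .groups = "drop"
  )

  structure(
    list(
      predator_species = pair$predator_species,
      prey_species = pair$prey_species,
      beta0 = beta0,
      beta1 = beta1,
      vcov = if (converged) unname(vcov(fit)) else matrix(NA_real_, 2, 2),
      n_obs = nrow(records),
      loglik = as.numeric(logLik(fit)),
      t50 = t50,
      t50_defined = t50_defined,
      converged = converged,
      diagnostic = diagnostic,
      observed = obs
    ),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat("Decay model: ", x$predator_species, " detecting ", x$prey_species,
      "\n", sep = "")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf("  logit p(t) = %.4f %+.5f * t   (n = %d)\n",
              x$beta0, x$beta1, x$n_obs))
  if (x$t50_defined) {
    cat(sprintf("  T50 = %.2f h\n", x$t50))
  } else {
    cat("  T50 undefined (non-decaying fit)\n")
  }
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_model`.
#' @param ... Unused.
#' @method tidy decay_model
#' @export
tidy.decay_model <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- c(x$beta0, x$beta1)
  tibble::tibble(
    term = c("(Intercept)", "hours_post_feeding"),
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * pnorm(-abs(est / se))
  )
}

#' @rdname fit_decay
#' @method glance decay_model
#' @export
glance.decay_model <- function(x, ...) {
  ci <- t50_ci(x)
  tibble::tibble(
    predator_species = x$predator_species,
    prey_species = x$prey_species,
    nobs = x$n_obs,
    logLik = x$loglik,
    t50 = x$t50,
    t50_low = ci[1],
    t50_high = ci[2],
    converged = x$converged
  )
}

#' Delta-method confidence interval for T50
#'
#' Propagates the coefficient covariance through `T50 = -beta0/beta1`
#' (gradient `(-1/beta1, beta0/beta1^2)`). Reported as an extra
#' diagnostic; T50 point estimates are the primary output.
#'
#' @param model A converged `decay_model`.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`, `NA` if T50 is undefined.
#' @export
t50_ci <- function(model, level = 0.95) {
  stopifnot(inherits(model, "decay_model"))
  if (!isTRUE(model$t50_defined)) return(c(NA_real_, NA_real_))
  grad <- c(-1 / model$beta1, model$beta0 / model$beta1^2)
  se <- sqrt(drop(t(grad) %*% model$vcov %*% grad))
  z <- stats::qnorm(1 - (1 - level) / 2)
  model$t50 + c(-1, 1) * z * se
}

#' Detection probability at a given time post feeding
#'
#' Evaluates the fitted decay curve `plogis(beta0 + beta1 * t)`. Strictly
#' decreasing in `t` when `beta1 < 0`. Negative `t` is allowed for
#' extrapolation by the detectability correction.
#'
#' @param model A converged `decay_model`.
#' @param t Hours post feeding (vectorized).
#' @return Detection probabilities.
#' @export
detect_prob <- function(model, t) {
  stopifnot(inherits(model, "decay_model"))
  if (!model$converged) {
    abort("decay model did not converge; no detection probabilities available")
  }
  plogis(model$beta0 + model$beta1 * t)
}

#' Time post feeding at which a detection proportion is reached
#'
#' Solves the fitted decay model for time: `t = (qlogis(p) - beta0) /
#' beta1`, the inverse of [detect_prob()]. This is the first step of the
#' digestion-rate correction: the observed field proportion is mapped to
#' the time since feeding at which the trial curve reaches it.
#'
#' @param model A converged `decay_model` with non-zero slope.
#' @param p Detection proportion strictly inside (0, 1) (vectorized).
#' @return Hours post feeding (may be negative: extrapolation above the
#'   curve's intercept).
#' @export
invert_detect <- function(model, p) {
  stopifnot(inherits(model, "decay_model"))
  if (!model$converged) abort("decay model did not converge")
  if (any(p <= 0 | p >= 1)) {
    abort("p must lie strictly inside (0, 1): logit undefined at 0 and 1")
  }
  if (is.na(model$beta1) || model$beta1 == 0) {
    abort("slope is zero; the decay curve cannot be inverted")
  }
  (qlogis(p) - model$beta0) / model$beta1
}

#' Compare detectability between two predators by likelihood-ratio test
#'
#' Pools the two feeding-trial collections and compares the full model
#' `detected ~ hours * predator` against the reduced `detected ~ hours`
#' by a chi-square LRT with 2 degrees of freedom, testing jointly for a
#' level and a rate difference between the predators' decay curves.
#'
#' @param records_a,records_b Feeding-trial tibbles, one predator each.
#' @param check_prey If `TRUE` (default) both collections must share one
#'   prey species. Set `FALSE` to compare detectability of each
#'   predator's respective heterospecific prey, where the prey labels
#'   necessarily differ.
#' @return A `decay_lrt` object with `statistic`, `df`, `p_value` and a
#'   `reliable` flag (FALSE when the full fit shows separation).
#' @export
compare_decay_lrt <- function(records_a, records_b, check_prey = TRUE) {
  records_a <- tibble::as_tibble(records_a)
  records_b <- tibble::as_tibble(records_b)
  pred_a <- unique(records_a$predator_species)
  pred_b <- unique(records_b$predator_species)
  if (length(pred_a) != 1 || length(pred_b) != 1 || pred_a == pred_b) {
    abort("each collection must hold one predator, and the two must differ")
  }
  if (check_prey) {
    prey <- unique(c(records_a$prey_species, records_b$prey_species))
    if (length(prey) != 1) {
      abort(paste0(
        "collections must share one prey species (got ",
        paste(prey, collapse = ", "),
        "); use check_prey = FALSE for cross-prey comparisons"
      ))
    }
  }
  pooled <- dplyr::bind_rows(records_a, records_b)
  pooled$detected <- as.logical(pooled$detected)
  pooled$predator_species <- factor(pooled$predator_species)

  full <- suppressWarnings(glm(
    detected ~ hours_post_feeding * predator_species,
    family = binomial(), data = pooled
  ))
  reduced <- suppressWarnings(glm(
    detected ~ hours_post_feeding,
    family = binomial(), data = pooled
  ))
  statistic <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  df <- 2L
  reliable <- full$converged && all(abs(coef(full)) <= 15)
  structure(
    list(
      statistic = statistic,
      df = df,
      p_value = pchisq(statistic, df = df, lower.tail = FALSE),
      reliable = reliable,
      predators = c(pred_a, pred_b)
    ),
    class = "decay_lrt"
  )
}

#' @export
print.decay_lrt <- function(x, ...) {
  cat("Likelihood-ratio test of detectability: ",
      paste(x$predators, collapse = " vs "), "\n", sep = "")
  cat(sprintf("  chi-square = %.3f, df = %d, P = %.3g\n",
              x$statistic, x$df, x$p_value))
  if (!x$reliable) cat("  (unreliable: separation in the full fit)\n")
  invisible(x)
}

#' @rdname compare_decay_lrt
#' @param x A `decay_lrt`.
#' @param ... Unused.
#' @method tidy decay_lrt
#' @export
tidy.decay_lrt <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p_value,
    reliable = x$reliable
  )
}

#' Fit decay models for every predator-prey pair in a dataset
#'
#' @param records Feeding-trial tibble covering one or more pairs.
#' @return Tibble with one row per pair: glance columns plus a `model`
#'   list-column of `decay_model` objects.
#' @export
fit_decay_table <- function(records) {
  records <- tibble::as_tibble(records)
  groups <- dplyr::group_split(
    records, .data$predator_species, .data$prey_species
  )
  models <- purrr::map(groups, fit_decay)
  out <- purrr::map_dfr(models, glance)
  out$model <- models
  out
}

#' Plot a fitted decay curve with observed proportions
#'
#' @param object A converged `decay_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decay_model
#' @export
autoplot.decay_model <- function(object, ...) {
  stopifnot(object$converged)
  grid <- tibble::tibble(
    hours = seq(0, max(object$observed$hours), length.out = 200)
  )
  grid$p <- detect_prob(object, grid$hours)
  obs <- dplyr::mutate(object$observed, p = .data$n_pos / .data$n)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$hours, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "Hours post feeding", y = "Detection probability",
      title = paste0(object$predator_species, " detecting ",
                     object$prey_species),
      subtitle = if (object$t50_defined) {
        sprintf("T50 = %.2f h", object$t50)
      } else {
        "T50 undefined"
      }
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
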