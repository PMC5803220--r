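# Independent oracles: none of these call the package code paths they
# are used to check.

# Expected positive count under the two-part model, by numerical
# quadrature over the feeding-time window:
#   E[count] = sum_i sum_c w_c * plogis(alpha_c + gamma_c * d_i)
#              * (1/W) * integral_0^W plogis(b0 + b1 * tau) dtau
quad_expected_count <- function(alpha, gamma, weights, densities, b0, b1, W) {
  det_mean <- stats::integrate(
    function(tau) stats::plogis(b0 + b1 * tau), 0, W
  )$value / W
  p_pred <- vapply(densities, function(d) {
    sum(weights * stats::plogis(alpha + gamma * d))
  }, numeric(1))
  sum(p_pred) * det_mean
}

# Per-larva positive probability under the two-part model (same algebra,
# no count sum); used to generate "field truth" in power scenarios.
quad_positive_prob <- function(alpha, gamma, weights, densities, b0, b1, W) {
  det_mean <- stats::integrate(
    function(tau) stats::plogis(b0 + b1 * tau), 0, W
  )$value / W
  vapply(densities, function(d) {
    sum(weights * stats::plogis(alpha + gamma * d)) * det_mean
  }, numeric(1))
}

# Brute-force logistic log-likelihood maximization (Nelder-Mead on the
# hand-written likelihood), independent of glm's IRLS.
brute_logistic_loglik <- function(t, y) {
  nll <- function(par) {
    eta <- par[1] + par[2] * t
    -sum(y * stats::plogis(eta, log.p = TRUE) +
           (1 - y) * stats::plogis(-eta, log.p = TRUE))
  }
  opt <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  -opt$value
}

# Naive string-scan amplicon search (exact matching only): slide both
# primers over the template and enumerate inclusive product lengths.
brute_amplicons <- function(template, forward, reverse) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  find_sites <- function(needle) {
    n <- nchar(needle)
    hits <- integer()
    for (i in seq_len(nchar(template) - n + 1)) {
      if (substr(template, i, i + n - 1) == needle) hits <- c(hits, i)
    }
    hits
  }
  f_sites <- find_sites(forward)
  r_sites <- find_sites(revcomp(reverse))
  lens <- integer()
  for (fs in f_sites) {
    for (rs in r_sites) {
      if (rs >= fs + nchar(forward)) {
        lens <- c(lens, rs + nchar(reverse) - fs)
      }
    }
  }
  sort(lens)
}

# Directly-constructed decay model (fields documented in fit_decay),
# for certainty/degenerate cases where a fitted model cannot reach the
# required probabilities exactly.
make_decay <- function(beta0, beta1, predator = "A", prey = "B") {
  structure(
    list(
      predator_species = predator, prey_species = prey,
      beta0 = beta0, beta1 = beta1,
      vcov = diag(1e-6, 2), n_obs = 0L, loglik = NA_real_,
      t50 = -beta0 / beta1, t50_defined = beta1 < 0,
      converged = TRUE, diagnostic = NULL,
      observed = tibble::tibble(hours = c(0, 24), n = 0L, n_pos = 0L)
    ),
    class = "decay_model"
  )
}

# Hand-built stage-model table (columns as documented in
# fit_stage_models).
make_stage_models <- function(species, alpha, gamma) {
  tibble::tibble(
    ig_predator_species = species,
    prey_stage_class = c("immobile", "small_larvae", "similar_larvae"),
    alpha = rep_len(alpha, 3),
    gamma = rep_len(gamma, 3),
    alpha_se = NA_real_, gamma_se = NA_real_,
    n_obs = 0L, converged = TRUE
  )
}
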