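#' Simulate study-level trial effects
#'
#' Generates study-level log relative risks with the hierarchical structure
#' the random-effects meta-analysis assumes: per study, a within-study
#' standard error drawn uniformly on `[se_low, se_high]`, a true study
#' effect drawn from `Normal(true_log_rr, tau2)`, and an observed effect
#' drawn around the true one with the study's se. Stands in for the
#' unpublished study-level data behind the pooled FeNO effect.
#'
#' @param k Number of studies (default 8).
#' @param true_log_rr True pooled log relative risk (default `log(0.76)`).
#' @param tau2 Between-study variance (>= 0).
#' @param se_low,se_high Bounds for the within-study standard errors; the
#'   defaults straddle the scale implied by the published pooled interval.
#' @param seed Optional seed; the same seed reproduces the same studies.
#' @return A tibble with columns `label`, `log_rr`, `se`, ready for
#'   [dl_pool()].
#' @examples
#' simulate_trials(k = 8, seed = 7)
#' @export
simulate_trials <- function(k = 8, true_log_rr = log(0.76), tau2 = 0.01,
                            se_low = 0.15, se_high = 0.35, seed = NULL) {
  if (k < 1) abort("k must be >= 1.")
  if (tau2 < 0) abort("tau2 must be >= 0.")
  if (se_low <= 0 || se_low > se_high) abort("need 0 < se_low <= se_high.")
  with_seed(seed, {
    se <- runif(k, se_low, se_high)
    theta <- rnorm(k, true_log_rr, sqrt(tau2))
    y <- rnorm(k, theta, se)
    tibble::tibble(label = sprintf("trial_%02d", seq_len(k)),
                   log_rr = y, se = se)
  })
}

#' Randomly perturb a configuration
#'
#' Applies an independent relative `Normal(0, scale)` shock to every cost
#' mean, utility, off-diagonal transition probability and the pooled relative
#' risk, re-projecting each transition row onto the simplex through its stay
#' probability and truncating probabilities to their domain. `scale = 0`
#' returns the configuration unchanged. Used for robustness experiments:
#' conclusions should survive moderate perturbation of all inputs.
#'
#' @param config A `feno_config`.
#' @param scale Relative shock standard deviation (>= 0).
#' @param seed Optional seed.
#' @return A valid perturbed `feno_config`.
#' @export
perturb_config <- function(config, scale = 0.05, seed = NULL) {
  if (scale < 0) abort("scale must be >= 0.")
  if (scale == 0) return(config)
  with_seed(seed, {
    jitter <- function(x) x * (1 + rnorm(length(x), 0, scale))
    config$costs$mean <- pmax(0, jitter(config$costs$mean))
    # keep means strictly positive for the gamma family
    config$costs$mean <- pmax(config$costs$mean, 1e-6)
    # widen any one-way range the shocked mean has left
    config$costs$sa_low <- pmin(config$costs$sa_low, config$costs$mean)
    config$costs$sa_high <- pmax(config$costs$sa_high, config$costs$mean)
    for (s in STATES) {
      config$utilities[[s]] <- min(1 - 1e-9, max(1e-9, jitter(config$utilities[[s]])))
    }
    for (from in STATES) {
      row <- config$transitions[from, ]
      off <- setdiff(STATES, from)
      row[off] <- pmin(1, pmax(0, jitter(row[off])))
      if (sum(row[off]) >= 1) row[off] <- row[off] / (sum(row[off]) + 1e-9)
      row[from] <- 1 - sum(row[off])
      config$transitions[from, ] <- row
    }
    rr <- max(1e-9, jitter(config$effect$rr))
    config$effect$rr <- rr
    config$effect$ci_low <- min(config$effect$ci_low, rr)
    config$effect$ci_high <- max(config$effect$ci_high, rr)
    config$strategies$rr_exacerbation[config$strategies$uses_effect_rr] <- rr
  })
  # perturbed probabilities can leave a reported sd infeasible for the beta
  # bound; shrink the sd to stay inside it rather than fail
  for (from in STATES) for (to in setdiff(STATES, from)) {
    sd <- config$transition_sd[from, to]
    if (is.na(sd)) next
    m <- config$transitions[from, to]
    bound <- sqrt(m * (1 - m))
    if (sd >= bound) config$transition_sd[from, to] <- 0.99 * bound
  }
  for (s in STATES) {
    bound <- sqrt(config$utilities[[s]] * (1 - config$utilities[[s]]))
    if (config$utility_sd[[s]] >= bound) config$utility_sd[[s]] <- 0.99 * bound
  }
  validate_config(config)
  config
}
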