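#' Moment-matched beta parameters
#'
#' Converts a (mean, sd) pair into beta shape parameters by the method of
#' moments, as used to draw utilities and probabilities in the probabilistic
#' sensitivity analysis. The variance must respect the Bernoulli bound
#' `sd^2 < mean * (1 - mean)`; an infeasible pair is an error, never a silent
#' clamp.
#'
#' @param mean Mean(s) in (0, 1).
#' @param sd Standard deviation(s), > 0.
#' @return A tibble with columns `shape1`, `shape2`.
#' @examples
#' beta_from_mean_sd(0.097, 0.029)
#' @export
beta_from_mean_sd <- function(mean, sd) {
  stopifnot(length(mean) == length(sd))
  if (any(mean <= 0 | mean >= 1)) {
    abort("beta mean must lie strictly in (0, 1).")
  }
  if (any(sd <= 0)) abort("beta sd must be > 0.")
  if (any(sd^2 >= mean * (1 - mean))) {
    abort("infeasible beta variance: sd^2 must be < mean * (1 - mean).")
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  tibble::tibble(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Moment-matched gamma parameters
#'
#' Converts a (mean, sd) pair into gamma shape/scale by the method of moments,
#' as used to draw costs. A zero sd is flagged as a degenerate point mass
#' rather than an error, so fixed costs pass through sampling unchanged.
#'
#' @param mean Mean(s), > 0.
#' @param sd Standard deviation(s), >= 0.
#' @return A tibble with columns `shape`, `scale`, `degenerate`.
#' @examples
#' gamma_from_mean_sd(95.05, 8.53)
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  stopifnot(length(mean) == length(sd))
  if (any(mean <= 0)) abort("gamma mean must be > 0.")
  if (any(sd < 0)) abort("gamma sd must be >= 0.")
  degenerate <- sd == 0
  shape <- ifelse(degenerate, Inf, (mean / sd)^2)
  scale <- ifelse(degenerate, 0, sd^2 / mean)
  tibble::tibble(shape = shape, scale = scale, degenerate = degenerate)
}

#' Lognormal parameters from a point estimate and confidence interval
#'
#' Recovers the log-scale mean and standard deviation of a relative risk
#' reported as a point estimate with a symmetric-on-the-log-scale confidence
#' interval: `meanlog = log(point)`, `sdlog = log(high/low) / (2 z)`. The
#' sampled distribution's median equals the point estimate.
#'
#' @param point Point estimate (ratio scale), > 0.
#' @param ci_low,ci_high Confidence bounds, `0 < ci_low <= point <= ci_high`.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `meanlog`, `sdlog`.
#' @examples
#' lognormal_from_ci(0.76, 0.63, 0.92)
#' @export
lognormal_from_ci <- function(point, ci_low, ci_high, level = 0.95) {
  if (any(ci_low <= 0) || any(point <= 0)) abort("bounds must be positive.")
  if (any(ci_low > point | point > ci_high)) {
    abort("need ci_low <= point <= ci_high.")
  }
  if (any(ci_low > ci_high)) abort("ci_low must be <= ci_high.")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1).")
  z <- qnorm((1 + level) / 2)
  tibble::tibble(meanlog = log(point), sdlog = log(ci_high / ci_low) / (2 * z))
}

#' Dirichlet concentration for a transition-matrix row
#'
#' Builds the concentration vector of a Dirichlet distribution whose mean is
#' the given row of transition probabilities. The effective sample size is
#' solved from the marginal-beta variance of one reference component (the
#' transition whose standard deviation is reported): `n = m(1-m)/s^2 - 1`,
#' then `concentration = n * means`. Each marginal mean equals the input
#' mean; only the reference component's marginal sd is matched exactly.
#'
#' @param means Probability vector summing to 1.
#' @param reference_sd Reported sd of the reference component, > 0.
#' @param reference_index 1-based index of the reference component.
#' @return Numeric concentration vector (same names as `means`).
#' @examples
#' dirichlet_from_row(c(0.899, 0.097, 0.004), 0.029, 2)
#' @export
dirichlet_from_row <- function(means, reference_sd, reference_index) {
  if (abs(sum(means) - 1) > 1e-9) {
    abort("`means` must sum to 1 (tolerance 1e-9).")
  }
  if (any(means < 0)) abort("`means` must be non-negative.")
  if (reference_index < 1 || reference_index > length(means)) {
    abort("`reference_index` out of range.")
  }
  m <- means[[reference_index]]
  if (m <= 0 || m >= 1) abort("reference component must lie strictly in (0, 1).")
  if (reference_sd <= 0 || reference_sd^2 >= m * (1 - m)) {
    abort("infeasible reference variance for the Dirichlet row.")
  }
  n <- m * (1 - m) / reference_sd^2 - 1
  n * means
}

#' Draw from a Dirichlet distribution
#'
#' @param n Number of draws.
#' @param alpha Concentration vector (all > 0).
#' @return An `n x length(alpha)` matrix; rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) abort("Dirichlet concentration must be positive.")
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1), nrow = n)
  # guard against underflow to an all-zero row at very small concentrations
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, which.max(alpha)] <- 1
  sweep(x, 1, rowSums(x), "/")
}

#' Build a parameter specification
#'
#' A parameter is a named (mean, sd) pair with a sampling family and an
#' optional one-way sensitivity range. Families: `"beta"` (probabilities and
#' utilities), `"gamma"` (costs), `"lognormal"` (relative risks; `sd` is the
#' log-scale sd), `"fixed"`.
#'
#' @param name Identifier.
#' @param mean Base-case value.
#' @param sd Standard deviation (>= 0; 0 means fixed at the mean).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param sa_low,sa_high Optional one-way sensitivity bounds with
#'   `sa_low <= mean <= sa_high`.
#' @return A one-row tibble.
#' @export
param_spec <- function(name, mean, sd, family = "gamma",
                       sa_low = NA_real_, sa_high = NA_real_) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "fixed"))
  if (sd < 0) abort(sprintf("'%s': sd must be >= 0.", name))
  if (family == "beta" && sd > 0) beta_from_mean_sd(mean, sd)  # validates
  if (family == "gamma" && mean <= 0) abort(sprintf("'%s': gamma mean must be > 0.", name))
  if (!is.na(sa_low) && !is.na(sa_high) && !(sa_low <= mean && mean <= sa_high)) {
    abort(sprintf("'%s': need sa_low <= mean <= sa_high.", name))
  }
  tibble::tibble(name = name, mean = mean, sd = sd, family = family,
                 sa_low = sa_low, sa_high = sa_high)
}

#' Sample from a parameter specification
#'
#' Draws from the moment-matched distribution implied by a parameter's
#' (mean, sd, family). A zero sd always returns the mean. Draws use the
#' current R random number stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param spec A one-row data frame as returned by [param_spec()] (or any list
#'   with `mean`, `sd`, `family`).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_param <- function(spec, n = 1) {
  mean <- spec$mean[[1]]; sd <- spec$sd[[1]]; family <- spec$family[[1]]
  if (sd == 0 || family == "fixed") return(rep(mean, n))
  switch(family,
    beta = {
      p <- beta_from_mean_sd(mean, sd)
      rbeta(n, p$shape1, p$shape2)
    },
    gamma = {
      p <- gamma_from_mean_sd(mean, sd)
      rgamma(n, shape = p$shape, scale = p$scale)
    },
    lognormal = rlnorm(n, meanlog = log(mean), sdlog = sd),
    abort(sprintf("unknown distribution family '%s'.", family))
  )
}
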