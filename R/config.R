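#' Build a weekly transition matrix from its off-diagonal entries
#'
#' The model has three non-absorbing states: well-controlled (`W`),
#' suboptimal control without exacerbation (`S`) and asthma exacerbation
#' (`A`). The six transition probabilities between distinct states are
#' supplied; each diagonal (stay) probability is the row complement.
#'
#' @param w_s,w_a,s_w,s_a,a_w,a_s Weekly transition probabilities.
#' @return A 3x3 row-stochastic matrix with dimnames `W`, `S`, `A`.
#' @examples
#' transition_matrix(0.097, 0.004, 0.817, 0.007, 0.271, 0.052)
#' @export
transition_matrix <- function(w_s, w_a, s_w, s_a, a_w, a_s) {
  p <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  p["W", "S"] <- w_s; p["W", "A"] <- w_a
  p["S", "W"] <- s_w; p["S", "A"] <- s_a
  p["A", "W"] <- a_w; p["A", "S"] <- a_s
  diag(p) <- 1 - rowSums(p)
  validate_transition_matrix(p)
  p
}

validate_transition_matrix <- function(p) {
  if (!is.matrix(p) || !all(dim(p) == c(3, 3))) {
    abort("transition matrix must be 3x3.")
  }
  assert_prob(as.vector(p), "transition probabilities")
  if (any(abs(rowSums(p) - 1) > 1e-12)) {
    abort("transition matrix rows must sum to 1 (tolerance 1e-12).")
  }
  invisible(p)
}

#' Define a treatment strategy
#'
#' A strategy is a relative-risk modifier on the transitions into the
#' exacerbation state plus an add-on per-cycle monitoring cost. Standard
#' therapy has modifier 1 and no add-on; the FeNO-guided arm applies the
#' pooled relative risk and pays for monitoring.
#'
#' @param name Strategy label.
#' @param rr_exacerbation Relative risk applied to the exacerbation-entry
#'   transitions (>= 0; 1 leaves the matrix unchanged).
#' @param addon_cost_per_cycle Add-on cost per weekly cycle, US$ (>= 0).
#' @param uses_effect_rr If `TRUE`, probabilistic analysis replaces
#'   `rr_exacerbation` with a draw from the pooled-effect distribution.
#' @param addon_component Optional cost-component name whose sampled value
#'   rescales the add-on in probabilistic analysis.
#' @return A one-row tibble.
#' @export
strategy_spec <- function(name, rr_exacerbation = 1, addon_cost_per_cycle = 0,
                          uses_effect_rr = FALSE, addon_component = NA_character_) {
  if (rr_exacerbation < 0) abort("rr_exacerbation must be >= 0.")
  if (addon_cost_per_cycle < 0) abort("addon_cost_per_cycle must be >= 0.")
  tibble::tibble(name = name, rr_exacerbation = rr_exacerbation,
                 addon_cost_per_cycle = addon_cost_per_cycle,
                 uses_effect_rr = uses_effect_rr,
                 addon_component = addon_component)
}

#' Default per-state cost recipe
#'
#' How the per-cycle cost of each health state is assembled from the cost
#' components: `W` carries a week of maintenance drugs; `S` adds a specialist
#' referral and a week of caregiver productivity loss; `A` carries an
#' emergency-department day plus a week of ward stay, all direct medical
#' per-patient-day items and productivity loss, with an optional PICU term
#' weighted by an admission fraction `p_picu` (0 by default). `calibration`
#' scales each state's assembled cost; `overrides` replaces it outright.
#'
#' @param p_picu Fraction of exacerbation weeks incurring PICU daily costs.
#' @param calibration Named multiplier per state (default all 1).
#' @param overrides Named per-state weekly cost overriding the recipe (NA =
#'   use the recipe).
#' @return A list with elements `p_picu`, `calibration`, `overrides`.
#' @export
cost_recipe <- function(p_picu = 0,
                        calibration = c(W = 1, S = 1, A = 1),
                        overrides = c(W = NA_real_, S = NA_real_, A = NA_real_)) {
  stopifnot(p_picu >= 0, p_picu <= 1)
  calibration <- calibration[STATES]
  overrides <- overrides[STATES]
  names(calibration) <- names(overrides) <- STATES
  if (any(is.na(calibration)) || any(calibration < 0)) {
    abort("calibration factors must be non-negative and given for W, S, A.")
  }
  list(p_picu = p_picu, calibration = calibration, overrides = overrides)
}

#' Assemble a full model configuration
#'
#' Bundles every model input: the weekly transition matrix with the reported
#' per-transition standard deviations, per-state utilities, the cost
#' component table, the pooled FeNO effect, the strategy list and run
#' settings (cycles, willingness to pay, PSA iterations, seed). All
#' invariants are checked at construction.
#'
#' @param transitions 3x3 row-stochastic matrix ([transition_matrix()]).
#' @param transition_sd 3x3 matrix of reported sds for the off-diagonal
#'   transitions (diagonal ignored).
#' @param utilities Named per-state utilities in `[0, 1]` (`W`, `S`, `A`).
#' @param utility_sd Named per-state utility sds.
#' @param costs Tibble of cost components ([param_spec()] rows, US$).
#' @param effect List with `rr`, `ci_low`, `ci_high`, `table_sd`,
#'   optionally `use_table_sd` (default `FALSE`: sample on the log scale with
#'   the CI-derived sd) and `level`.
#' @param strategies Tibble of [strategy_spec()] rows.
#' @param n_cycles Number of weekly cycles (default 52, a 12-month horizon).
#' @param cycle_length_years Cycle length in years (default 1/52).
#' @param wtp Willingness to pay, US$ per QALY (default 20000).
#' @param psa_iterations Monte Carlo iterations for the PSA (default 1000).
#' @param seed Master seed for all stochastic stages.
#' @param population_for_pevpi Optional population size scaling the expected
#'   value of perfect information; `NULL` disables the population figure.
#' @param half_cycle_correction Apply trapezoidal half-cycle weighting
#'   (default `FALSE`).
#' @param rr_targets Transitions the relative risk applies to (default both
#'   entries into the exacerbation state).
#' @param recipe Per-state cost recipe ([cost_recipe()]).
#' @param init Initial state distribution (default: whole cohort
#'   well-controlled).
#' @param dirichlet_reference Named character: for each row, the destination
#'   state of the transition whose reported sd anchors the Dirichlet
#'   effective sample size.
#' @return An object of class `feno_config`.
#' @seealso [paper_fixture()] for the published baseline.
#' @export
feno_config <- function(transitions, transition_sd, utilities, utility_sd,
                        costs, effect, strategies,
                        n_cycles = 52L, cycle_length_years = 1 / 52,
                        wtp = 20000, psa_iterations = 1000L, seed = 1L,
                        population_for_pevpi = NULL,
                        half_cycle_correction = FALSE,
                        rr_targets = c("W->A", "S->A"),
                        recipe = cost_recipe(),
                        init = c(W = 1, S = 0, A = 0),
                        dirichlet_reference = c(W = "S", S = "W", A = "W")) {
  effect$use_table_sd <- effect$use_table_sd %||% FALSE
  effect$level <- effect$level %||% 0.95
  effect$sigma_log <- lognormal_from_ci(effect$rr, effect$ci_low, effect$ci_high,
                                        effect$level)$sdlog
  cfg <- structure(list(
    transitions = transitions, transition_sd = transition_sd,
    utilities = utilities[STATES], utility_sd = utility_sd[STATES],
    costs = costs, effect = effect, strategies = strategies,
    n_cycles = as.integer(n_cycles), cycle_length_years = cycle_length_years,
    wtp = wtp, psa_iterations = as.integer(psa_iterations),
    seed = as.integer(seed), population_for_pevpi = population_for_pevpi,
    half_cycle_correction = half_cycle_correction,
    rr_targets = rr_targets, recipe = recipe, init = init[STATES],
    dirichlet_reference = dirichlet_reference
  ), class = "feno_config")
  validate_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every structural invariant: row-stochastic transitions, utilities
#' and initial distribution on their domains, non-negative costs, feasible
#' beta variances for all probability parameters, coherent one-way
#' sensitivity ranges and run settings.
#'
#' @param config A `feno_config`.
#' @return The config, invisibly unchanged, or an error naming the offending
#'   field.
#' @export
validate_config <- function(config) {
  validate_transition_matrix(config$transitions)
  assert_prob(config$utilities, "utilities")
  assert_prob(config$init, "initial distribution")
  if (abs(sum(config$init) - 1) > 1e-9) abort("initial distribution must sum to 1.")
  if (anyNA(config$utilities)) abort("utilities must be named W, S, A.")
  if (any(config$costs$mean < 0) || any(config$costs$sd < 0)) {
    abort("cost means and sds must be >= 0.")
  }
  bad_range <- !is.na(config$costs$sa_low) & !is.na(config$costs$sa_high) &
    !(config$costs$sa_low <= config$costs$mean &
        config$costs$mean <= config$costs$sa_high)
  if (any(bad_range)) {
    abort(sprintf("one-way range must bracket the mean for: %s.",
                  paste(config$costs$name[bad_range], collapse = ", ")))
  }
  # beta feasibility for utilities and for reported transition sds
  for (s in STATES) {
    if (config$utility_sd[[s]] > 0) {
      beta_from_mean_sd(config$utilities[[s]], config$utility_sd[[s]])
    }
  }
  for (from in STATES) for (to in setdiff(STATES, from)) {
    sd <- config$transition_sd[from, to]
    if (!is.na(sd) && sd > 0) beta_from_mean_sd(config$transitions[from, to], sd)
  }
  eff <- config$effect
  if (!(eff$ci_low <= eff$rr && eff$rr <= eff$ci_high) || eff$ci_low <= 0) {
    abort("effect: need 0 < ci_low <= rr <= ci_high.")
  }
  if (config$n_cycles < 1) abort("n_cycles must be >= 1.")
  if (config$wtp < 0) abort("wtp must be >= 0.")
  if (config$psa_iterations < 1) abort("psa_iterations must be >= 1.")
  for (key in config$rr_targets) parse_transition_key(key)
  if (!all(c("name", "rr_exacerbation", "addon_cost_per_cycle") %in%
             names(config$strategies))) {
    abort("strategies must have name, rr_exacerbation, addon_cost_per_cycle.")
  }
  invisible(config)
}

cost_mean <- function(config, name) {
  i <- match(name, config$costs$name)
  if (anyNA(i)) abort(sprintf("unknown cost component '%s'.",
                              paste(name[is.na(i)], collapse = ", ")))
  config$costs$mean[i]
}

#' @export
print.feno_config <- function(x, ...) {
  cat("<feno_config>\n")
  cat(sprintf("  states: %s | cycles: %d (1 week each) | horizon: %.2f y\n",
              paste(STATES, collapse = "/"), x$n_cycles,
              x$n_cycles * x$cycle_length_years))
  cat(sprintf("  strategies: %s\n", paste(x$strategies$name, collapse = ", ")))
  cat(sprintf("  pooled RR: %.2f (%.2f-%.2f) on %s\n", x$effect$rr,
              x$effect$ci_low, x$effect$ci_high,
              paste(x$rr_targets, collapse = ", ")))
  cat(sprintf("  wtp: %s US$/QALY | PSA iterations: %d | seed: %d\n",
              format(x$wtp, big.mark = ","), x$psa_iterations, x$seed))
  cal <- x$recipe$calibration
  if (any(cal != 1)) {
    cat(sprintf("  state-cost calibration: W %.4f, S %.4f, A %.4f\n",
                cal[["W"]], cal[["S"]], cal[["A"]]))
  }
  invisible(x)
}
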