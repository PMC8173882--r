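#' List the scalar parameters of a configuration
#'
#' Named vector of every sweepable scalar: cost-component means, the six
#' off-diagonal transition probabilities, per-state utilities and the pooled
#' relative risk. Used both to address parameters in one-way analysis and to
#' assert the holding-fixed contract (non-swept parameters stay at base
#' case).
#'
#' @param config A `feno_config`.
#' @return Named numeric vector.
#' @export
get_parameters <- function(config) {
  trans <- c()
  for (from in STATES) for (to in setdiff(STATES, from)) {
    trans[transition_key(from, to)] <- config$transitions[from, to]
  }
  c(setNames(config$costs$mean, config$costs$name), trans,
    setNames(config$utilities, paste0("utility_", STATES)),
    rr = config$effect$rr)
}

#' Set one scalar parameter of a configuration
#'
#' Cost components are addressed by name, transitions as `"W->A"` (the
#' difference is absorbed into the row's stay probability), utilities as
#' `"utility_W"`, and the pooled relative risk as `"rr"` (which propagates to
#' every strategy that uses the pooled effect). All other parameters are
#' untouched; the modified configuration is re-validated.
#'
#' @param config A `feno_config`.
#' @param parameter Parameter name (see [get_parameters()]).
#' @param value New value; must respect the parameter's domain.
#' @return The modified configuration.
#' @export
set_parameter <- function(config, parameter, value) {
  if (parameter %in% config$costs$name) {
    if (value < 0) abort(sprintf("'%s' must be >= 0.", parameter))
    config$costs$mean[config$costs$name == parameter] <- value
  } else if (grepl("->", parameter, fixed = TRUE)) {
    ft <- parse_transition_key(parameter)
    assert_prob(value, parameter)
    old <- config$transitions[ft[1], ft[2]]
    config$transitions[ft[1], ft[1]] <- config$transitions[ft[1], ft[1]] + old - value
    config$transitions[ft[1], ft[2]] <- value
    if (config$transitions[ft[1], ft[1]] < 0) {
      abort(sprintf("'%s' = %g leaves a negative stay probability.", parameter, value))
    }
  } else if (parameter %in% paste0("utility_", STATES)) {
    assert_prob(value, parameter)
    config$utilities[[sub("utility_", "", parameter)]] <- value
  } else if (parameter == "rr") {
    if (value < 0) abort("rr must be >= 0.")
    config$effect$rr <- value
    config$effect$ci_low <- min(config$effect$ci_low, value)
    config$effect$ci_high <- max(config$effect$ci_high, value)
    config$strategies$rr_exacerbation[config$strategies$uses_effect_rr] <- value
  } else {
    abort(sprintf("unknown parameter '%s'.", parameter))
  }
  validate_config(config)
  config
}

incremental_outcomes <- function(config, comparator = "standard") {
  comp <- compare_strategies(run_base_case(config), comparator = comparator)
  g <- glance(comp)
  tibble::tibble(
    delta_cost = g$delta_cost, delta_qaly = g$delta_qaly,
    inmb = net_monetary_benefit(g$delta_cost, g$delta_qaly, config$wtp),
    verdict = g$verdict
  )
}

#' One-way deterministic sensitivity sweep
#'
#' Re-runs the deterministic model with a single parameter set to each of two
#' bounds, every other parameter held at base case, and reports the
#' incremental outcomes (intervention vs comparator) at both bounds. The full
#' parameter vector used at each bound is attached as attribute
#' `"param_log"` so the holding-fixed contract can be audited.
#'
#' @param config A `feno_config`.
#' @param parameter Parameter name (see [get_parameters()]).
#' @param low,high Bounds with `low <= high`.
#' @param comparator Reference strategy.
#' @return A tibble with rows `low`/`high`: `parameter`, `bound`, `value`,
#'   `delta_cost`, `delta_qaly`, `inmb`, `verdict`.
#' @export
one_way_sweep <- function(config, parameter, low, high,
                          comparator = "standard") {
  if (low > high) abort("need low <= high.")
  log <- list()
  rows <- purrr::map2(c("low", "high"), c(low, high), function(bound, value) {
    cfg <- set_parameter(config, parameter, value)
    log[[bound]] <<- get_parameters(cfg)
    dplyr::bind_cols(tibble::tibble(parameter = parameter, bound = bound,
                                    value = value),
                     incremental_outcomes(cfg, comparator))
  })
  out <- purrr::list_rbind(rows)
  attr(out, "param_log") <- log
  out
}

tornado_bounds <- function(config) {
  costs <- config$costs |>
    dplyr::mutate(
      low = ifelse(!is.na(.data$sa_low) & !is.na(.data$sa_high), .data$sa_low,
                   pmax(0, .data$mean - .data$sd)),
      high = ifelse(!is.na(.data$sa_low) & !is.na(.data$sa_high), .data$sa_high,
                    .data$mean + .data$sd)
    ) |>
    dplyr::transmute(parameter = .data$name, .data$low, .data$high)
  trans <- purrr::map(STATES, function(from) {
    purrr::map(setdiff(STATES, from), function(to) {
      m <- config$transitions[from, to]; s <- config$transition_sd[from, to]
      tibble::tibble(parameter = transition_key(from, to),
                     low = max(0, m - s), high = min(1, m + s))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  dplyr::bind_rows(
    costs, trans,
    tibble::tibble(parameter = "rr", low = config$effect$ci_low,
                   high = config$effect$ci_high)
  )
}

#' Tornado table of one-way sensitivity analyses
#'
#' Sweeps every cost component over its published one-way range (mean +/- 1
#' sd when no valid range is printed), every transition probability over
#' mean +/- 1 reported sd truncated to `[0, 1]` with the stay probability
#' absorbing the difference, and the pooled relative risk over its 95% CI.
#' Entries are sorted by descending swing of the chosen outcome.
#'
#' @param config A `feno_config`.
#' @param outcome One of `"inmb"` (incremental net monetary benefit at the
#'   configured willingness to pay, the default), `"delta_cost"`,
#'   `"delta_qaly"`.
#' @param comparator Reference strategy.
#' @return A tibble of class `feno_tornado`: `parameter`, `low`, `high`,
#'   `outcome_low`, `outcome_high`, `swing`, `verdict_low`, `verdict_high`,
#'   sorted by descending `swing`.
#' @export
tornado_table <- function(config, outcome = c("inmb", "delta_cost", "delta_qaly"),
                          comparator = "standard") {
  outcome <- match.arg(outcome)
  bounds <- tornado_bounds(config)
  rows <- purrr::pmap(bounds, function(parameter, low, high) {
    sweep <- one_way_sweep(config, parameter, low, high, comparator)
    tibble::tibble(
      parameter = parameter, low = low, high = high,
      outcome_low = sweep[[outcome]][sweep$bound == "low"],
      outcome_high = sweep[[outcome]][sweep$bound == "high"],
      verdict_low = sweep$verdict[sweep$bound == "low"],
      verdict_high = sweep$verdict[sweep$bound == "high"]
    )
  })
  out <- purrr::list_rbind(rows) |>
    dplyr::mutate(swing = abs(.data$outcome_high - .data$outcome_low)) |>
    dplyr::relocate("swing", .after = "outcome_high") |>
    dplyr::arrange(dplyr::desc(.data$swing))
  attr(out, "outcome") <- outcome
  class(out) <- c("feno_tornado", class(out))
  out
}
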