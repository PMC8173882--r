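# lean scalar moment matching for the sampling hot path (validated already
# at configuration time)
beta_ab <- function(mean, sd) {
  nu <- mean * (1 - mean) / sd^2 - 1
  c(mean * nu, (1 - mean) * nu)
}

sample_parameter_set <- function(config, sd_scale = 1) {
  # order of draws is fixed; reproducibility depends on it
  trans <- config$transitions
  for (from in STATES) {
    ref_to <- config$dirichlet_reference[[from]]
    sd <- config$transition_sd[from, ref_to] * sd_scale
    if (is.na(sd) || sd == 0) next
    m <- trans[from, ref_to]
    n_eff <- m * (1 - m) / sd^2 - 1
    trans[from, ] <- rdirichlet(1, n_eff * trans[from, ])
  }
  utilities <- config$utilities
  for (s in STATES) {
    sd <- config$utility_sd[[s]] * sd_scale
    if (sd > 0) {
      ab <- beta_ab(utilities[[s]], sd)
      utilities[[s]] <- rbeta(1, ab[[1]], ab[[2]])
    }
  }
  comp <- setNames(config$costs$mean, config$costs$name)
  sds <- config$costs$sd * sd_scale
  for (i in seq_along(comp)) {
    if (sds[[i]] > 0) {
      comp[[i]] <- rgamma(1, shape = (comp[[i]] / sds[[i]])^2,
                          scale = sds[[i]]^2 / comp[[i]])
    }
  }
  sdlog <- (if (isTRUE(config$effect$use_table_sd)) config$effect$table_sd
            else config$effect$sigma_log) * sd_scale
  rr <- if (sdlog > 0) rlnorm(1, log(config$effect$rr), sdlog) else config$effect$rr
  list(transitions = trans, utilities = utilities, components = comp, rr = rr)
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws one joint parameter set per iteration — Dirichlet transition rows,
#' beta utilities, gamma cost components and a lognormal relative risk — and
#' runs every strategy through the cohort model on that shared set (only the
#' strategy-specific relative risk and add-on cost differ within an
#' iteration). Fully reproducible from the seed.
#'
#' @param config A `feno_config`.
#' @param iterations Number of iterations (default `config$psa_iterations`).
#' @param seed Seed for this stage (default derived from `config$seed`).
#' @param sd_scale Scale factor on every standard deviation; 0 collapses all
#'   distributions to their means (every iteration equals the base case).
#' @param param_log Keep the sampled parameters per iteration.
#' @return An object of class `feno_psa` with the per-iteration,
#'   per-strategy `(cost, qaly)` draws; [generics::tidy()] returns them,
#'   [generics::glance()] summarizes means with normal-approximation 95%
#'   confidence intervals.
#' @export
run_psa <- function(config, iterations = NULL, seed = NULL, sd_scale = 1,
                    param_log = FALSE) {
  iterations <- iterations %||% config$psa_iterations
  if (iterations < 1) abort("iterations must be >= 1.")
  if (sd_scale < 0) abort("sd_scale must be >= 0.")
  seed <- seed %||% derive_seed(config$seed, 1L)
  strategies <- config$strategies
  n_s <- nrow(strategies)
  cost <- matrix(NA_real_, iterations, n_s,
                 dimnames = list(NULL, strategies$name))
  qaly <- cost
  logs <- if (param_log) vector("list", iterations) else NULL
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      draw <- sample_parameter_set(config, sd_scale)
      state_costs <- assemble_state_costs(config, draw$components)
      if (param_log) logs[[it]] <- draw
      for (j in seq_len(n_s)) {
        st <- strategies[j, ]
        rr <- if (isTRUE(st$uses_effect_rr)) draw$rr else st$rr_exacerbation
        addon <- st$addon_cost_per_cycle
        if (!is.na(st$addon_component) && addon > 0) {
          base_comp <- cost_mean(config, st$addon_component)
          addon <- addon * draw$components[[st$addon_component]] / base_comp
        }
        p <- apply_relative_risk(draw$transitions, rr, config$rr_targets)
        occ <- cohort_trace_matrix(p, config$init, config$n_cycles)
        totals <- occupancy_totals(occ, config$half_cycle_correction)
        cost[it, j] <- sum(totals * state_costs) +
          config$n_cycles * addon
        qaly[it, j] <- sum(totals * draw$utilities) * config$cycle_length_years
      }
    }
  })
  draws <- tibble::tibble(
    iteration = rep(seq_len(iterations), times = n_s),
    strategy = rep(strategies$name, each = iterations),
    cost = as.vector(cost), qaly = as.vector(qaly)
  )
  structure(list(draws = draws, cost = cost, qaly = qaly,
                 n_iter = iterations, seed = seed, wtp = config$wtp,
                 strategies = strategies$name, params = logs),
            class = "feno_psa")
}

#' @export
print.feno_psa <- function(x, ...) {
  cat(sprintf("<feno_psa> %d iterations x %d strategies (seed %d)\n",
              x$n_iter, length(x$strategies), x$seed))
  print(glance(x))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `feno_psa` object.
#' @param ... Unused.
#' @export
tidy.feno_psa <- function(x, ...) x$draws

#' @rdname run_psa
#' @export
glance.feno_psa <- function(x, ...) {
  purrr::map(c(cost = "cost", qaly = "qaly"), function(metric) {
    m <- x[[metric]]
    tibble::tibble(strategy = colnames(m), metric = metric,
                   mean = unname(colMeans(m)),
                   se = unname(apply(m, 2, stats::sd)) / sqrt(nrow(m)))
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$strategy, .data$metric) |>
    dplyr::mutate(ci_low = .data$mean - qnorm(0.975) * .data$se,
                  ci_high = .data$mean + qnorm(0.975) * .data$se)
}

psa_increments <- function(psa, comparator = "standard",
                           intervention = NULL) {
  if (!comparator %in% psa$strategies) {
    abort(sprintf("comparator '%s' not in the PSA.", comparator))
  }
  intervention <- intervention %||% setdiff(psa$strategies, comparator)[[1]]
  tibble::tibble(
    iteration = seq_len(psa$n_iter),
    delta_cost = psa$cost[, intervention] - psa$cost[, comparator],
    delta_qaly = psa$qaly[, intervention] - psa$qaly[, comparator]
  )
}

#' Cost-effectiveness plane summary
#'
#' Classifies each iteration's incremental (QALY, cost) pair against the
#' comparator into the four plane quadrants — quadrant 1: more effective and
#' more costly; quadrant 2: more effective and cheaper; quadrant 3: less
#' effective and cheaper; quadrant 4: less effective and more costly — with
#' exact zeros counted as a separate boundary class. Also reports
#' per-strategy mean cost and QALYs with normal-approximation 95% CIs.
#'
#' @param psa A `feno_psa`.
#' @param comparator Reference strategy name.
#' @param intervention Intervention strategy (default: the other one).
#' @return An object of class `feno_ce_plane` with elements `quadrants`
#'   (tibble: region, n, fraction), `increments`, `means`.
#' @export
ce_plane_summary <- function(psa, comparator = "standard",
                             intervention = NULL) {
  inc <- psa_increments(psa, comparator, intervention)
  region <- dplyr::case_when(
    inc$delta_cost == 0 | inc$delta_qaly == 0 ~ "boundary",
    inc$delta_qaly > 0 & inc$delta_cost > 0 ~ "quadrant_1",
    inc$delta_qaly > 0 & inc$delta_cost < 0 ~ "quadrant_2",
    inc$delta_qaly < 0 & inc$delta_cost < 0 ~ "quadrant_3",
    .default = "quadrant_4"
  )
  levels <- c("quadrant_1", "quadrant_2", "quadrant_3", "quadrant_4", "boundary")
  quadrants <- tibble::tibble(region = factor(region, levels = levels)) |>
    dplyr::count(.data$region, .drop = FALSE, name = "n") |>
    dplyr::mutate(region = as.character(.data$region),
                  fraction = .data$n / sum(.data$n))
  structure(list(quadrants = quadrants, increments = inc,
                 means = glance(psa), comparator = comparator),
            class = "feno_ce_plane")
}

#' @export
print.feno_ce_plane <- function(x, ...) {
  cat(sprintf("<feno_ce_plane> vs %s\n", x$comparator))
  print(x$quadrants)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of iterations in which
#' each strategy attains the maximal net monetary benefit (exact ties split
#' equally). The strategy with the maximal expected net benefit at each
#' threshold is flagged, which traces the acceptability frontier.
#'
#' @param psa A `feno_psa`.
#' @param wtp_grid Willingness-to-pay grid, US$/QALY (default 0 to 40,000 in
#'   steps of 1,000).
#' @return A tibble of class `feno_ceac`: `wtp`, `strategy`, `probability`,
#'   `on_frontier`. Probabilities sum to 1 at every threshold.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 40000, by = 1000)) {
  if (length(wtp_grid) < 1 || any(wtp_grid < 0)) {
    abort("wtp_grid must be non-empty and non-negative.")
  }
  out <- purrr::map(wtp_grid, function(w) {
    nmb <- w * psa$qaly - psa$cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)   # ties split equally
    mean_nmb <- colMeans(nmb)
    tibble::tibble(wtp = w, strategy = colnames(nmb),
                   probability = colMeans(share),
                   on_frontier = mean_nmb == max(mean_nmb))
  }) |> purrr::list_rbind()
  class(out) <- c("feno_ceac", class(out))
  out
}

#' Expected value of perfect information
#'
#' Per-person EVPI at a willingness-to-pay threshold: the expectation over
#' iterations of the maximal net monetary benefit, minus the maximum over
#' strategies of the expected net monetary benefit. It is the ceiling price
#' of removing all parameter uncertainty, and is zero exactly when the same
#' strategy wins every iteration. Multiplying by an affected population size
#' gives the population EVPI.
#'
#' @param psa A `feno_psa`.
#' @param wtp Willingness-to-pay value(s), US$/QALY (default the configured
#'   threshold).
#' @param population Optional population size for the population EVPI.
#' @return A tibble with one row per `wtp`: `wtp`, `e_max_nmb`, `max_e_nmb`,
#'   `evpi`, `pevpi` (`NA` when no population is given).
#' @export
evpi <- function(psa, wtp = NULL, population = NULL) {
  wtp <- wtp %||% psa$wtp
  purrr::map(wtp, function(w) {
    nmb <- w * psa$qaly - psa$cost
    e_max <- mean(apply(nmb, 1, max))
    max_e <- max(colMeans(nmb))
    tibble::tibble(wtp = w, e_max_nmb = e_max, max_e_nmb = max_e,
                   evpi = e_max - max_e,
                   pevpi = if (is.null(population)) NA_real_
                           else (e_max - max_e) * population)
  }) |> purrr::list_rbind()
}
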