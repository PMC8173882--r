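config_to_list <- function(config) {
  mat_to_list <- function(m) {
    lapply(setNames(STATES, STATES), function(from) {
      row <- as.list(m[from, ])
      row[!is.na(unlist(row))]
    })
  }
  list(
    transitions = mat_to_list(config$transitions),
    transition_sd = mat_to_list(config$transition_sd),
    utilities = as.list(config$utilities),
    utility_sd = as.list(config$utility_sd),
    effect = config$effect[c("rr", "ci_low", "ci_high", "table_sd",
                             "use_table_sd", "level")],
    costs = purrr::pmap(config$costs, function(...) {
      row <- list(...)
      row[!vapply(row, function(v) is.na(v) || (is.character(v) && v == ""), TRUE)]
    }),
    strategies = purrr::pmap(config$strategies, function(...) {
      row <- list(...)
      row[!vapply(row, is.na, TRUE)]
    }),
    settings = list(
      n_cycles = config$n_cycles,
      cycle_length_years = config$cycle_length_years,
      wtp = config$wtp, psa_iterations = config$psa_iterations,
      seed = config$seed,
      population_for_pevpi = config$population_for_pevpi,
      half_cycle_correction = config$half_cycle_correction,
      rr_targets = as.list(config$rr_targets)
    ),
    recipe = list(p_picu = config$recipe$p_picu,
                  calibration = as.list(config$recipe$calibration),
                  overrides = as.list(config$recipe$overrides[
                    !is.na(config$recipe$overrides)])),
    init = as.list(config$init),
    dirichlet_reference = as.list(config$dirichlet_reference)
  )
}

list_to_config <- function(x, path = "<config>") {
  need <- function(field) {
    if (is.null(x[[field]])) {
      abort(sprintf("%s: missing required section '%s'.", path, field),
            class = "fenocea_schema_error")
    }
    x[[field]]
  }
  list_to_mat <- function(lst, default = NA_real_) {
    m <- matrix(default, 3, 3, dimnames = list(STATES, STATES))
    for (from in names(lst)) for (to in names(lst[[from]])) {
      m[from, to] <- as.numeric(lst[[from]][[to]])
    }
    m
  }
  trans <- list_to_mat(need("transitions"), 0)
  costs <- purrr::map(need("costs"), function(row) {
    param_spec(row$name, as.numeric(row$mean), as.numeric(row$sd),
               family = row$family %||% "gamma",
               sa_low = as.numeric(row$sa_low %||% NA),
               sa_high = as.numeric(row$sa_high %||% NA))
  }) |> purrr::list_rbind()
  strategies <- purrr::map(need("strategies"), function(row) {
    strategy_spec(row$name, as.numeric(row$rr_exacerbation),
                  as.numeric(row$addon_cost_per_cycle),
                  uses_effect_rr = isTRUE(row$uses_effect_rr),
                  addon_component = row$addon_component %||% NA_character_)
  }) |> purrr::list_rbind()
  st <- need("settings")
  rec <- x$recipe %||% list()
  overrides <- c(W = NA_real_, S = NA_real_, A = NA_real_)
  for (s in names(rec$overrides %||% list())) overrides[[s]] <- rec$overrides[[s]]
  feno_config(
    transitions = trans,
    transition_sd = list_to_mat(need("transition_sd")),
    utilities = unlist(need("utilities"))[STATES],
    utility_sd = unlist(need("utility_sd"))[STATES],
    costs = costs,
    effect = need("effect"),
    strategies = strategies,
    n_cycles = st$n_cycles %||% 52L,
    cycle_length_years = st$cycle_length_years %||% (1 / 52),
    wtp = st$wtp %||% 20000,
    psa_iterations = st$psa_iterations %||% 1000L,
    seed = st$seed %||% 1L,
    population_for_pevpi = st$population_for_pevpi,
    half_cycle_correction = isTRUE(st$half_cycle_correction),
    rr_targets = unlist(st$rr_targets %||% list("W->A", "S->A")),
    recipe = cost_recipe(
      p_picu = rec$p_picu %||% 0,
      calibration = unlist(rec$calibration %||%
                             list(W = 1, S = 1, A = 1))[STATES],
      overrides = overrides
    ),
    init = unlist(x$init %||% list(W = 1, S = 0, A = 0))[STATES],
    dirichlet_reference = unlist(x$dirichlet_reference %||%
                                   list(W = "S", S = "W", A = "W"))[STATES]
  )
}

#' Read a model configuration from YAML or JSON
#'
#' Loads and schema-validates a configuration file; every structural
#' invariant (row-stochastic transitions, domains, feasible variances) is
#' enforced at load time with an error naming the offending field. The
#' package ships the published baseline as
#' `system.file("extdata", "paper_baseline.yaml", package = "fenocea")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `feno_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "fenocea_io_error")
  }
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  list_to_config(x, path = path)
}

#' Write a model configuration to YAML or JSON
#'
#' @param config A `feno_config`.
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Read study effects from CSV
#'
#' Accepts either `label, log_rr, se` or `label, rr, ci_low, ci_high`
#' columns; the latter are converted with [se_from_ci()].
#'
#' @param path CSV path.
#' @return A tibble ready for [dl_pool()].
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("studies file not found: %s", path), class = "fenocea_io_error")
  }
  as_study_effects(read.csv(path))
}

write_result_csv <- function(x, dir, name, manifest) {
  path <- file.path(dir, name)
  write.csv(x, path, row.names = FALSE)
  c(manifest, name)
}

#' Run the full analysis pipeline from the command line
#'
#' A thin argv-style interface over the package functions, also installed as
#' the executable script `inst/cli/fenocea`. Subcommands: `basecase`, `psa`,
#' `ceac`, `evpi`, `owsa`, `meta`, `simulate-trials`, `all`. Flags:
#' `--config PATH` (default: the shipped published baseline, calibrated),
#' `--out DIR`, `--seed INT`, `--iterations INT`, `--wtp FLOAT`,
#' `--population INT`, `--studies PATH` (for `meta`). All outputs are CSV
#' plus a JSON run manifest written last; all randomness is funneled through
#' the seed.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, non-zero on failure.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    run_cli_impl(args)
    0L
  }, fenocea_usage_error = function(e) {
    message(conditionMessage(e))
    2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_usage <- function() {
  paste(
    "usage: fenocea <subcommand> [--config PATH] [--out DIR] [--seed INT]",
    "               [--iterations INT] [--wtp FLOAT] [--population INT]",
    "               [--studies PATH]",
    "subcommands: basecase psa ceac evpi owsa meta simulate-trials all",
    sep = "\n"
  )
}

parse_cli_args <- function(args) {
  subcommands <- c("basecase", "psa", "ceac", "evpi", "owsa", "meta",
                   "simulate-trials", "all")
  if (length(args) == 0 || !args[[1]] %in% subcommands) {
    abort(cli_usage(), class = "fenocea_usage_error")
  }
  opts <- list(subcommand = args[[1]], out = ".", config = NULL, seed = NULL,
               iterations = NULL, wtp = NULL, population = NULL, studies = NULL)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    flag <- rest[[i]]
    key <- switch(flag, `--config` = "config", `--out` = "out",
                  `--seed` = "seed", `--iterations` = "iterations",
                  `--wtp` = "wtp", `--population` = "population",
                  `--studies` = "studies",
                  abort(paste0("unknown flag: ", flag, "\n", cli_usage()),
                        class = "fenocea_usage_error"))
    if (i == length(rest)) {
      abort(paste0("flag ", flag, " needs a value"), class = "fenocea_usage_error")
    }
    val <- rest[[i + 1]]
    opts[[key]] <- if (key %in% c("seed", "iterations", "population")) {
      as.integer(val)
    } else if (key == "wtp") as.numeric(val) else val
    i <- i + 2
  }
  opts
}

run_cli_impl <- function(args) {
  opts <- parse_cli_args(args)
  config <- if (is.null(opts$config)) {
    calibrate_state_costs(paper_fixture(feno_addon_basis = "weekly"))
  } else {
    read_config(opts$config)
  }
  if (!is.null(opts$seed)) config$seed <- opts$seed
  if (!is.null(opts$iterations)) config$psa_iterations <- opts$iterations
  if (!is.null(opts$wtp)) config$wtp <- opts$wtp
  if (!is.null(opts$population)) config$population_for_pevpi <- opts$population
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  log_stage <- function(stage) {
    message(sprintf("[fenocea] stage=%s seed=%d out=%s", stage, config$seed,
                    opts$out))
  }
  sub <- opts$subcommand
  emit <- function(x, name) files <<- write_result_csv(x, opts$out, name, files)

  if (sub %in% c("basecase", "all")) {
    log_stage("basecase")
    base <- run_base_case(config)
    emit(tidy(compare_strategies(base)), "basecase_comparison.csv")
    for (run in attr(base, "runs")) {
      emit(run$trace, paste0("trace_", run$strategy, ".csv"))
    }
  }
  psa <- NULL
  if (sub %in% c("psa", "ceac", "evpi", "all")) {
    log_stage("psa")
    psa <- run_psa(config)
  }
  if (sub %in% c("psa", "all")) {
    emit(tidy(psa), "psa_iterations.csv")
    plane <- ce_plane_summary(psa)
    emit(plane$quadrants, "ce_plane_summary.csv")
    emit(plane$means, "psa_means.csv")
  }
  if (sub %in% c("ceac", "all")) {
    log_stage("ceac")
    emit(ceac(psa), "ceac.csv")
  }
  if (sub %in% c("evpi", "all")) {
    log_stage("evpi")
    emit(evpi(psa, population = config$population_for_pevpi), "evpi.csv")
  }
  if (sub %in% c("owsa", "all")) {
    log_stage("owsa")
    emit(tornado_table(config), "tornado.csv")
  }
  if (sub %in% c("meta", "all")) {
    log_stage("meta")
    studies <- if (!is.null(opts$studies)) {
      read_studies(opts$studies)
    } else {
      simulate_trials(seed = derive_seed(config$seed, 2L))
    }
    pooled <- dl_pool(studies)
    emit(glance(pooled), "pooled_effect.csv")
    emit(forest_table(pooled), "forest.csv")
  }
  if (sub %in% c("simulate-trials", "all")) {
    log_stage("simulate-trials")
    emit(simulate_trials(seed = derive_seed(config$seed, 2L)), "trials.csv")
  }
  manifest <- list(
    package = "fenocea",
    version = as.character(packageVersion("fenocea")),
    subcommand = sub,
    seed = config$seed,
    config_hash = rlang::hash(config_to_list(config)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(opts$out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
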