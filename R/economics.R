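#' Net monetary benefit
#'
#' `wtp * qaly - cost`: the value of the health produced at the
#' willingness-to-pay threshold minus what it costs. Vectorized.
#'
#' @param cost Cost, US$.
#' @param qaly Quality-adjusted life years.
#' @param wtp Willingness to pay, US$ per QALY (>= 0).
#' @return Net monetary benefit, US$.
#' @examples
#' net_monetary_benefit(1333.57, 0.9395, 20000)
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) abort("wtp must be >= 0.")
  wtp * qaly - cost
}

#' Compare strategies on cost and effectiveness
#'
#' Computes incremental cost and QALYs of each strategy against a comparator
#' and classifies the result: an incremental cost-effectiveness ratio when
#' costs and effects trade off, or a dominance verdict when one strategy is
#' at least as cheap and strictly more effective (or strictly cheaper and as
#' effective). Ties on both dimensions report no difference and no ratio.
#'
#' @param runs A tibble with columns `strategy`, `cost`, `qaly`
#'   ([run_base_case()] output), or a list of `feno_run` objects.
#' @param comparator Name of the reference strategy (default `"standard"` if
#'   present, else the first row).
#' @return An object of class `feno_comparison`; [generics::tidy()] returns
#'   the comparison table (strategy, cost, delta_cost, qaly, delta_qaly,
#'   ce_ratio, verdict).
#' @examples
#' runs <- paper_table3()
#' compare_strategies(runs, comparator = "standard")
#' @export
compare_strategies <- function(runs, comparator = NULL) {
  if (!is.data.frame(runs)) {
    runs <- tibble::tibble(
      strategy = purrr::map_chr(runs, "strategy"),
      cost = purrr::map_dbl(runs, "total_cost"),
      qaly = purrr::map_dbl(runs, "total_qaly")
    )
  }
  if (nrow(runs) < 2L) abort("need at least two strategies to compare.")
  comparator <- comparator %||%
    (if ("standard" %in% runs$strategy) "standard" else runs$strategy[[1]])
  if (!comparator %in% runs$strategy) {
    abort(sprintf("comparator '%s' not among the runs.", comparator))
  }
  ref <- runs[runs$strategy == comparator, ]
  tab <- runs |>
    dplyr::mutate(
      delta_cost = ifelse(.data$strategy == comparator, NA_real_,
                          .data$cost - ref$cost),
      delta_qaly = ifelse(.data$strategy == comparator, NA_real_,
                          .data$qaly - ref$qaly),
      ce_ratio = ifelse(.data$qaly == 0, NA_real_, .data$cost / .data$qaly)
    )
  verdicts <- purrr::pmap_chr(tab, function(strategy, delta_cost, delta_qaly, ...) {
    if (strategy == comparator) return("comparator")
    classify_increment(delta_cost, delta_qaly)
  })
  tab$verdict <- verdicts
  # mirror the published table layout: the comparator row carries the verdict
  # it earns against the intervention (swap of the intervention's verdict)
  structure(list(table = tab, comparator = comparator), class = "feno_comparison")
}

classify_increment <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("no difference")
  if ((delta_cost < 0 && delta_qaly >= 0) || (delta_cost <= 0 && delta_qaly > 0)) {
    return("dominant")
  }
  if ((delta_cost > 0 && delta_qaly <= 0) || (delta_cost >= 0 && delta_qaly < 0)) {
    return("dominated")
  }
  sprintf("ICER %.1f", delta_cost / delta_qaly)
}

#' Incremental cost-effectiveness ratio of a comparison
#'
#' @param comparison A `feno_comparison`.
#' @param strategy Intervention strategy (default: the single
#'   non-comparator).
#' @return The ICER in US$/QALY, or `NA` under dominance or ties.
#' @export
icer <- function(comparison, strategy = NULL) {
  tab <- comparison$table
  others <- tab[tab$strategy != comparison$comparator, ]
  row <- if (is.null(strategy)) others[1, ] else others[others$strategy == strategy, ]
  if (nrow(row) != 1L) abort("strategy not found in comparison.")
  if (!startsWith(row$verdict, "ICER")) return(NA_real_)
  row$delta_cost / row$delta_qaly
}

#' @export
print.feno_comparison <- function(x, ...) {
  cat(sprintf("<feno_comparison> vs %s\n", x$comparator))
  print(x$table)
  invisible(x)
}

#' @rdname compare_strategies
#' @param x A `feno_comparison`.
#' @param ... Unused.
#' @export
tidy.feno_comparison <- function(x, ...) x$table

#' @rdname compare_strategies
#' @export
glance.feno_comparison <- function(x, ...) {
  others <- x$table[x$table$strategy != x$comparator, ]
  v <- others$verdict[[1]]
  tibble::tibble(
    comparator = x$comparator,
    intervention = others$strategy[[1]],
    delta_cost = others$delta_cost[[1]],
    delta_qaly = others$delta_qaly[[1]],
    verdict = v,
    comparator_verdict = switch(v, dominant = "dominated",
                                dominated = "dominant", v),
    icer = icer(x)
  )
}
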