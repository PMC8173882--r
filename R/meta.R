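#' Standard error of a log relative risk from its confidence interval
#'
#' Standard back-calculation for trials reported as RR with a 95% CI:
#' `se = log(ci_high / ci_low) / (2 z)`.
#'
#' @param rr Point estimate (> 0).
#' @param ci_low,ci_high Confidence bounds, `0 < ci_low <= rr <= ci_high`.
#' @param level Confidence level, default 0.95.
#' @return Standard error of the log relative risk.
#' @examples
#' se_from_ci(0.76, 0.63, 0.92)
#' @export
se_from_ci <- function(rr, ci_low, ci_high, level = 0.95) {
  lognormal_from_ci(rr, ci_low, ci_high, level)$sdlog
}

as_study_effects <- function(studies, level = 0.95) {
  studies <- tibble::as_tibble(studies)
  if (!all(c("log_rr", "se") %in% names(studies))) {
    if (!all(c("rr", "ci_low", "ci_high") %in% names(studies))) {
      abort("studies need columns (log_rr, se) or (rr, ci_low, ci_high).")
    }
    studies <- studies |>
      dplyr::mutate(log_rr = log(.data$rr),
                    se = se_from_ci(.data$rr, .data$ci_low, .data$ci_high, level))
  }
  if (!"label" %in% names(studies)) {
    studies$label <- paste0("study_", seq_len(nrow(studies)))
  }
  if (any(studies$se <= 0)) abort("study standard errors must be > 0.")
  studies[, c("label", "log_rr", "se")]
}

#' DerSimonian-Laird random-effects pooling of relative risks
#'
#' Pools study-level log relative risks with the DerSimonian-Laird moment
#' estimator of between-study variance: fixed-effect weights `1/se^2` give
#' Cochran's Q; `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`;
#' random-effects weights `1/(se^2 + tau2)` give the pooled estimate and its
#' normal-theory confidence interval. A single study is returned as-is with
#' `tau2 = 0`. `I^2 = max(0, (Q - (k-1))/Q)` summarizes heterogeneity.
#'
#' @param studies A data frame with columns `label` and either `log_rr`,
#'   `se`, or `rr`, `ci_low`, `ci_high` (the latter converted via
#'   [se_from_ci()]).
#' @param level Confidence level for the pooled interval.
#' @return An object of class `feno_meta`; [generics::tidy()] gives the
#'   per-study table, [generics::glance()] the pooled summary.
#' @examples
#' dl_pool(data.frame(log_rr = c(0, 0.5), se = c(0.1, 0.1)))
#' @export
dl_pool <- function(studies, level = 0.95) {
  studies <- as_study_effects(studies, level)
  k <- nrow(studies)
  if (k < 1L) abort("at least one study is required.")
  y <- studies$log_rr
  w <- 1 / studies$se^2
  y_fixed <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fixed)^2)
  if (k == 1L) {
    tau2 <- 0; i2 <- 0
  } else {
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / denom)
    i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  }
  w_re <- 1 / (studies$se^2 + tau2)
  mu <- sum(w_re * y) / sum(w_re)
  se_pooled <- sqrt(1 / sum(w_re))
  z <- qnorm((1 + level) / 2)
  structure(list(
    studies = studies, k = k, level = level,
    weights = w_re / sum(w_re),
    log_rr = mu, se = se_pooled,
    rr = exp(mu), ci_low = exp(mu - z * se_pooled),
    ci_high = exp(mu + z * se_pooled),
    tau2 = tau2, q = q, i2 = i2
  ), class = "feno_meta")
}

#' @export
print.feno_meta <- function(x, ...) {
  cat(sprintf("<feno_meta> DL random-effects pooling of %d studies\n", x$k))
  cat(sprintf("  RR %.3f (%.0f%% CI %.3f-%.3f)\n", x$rr, 100 * x$level,
              x$ci_low, x$ci_high))
  cat(sprintf("  tau^2 %.4f | Q %.3f | I^2 %.1f%%\n", x$tau2, x$q, 100 * x$i2))
  invisible(x)
}

#' @rdname dl_pool
#' @param x A `feno_meta` object.
#' @param ... Unused.
#' @export
tidy.feno_meta <- function(x, ...) {
  z <- qnorm((1 + x$level) / 2)
  x$studies |>
    dplyr::mutate(rr = exp(.data$log_rr),
                  ci_low = exp(.data$log_rr - z * .data$se),
                  ci_high = exp(.data$log_rr + z * .data$se),
                  weight = x$weights)
}

#' @rdname dl_pool
#' @export
glance.feno_meta <- function(x, ...) {
  tibble::tibble(k = x$k, rr = x$rr, ci_low = x$ci_low, ci_high = x$ci_high,
                 log_rr = x$log_rr, se = x$se, tau2 = x$tau2, q = x$q,
                 i2 = x$i2)
}

#' Tabular forest-plot summary
#'
#' One row per study (RR, CI, random-effects weight in percent) plus a pooled
#' row; the tabular stand-in for a forest plot.
#'
#' @param pooled A `feno_meta` object.
#' @return A tibble with columns `label`, `rr`, `ci_low`, `ci_high`,
#'   `weight_pct`; study weights sum to 100.
#' @export
forest_table <- function(pooled) {
  stopifnot(inherits(pooled, "feno_meta"))
  studies <- tidy(pooled)
  dplyr::bind_rows(
    studies |>
      dplyr::transmute(.data$label, .data$rr, .data$ci_low, .data$ci_high,
                       weight_pct = 100 * .data$weight),
    tibble::tibble(label = "pooled (DL)", rr = pooled$rr,
                   ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                   weight_pct = 100)
  )
}

#' Convert a pooled effect into the model's effect specification
#'
#' @param pooled A `feno_meta` object.
#' @return A list suitable as the `effect` field of [feno_config()].
#' @export
as_effect_spec <- function(pooled) {
  stopifnot(inherits(pooled, "feno_meta"))
  list(rr = pooled$rr, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
       table_sd = pooled$se, use_table_sd = FALSE, level = pooled$level)
}
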