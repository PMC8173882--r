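#' @importFrom rlang %||% abort .data
#' @importFrom stats qnorm rbeta rgamma rlnorm rnorm runif setNames
#' @importFrom utils write.csv read.csv packageVersion
NULL

# State labels, fixed by the model structure: well-controlled / suboptimal
# control without exacerbation / asthma exacerbation.
STATES <- c("W", "S", "A")

state_labels <- function() {
  c(W = "no symptoms or asthma controlled",
    S = "suboptimal control without exacerbation",
    A = "asthma exacerbation")
}

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Each stochastic stage (PSA, synthetic trials, perturbations) draws from its
#' own stream so that re-running one stage never shifts another. Sub-seeds are
#' a deterministic function of the master seed and a stage offset, kept within
#' the 32-bit integer range.
#'
#' @param master Integer master seed.
#' @param offset Integer stage offset (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(master, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(as.numeric(master)) + as.numeric(offset) * 1000003) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]; got %s.", what,
                  paste(signif(x, 6), collapse = ", ")))
  }
  invisible(x)
}

transition_key <- function(from, to) paste0(from, "->", to)

parse_transition_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(parts %in% STATES)) {
    abort(sprintf("Unknown transition '%s'; use e.g. 'W->A'.", key))
  }
  parts
}
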