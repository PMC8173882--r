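# shared fixtures; built once per test run

baseline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- paper_fixture()
    cache
  }
})

# the paper-matching configuration: weekly FeNO add-on, state costs solved
# against the published totals
calibrated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- calibrate_state_costs(paper_fixture(feno_addon_basis = "weekly"))
    }
    cache
  }
})

table1_matrix <- function() {
  transition_matrix(w_s = 0.097, w_a = 0.004,
                    s_w = 0.817, s_a = 0.007,
                    a_w = 0.271, a_s = 0.052)
}

# a feno_psa shell with hand-set (cost, qaly) draws, for enumeration tests
manual_psa <- function(cost, qaly, wtp = 20000) {
  structure(list(
    draws = NULL, cost = cost, qaly = qaly, n_iter = nrow(cost),
    seed = 0L, wtp = wtp, strategies = colnames(cost), params = NULL
  ), class = "feno_psa")
}
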