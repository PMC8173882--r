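test_that("beta moment matching reproduces mean and sd", {
  # symmetric case: var = 1/(4(2a+1)) at a = b
  p <- beta_from_mean_sd(0.5, sqrt(1 / 8))
  expect_equal(p$shape1, 0.5, tolerance = 1e-9)
  expect_equal(p$shape2, 0.5, tolerance = 1e-9)

  p <- beta_from_mean_sd(0.097, 0.029)
  expect_equal(p$shape1, 10.0057, tolerance = 1e-4)
  expect_equal(p$shape2, 93.1454, tolerance = 1e-4)

  # analytic round trip at 1e-9 for every probability-type input of the
  # published baseline
  cfg <- baseline_fixture()
  cases <- rbind(
    cbind(mean = as.vector(cfg$transitions), sd = as.vector(cfg$transition_sd)),
    cbind(mean = cfg$utilities, sd = cfg$utility_sd)
  )
  cases <- cases[!is.na(cases[, "sd"]), ]
  for (i in seq_len(nrow(cases))) {
    p <- beta_from_mean_sd(cases[i, "mean"], cases[i, "sd"])
    s <- p$shape1 + p$shape2
    expect_equal(p$shape1 / s, unname(cases[i, "mean"]), tolerance = 1e-9)
    expect_equal(sqrt(p$shape1 * p$shape2 / (s^2 * (s + 1))),
                 unname(cases[i, "sd"]), tolerance = 1e-9)
  }
})

test_that("infeasible beta variance errors rather than clamps", {
  expect_error(beta_from_mean_sd(0.5, 0.6), "infeasible")
  expect_error(beta_from_mean_sd(0.5, 0.5), "infeasible")
  expect_error(beta_from_mean_sd(1.2, 0.1), "mean")
})

test_that("gamma moment matching is exact and flags point masses", {
  p <- gamma_from_mean_sd(95.05, 8.53)
  expect_equal(p$shape, (95.05 / 8.53)^2, tolerance = 1e-12)
  expect_equal(p$scale, 8.53^2 / 95.05, tolerance = 1e-12)
  expect_equal(p$shape, 124.166, tolerance = 1e-4)
  expect_equal(p$scale, 0.76550, tolerance = 1e-4)

  expect_equal(unlist(gamma_from_mean_sd(1, 1)[, c("shape", "scale")]),
               c(shape = 1, scale = 1))

  # mean and variance identities for every cost in the baseline
  cfg <- baseline_fixture()
  live <- cfg$costs[cfg$costs$sd > 0, ]
  p <- gamma_from_mean_sd(live$mean, live$sd)
  expect_equal(p$shape * p$scale, live$mean, tolerance = 1e-9)
  expect_equal(p$shape * p$scale^2, live$sd^2, tolerance = 1e-9)

  expect_true(gamma_from_mean_sd(10, 0)$degenerate)
  expect_error(gamma_from_mean_sd(-1, 1), "mean")
})

test_that("lognormal parameters recover the reported interval", {
  p <- lognormal_from_ci(0.76, 0.63, 0.92)
  expect_equal(p$meanlog, log(0.76), tolerance = 1e-12)
  expect_equal(p$sdlog, log(0.92 / 0.63) / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(p$meanlog, -0.27444, tolerance = 1e-4)
  expect_equal(p$sdlog, 0.09660, tolerance = 1e-4)

  degenerate <- lognormal_from_ci(1, 1, 1)
  expect_equal(degenerate$meanlog, 0)
  expect_equal(degenerate$sdlog, 0)

  expect_error(lognormal_from_ci(0.76, 0.92, 0.63), "ci_low")
})

test_that("lognormal draws have the point estimate as median", {
  p <- lognormal_from_ci(0.76, 0.63, 0.92)
  set.seed(401)
  draws <- rlnorm(1e5, p$meanlog, p$sdlog)
  # MC error of the median ~ 1.25 * sd/sqrt(n) on the log scale
  expect_equal(median(draws), 0.76, tolerance = 2e-3)
})

test_that("Dirichlet row concentration matches the reference marginal", {
  conc <- dirichlet_from_row(c(0.899, 0.097, 0.004), 0.029, 2)
  expect_equal(conc, c(92.729, 10.006, 0.4126), tolerance = 1e-3)
  n <- sum(conc)
  # marginal of the reference component is beta with the requested moments
  expect_equal(conc[2] / n, 0.097, tolerance = 1e-12)
  expect_equal(sqrt(0.097 * (1 - 0.097) / (n + 1)), 0.029, tolerance = 1e-9)
  # marginals agree with the direct beta fit
  b <- beta_from_mean_sd(0.097, 0.029)
  expect_equal(conc[2], b$shape1, tolerance = 1e-9)
  expect_equal(n - conc[2], b$shape2, tolerance = 1e-9)

  # uniform case: effective sample size 3 on the uniform simplex point
  expect_equal(dirichlet_from_row(rep(1, 3) / 3, sqrt(1 / 18), 1),
               rep(1, 3), tolerance = 1e-12)

  expect_error(dirichlet_from_row(c(0.5, 0.6, -0.1), 0.1, 1), "non-negative")
  expect_error(dirichlet_from_row(c(0.5, 0.6, 0.2), 0.1, 1), "sum to 1")
  expect_error(dirichlet_from_row(c(0.899, 0.097, 0.004), 0.5, 2), "infeasible")
})

test_that("sampled quantities respect their domains", {
  set.seed(77)
  for (rep in 1:20) {
    row <- rdirichlet(1, dirichlet_from_row(c(0.899, 0.097, 0.004), 0.029, 2))
    expect_equal(sum(row), 1, tolerance = 1e-12)
    expect_true(all(row >= 0 & row <= 1))
  }
  cost <- sample_param(param_spec("ward", 95.05, 8.53, "gamma"), 1000)
  expect_true(all(cost >= 0))
  util <- sample_param(param_spec("u", 0.99, 0.016, "beta"), 1000)
  expect_true(all(util >= 0 & util <= 1))
})

test_that("sample_param matches its target moments and is deterministic", {
  spec <- param_spec("u_well", 0.99, 0.016, "beta")
  set.seed(42)
  draws <- sample_param(spec, 1e5)
  se <- 0.016 / sqrt(1e5)
  expect_lt(abs(mean(draws) - 0.99), 3 * se)

  expect_equal(sample_param(param_spec("fixed", 5, 0), 10), rep(5, 10))

  set.seed(9); a <- sample_param(spec, 100)
  set.seed(9); b <- sample_param(spec, 100)
  expect_identical(a, b)
})
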