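test_that("degenerate distributions collapse the PSA onto the base case", {
  cfg <- calibrated_fixture()
  base <- run_base_case(cfg)
  psa <- run_psa(cfg, iterations = 5, seed = 1, sd_scale = 0)
  for (s in base$strategy) {
    expect_equal(unname(psa$cost[, s]), rep(base$cost[base$strategy == s], 5),
                 tolerance = 1e-12)
    expect_equal(unname(psa$qaly[, s]), rep(base$qaly[base$strategy == s], 5),
                 tolerance = 1e-12)
  }
})

test_that("the PSA is reproducible from its seed", {
  cfg <- calibrated_fixture()
  a <- run_psa(cfg, iterations = 40, seed = 7)
  b <- run_psa(cfg, iterations = 40, seed = 7)
  expect_identical(a$draws, b$draws)

  # different seeds agree statistically: quadrant-2 fractions within 3
  # binomial standard errors at n = 300
  q2 <- vapply(c(101, 202), function(s) {
    psa <- run_psa(cfg, iterations = 300, seed = s)
    plane <- ce_plane_summary(psa)
    plane$quadrants$fraction[plane$quadrants$region == "quadrant_2"]
  }, 0)
  se <- sqrt(mean(q2) * (1 - mean(q2)) * 2 / 300)
  expect_lt(abs(diff(q2)), 3 * se)
})

test_that("PSA draws share parameters within an iteration", {
  cfg <- calibrated_fixture()
  psa <- run_psa(cfg, iterations = 10, seed = 3, param_log = TRUE)
  expect_length(psa$params, 10)
  # the logged joint draw satisfies every domain constraint
  for (draw in psa$params) {
    expect_true(all(abs(rowSums(draw$transitions) - 1) < 1e-9))
    expect_true(all(draw$transitions >= 0 & draw$transitions <= 1))
    expect_true(all(draw$utilities >= 0 & draw$utilities <= 1))
    expect_true(all(draw$components >= 0))
    expect_gt(draw$rr, 0)
  }
  expect_true(all(is.finite(psa$cost)))
  expect_true(all(is.finite(psa$qaly)))
})

test_that("PSA means converge to the base case as uncertainty shrinks", {
  cfg <- calibrated_fixture()
  base <- run_base_case(cfg)
  base_cost <- base$cost[base$strategy == "standard"]
  err <- vapply(c(1, 0.1, 0.01), function(sc) {
    psa <- run_psa(cfg, iterations = 150, seed = 10, sd_scale = sc)
    abs(mean(psa$cost[, "standard"]) - base_cost)
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("plane quadrants partition the iterations", {
  cfg <- calibrated_fixture()
  psa <- run_psa(cfg, iterations = 200, seed = 5)
  plane <- ce_plane_summary(psa, comparator = "standard")
  expect_equal(sum(plane$quadrants$fraction), 1, tolerance = 1e-15)
  expect_equal(sum(plane$quadrants$n), 200)
  expect_error(ce_plane_summary(psa, comparator = "nope"), "not in the PSA")

  # forced single iteration at the published increments: quadrant 2
  one <- manual_psa(cost = cbind(standard = 1452.38, feno = 1333.57),
                    qaly = cbind(standard = 0.9233, feno = 0.9395))
  q <- ce_plane_summary(one, "standard")$quadrants
  expect_equal(q$fraction[q$region == "quadrant_2"], 1)

  # exact zero increments land on the boundary
  flat <- manual_psa(cost = cbind(a = c(1, 1), b = c(1, 1)),
                     qaly = cbind(a = c(0.5, 0.5), b = c(0.5, 0.5)))
  q <- ce_plane_summary(flat, "a")$quadrants
  expect_equal(q$fraction[q$region == "boundary"], 1)
})

test_that("the mean summaries use the normal approximation of the mean", {
  cfg <- calibrated_fixture()
  psa <- run_psa(cfg, iterations = 100, seed = 2)
  g <- glance(psa)
  row <- g[g$strategy == "feno" & g$metric == "cost", ]
  x <- psa$cost[, "feno"]
  expect_equal(row$mean, mean(x), tolerance = 1e-12)
  expect_equal(row$ci_high - row$ci_low,
               2 * qnorm(0.975) * sd(x) / sqrt(100), tolerance = 1e-12)
})

test_that("acceptability probabilities normalize and handle ties", {
  cfg <- calibrated_fixture()
  psa <- run_psa(cfg, iterations = 120, seed = 6)
  curve <- ceac(psa, wtp_grid = seq(0, 40000, by = 5000))
  sums <- tapply(curve$probability, curve$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))

  # zero-variance PSA: the dominant strategy wins with probability 1
  flat <- run_psa(cfg, iterations = 3, seed = 1, sd_scale = 0)
  curve <- ceac(flat, wtp_grid = c(0, 20000, 40000))
  expect_true(all(curve$probability[curve$strategy == "feno"] == 1))

  # two iterations with opposite winners split 50/50 at every threshold
  swap <- manual_psa(cost = cbind(a = c(0, 10), b = c(10, 0)),
                     qaly = cbind(a = c(1, 1), b = c(1, 1)))
  curve <- ceac(swap, wtp_grid = c(0, 1000))
  expect_true(all(curve$probability == 0.5))

  # exact ties split equally
  tie <- manual_psa(cost = cbind(a = 5, b = 5), qaly = cbind(a = 1, b = 1))
  expect_true(all(ceac(tie, 1000)$probability == 0.5))
})

test_that("EVPI equals expected max benefit minus max expected benefit", {
  # exhaustive enumeration: two equiprobable draws with NMB (10, 0), (0, 10)
  psa <- manual_psa(cost = cbind(a = c(-10, 0), b = c(0, -10)),
                    qaly = cbind(a = c(0, 0), b = c(0, 0)), wtp = 0)
  res <- evpi(psa, wtp = 0)
  expect_equal(res$e_max_nmb, 10)
  expect_equal(res$max_e_nmb, 5)
  expect_equal(res$evpi, 5)
  expect_equal(evpi(psa, wtp = 0, population = 1000)$pevpi, 5000)

  # one strategy winning every iteration has nothing to learn
  cfg <- calibrated_fixture()
  flat <- run_psa(cfg, iterations = 4, seed = 1, sd_scale = 0)
  expect_equal(evpi(flat)$evpi, 0, tolerance = 1e-9)

  # EVPI is never negative and vanishes only with a universal winner
  psa <- run_psa(cfg, iterations = 150, seed = 12)
  res <- evpi(psa, wtp = c(0, 20000, 40000))
  expect_true(all(res$evpi >= -1e-12))
  nmb <- 20000 * psa$qaly - psa$cost
  universal <- all(nmb[, "feno"] >= nmb[, "standard"])
  expect_equal(evpi(psa, 20000)$evpi == 0, universal)
})
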