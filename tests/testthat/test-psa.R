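# Probabilistic sensitivity analysis machinery.

test_that("beta method-of-moments recovers its targets", {
  # nu = 2 at mean 1/2 gives the uniform distribution
  shape <- beta_from_moments(0.5, sqrt(0.25 / 3))
  expect_equal(unname(shape), c(1, 1), tolerance = 1e-9)

  # sampler mean matches the point estimate
  shape <- beta_from_moments(0.666, 0.01)
  set.seed(42)
  draws <- rbeta(1e5, shape[["alpha"]], shape[["beta"]])
  expect_lt(abs(mean(draws) - 0.666), 0.002)
  expect_lt(abs(sd(draws) - 0.01), 0.03 * 0.01 + 3 * 0.01 / sqrt(2 * 1e5))

  # infeasible moments name the parameter
  expect_error(beta_from_moments(0.5, 0.6, name = "p_tolac_success"),
               regexp = "p_tolac_success")
  expect_error(beta_from_moments(0, 0.1), class = "cea_validation_error")
})

test_that("parameter draws respect spreads, supports and the master seed", {
  specs <- default_psa_specs(base_config)
  expect_gt(length(specs), 25)

  # zero spreads return the base configuration unchanged
  specs0 <- lapply(specs, function(s) { s$spread <- 0; s })
  expect_equal(draw_parameters(base_config, specs0, seed = 1), base_config)

  # identical seeds give identical configurations, different seeds differ
  d1 <- draw_parameters(base_config, specs, seed = 9)
  d2 <- draw_parameters(base_config, specs, seed = 9)
  d3 <- draw_parameters(base_config, specs, seed = 10)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  expect_silent(validate_config(d1))

  # a sampled cost stream reproduces its nominal spread
  spec <- psa_spec("deliveries.ercd.consumables", "normal", 130.68,
                   0.1 * 130.68, "cost")
  set.seed(3)
  x <- tolaccea:::draw_values(spec, 1e5)
  expect_true(all(x >= 0))
  expect_lt(abs(sd(x) - spec$spread) / spec$spread, 0.03)

  # disutility draws are clipped to the unit interval
  dspec <- psa_spec("profiles.ercd.disutility_per_day", "normal", 0.99, 0.3,
                    "disutility")
  set.seed(4)
  y <- tolaccea:::draw_values(dspec, 1e4)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("zero-spread PSA collapses exactly to the deterministic result", {
  specs0 <- lapply(default_psa_specs(base_config),
                   function(s) { s$spread <- 0; s })
  psa <- run_psa(base_config, specs0, n_iter = 3, seed = 5)
  ev <- evaluate_tree(base_config)
  expect_identical(unique(psa$iterations$cost_tolac), ev$tolac$expected_cost)
  expect_identical(unique(psa$iterations$qaly_tolac), ev$tolac$expected_qaly)
  expect_identical(unique(psa$iterations$cost_ercd), ev$ercd$expected_cost)
  expect_identical(unique(psa$iterations$qaly_ercd), ev$ercd$expected_qaly)
})

test_that("seeded runs are bit-reproducible and seeds agree within MC error", {
  p1 <- run_psa(base_config, n_iter = 300, seed = 7)
  p2 <- run_psa(base_config, n_iter = 300, seed = 7)
  expect_identical(p1$iterations, p2$iterations)

  p3 <- run_psa(base_config, n_iter = 300, seed = 8)
  for (col in c("delta_cost", "delta_qaly")) {
    a <- p1$iterations[[col]]
    b <- p3$iterations[[col]]
    se <- sqrt(sd(a)^2 / length(a) + sd(b)^2 / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se)
  }
})

test_that("quadrant labels follow the documented axis convention", {
  expect_identical(quadrant(-2200, 0.14), "SE")
  expect_identical(quadrant(1, -0.1), "NW")
  expect_identical(quadrant(500, 0.1), "NE")
  expect_identical(quadrant(-500, -0.1), "SW")
  # exact zeros resolve against the intervention: west and north
  expect_identical(quadrant(0, 0), "NW")
  expect_identical(quadrant(-1, 0), "SW")
  expect_identical(quadrant(0, 0.1), "NE")
})

test_that("cost-effectiveness probability is the NMB recount and feeds the CEAC", {
  psa <- run_psa(base_config, n_iter = 200, seed = 3)

  # brute-force recount of iterations with positive net monetary benefit
  it <- psa$iterations
  for (lambda in c(0, 20000, 45000, 100000)) {
    manual <- sum(lambda * it$delta_qaly - it$delta_cost > 0) / nrow(it)
    expect_equal(prob_cost_effective(psa, lambda), manual)
  }

  # an all-south-east cloud is certainly cost-effective at any threshold
  if (all(it$quadrant == "SE")) {
    expect_equal(prob_cost_effective(psa, 1), 1)
    expect_equal(prob_cost_effective(psa, 1e6), 1)
  }

  curve <- ceac(psa, c(0, 45000, 90000))
  expect_identical(nrow(curve), 3L)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_error(ceac(psa, numeric(0)), class = "cea_validation_error")
})
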