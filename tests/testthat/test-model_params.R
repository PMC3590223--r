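# Parameter containers, validation, and the published base case.

test_that("base case reproduces every published table value field-for-field", {
  cfg <- base_config

  # Disutility profiles: QWB components, per-day total, duration (days).
  prof_expect <- list(
    tolac_unassisted = c(0.256, 0.031, 0.072, 0.054, 0.41, 7),
    emergency_cs     = c(0.424, 0.031, 0.072, 0.054, 0.58, 21),
    ercd             = c(0.424, 0.031, 0.072, 0.054, 0.58, 21)
  )
  for (nm in names(prof_expect)) {
    p <- cfg$profiles[[nm]]
    expect_equal(unlist(p[c("cpx", "mob", "pac", "sac", "disutility_per_day",
                            "duration_days")]),
                 prof_expect[[nm]], ignore_attr = TRUE)
  }
  comp_prof_expect <- list(
    uterine_rupture   = c(0.424, 0.031, 0.072, 0.054, 0.58, 21),
    hysterectomy      = c(0.424, 0.031, 0.072, 0.054, 0.58, 21),
    operative_injury  = c(0.369, 0.031, 0.072, 0.054, 0.53, 21),
    blood_transfusion = c(0.256, 0.031, 0.072, 0.054, 0.41, 7),
    endometritis      = c(0.160, 0.089, 0.072, 0.054, 0.38, 14)
  )
  for (nm in names(comp_prof_expect)) {
    p <- cfg$complications[[nm]]$profile
    expect_equal(unlist(p[c("cpx", "mob", "pac", "sac", "disutility_per_day",
                            "duration_days")]),
                 comp_prof_expect[[nm]], ignore_attr = TRUE)
  }

  # Delivery cost specifications.
  del_expect <- list(  # consumables, staff, LOS, DRG rate
    tolac_unassisted = c(104.44, 523.50, 2, NA),
    tolac_ventouse   = c(180.34, 573.75, 3, 883),
    emergency_cs     = c(173.06, 767.33, 5, 1161),
    ercd             = c(130.68, 481.33, 5, 1161)
  )
  for (nm in names(del_expect)) {
    d <- cfg$deliveries[[nm]]
    expect_equal(c(d$consumables, d$staff, d$baseline_los_days,
                   d$drg_bed_day_rate), del_expect[[nm]])
    expect_identical(d$shared_days, 2L)
  }
  expect_equal(cfg$deliveries$tolac_unassisted$complication_bed_day_rate, 883)

  # Complication add-on costs and lengths of stay.
  expect_equal(
    vapply(cfg$complications, `[[`, numeric(1), "addon_cost"),
    c(uterine_rupture = 1235.33, hysterectomy = 905.94,
      operative_injury = 355.25, blood_transfusion = 596.63,
      endometritis = 49.50))
  expect_equal(
    vapply(cfg$complications, `[[`, integer(1), "los_days"),
    c(uterine_rupture = 5L, hysterectomy = 11L, operative_injury = 6L,
      blood_transfusion = 5L, endometritis = NA_integer_))

  # Branch probabilities (morbidity at full cohort-table precision).
  expect_equal(cfg$probs$p_tolac_success, 0.666)
  expect_equal(cfg$probs$p_ventouse_given_success, 0.13)
  expect_equal(unname(cfg$probs$p_morbidity),
               c(124 / 5797, 19 / 867, 465 / 3336, 290 / 10000))
  expect_equal(unname(cfg$probs$p_death), c(0, 0, 0, 1e-4))

  # Conditional complication weights from the cohort counts.
  expect_equal(unname(cfg$morbidity_weights$tolac_unassisted),
               c(21, 5, 4, 19, 76) / 125)
  expect_equal(unname(cfg$morbidity_weights$ercd),
               c(0, 11, 56, 27, 196) / 290)

  # Frame parameters.
  expect_identical(cfg$horizon_days, 42L)
  expect_identical(cfg$cohort_n, 10000L)
  expect_equal(cfg$wtp_threshold, 45000)
})

test_that("validation rejects out-of-range and inconsistent parameters", {
  cfg <- base_config

  # probability bound
  bad <- cfg
  bad$probs$p_ventouse_given_success <- 1.3
  expect_error(do.call(branch_probabilities, unclass(bad$probs)),
               class = "cea_validation_error")

  # QWB components must sum to the per-day total within 0.005
  expect_error(disutility_profile(0.3, 0.1, 0.1, 0.1, 0.41, 7),
               class = "cea_validation_error")
  expect_silent(disutility_profile(0.160, 0.089, 0.072, 0.054, 0.38, 14))

  # chance-node closure is a distinct error class
  expect_error(
    branch_probabilities(0.5, 0.1,
                         p_morbidity = c(tolac_unassisted = 0.6,
                                         tolac_ventouse = 0, emergency_cs = 0,
                                         ercd = 0),
                         p_death = c(tolac_unassisted = 0.6,
                                     tolac_ventouse = 0, emergency_cs = 0,
                                     ercd = 0)),
    class = "cea_probability_error")

  # morbidity weights must sum to 1 (within printed rounding)
  bad <- cfg
  bad$morbidity_weights$ercd <- bad$morbidity_weights$ercd * 0.5
  expect_error(validate_config(bad), class = "cea_weight_error")

  # negative money
  expect_error(delivery_cost_spec(-1, 100, 2), class = "cea_validation_error")

  # missing field named in the error
  expect_error(validate_config(unclass(cfg)[-1]), regexp = "horizon_days")
})

test_that("configurations round-trip through YAML unchanged", {
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(base_config, path)
  reread <- load_config(path)
  expect_equal(reread, base_config, tolerance = 1e-9)

  # the bundled file is the base case
  bundled <- system.file("extdata", "paper_base_case.yaml", package = "tolaccea")
  expect_true(nzchar(bundled))
  expect_equal(load_config(bundled), base_config, tolerance = 1e-9)

  # corrupt configs fail with a named validation error
  txt <- readLines(path)
  writeLines(sub("p_ventouse_given_success: 0.13",
                 "p_ventouse_given_success: 1.3", txt, fixed = TRUE), path)
  expect_error(load_config(path), class = "cea_validation_error")
})

test_that("any validated configuration yields finite expected values", {
  for (seed in 1:10) {
    cfg <- random_config(seed = seed, scale = 0.2)
    expect_silent(validate_config(cfg))
    ev <- evaluate_tree(cfg)
    vals <- c(ev$tolac$expected_cost, ev$tolac$expected_qaly,
              ev$ercd$expected_cost, ev$ercd$expected_qaly)
    expect_true(all(is.finite(vals)))
    expect_true(all(c(ev$tolac$expected_qaly, ev$ercd$expected_qaly) >= 0))
    expect_true(all(c(ev$tolac$expected_qaly, ev$ercd$expected_qaly) <= 1))
  }
})
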