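# Micro-costing: bottom-up components plus DRG bed-days beyond shared stay.

test_that("all four published per-woman delivery costs are reproduced exactly", {
  totals <- vapply(base_config$deliveries,
                   function(d) delivery_cost(d)$total, numeric(1))
  expect_equal(unname(totals), c(627.94, 1637.09, 4423.39, 4095.01))

  # the breakdown components recompose the totals
  b <- delivery_cost(base_config$deliveries$emergency_cs)
  expect_equal(b$total,
               b$consumables + b$staff + b$bed_day_addon + b$complication_addon)
  expect_equal(b$bed_day_addon, 3 * 1161)
})

test_that("bed-day billing handles missing DRG rates and zero excess", {
  # stay equal to shared days, no rate: zero add-on, no error
  b <- delivery_cost(delivery_cost_spec(100, 200, 2, NA_real_, shared_days = 2))
  expect_equal(b$bed_day_addon, 0)
  expect_equal(b$total, 300)

  # excess days without a rate is an explicit error (at construction)
  expect_error(delivery_cost_spec(100, 200, 4, NA_real_, shared_days = 2),
               class = "cea_validation_error")
})

test_that("complication costs add the printed add-on plus extended bed-days", {
  ercd <- base_config$deliveries$ercd
  comps <- base_config$complications

  # endometritis: pure add-on, no stay extension
  expect_equal(pathway_cost_with_complication(ercd, comps$endometritis)$total,
               4095.01 + 49.50)
  # hysterectomy after ERCD: 11-day stay, 6 days beyond the 5-day baseline
  expect_equal(pathway_cost_with_complication(ercd, comps$hysterectomy)$total,
               4095.01 + 905.94 + 6 * 1161)
  # uterine rupture after ERCD: 5-day stay does not exceed the baseline
  expect_equal(pathway_cost_with_complication(ercd, comps$uterine_rupture)$total,
               4095.01 + 1235.33)
  # vaginal pathway bills extensions at the assisted-delivery bed-day rate
  ua <- base_config$deliveries$tolac_unassisted
  expect_equal(pathway_cost_with_complication(ua, comps$hysterectomy)$total,
               627.94 + 905.94 + 9 * 883)

  # a free complication that fits within the baseline changes nothing
  nil <- complication_spec("endometritis", 0, NA,
                           base_config$complications$endometritis$profile)
  expect_equal(pathway_cost_with_complication(ercd, nil)$total,
               delivery_cost(ercd)$total)
})

test_that("composite morbidity cost is the weighted mean of pathway costs", {
  ercd <- base_config$deliveries$ercd
  comps <- base_config$complications
  cx <- cea_complications()

  # degenerate weights collapse to a single complication
  w1 <- setNames(c(0, 1, 0, 0, 0), cx)
  expect_equal(composite_morbidity_cost(w1, comps, ercd),
               pathway_cost_with_complication(ercd, comps$hysterectomy)$total)

  # published ERCD weights: brute-force weighted sum written out longhand
  w <- base_config$morbidity_weights$ercd
  manual <- sum(vapply(cx, function(nm) {
    w[[nm]] * pathway_cost_with_complication(ercd, comps[[nm]])$total
  }, numeric(1)))
  expect_equal(composite_morbidity_cost(w, comps, ercd), manual)

  # equal weight on two identical complications equals either one alone
  twin <- comps
  twin$hysterectomy <- complication_spec("hysterectomy", 49.50, NA,
                                         comps$endometritis$profile)
  w2 <- setNames(c(0, 0.5, 0, 0, 0.5), cx)
  expect_equal(composite_morbidity_cost(w2, twin, ercd),
               pathway_cost_with_complication(ercd, twin$endometritis)$total)

  # weight-sum violation is rejected
  expect_error(composite_morbidity_cost(w * 0.8, comps, ercd),
               class = "cea_weight_error")
})

test_that("delivery cost is monotone and composites stay within bounds", {
  base <- delivery_cost(base_config$deliveries$ercd)$total
  bump <- function(field, by) {
    d <- unclass(base_config$deliveries$ercd)
    d[[field]] <- d[[field]] + by
    delivery_cost(do.call(delivery_cost_spec, d))$total
  }
  expect_gte(bump("consumables", 10), base)
  expect_gte(bump("staff", 10), base)
  expect_gte(bump("baseline_los_days", 1), base)
  expect_gte(bump("drg_bed_day_rate", 50), base)

  for (seed in 1:5) {
    cfg <- random_config(seed = seed, scale = 0.3)
    for (p in cea_pathways()) {
      d <- cfg$deliveries[[p]]
      totals <- vapply(cea_complications(), function(nm) {
        pathway_cost_with_complication(d, cfg$complications[[nm]])$total
      }, numeric(1))
      comp <- composite_morbidity_cost(cfg$morbidity_weights[[p]],
                                       cfg$complications, d)
      expect_gte(comp, min(totals))
      expect_lte(comp, max(totals))
    }
  }
})
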