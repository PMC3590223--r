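## Micro-costing of delivery pathways and complications.
##
## Bottom-up components (consumables, staff) are summed with a top-down
## per-diem element: the pathway's DRG bed-day rate is billed for every day
## of stay beyond the days shared by both arms. Complications add their
## printed add-on cost, plus bed-days for any stay beyond the delivery
## pathway's own baseline.

new_cost_breakdown <- function(consumables, staff, bed_day_addon,
                               complication_addon) {
  structure(
    list(consumables = consumables, staff = staff,
         bed_day_addon = bed_day_addon,
         complication_addon = complication_addon,
         total = consumables + staff + bed_day_addon + complication_addon),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cost_breakdown> consumables %.2f + staff %.2f + bed-days %.2f + complication %.2f = EUR %.2f\n",
    x$consumables, x$staff, x$bed_day_addon, x$complication_addon, x$total))
  invisible(x)
}

#' Total per-woman cost of an uncomplicated delivery pathway
#'
#' `total = consumables + staff + max(0, baseline_los_days - shared_days) *
#' drg_bed_day_rate`. A missing DRG rate is an error only when there are
#' excess days to bill.
#'
#' @param spec A [delivery_cost_spec()].
#' @return A `cost_breakdown` with components and `total` (EUR, full
#'   precision; round only for reporting).
#' @examples
#' ercd <- delivery_cost_spec(130.68, 481.33, 5, 1161)
#' delivery_cost(ercd)$total # 4095.01
#' @export
delivery_cost <- function(spec) {
  if (!inherits(spec, "delivery_cost_spec")) {
    abort_validation("`spec` must be a delivery_cost_spec")
  }
  excess <- max(0L, spec$baseline_los_days - spec$shared_days)
  if (excess > 0L && is.na(spec$drg_bed_day_rate)) {
    abort_validation(sprintf(
      "pathway has %d excess bed-day(s) but no drg_bed_day_rate", excess))
  }
  addon <- if (excess > 0L) excess * spec$drg_bed_day_rate else 0
  new_cost_breakdown(spec$consumables, spec$staff, addon, 0)
}

# Bed-day rate used to bill complication-extended stays for this pathway.
complication_rate <- function(delivery) {
  if (!is.na(delivery$drg_bed_day_rate)) delivery$drg_bed_day_rate
  else delivery$complication_bed_day_rate
}

#' Per-woman cost of a delivery pathway with a complication
#'
#' The complication contributes its add-on cost ("cost excluding mode of
#' delivery") plus, when its length of stay exceeds the delivery pathway's
#' baseline stay, the excess days billed at the pathway's bed-day rate. A
#' complication with `los_days = NA` never extends the stay.
#'
#' @param delivery A [delivery_cost_spec()].
#' @param comp A [complication_spec()].
#' @return A `cost_breakdown`; `bed_day_addon` includes both the delivery's
#'   beyond-shared days and the complication's beyond-baseline days.
#' @export
pathway_cost_with_complication <- function(delivery, comp) {
  if (!inherits(comp, "complication_spec")) {
    abort_validation("`comp` must be a complication_spec")
  }
  base <- delivery_cost(delivery)
  extra_days <- if (is.na(comp$los_days)) 0L
                else max(0L, comp$los_days - delivery$baseline_los_days)
  extra_bed <- 0
  if (extra_days > 0L) {
    rate <- complication_rate(delivery)
    if (is.na(rate)) {
      abort_validation(sprintf(
        "complication %s extends the stay by %d day(s) but the pathway has no bed-day rate",
        comp$name, extra_days))
    }
    extra_bed <- extra_days * rate
  }
  new_cost_breakdown(base$consumables, base$staff,
                     base$bed_day_addon + extra_bed, comp$addon_cost)
}

#' Expected cost of the composite morbidity state
#'
#' The five complications are pooled into one health state; its cost is the
#' conditional-weight-weighted mean of the per-complication pathway costs.
#'
#' @param weights Named numeric vector over [cea_complications()], summing to
#'   1 (within 0.02).
#' @param comps Named list of [complication_spec()].
#' @param delivery A [delivery_cost_spec()].
#' @return Expected cost in EUR.
#' @export
composite_morbidity_cost <- function(weights, comps, delivery) {
  weights <- unlist(weights)[cea_complications()]
  check_prob(weights, "weights")
  if (abs(sum(weights) - 1) > 0.02) {
    abort_validation(sprintf("complication weights sum to %.4f, not 1",
                             sum(weights)), class = "cea_weight_error")
  }
  totals <- vapply(cea_complications(), function(nm) {
    pathway_cost_with_complication(delivery, comps[[nm]])$total
  }, numeric(1))
  sum(weights * totals)
}

#' Cost table across all pathways and complications
#'
#' A long-format reconstruction of the published cost table: one row per
#' pathway for the uncomplicated delivery, and one row per pathway x
#' complication combination.
#'
#' @param config A validated `cea_config`.
#' @return A data.frame with columns `pathway`, `complication` (`"none"` for
#'   the uncomplicated delivery), `consumables`, `staff`, `bed_day_addon`,
#'   `complication_addon`, `total` (EUR, 2 dp).
#' @export
cost_table <- function(config) {
  config <- validate_config(config)
  rows <- list()
  for (p in cea_pathways()) {
    d <- config$deliveries[[p]]
    b <- delivery_cost(d)
    rows[[length(rows) + 1L]] <- data.frame(
      pathway = p, complication = "none",
      consumables = b$consumables, staff = b$staff,
      bed_day_addon = b$bed_day_addon, complication_addon = 0,
      total = b$total)
    for (cc in cea_complications()) {
      bc <- pathway_cost_with_complication(d, config$complications[[cc]])
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = p, complication = cc,
        consumables = bc$consumables, staff = bc$staff,
        bed_day_addon = bc$bed_day_addon,
        complication_addon = bc$complication_addon, total = bc$total)
    }
  }
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 2)
  out
}
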