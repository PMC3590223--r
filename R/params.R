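## Canonical labels used throughout the model ---------------------------------

#' Delivery pathways and maternal complications in the model
#'
#' `cea_pathways()` returns the four terminal delivery pathways of the
#' decision tree: unassisted vaginal delivery after a successful trial of
#' labour, ventouse (assisted vaginal) delivery after a successful trial,
#' emergency caesarean section after a failed trial, and elective repeat
#' caesarean delivery. `cea_complications()` returns the five maternal
#' complications pooled into the composite morbidity state.
#'
#' @return A character vector of canonical names.
#' @export
cea_pathways <- function() {
  c("tolac_unassisted", "tolac_ventouse", "emergency_cs", "ercd")
}

#' @rdname cea_pathways
#' @export
cea_complications <- function() {
  c("uterine_rupture", "hysterectomy", "operative_injury",
    "blood_transfusion", "endometritis")
}

## Classed validation errors ---------------------------------------------------

abort_validation <- function(msg, class = "cea_validation_error") {
  stop(structure(
    class = c(class, "cea_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort_validation(sprintf("`%s` must be a probability in [0, 1] (got %s)",
                             what, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_money <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort_validation(sprintf("`%s` must be a single non-negative amount (EUR)", what))
  }
  invisible(x)
}

check_count <- function(x, what, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == trunc(x) && x >= if (positive) 1 else 0
  if (!ok) {
    abort_validation(sprintf("`%s` must be a%s integer day/count", what,
                             if (positive) " positive" else " non-negative"))
  }
  invisible(as.integer(x))
}

require_fields <- function(x, fields, where) {
  missing <- setdiff(fields, names(x))
  if (length(missing)) {
    abort_validation(sprintf("%s: missing field(s) %s", where,
                             paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(x)
}

## Domain types ----------------------------------------------------------------

#' Disutility profile for a delivery pathway or complication
#'
#' A per-day decrement from perfect health with a finite duration, decomposed
#' into the four Quality of Well-Being (QWB) dimensions: symptom complexes
#' (`cpx`), mobility (`mob`), physical activity (`pac`) and social activity
#' (`sac`). The per-day disutility must equal the sum of the four components
#' within a rounding tolerance of 0.005, matching how published QWB tables
#' round the total to two decimals.
#'
#' @param cpx,mob,pac,sac QWB component weights, each in \[0, 1\].
#' @param disutility_per_day Total per-day disutility in \[0, 1\].
#' @param duration_days Integer number of days the decrement lasts (>= 0).
#'   Durations longer than the analysis horizon are clipped at integration
#'   time, not here.
#' @return An object of class `disutility_profile`.
#' @examples
#' disutility_profile(0.256, 0.031, 0.072, 0.054, 0.41, 7)
#' @export
disutility_profile <- function(cpx, mob, pac, sac, disutility_per_day,
                               duration_days) {
  for (w in c(cpx = cpx, mob = mob, pac = pac, sac = sac)) check_prob(w, "QWB component")
  check_prob(disutility_per_day, "disutility_per_day")
  duration_days <- check_count(duration_days, "duration_days")
  if (abs((cpx + mob + pac + sac) - disutility_per_day) > 0.005 + 1e-9) {
    abort_validation(sprintf(
      "disutility_per_day (%.3f) must equal cpx+mob+pac+sac (%.3f) within 0.005",
      disutility_per_day, cpx + mob + pac + sac))
  }
  structure(
    list(cpx = cpx, mob = mob, pac = pac, sac = sac,
         disutility_per_day = disutility_per_day,
         duration_days = duration_days),
    class = "disutility_profile"
  )
}

# Rescale the QWB components so the profile totals `new_total`, preserving the
# component proportions (used when a PSA draw moves the per-day disutility).
rescale_profile <- function(profile, new_total) {
  new_total <- min(max(new_total, 0), 1)
  if (new_total == profile$disutility_per_day) return(profile)
  comp_sum <- profile$cpx + profile$mob + profile$pac + profile$sac
  if (comp_sum > 0) {
    f <- new_total / comp_sum  # components then sum exactly to new_total
    comps <- c(profile$cpx, profile$mob, profile$pac, profile$sac) * f
  } else {
    comps <- rep(new_total / 4, 4)
  }
  disutility_profile(comps[1], comps[2], comps[3], comps[4], new_total,
                     profile$duration_days)
}

#' Micro-costed delivery pathway specification
#'
#' Bottom-up cost components of one delivery pathway, plus the inputs for the
#' top-down length-of-stay rule: a DRG (diagnosis-related group) cost per
#' bed-day is billed for each day of stay beyond the `shared_days` common to
#' every pathway (two days in the base case).
#'
#' @param consumables Medical consumables and pharmaceuticals, EUR.
#' @param staff Staff costs, EUR.
#' @param baseline_los_days Median length of stay for the pathway, days.
#' @param drg_bed_day_rate DRG cost per bed-day, EUR; `NA` when no per-diem
#'   rate applies (the unassisted vaginal pathway, whose stay equals the
#'   shared days).
#' @param shared_days Days of stay common to all pathways and therefore not
#'   billed per-diem.
#' @param complication_bed_day_rate Bed-day rate used when a complication
#'   extends the stay and `drg_bed_day_rate` is `NA`; defaults to
#'   `drg_bed_day_rate`.
#' @return An object of class `delivery_cost_spec`.
#' @export
delivery_cost_spec <- function(consumables, staff, baseline_los_days,
                               drg_bed_day_rate = NA_real_, shared_days = 2L,
                               complication_bed_day_rate = drg_bed_day_rate) {
  check_money(consumables, "consumables")
  check_money(staff, "staff")
  baseline_los_days <- check_count(baseline_los_days, "baseline_los_days")
  shared_days <- check_count(shared_days, "shared_days")
  if (!is.na(drg_bed_day_rate)) check_money(drg_bed_day_rate, "drg_bed_day_rate")
  if (!is.na(complication_bed_day_rate)) {
    check_money(complication_bed_day_rate, "complication_bed_day_rate")
  }
  if (baseline_los_days > shared_days && is.na(drg_bed_day_rate)) {
    abort_validation(
      "baseline_los_days exceeds shared_days but no drg_bed_day_rate is given")
  }
  structure(
    list(consumables = consumables, staff = staff,
         baseline_los_days = baseline_los_days,
         drg_bed_day_rate = drg_bed_day_rate,
         shared_days = shared_days,
         complication_bed_day_rate = complication_bed_day_rate),
    class = "delivery_cost_spec"
  )
}

#' Maternal complication specification
#'
#' An add-on cost ("cost excluding mode of delivery"), a complication length
#' of stay, and a disutility profile. `los_days = NA` means the complication
#' does not extend the stay beyond the delivery pathway's baseline (used for
#' endometritis, which is priced purely as an add-on).
#'
#' @param name One of [cea_complications()].
#' @param addon_cost Add-on cost excluding mode of delivery, EUR.
#' @param los_days Complication length of stay in days, or `NA` for "no
#'   extension beyond the pathway baseline".
#' @param profile A [disutility_profile()].
#' @return An object of class `complication_spec`.
#' @export
complication_spec <- function(name, addon_cost, los_days, profile) {
  if (!is.character(name) || length(name) != 1L || !name %in% cea_complications()) {
    abort_validation(sprintf("`name` must be one of: %s",
                             paste(cea_complications(), collapse = ", ")))
  }
  check_money(addon_cost, "addon_cost")
  if (!is.na(los_days)) los_days <- check_count(los_days, "los_days")
  if (!inherits(profile, "disutility_profile")) {
    abort_validation(sprintf("`profile` for %s must be a disutility_profile", name))
  }
  structure(
    list(name = name, addon_cost = addon_cost,
         los_days = if (is.na(los_days)) NA_integer_ else los_days,
         profile = profile),
    class = "complication_spec"
  )
}

#' Branch probabilities of the decision tree
#'
#' @param p_tolac_success Probability that a trial of labour succeeds
#'   (vaginal delivery).
#' @param p_ventouse_given_success Probability of a ventouse (assisted)
#'   delivery given a successful trial.
#' @param p_morbidity Named numeric vector over [cea_pathways()]: probability
#'   of any maternal morbidity given the terminal pathway.
#' @param p_death Named numeric vector over [cea_pathways()]: probability of
#'   maternal death given the terminal pathway.
#' @return An object of class `branch_probabilities`.
#' @export
branch_probabilities <- function(p_tolac_success, p_ventouse_given_success,
                                 p_morbidity, p_death) {
  check_prob(p_tolac_success, "p_tolac_success")
  check_prob(p_ventouse_given_success, "p_ventouse_given_success")
  pw <- cea_pathways()
  for (nm in c("p_morbidity", "p_death")) {
    v <- get(nm)
    if (!all(pw %in% names(v))) {
      abort_validation(sprintf("`%s` must be named over all pathways: %s",
                               nm, paste(pw, collapse = ", ")))
    }
  }
  p_morbidity <- unlist(p_morbidity)[pw]
  p_death <- unlist(p_death)[pw]
  check_prob(p_morbidity, "p_morbidity")
  check_prob(p_death, "p_death")
  bad <- p_morbidity + p_death > 1 + 1e-12
  if (any(bad)) {
    abort_validation(sprintf(
      "probability closure failure: p_morbidity + p_death > 1 for %s",
      paste(pw[bad], collapse = ", ")), class = "cea_probability_error")
  }
  structure(
    list(p_tolac_success = p_tolac_success,
         p_ventouse_given_success = p_ventouse_given_success,
         p_morbidity = p_morbidity, p_death = p_death),
    class = "branch_probabilities"
  )
}

#' Assemble and validate a full model configuration
#'
#' The configuration bundles every input of the decision-analytic model:
#' the analysis horizon, cohort size and willingness-to-pay threshold; the
#' branch probabilities; per-pathway delivery cost specifications and
#' disutility profiles; the five complication specifications; and the
#' conditional weights that pool the complications into one composite
#' morbidity state per pathway (each pathway's weights must sum to 1 within
#' 0.02, the slack printed percentage columns can accumulate).
#'
#' @param horizon_days Analysis horizon in days (default 42, six weeks).
#' @param cohort_n Hypothetical cohort size per arm.
#' @param wtp_threshold Willingness-to-pay threshold, EUR per QALY.
#' @param qaly_basis `"horizon"` (average utility over the horizon) or
#'   `"annual"` (horizon utility plus full health to day 365, divided by 365).
#' @param combine_rule How a delivery and a complication disutility combine:
#'   `"max_disutility"` (per-day worst state) or `"additive_capped"`.
#' @param probs A [branch_probabilities()] object.
#' @param deliveries Named list of [delivery_cost_spec()] over [cea_pathways()].
#' @param profiles Named list of [disutility_profile()] over [cea_pathways()].
#' @param complications Named list of [complication_spec()] over
#'   [cea_complications()].
#' @param morbidity_weights Named list over pathways; each element a named
#'   numeric vector of conditional complication weights summing to 1.
#' @return A validated object of class `cea_config`.
#' @seealso [default_paper_config()], [load_config()], [save_config()]
#' @export
model_config <- function(horizon_days = 42L, cohort_n = 10000L,
                         wtp_threshold = 45000,
                         qaly_basis = c("horizon", "annual"),
                         combine_rule = c("max_disutility", "additive_capped"),
                         probs, deliveries, profiles, complications,
                         morbidity_weights) {
  config <- structure(
    list(horizon_days = horizon_days, cohort_n = cohort_n,
         wtp_threshold = wtp_threshold,
         qaly_basis = match.arg(qaly_basis),
         combine_rule = match.arg(combine_rule),
         probs = probs, deliveries = deliveries, profiles = profiles,
         complications = complications,
         morbidity_weights = morbidity_weights),
    class = "cea_config"
  )
  validate_config(config)
}

#' Validate a model configuration
#'
#' Checks every structural invariant: field presence and types, probability
#' bounds and closure at each chance node, QWB component sums, money signs,
#' and per-pathway conditional morbidity weights summing to 1 (within 0.02).
#' Errors carry class `cea_validation_error`; probability-closure failures
#' additionally carry `cea_probability_error`.
#'
#' @param config A `cea_config` (or plain list with the same fields).
#' @return The validated config, invisibly classed as `cea_config`.
#' @export
validate_config <- function(config) {
  require_fields(config, c("horizon_days", "cohort_n", "wtp_threshold",
                           "qaly_basis", "combine_rule", "probs", "deliveries",
                           "profiles", "complications", "morbidity_weights"),
                 "config")
  config$horizon_days <- check_count(config$horizon_days, "horizon_days", positive = TRUE)
  config$cohort_n <- check_count(config$cohort_n, "cohort_n", positive = TRUE)
  check_money(config$wtp_threshold, "wtp_threshold")
  if (!config$qaly_basis %in% c("horizon", "annual")) {
    abort_validation("`qaly_basis` must be 'horizon' or 'annual'")
  }
  if (!config$combine_rule %in% c("max_disutility", "additive_capped")) {
    abort_validation("`combine_rule` must be 'max_disutility' or 'additive_capped'")
  }
  if (!inherits(config$probs, "branch_probabilities")) {
    config$probs <- do.call(branch_probabilities, unclass(config$probs))
  }
  pw <- cea_pathways()
  cx <- cea_complications()
  require_fields(config$deliveries, pw, "deliveries")
  require_fields(config$profiles, pw, "profiles")
  require_fields(config$complications, cx, "complications")
  require_fields(config$morbidity_weights, pw, "morbidity_weights")
  for (p in pw) {
    if (!inherits(config$deliveries[[p]], "delivery_cost_spec")) {
      abort_validation(sprintf("deliveries$%s is not a delivery_cost_spec", p))
    }
    if (!inherits(config$profiles[[p]], "disutility_profile")) {
      abort_validation(sprintf("profiles$%s is not a disutility_profile", p))
    }
    w <- unlist(config$morbidity_weights[[p]])
    if (!all(cx %in% names(w))) {
      abort_validation(sprintf("morbidity_weights$%s must be named over: %s",
                               p, paste(cx, collapse = ", ")))
    }
    w <- w[cx]
    check_prob(w, sprintf("morbidity_weights$%s", p))
    if (abs(sum(w) - 1) > 0.02) {
      abort_validation(sprintf(
        "morbidity_weights$%s sum to %.4f, not 1 (tolerance 0.02)", p, sum(w)),
        class = "cea_weight_error")
    }
    config$morbidity_weights[[p]] <- w
  }
  for (cc in cx) {
    if (!inherits(config$complications[[cc]], "complication_spec")) {
      abort_validation(sprintf("complications$%s is not a complication_spec", cc))
    }
  }
  invisible(config)
}

## The published base case -----------------------------------------------------

#' The published base-case model configuration
#'
#' Returns the model exactly as printed in the source study's tables: QWB
#' disutility profiles and durations; micro-costed delivery pathway costs
#' with DRG bed-day rates and lengths of stay; complication add-on costs and
#' lengths of stay; branch probabilities (66.6% trial-of-labour success, 13%
#' ventouse given success, per-pathway morbidity proportions stored at full
#' precision from the 10,000-woman cohort table, 1/10,000 maternal mortality
#' in the ERCD arm only); conditional complication weights; a six-week
#' horizon; and a willingness-to-pay threshold of EUR 45,000 per QALY.
#'
#' Two published gaps are filled by documented package choices (see the
#' methods vignette): the ventouse delivery is assigned the caesarean
#' disutility profile (0.58 over 21 days), and endometritis extends no stay
#' beyond the pathway baseline.
#'
#' @return A validated `cea_config`.
#' @examples
#' config <- default_paper_config()
#' config$probs$p_tolac_success
#' @export
default_paper_config <- function() {
  prof_vaginal <- disutility_profile(0.256, 0.031, 0.072, 0.054, 0.41, 7)
  prof_cs      <- disutility_profile(0.424, 0.031, 0.072, 0.054, 0.58, 21)
  prof_opinj   <- disutility_profile(0.369, 0.031, 0.072, 0.054, 0.53, 21)
  prof_endo    <- disutility_profile(0.160, 0.089, 0.072, 0.054, 0.38, 14)

  deliveries <- list(
    tolac_unassisted = delivery_cost_spec(104.44, 523.50, 2, NA_real_,
                                          shared_days = 2,
                                          complication_bed_day_rate = 883),
    tolac_ventouse   = delivery_cost_spec(180.34, 573.75, 3, 883),
    emergency_cs     = delivery_cost_spec(173.06, 767.33, 5, 1161),
    ercd             = delivery_cost_spec(130.68, 481.33, 5, 1161)
  )

  profiles <- list(
    tolac_unassisted = prof_vaginal,
    tolac_ventouse   = prof_cs,   # package choice: no published ventouse row
    emergency_cs     = prof_cs,
    ercd             = prof_cs
  )

  complications <- list(
    uterine_rupture   = complication_spec("uterine_rupture", 1235.33, 5, prof_cs),
    hysterectomy      = complication_spec("hysterectomy", 905.94, 11, prof_cs),
    operative_injury  = complication_spec("operative_injury", 355.25, 6, prof_opinj),
    blood_transfusion = complication_spec("blood_transfusion", 596.63, 5, prof_vaginal),
    endometritis      = complication_spec("endometritis", 49.50, NA, prof_endo)
  )

  # Conditional complication weights: published cohort counts, full precision.
  wt <- function(counts) stats::setNames(counts / sum(counts), cea_complications())
  morbidity_weights <- list(
    tolac_unassisted = wt(c(21, 5, 4, 19, 76)),
    tolac_ventouse   = wt(c(3, 1, 1, 3, 11)),
    emergency_cs     = wt(c(69, 7, 91, 20, 277)),
    ercd             = wt(c(0, 11, 56, 27, 196))
  )

  probs <- branch_probabilities(
    p_tolac_success = 0.666,
    p_ventouse_given_success = 0.13,
    p_morbidity = c(tolac_unassisted = 124 / 5797,
                    tolac_ventouse = 19 / 867,
                    emergency_cs = 465 / 3336,
                    ercd = 290 / 10000),
    p_death = c(tolac_unassisted = 0, tolac_ventouse = 0,
                emergency_cs = 0, ercd = 1 / 10000)
  )

  model_config(horizon_days = 42L, cohort_n = 10000L, wtp_threshold = 45000,
               qaly_basis = "horizon", combine_rule = "max_disutility",
               probs = probs, deliveries = deliveries, profiles = profiles,
               complications = complications,
               morbidity_weights = morbidity_weights)
}

## YAML round-trip -------------------------------------------------------------

config_to_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(x, strip)
    } else if (is.numeric(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  c(list(schema_version = 1L), strip(unclass(validate_config(config))))
}

#' Write a model configuration to a YAML file
#'
#' @param config A validated `cea_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
save_config <- function(config, path) {
  writeLines(yaml::as.yaml(config_to_list(config), precision = 15L), path)
  invisible(path)
}

#' Read and validate a model configuration from a YAML file
#'
#' The file must follow the schema written by [save_config()] (see the
#' bundled base case at
#' `system.file("extdata", "paper_base_case.yaml", package = "tolaccea")`).
#' Every structural invariant is re-checked on load; violations raise a
#' `cea_validation_error` naming the offending field, and probability-closure
#' failures raise the distinct class `cea_probability_error`.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `cea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  require_fields(raw, c("probs", "deliveries", "profiles", "complications",
                        "morbidity_weights", "horizon_days", "cohort_n",
                        "wtp_threshold", "qaly_basis", "combine_rule"),
                 "config file")

  probs <- do.call(branch_probabilities, lapply(raw$probs, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
  deliveries <- lapply(raw$deliveries, function(d) {
    require_fields(d, c("consumables", "staff", "baseline_los_days"), "delivery spec")
    delivery_cost_spec(
      d$consumables, d$staff, d$baseline_los_days,
      drg_bed_day_rate = if (is.null(d$drg_bed_day_rate)) NA_real_ else d$drg_bed_day_rate,
      shared_days = if (is.null(d$shared_days)) 2L else d$shared_days,
      complication_bed_day_rate =
        if (is.null(d$complication_bed_day_rate)) NA_real_ else d$complication_bed_day_rate)
  })
  build_profile <- function(p) {
    require_fields(p, c("cpx", "mob", "pac", "sac", "disutility_per_day",
                        "duration_days"), "disutility profile")
    disutility_profile(p$cpx, p$mob, p$pac, p$sac, p$disutility_per_day,
                       p$duration_days)
  }
  profiles <- lapply(raw$profiles, build_profile)
  complications <- lapply(raw$complications, function(cc) {
    require_fields(cc, c("name", "addon_cost", "los_days", "profile"),
                   "complication spec")
    complication_spec(cc$name, cc$addon_cost,
                      if (is.null(cc$los_days) || is.na(cc$los_days)) NA else cc$los_days,
                      build_profile(cc$profile))
  })
  morbidity_weights <- lapply(raw$morbidity_weights, unlist)

  model_config(horizon_days = raw$horizon_days, cohort_n = raw$cohort_n,
               wtp_threshold = raw$wtp_threshold,
               qaly_basis = raw$qaly_basis, combine_rule = raw$combine_rule,
               probs = probs, deliveries = deliveries, profiles = profiles,
               complications = complications,
               morbidity_weights = morbidity_weights)
}

#' @export
print.cea_config <- function(x, ...) {
  cat("<cea_config>\n")
  cat(sprintf("  horizon: %d days | cohort: %s | WTP: EUR %s/QALY\n",
              x$horizon_days, format(x$cohort_n, big.mark = ","),
              format(x$wtp_threshold, big.mark = ",")))
  cat(sprintf("  qaly_basis: %s | combine_rule: %s\n", x$qaly_basis, x$combine_rule))
  cat(sprintf("  P(TOLAC success) = %.4f, P(ventouse | success) = %.3f\n",
              x$probs$p_tolac_success, x$probs$p_ventouse_given_success))
  cat(sprintf("  P(morbidity): %s\n",
              paste(sprintf("%s %.4f", cea_pathways(), x$probs$p_morbidity),
                    collapse = ", ")))
  invisible(x)
}
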