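## Probabilistic sensitivity analysis.
##
## Monetary parameters and per-day disutilities receive normal distributions;
## branch probabilities receive beta distributions parameterised by the
## method of moments from their point estimate and a binomial standard error
## at the published cohort denominators. Parameters are sampled in a fixed
## registry order as vectorised per-parameter streams from a single master
## seed, so iteration i is row i of the draw matrix and any run is
## bit-reproducible.

#' Beta shape parameters from a mean and standard error
#'
#' Method of moments: `nu = mean * (1 - mean) / se^2 - 1`, `alpha = mean *
#' nu`, `beta = (1 - mean) * nu`. Feasibility requires `se^2 < mean * (1 -
#' mean)`.
#'
#' @param mean Point estimate in (0, 1).
#' @param se Standard error (> 0).
#' @param name Parameter name used in error messages.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_from_moments(0.5, sqrt(1 / 12)) # alpha = beta = 1 (uniform)
#' @export
beta_from_moments <- function(mean, se, name = "parameter") {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    abort_validation(sprintf("%s: beta mean must lie strictly in (0, 1)", name))
  }
  if (!is.numeric(se) || se <= 0) {
    abort_validation(sprintf("%s: beta se must be positive", name))
  }
  if (se^2 >= mean * (1 - mean)) {
    abort_validation(sprintf(
      "%s: infeasible beta moments (se^2 = %.3g >= mean*(1-mean) = %.3g)",
      name, se^2, mean * (1 - mean)))
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Define a sampled parameter for the PSA
#'
#' @param path Dot-separated location of the parameter inside a `cea_config`,
#'   e.g. `"deliveries.ercd.consumables"` or `"probs.p_morbidity.ercd"`.
#' @param family `"normal"` or `"beta"`.
#' @param mean Point estimate (the deterministic value).
#' @param spread Standard error; 0 keeps the parameter fixed at `mean`.
#' @param kind `"cost"` (normal, resampled if negative), `"disutility"`
#'   (normal, clipped to \[0, 1\]) or `"probability"` (beta).
#' @return A `psa_spec` list.
#' @export
psa_spec <- function(path, family = c("normal", "beta"), mean, spread,
                     kind = c("cost", "disutility", "probability")) {
  family <- match.arg(family)
  kind <- match.arg(kind)
  if (family == "beta" && kind != "probability") {
    abort_validation("beta distributions are reserved for probabilities")
  }
  if (!is.numeric(spread) || spread < 0) {
    abort_validation(sprintf("%s: spread must be >= 0", path))
  }
  structure(list(path = path, family = family, mean = mean, spread = spread,
                 kind = kind),
            class = "psa_spec")
}

#' Default distribution assignments for every sampled parameter
#'
#' Builds the bundled PSA specification from a configuration: normal
#' distributions with a 10% coefficient of variation on every monetary
#' parameter (consumables, staff, bed-day rates, complication add-ons),
#' normal distributions with an absolute standard error of 0.02 on every
#' per-day disutility (pathway and complication profiles), and beta
#' distributions on branch probabilities with binomial standard errors
#' `sqrt(p * (1 - p) / n)` at the published cohort denominators (10,000
#' women per arm; 6,664 successful trials; 5,797 / 867 / 3,336 / 10,000 per
#' terminal pathway). Probabilities equal to 0 and disutility durations are
#' held fixed; conditional morbidity weights are not sampled.
#'
#' @param config A validated `cea_config`.
#' @param cost_cv Coefficient of variation for monetary parameters.
#' @param disutility_se Absolute standard error for per-day disutilities.
#' @return A list of [psa_spec()] entries in registry order.
#' @export
default_psa_specs <- function(config, cost_cv = 0.10, disutility_se = 0.02) {
  config <- validate_config(config)
  specs <- list()
  push <- function(s) specs[[length(specs) + 1L]] <<- s
  norm_cost <- function(path, mean) {
    push(psa_spec(path, "normal", mean, cost_cv * mean, "cost"))
  }

  for (p in cea_pathways()) {
    d <- config$deliveries[[p]]
    norm_cost(sprintf("deliveries.%s.consumables", p), d$consumables)
    norm_cost(sprintf("deliveries.%s.staff", p), d$staff)
    if (!is.na(d$drg_bed_day_rate)) {
      norm_cost(sprintf("deliveries.%s.drg_bed_day_rate", p), d$drg_bed_day_rate)
    } else if (!is.na(d$complication_bed_day_rate)) {
      norm_cost(sprintf("deliveries.%s.complication_bed_day_rate", p),
                d$complication_bed_day_rate)
    }
  }
  for (cc in cea_complications()) {
    norm_cost(sprintf("complications.%s.addon_cost", cc),
              config$complications[[cc]]$addon_cost)
  }
  for (p in cea_pathways()) {
    push(psa_spec(sprintf("profiles.%s.disutility_per_day", p), "normal",
                  config$profiles[[p]]$disutility_per_day, disutility_se,
                  "disutility"))
  }
  for (cc in cea_complications()) {
    push(psa_spec(sprintf("complications.%s.profile.disutility_per_day", cc),
                  "normal",
                  config$complications[[cc]]$profile$disutility_per_day,
                  disutility_se, "disutility"))
  }

  # Published cohort denominators behind each branch probability.
  denom <- c(p_tolac_success = 10000, p_ventouse_given_success = 6664,
             tolac_unassisted = 5797, tolac_ventouse = 867,
             emergency_cs = 3336, ercd = 10000)
  bin_se <- function(p, n) sqrt(p * (1 - p) / n)
  pr <- config$probs
  push(psa_spec("probs.p_tolac_success", "beta", pr$p_tolac_success,
                bin_se(pr$p_tolac_success, denom[["p_tolac_success"]]),
                "probability"))
  push(psa_spec("probs.p_ventouse_given_success", "beta",
                pr$p_ventouse_given_success,
                bin_se(pr$p_ventouse_given_success,
                       denom[["p_ventouse_given_success"]]),
                "probability"))
  for (p in cea_pathways()) {
    pm <- pr$p_morbidity[[p]]
    push(psa_spec(sprintf("probs.p_morbidity.%s", p), "beta", pm,
                  bin_se(pm, denom[[p]]), "probability"))
    pd <- pr$p_death[[p]]
    if (pd > 0) {
      push(psa_spec(sprintf("probs.p_death.%s", p), "beta", pd,
                    bin_se(pd, denom[[p]]), "probability"))
    }
  }
  specs
}

# n draws from one psa_spec, in a deterministic RNG order. Negative cost
# draws are resampled (up to 100 rounds) rather than clipped; disutilities
# are clipped to [0, 1].
draw_values <- function(spec, n) {
  if (spec$spread == 0) return(rep(spec$mean, n))
  if (spec$family == "normal") {
    x <- rnorm(n, spec$mean, spec$spread)
    if (spec$kind == "cost") {
      for (round in seq_len(100L)) {
        bad <- which(x < 0)
        if (!length(bad)) break
        x[bad] <- rnorm(length(bad), spec$mean, spec$spread)
      }
      if (any(x < 0)) {
        abort_validation(sprintf(
          "%s: could not draw a non-negative value in 100 resampling rounds",
          spec$path))
      }
    } else {
      x <- pmin(pmax(x, 0), 1)
    }
    x
  } else {
    shape <- beta_from_moments(spec$mean, spec$spread, name = spec$path)
    rbeta(n, shape[["alpha"]], shape[["beta"]])
  }
}

# Write one sampled value into the config; disutility draws rescale the QWB
# components so the profile invariant is preserved.
apply_parameter <- function(config, path, value) {
  apply_parameter_parts(config, strsplit(path, ".", fixed = TRUE)[[1]], value)
}

apply_parameter_parts <- function(config, parts, value) {
  if (parts[length(parts)] == "disutility_per_day") {
    prof_path <- parts[-length(parts)]
    config[[prof_path]] <- rescale_profile(config[[prof_path]], value)
  } else {
    config[[parts]] <- value
  }
  config
}

#' Draw one sampled configuration
#'
#' Applies one random draw of every [psa_spec()] to the base configuration.
#' Parameters without a spec (or with zero spread) pass through unchanged;
#' the returned configuration satisfies all validation invariants.
#'
#' @param config Base `cea_config`.
#' @param specs List of [psa_spec()], e.g. [default_psa_specs()].
#' @param seed Optional integer seed (set before drawing).
#' @return A sampled `cea_config`.
#' @export
draw_parameters <- function(config, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (spec in specs) {
    config <- apply_parameter(config, spec$path, draw_values(spec, 1L))
  }
  validate_config(config)
  config
}

#' Run the probabilistic sensitivity analysis
#'
#' For each Monte Carlo iteration, one value of every sampled parameter is
#' drawn, the decision tree is re-evaluated, and per-arm costs and QALYs plus
#' incremental pairs are recorded. Runs are bit-reproducible for a given
#' seed.
#'
#' @param config Base `cea_config`.
#' @param specs List of [psa_spec()]; defaults to [default_psa_specs()].
#' @param n_iter Number of Monte Carlo iterations (>= 1).
#' @param seed Integer master seed.
#' @return An object of class `cea_psa`: `iterations` (data.frame with
#'   `cost_tolac`, `qaly_tolac`, `cost_ercd`, `qaly_ercd`, `delta_cost`,
#'   `delta_qaly`, `quadrant`), `n_iter`, `seed`, `wtp_threshold`, and the
#'   means of each column.
#' @examples
#' config <- default_paper_config()
#' psa <- run_psa(config, n_iter = 50, seed = 1)
#' prob_cost_effective(psa, 45000)
#' @export
run_psa <- function(config, specs = default_psa_specs(config), n_iter = 10000L,
                    seed = 1L) {
  n_iter <- check_count(n_iter, "n_iter", positive = TRUE)
  config <- validate_config(config)
  set.seed(seed)
  draws <- vapply(specs, draw_values, numeric(n_iter), n = n_iter)
  draws <- matrix(draws, nrow = n_iter)
  paths <- vapply(specs, `[[`, character(1), "path")
  parts <- strsplit(paths, ".", fixed = TRUE)

  cost_tolac <- qaly_tolac <- cost_ercd <- qaly_ercd <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    cfg <- config
    for (j in seq_along(parts)) {
      cfg <- apply_parameter_parts(cfg, parts[[j]], draws[i, j])
    }
    ev <- evaluate_expectations(cfg)
    cost_tolac[i] <- ev[["cost_tolac"]]
    qaly_tolac[i] <- ev[["qaly_tolac"]]
    cost_ercd[i] <- ev[["cost_ercd"]]
    qaly_ercd[i] <- ev[["qaly_ercd"]]
  }
  dc <- cost_tolac - cost_ercd
  de <- qaly_tolac - qaly_ercd
  iterations <- data.frame(
    iteration = seq_len(n_iter),
    cost_tolac = cost_tolac, qaly_tolac = qaly_tolac,
    cost_ercd = cost_ercd, qaly_ercd = qaly_ercd,
    delta_cost = dc, delta_qaly = de,
    quadrant = quadrant(dc, de))
  structure(
    list(iterations = iterations, n_iter = n_iter, seed = seed,
         wtp_threshold = config$wtp_threshold,
         mean_cost_tolac = mean(cost_tolac), mean_qaly_tolac = mean(qaly_tolac),
         mean_cost_ercd = mean(cost_ercd), mean_qaly_ercd = mean(qaly_ercd)),
    class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %d iterations (seed %d)\n", x$n_iter, x$seed))
  cat(sprintf("  mean TOLAC: EUR %.2f, %.4f QALYs | mean ERCD: EUR %.2f, %.4f QALYs\n",
              x$mean_cost_tolac, x$mean_qaly_tolac,
              x$mean_cost_ercd, x$mean_qaly_ercd))
  tab <- table(factor(x$iterations$quadrant, levels = c("NE", "SE", "SW", "NW")))
  cat(sprintf("  quadrants: %s\n",
              paste(sprintf("%s %.1f%%", names(tab), 100 * tab / x$n_iter),
                    collapse = ", ")))
  cat(sprintf("  P(cost-effective at EUR %s/QALY) = %.3f\n",
              format(x$wtp_threshold, big.mark = ","),
              prob_cost_effective(x, x$wtp_threshold)))
  invisible(x)
}

#' Cost-effectiveness plane quadrant of an incremental pair
#'
#' Effects run east (positive) to west; costs run north (positive) to south.
#' SE means the intervention is cheaper and more effective (dominant); NW
#' means dominated. Exact zeros on an axis are assigned conservatively for
#' the intervention: a zero QALY increment counts as west, a zero cost
#' increment as north, so `(0, 0)` is NW.
#'
#' @param delta_cost,delta_qaly Numeric vectors of incremental cost and
#'   effect (intervention minus control).
#' @return Character vector with values in `c("NE", "SE", "SW", "NW")`.
#' @export
quadrant <- function(delta_cost, delta_qaly) {
  ew <- ifelse(delta_qaly > 0, "E", "W")
  ns <- ifelse(delta_cost < 0, "S", "N")
  paste0(ns, ew)
}

#' Probability that the intervention is cost-effective
#'
#' The fraction of PSA iterations with positive net monetary benefit
#' `threshold * delta_qaly - delta_cost > 0`.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param threshold Willingness-to-pay threshold(s), EUR per QALY (length 1).
#' @return A probability in \[0, 1\].
#' @export
prob_cost_effective <- function(psa, threshold = psa$wtp_threshold) {
  if (!inherits(psa, "cea_psa")) abort_validation("`psa` must be a cea_psa")
  if (length(threshold) != 1L || !is.numeric(threshold)) {
    abort_validation("`threshold` must be a single number")
  }
  it <- psa$iterations
  mean(threshold * it$delta_qaly - it$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param thresholds Non-empty numeric vector of willingness-to-pay values.
#' @return A data.frame with columns `threshold` and `probability`.
#' @export
ceac <- function(psa, thresholds = seq(0, 100000, by = 5000)) {
  if (length(thresholds) == 0L || !is.numeric(thresholds)) {
    abort_validation("`thresholds` must be a non-empty numeric vector")
  }
  data.frame(
    threshold = thresholds,
    probability = vapply(thresholds, function(th) prob_cost_effective(psa, th),
                         numeric(1)))
}
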