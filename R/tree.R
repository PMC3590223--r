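## Decision-tree engine.
##
## TOLAC arm: success (unassisted or ventouse vaginal delivery) versus failed
## trial ending in emergency caesarean; ERCD arm: a single elective-repeat
## pathway. Every terminal pathway then resolves to healthy, composite
## morbidity, or death. Payoffs are per-woman cost (EUR) and QALYs over the
## configured horizon.

# Probability of reaching each terminal pathway within an arm.
pathway_probabilities <- function(config, arm) {
  if (arm == "tolac") {
    ps <- config$probs$p_tolac_success
    pv <- config$probs$p_ventouse_given_success
    c(tolac_unassisted = ps * (1 - pv),
      tolac_ventouse = ps * pv,
      emergency_cs = 1 - ps)
  } else {
    c(ercd = 1)
  }
}

# Payoffs for one pathway: healthy / per-complication morbidity / death.
pathway_payoffs <- function(config, pathway) {
  h <- config$horizon_days
  basis <- config$qaly_basis
  delivery <- config$deliveries[[pathway]]
  dcost <- delivery_cost(delivery)$total
  dtraj <- utility_trajectory(config$profiles[[pathway]], h)
  comp_names <- cea_complications()
  comp_cost <- comp_qaly <- setNames(numeric(length(comp_names)), comp_names)
  for (nm in comp_names) {
    comp <- config$complications[[nm]]
    comp_cost[nm] <- pathway_cost_with_complication(delivery, comp)$total
    ctraj <- combine_trajectories(dtraj, utility_trajectory(comp$profile, h),
                                  rule = config$combine_rule)
    comp_qaly[nm] <- qalys(ctraj, basis = basis)
  }
  list(
    healthy_cost = dcost,
    healthy_qaly = qalys(dtraj, basis = basis),
    comp_cost = comp_cost,
    comp_qaly = comp_qaly,
    death_cost = dcost,  # maternal death carries the delivery cost, no add-on
    death_qaly = 0
  )
}

# Terminal vectors for one arm (composite or expanded morbidity), in a fixed
# order: per pathway, healthy / morbidity (or the five complications) / death.
arm_vectors <- function(config, arm, expand_morbidity = FALSE) {
  pp <- pathway_probabilities(config, arm)
  pathway <- state <- character(0)
  probability <- cost <- qaly <- numeric(0)
  for (pw in names(pp)) {
    pm <- config$probs$p_morbidity[[pw]]
    pd <- config$probs$p_death[[pw]]
    ph <- 1 - pm - pd
    if (ph < -1e-12) {
      abort_validation(sprintf(
        "probability closure failure in pathway %s: p_morbidity + p_death > 1",
        pw), class = "cea_probability_error")
    }
    ph <- max(ph, 0)
    pay <- pathway_payoffs(config, pw)
    w <- config$morbidity_weights[[pw]]
    w <- w / sum(w)
    if (expand_morbidity) {
      state <- c(state, "healthy", cea_complications(), "death")
      probability <- c(probability, pp[[pw]] * ph, pp[[pw]] * pm * w,
                       pp[[pw]] * pd)
      cost <- c(cost, pay$healthy_cost, pay$comp_cost, pay$death_cost)
      qaly <- c(qaly, pay$healthy_qaly, pay$comp_qaly, pay$death_qaly)
    } else {
      state <- c(state, "healthy", "morbidity", "death")
      probability <- c(probability, pp[[pw]] * ph, pp[[pw]] * pm, pp[[pw]] * pd)
      cost <- c(cost, pay$healthy_cost, sum(w * pay$comp_cost), pay$death_cost)
      qaly <- c(qaly, pay$healthy_qaly, sum(w * pay$comp_qaly), pay$death_qaly)
    }
    pathway <- c(pathway, rep(pw, if (expand_morbidity) 7L else 3L))
  }
  list(arm = arm, pathway = pathway, state = state,
       probability = unname(probability), cost = unname(cost),
       qaly = unname(qaly))
}

arm_terminals <- function(config, arm, expand_morbidity = FALSE) {
  v <- arm_vectors(config, arm, expand_morbidity)
  data.frame(arm = v$arm, pathway = v$pathway, state = v$state,
             probability = v$probability, cost = v$cost, qaly = v$qaly)
}

#' Build the terminal outcomes of the decision tree
#'
#' Composes the chance-node probabilities by the chain rule and attaches the
#' per-terminal payoffs (cost, QALY). By default each pathway carries a
#' single composite morbidity terminal whose payoff is the conditional-weight
#' average over the five complications; `expand_morbidity = TRUE` splits it
#' into one terminal per complication (same expectations, used for cohort
#' tabulation and microsimulation).
#'
#' @param config A validated `cea_config`.
#' @param expand_morbidity Split the composite morbidity state per
#'   complication?
#' @return A named list with elements `tolac` and `ercd`, each a data.frame
#'   of terminals (`pathway`, `state`, `probability`, `cost`, `qaly`);
#'   probabilities within an arm sum to 1.
#' @export
build_tree <- function(config, expand_morbidity = FALSE) {
  list(tolac = arm_terminals(config, "tolac", expand_morbidity),
       ercd = arm_terminals(config, "ercd", expand_morbidity))
}

#' Evaluate the decision tree: expected cost and QALYs per arm
#'
#' @param config A validated `cea_config`.
#' @return An object of class `cea_evaluation`: a list with elements `tolac`
#'   and `ercd`, each of class `cea_arm_result` holding `expected_cost`
#'   (EUR), `expected_qaly`, and the `terminals` data.frame.
#' @examples
#' ev <- evaluate_tree(default_paper_config())
#' round(ev$tolac$expected_qaly, 2) # 0.84
#' @export
evaluate_tree <- function(config) {
  res <- lapply(c(tolac = "tolac", ercd = "ercd"), function(arm) {
    v <- arm_vectors(config, arm)
    structure(
      list(expected_cost = sum(v$probability * v$cost),
           expected_qaly = sum(v$probability * v$qaly),
           terminals = data.frame(arm = v$arm, pathway = v$pathway,
                                  state = v$state, probability = v$probability,
                                  cost = v$cost, qaly = v$qaly)),
      class = "cea_arm_result")
  })
  structure(res, class = "cea_evaluation")
}

# Expected (cost, qaly) per arm without constructing data.frames; identical
# arithmetic (and summation order) to evaluate_tree. Used in the PSA loop.
evaluate_expectations <- function(config) {
  vt <- arm_vectors(config, "tolac")
  ve <- arm_vectors(config, "ercd")
  c(cost_tolac = sum(vt$probability * vt$cost),
    qaly_tolac = sum(vt$probability * vt$qaly),
    cost_ercd = sum(ve$probability * ve$cost),
    qaly_ercd = sum(ve$probability * ve$qaly))
}

#' @export
print.cea_evaluation <- function(x, ...) {
  cat("<cea_evaluation>\n")
  for (arm in names(x)) {
    cat(sprintf("  %-5s expected cost EUR %10.2f | expected QALYs %.4f\n",
                toupper(arm), x[[arm]]$expected_cost, x[[arm]]$expected_qaly))
  }
  invisible(x)
}

#' Incremental cost-effectiveness of TOLAC versus ERCD
#'
#' Increments are intervention (TOLAC) minus control (ERCD). When the
#' intervention is cheaper and more effective it dominates (no ratio is
#' reported); when costlier and less effective it is dominated
#' (`control_dominates`); otherwise a trade-off ICER `delta_cost /
#' delta_qaly` is reported (undefined when `delta_qaly` is zero).
#' Cost-effectiveness at the threshold is judged by net monetary benefit
#' `threshold * delta_qaly - delta_cost > 0`.
#'
#' @param tolac,ercd `cea_arm_result` objects from [evaluate_tree()].
#' @param threshold Willingness-to-pay threshold, EUR per QALY.
#' @return An object of class `cea_icer`: `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` under dominance or zero QALY increment), `label` (one of
#'   `intervention_dominates`, `control_dominates`, `trade_off`), and
#'   `cost_effective`.
#' @export
icer <- function(tolac, ercd, threshold = 45000) {
  dc <- tolac$expected_cost - ercd$expected_cost
  de <- tolac$expected_qaly - ercd$expected_qaly
  label <- if (dc < 0 && de > 0) "intervention_dominates"
           else if (dc > 0 && de < 0) "control_dominates"
           else "trade_off"
  ratio <- if (label != "trade_off" || de == 0) NA_real_ else dc / de
  structure(
    list(delta_cost = dc, delta_qaly = de, icer = ratio, label = label,
         threshold = threshold,
         cost_effective = (threshold * de - dc) > 0),
    class = "cea_icer")
}

#' @export
print.cea_icer <- function(x, ...) {
  cat(sprintf("<cea_icer> dCost EUR %.2f | dQALY %.4f | %s",
              x$delta_cost, x$delta_qaly,
              switch(x$label,
                     intervention_dominates = "TOLAC dominates",
                     control_dominates = "ERCD dominates",
                     sprintf("ICER EUR %.0f/QALY", x$icer))))
  cat(sprintf(" | cost-effective at EUR %s/QALY: %s\n",
              format(x$threshold, big.mark = ","), x$cost_effective))
  invisible(x)
}

# Round expected counts to integers summing exactly to n (largest remainder).
largest_remainder <- function(expected, n) {
  fl <- floor(expected)
  rem <- expected - fl
  short <- n - sum(fl)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[top] <- fl[top] + 1
  }
  as.integer(fl)
}

#' Expected cohort outcome counts per terminal
#'
#' Projects a hypothetical cohort of `n` women per arm onto the expanded
#' terminals (per complication), rounding expected counts by the
#' largest-remainder method so counts sum exactly to `n` within each arm.
#'
#' @param config A validated `cea_config`.
#' @param n Cohort size per arm; defaults to `config$cohort_n`.
#' @return A data.frame with columns `arm`, `pathway`, `state`, `probability`,
#'   `expected` (`n * probability`) and `count`.
#' @export
cohort_counts <- function(config, n = config$cohort_n) {
  n <- check_count(n, "n")
  tree <- build_tree(config, expand_morbidity = TRUE)
  out <- lapply(tree, function(term) {
    term$expected <- n * term$probability
    term$count <- if (n == 0L) 0L else largest_remainder(term$expected, n)
    term[c("arm", "pathway", "state", "probability", "expected", "count")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
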