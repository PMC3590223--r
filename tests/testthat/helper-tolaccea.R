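# Shared fixtures: the published base case, built once per test run.
base_config <- default_paper_config()

# Independent enumeration of all expanded terminals of one arm: probabilities
# chained explicitly and payoffs computed directly from the costing and QALY
# operations, without build_tree's composite-morbidity shortcut. Used as the
# brute-force oracle for evaluate_tree().
enumerate_arm <- function(config, arm) {
  h <- config$horizon_days
  pw_probs <- if (arm == "tolac") {
    ps <- config$probs$p_tolac_success
    pv <- config$probs$p_ventouse_given_success
    c(tolac_unassisted = ps * (1 - pv), tolac_ventouse = ps * pv,
      emergency_cs = 1 - ps)
  } else {
    c(ercd = 1)
  }
  rows <- data.frame()
  for (pw in names(pw_probs)) {
    d <- config$deliveries[[pw]]
    dtraj <- utility_trajectory(config$profiles[[pw]], h)
    pm <- config$probs$p_morbidity[[pw]]
    pd <- config$probs$p_death[[pw]]
    rows <- rbind(rows, data.frame(
      probability = pw_probs[[pw]] * (1 - pm - pd),
      cost = delivery_cost(d)$total,
      qaly = qalys(dtraj, basis = config$qaly_basis)))
    w <- config$morbidity_weights[[pw]]
    for (nm in cea_complications()) {
      comp <- config$complications[[nm]]
      traj <- combine_trajectories(dtraj, utility_trajectory(comp$profile, h),
                                   rule = config$combine_rule)
      rows <- rbind(rows, data.frame(
        probability = pw_probs[[pw]] * pm * w[[nm]],
        cost = pathway_cost_with_complication(d, comp)$total,
        qaly = qalys(traj, basis = config$qaly_basis)))
    }
    rows <- rbind(rows, data.frame(
      probability = pw_probs[[pw]] * pd,
      cost = delivery_cost(d)$total,
      qaly = 0))
  }
  rows
}
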