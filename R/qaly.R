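## QALY integration over a finite horizon.
##
## Utilities live on a linear 0 (death) .. 1 (perfect health) scale, assumed
## constant within each day. A disutility profile subtracts a fixed per-day
## decrement for its duration (clipped at the horizon), after which full
## health resumes.

#' Daily utility trajectory implied by a disutility profile
#'
#' @param profile A [disutility_profile()].
#' @param horizon_days Positive integer horizon length in days.
#' @return A numeric vector of length `horizon_days` with values in \[0, 1\]:
#'   `1 - disutility_per_day` for days up to `min(duration_days,
#'   horizon_days)`, then 1.
#' @examples
#' # Successful vaginal delivery: 0.41 disutility for 7 days
#' traj <- utility_trajectory(disutility_profile(0.256, 0.031, 0.072, 0.054,
#'                                               0.41, 7), 42)
#' qalys(traj) # 0.93 over six weeks
#' @export
utility_trajectory <- function(profile, horizon_days) {
  horizon_days <- check_count(horizon_days, "horizon_days", positive = TRUE)
  if (!inherits(profile, "disutility_profile")) {
    abort_validation("`profile` must be a disutility_profile")
  }
  affected <- min(profile$duration_days, horizon_days)
  c(rep(1 - profile$disutility_per_day, affected),
    rep(1, horizon_days - affected))
}

#' All-zero utility trajectory for the death state
#'
#' @param horizon_days Positive integer horizon length in days.
#' @return A numeric zero vector of length `horizon_days`.
#' @export
death_trajectory <- function(horizon_days) {
  horizon_days <- check_count(horizon_days, "horizon_days", positive = TRUE)
  rep(0, horizon_days)
}

#' Combine two daily utility trajectories
#'
#' How a delivery-pathway decrement and a concurrent complication decrement
#' interact is not identified by the source tables, so the rule is explicit:
#' `"max_disutility"` takes the per-day worst (minimum utility) of the two
#' states, and `"additive_capped"` adds the two per-day disutilities with the
#' resulting utility floored at 0. The max rule is the package default
#' because additive stacking of QWB components can exceed total health.
#'
#' @param delivery,complication Equal-length numeric utility trajectories.
#' @param rule `"max_disutility"` or `"additive_capped"`.
#' @return A combined utility trajectory of the same length.
#' @export
combine_trajectories <- function(delivery, complication,
                                 rule = c("max_disutility", "additive_capped")) {
  rule <- match.arg(rule)
  if (length(delivery) != length(complication)) {
    abort_validation("trajectories must have equal length")
  }
  if (rule == "max_disutility") {
    pmin(delivery, complication)
  } else {
    pmax(0, 1 - ((1 - delivery) + (1 - complication)))
  }
}

#' Quality-adjusted life years of a utility trajectory
#'
#' On the `"horizon"` basis the trajectory is averaged over its own length,
#' giving the QALY fraction of the analysis window (the study's headline
#' scale: 0 = death throughout, 1 = perfect health throughout six weeks). On
#' the `"annual"` basis full health is assumed from the end of the horizon to
#' day 365 and the sum is divided by 365.
#'
#' @param traj A numeric utility trajectory (values in \[0, 1\]).
#' @param basis `"horizon"` or `"annual"`.
#' @return A single QALY value in \[0, 1\].
#' @export
qalys <- function(traj, basis = c("horizon", "annual")) {
  basis <- match.arg(basis)
  if (!is.numeric(traj) || length(traj) < 1L || anyNA(traj) ||
      any(traj < 0 | traj > 1)) {
    abort_validation("`traj` must be a numeric utility trajectory in [0, 1]")
  }
  if (basis == "horizon") {
    mean(traj)
  } else {
    if (length(traj) > 365L) {
      abort_validation("annual basis requires a horizon of at most 365 days")
    }
    (sum(traj) + (365 - length(traj))) / 365
  }
}
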