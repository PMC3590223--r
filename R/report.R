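## Report generation: deterministic tables, PSA outputs and a run manifest.
## Reports are pure functions of (config, seed, n_iter); re-running with the
## same inputs reproduces every file byte for byte.

cea_verbosity <- function() getOption("tolaccea.verbose", 1L)

#' Configure report logging
#'
#' Sets the package verbosity: 0 silences progress messages, 1 (default)
#' logs the run manifest facts (config hash, seed, iteration count), 2 adds
#' per-step messages. Results never depend on verbosity.
#'
#' @param verbosity Integer 0, 1 or 2.
#' @return The previous verbosity, invisibly.
#' @export
log_setup <- function(verbosity = 1L) {
  verbosity <- check_count(verbosity, "verbosity")
  old <- cea_verbosity()
  options(tolaccea.verbose = verbosity)
  invisible(old)
}

cea_log <- function(level, fmt, ...) {
  if (cea_verbosity() >= level) message(sprintf(fmt, ...))
}

#' Run the full analysis and write the report bundle
#'
#' Evaluates the deterministic tree, projects the cohort, runs the PSA, and
#' writes a plain-text report bundle to `out_dir`:
#' \describe{
#'   \item{costs.csv}{per-pathway and per-complication cost breakdowns}
#'   \item{cohort.csv}{expected cohort outcome counts per arm}
#'   \item{ce_results.csv}{deterministic and probabilistic cost, QALY and
#'     incremental results with the dominance/ICER label}
#'   \item{ce_plane.csv}{per-iteration incremental pairs and quadrants}
#'   \item{ceac.csv}{cost-effectiveness acceptability curve}
#'   \item{summary.json}{headline numbers in machine-readable form}
#'   \item{manifest.txt}{config hash, seed, iteration count, package version}
#' }
#'
#' @param config A `cea_config`, or a path to a YAML configuration file, or
#'   `NULL` for [default_paper_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed for the PSA.
#' @param n_iter Number of PSA iterations.
#' @param ceac_thresholds Willingness-to-pay grid for the CEAC.
#' @return Invisibly, a named character vector of the files written.
#' @export
run_all <- function(config = NULL, out_dir, seed = 1L, n_iter = 1000L,
                    ceac_thresholds = seq(0, 100000, by = 5000)) {
  if (is.null(config)) {
    config <- default_paper_config()
  } else if (is.character(config)) {
    config <- load_config(config)
  }
  config <- validate_config(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_validation(sprintf("cannot create output directory %s", out_dir))
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  cea_log(1L, "run_all: config md5 %s, seed %d, %d PSA iterations",
          cfg_hash, seed, n_iter)

  cea_log(2L, "evaluating deterministic tree")
  ev <- evaluate_tree(config)
  det <- icer(ev$tolac, ev$ercd, config$wtp_threshold)
  cea_log(2L, "running PSA")
  psa <- run_psa(config, n_iter = n_iter, seed = seed)
  curve <- ceac(psa, ceac_thresholds)

  files <- c(
    config = cfg_file,
    costs = file.path(out_dir, "costs.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    ce_results = file.path(out_dir, "ce_results.csv"),
    ce_plane = file.path(out_dir, "ce_plane.csv"),
    ceac = file.path(out_dir, "ceac.csv"),
    summary = file.path(out_dir, "summary.json"),
    manifest = file.path(out_dir, "manifest.txt"))

  write.csv(cost_table(config), files[["costs"]], row.names = FALSE)
  write.csv(cohort_counts(config), files[["cohort"]], row.names = FALSE)

  label <- switch(det$label,
                  intervention_dominates = "TOLAC dominates",
                  control_dominates = "ERCD dominates",
                  sprintf("%.2f", det$icer))
  ce <- data.frame(
    model = c("deterministic", "probabilistic"),
    cost_tolac = round(c(ev$tolac$expected_cost, psa$mean_cost_tolac), 2),
    qaly_tolac = round(c(ev$tolac$expected_qaly, psa$mean_qaly_tolac), 2),
    cost_ercd = round(c(ev$ercd$expected_cost, psa$mean_cost_ercd), 2),
    qaly_ercd = round(c(ev$ercd$expected_qaly, psa$mean_qaly_ercd), 2),
    delta_cost = round(c(det$delta_cost,
                         psa$mean_cost_tolac - psa$mean_cost_ercd), 2),
    delta_qaly = round(c(det$delta_qaly,
                         psa$mean_qaly_tolac - psa$mean_qaly_ercd), 2),
    icer = label)
  write.csv(ce, files[["ce_results"]], row.names = FALSE)

  plane <- psa$iterations[c("iteration", "delta_qaly", "delta_cost", "quadrant")]
  write.csv(plane, files[["ce_plane"]], row.names = FALSE)
  write.csv(curve, files[["ceac"]], row.names = FALSE)

  summary <- list(
    deterministic = list(
      cost_tolac = ev$tolac$expected_cost, qaly_tolac = ev$tolac$expected_qaly,
      cost_ercd = ev$ercd$expected_cost, qaly_ercd = ev$ercd$expected_qaly,
      delta_cost = det$delta_cost, delta_qaly = det$delta_qaly,
      label = det$label, cost_effective = det$cost_effective),
    probabilistic = list(
      n_iter = psa$n_iter, seed = psa$seed,
      mean_cost_tolac = psa$mean_cost_tolac,
      mean_qaly_tolac = psa$mean_qaly_tolac,
      mean_cost_ercd = psa$mean_cost_ercd,
      mean_qaly_ercd = psa$mean_qaly_ercd,
      prob_cost_effective = prob_cost_effective(psa, config$wtp_threshold),
      pct_south_east = 100 * mean(psa$iterations$quadrant == "SE")),
    wtp_threshold = config$wtp_threshold)
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE,
                       digits = NA)

  writeLines(c(
    sprintf("package: tolaccea %s", as.character(utils::packageVersion("tolaccea"))),
    sprintf("config_md5: %s", cfg_hash),
    sprintf("seed: %d", seed),
    sprintf("n_iter: %d", n_iter),
    sprintf("wtp_threshold: %s", format(config$wtp_threshold))),
    files[["manifest"]])

  cea_log(1L, "run_all: wrote %d files to %s", length(files), out_dir)
  invisible(files)
}
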