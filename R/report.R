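#' Configuration of a full validation run
#'
#' Bundles every setting of the simulate-pair-compare-calibrate pipeline.
#'
#' @param cohort A [cohort_config()].
#' @param rq_grid An [rq_grid()].
#' @param window_minutes Ventilator aggregation window, minutes (default 360).
#' @param min_coverage Minimum window coverage fraction (default 0.8).
#' @param bands List of `agreement` and `tight` ratio bands.
#' @param error_mode,difference_mode See [percentage_metrics()].
#' @param ccc_ci,n_boot CCC confidence-interval settings; see [lin_ccc()].
#' @param lambda_grid,cv_folds Ridge settings; see [fit_ridge()].
#' @param calibration_source `"calorimeter"` fits the calibration on the IC
#'   device's own VCO2 (its ceiling performance), `"ventilator"` on the paired
#'   block VCO2. The fitted formula is always evaluated on the ventilator
#'   pairs.
#' @param seed Root seed; overrides `cohort$seed` and seeds the bootstrap and
#'   CV shuffles.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       rq_grid = vco2ree::rq_grid(),
                       window_minutes = 360,
                       min_coverage = 0.8,
                       bands = list(agreement = c(0.85, 1.15),
                                    tight = c(0.95, 1.05)),
                       error_mode = "mean_abs_relative",
                       difference_mode = "mean_abs_pair_relative",
                       ccc_ci = "bootstrap",
                       n_boot = 2000L,
                       lambda_grid = 10^seq(-4, 2, length.out = 25),
                       cv_folds = 10L,
                       calibration_source = c("calorimeter", "ventilator"),
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(rq_grid, "rq_grid"))
  if (window_minutes <= 0) stop("`window_minutes` must be positive", call. = FALSE)
  calibration_source <- match.arg(calibration_source)
  cohort$seed <- as.integer(seed)
  structure(
    list(cohort = cohort, rq_grid = rq_grid, window_minutes = window_minutes,
         min_coverage = min_coverage, bands = bands, error_mode = error_mode,
         difference_mode = difference_mode, ccc_ci = ccc_ci,
         n_boot = as.integer(n_boot), lambda_grid = lambda_grid,
         cv_folds = as.integer(cv_folds),
         calibration_source = calibration_source, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Simulate a cohort and write its input files
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort)
  paths <- write_cohort(cohort, out_dir)
  message(sprintf("simulated %d patients, %d IC measurements -> %s",
                  length(cohort$traces), nrow(cohort$ic_samples), out_dir))
  invisible(paths)
}

#' Analyze IC and ventilator files into the full validation report
#'
#' Reads the two input CSVs, pairs each IC measurement with its preceding
#' ventilator block, computes the per-RQ agreement battery and Bland-Altman
#' points, fits the ridge calibration, derives the rounded simplified formula
#' and evaluates it on the ventilator pairs, then writes `paired.csv`,
#' `performance_table.csv`, `bland_altman.csv`, `calibration.json` and a
#' human-readable `report.md`. Every number in the report is re-derivable
#' from the written CSVs.
#'
#' @param ic_file,trace_file Input CSV paths (dialect of [write_cohort()]).
#' @param config A [run_config()].
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, a list with the paired dataset, performance table,
#'   calibration and output paths.
#' @export
cmd_analyze <- function(ic_file, trace_file, config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ic <- read_ic_measurements(ic_file)
  traces <- read_vent_traces(trace_file)

  ds <- build_paired_dataset(ic, traces, rq_grid = config$rq_grid,
                             window = config$window_minutes,
                             min_coverage = config$min_coverage,
                             coeffs = config$cohort$coeffs)
  write_paired(ds, file.path(out_dir, "paired.csv"))

  perf <- performance_table(ds, bands = config$bands,
                            error_mode = config$error_mode,
                            difference_mode = config$difference_mode,
                            ccc_ci = config$ccc_ci, n_boot = config$n_boot,
                            seed = config$seed)
  write_table_utf8(as.data.frame(perf), file.path(out_dir, "performance_table.csv"))

  grid <- attr(ds, "rq_grid")
  ba_points <- do.call(rbind, lapply(grid, function(rq) {
    ba <- bland_altman(ds[[sprintf("ree_vco2_rq%.2f", rq)]], ds$ree_ic)
    cbind(data.frame(rq = rq), as.data.frame(ba$points))
  }))
  write_table_utf8(ba_points, file.path(out_dir, "bland_altman.csv"))

  # calibration: by default on the calorimeter's own VCO2 (the method's
  # ceiling); evaluation always on the ventilator pairs
  if (config$calibration_source == "calorimeter") {
    cal_x <- ic$vco2_ml_min
    cal_y <- ree_weir(ic$vo2_ml_min, ic$vco2_ml_min, config$cohort$coeffs)
  } else {
    cal_x <- ds$block_vco2
    cal_y <- ds$ree_ic
  }
  cal <- fit_ridge(cal_x, cal_y, lambda_grid = config$lambda_grid,
                   cv_folds = config$cv_folds, seed = config$seed)
  simp <- round_to_simplified(cal)
  eval_row <- evaluate_formula(simp, ds, bands = config$bands,
                               error_mode = config$error_mode,
                               difference_mode = config$difference_mode,
                               ccc_ci = config$ccc_ci, n_boot = config$n_boot,
                               seed = config$seed)
  jsonlite::write_json(
    list(intercept = cal$intercept, slope = cal$slope, lambda = cal$lambda,
         r2 = cal$r2, n = cal$n, source = config$calibration_source,
         simplified = list(intercept = simp$intercept, slope = simp$slope),
         evaluation = as.list(eval_row)),
    file.path(out_dir, "calibration.json"),
    auto_unbox = TRUE, digits = NA
  )

  write_report_md(file.path(out_dir, "report.md"), ds, perf, cal, simp,
                  eval_row, config)
  message(sprintf("analyzed %d pairs -> %s", nrow(ds), out_dir))
  invisible(list(paired = ds, performance = perf, calibration = cal,
                 simplified = simp, evaluation = eval_row,
                 dir = out_dir))
}

#' Simulate and analyze in one deterministic run
#'
#' @inheritParams cmd_analyze
#' @param out_dir Output directory receiving both the simulated inputs and
#'   the analysis outputs.
#' @return Invisibly, the [cmd_analyze()] result.
#' @export
full_run <- function(config = run_config(), out_dir) {
  paths <- cmd_simulate(config, out_dir)
  cmd_analyze(paths[["ic"]], paths[["trace"]], config, out_dir)
}

fmt_frac <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
fmt_kcal <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
fmt_ci <- function(x, lo, hi) {
  ifelse(is.na(x), "NA", sprintf("%.2f (%.2f-%.2f)", x, lo, hi))
}

write_report_md <- function(path, ds, perf, cal, simp, eval_row, config) {
  # rows in descending RQ, the customary presentation
  perf <- perf[order(-perf$rq), , drop = FALSE]
  excl <- attr(ds, "excluded")
  lines <- c(
    "# VCO2-only REE validation report",
    "",
    sprintf("Pairs analyzed: %d (excluded: %d); window %g min, min coverage %.2f.",
            nrow(ds), nrow(excl), attr(ds, "window_minutes"),
            attr(ds, "min_coverage")),
    "",
    "## Agreement battery by fixed RQ",
    "",
    paste0("| Estimator | Mean difference | SD | % Error | % Difference | ",
           "Correlation | Concordance | Agreement | Tight agreement |"),
    "|---|---|---|---|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(perf))) {
    p <- perf[i, ]
    label <- sprintf("VCO2 with %.2f RQ", p$rq)
    if (abs(p$rq - 0.89) < 1e-9) label <- paste(label, "(~ 5.5 x VCO2 x 1.44)")
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
      label, fmt_kcal(p$mean_difference), fmt_kcal(p$sd_difference),
      fmt_frac(p$pct_error), fmt_frac(p$pct_difference),
      fmt_ci(p$pearson_r, p$pearson_ci_low, p$pearson_ci_high),
      fmt_ci(p$ccc, p$ccc_ci_low, p$ccc_ci_high),
      fmt_frac(p$agreement), fmt_frac(p$tight_agreement)
    ))
  }
  lines <- c(lines, "",
             "## Bland-Altman (estimate - reference)", "",
             "| Estimator | Bias | LoA low | LoA high | n |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(perf))) {
    p <- perf[i, ]
    lines <- c(lines, sprintf(
      "| VCO2 with %.2f RQ | %s | %s | %s | %d |",
      p$rq, fmt_kcal(p$mean_difference),
      fmt_kcal(p$mean_difference - 1.96 * p$sd_difference),
      fmt_kcal(p$mean_difference + 1.96 * p$sd_difference), p$n
    ))
  }
  lines <- c(
    lines, "",
    "Scatter/Bland-Altman point data: bland_altman.csv (pair mean, difference).",
    "",
    "## Ridge calibration", "",
    sprintf("Source: %s VCO2; n = %d; lambda = %g; R2 = %.2f.",
            config$calibration_source, cal$n, cal$lambda, cal$r2),
    sprintf("Fitted: REE = %.2f + %.4f * VCO2 (mL/min).",
            cal$intercept, cal$slope),
    sprintf("Simplified: REE = %g + %g * VCO2.", simp$intercept, simp$slope),
    "",
    "Evaluation of the simplified formula on the ventilator pairs:",
    "",
    sprintf(paste0("mean difference %s kcal/d, SD %s, %% error %s, ",
                   "%% difference %s, correlation %s, concordance %s, ",
                   "agreement %s, tight agreement %s (n = %d)."),
            fmt_kcal(eval_row$mean_difference), fmt_kcal(eval_row$sd_difference),
            fmt_frac(eval_row$pct_error), fmt_frac(eval_row$pct_difference),
            fmt_ci(eval_row$pearson_r, eval_row$pearson_ci_low,
                   eval_row$pearson_ci_high),
            fmt_ci(eval_row$ccc, eval_row$ccc_ci_low, eval_row$ccc_ci_high),
            fmt_frac(eval_row$agreement), fmt_frac(eval_row$tight_agreement),
            eval_row$n)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
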