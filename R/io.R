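# All delimited output uses comma separation, "." decimal separator, UTF-8,
# no row names, full double precision (deterministic across runs).
write_table_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_checked <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop(sprintf("malformed CSV %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad) > 0L) {
    stop(sprintf("%s: missing values at data line %d", path, bad[1] + 1L),
         call. = FALSE)
  }
  df
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `ic_measurements.csv` (patient_id, time_min, vo2_ml_min,
#' vco2_ml_min), `vent_trace.csv` (patient_id, time_min, vco2_ml_min) and
#' `ground_truth.csv` (patient_id, time_min, true_ree_kcal_d,
#' true_vco2_ml_min, true_rq) into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory; created if absent.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ic_path <- file.path(dir, "ic_measurements.csv")
  tr_path <- file.path(dir, "vent_trace.csv")
  gt_path <- file.path(dir, "ground_truth.csv")

  ic <- cohort$ic_samples[c("patient_id", "time_min", "vo2_ml_min", "vco2_ml_min")]
  write_table_utf8(ic, ic_path)

  tr <- do.call(rbind, lapply(cohort$traces, function(t) {
    data.frame(patient_id = t$patient_id, time_min = t$times,
               vco2_ml_min = t$vco2, stringsAsFactors = FALSE)
  }))
  tr <- tr[order(tr$patient_id, tr$time_min), , drop = FALSE]
  write_table_utf8(tr, tr_path)

  write_table_utf8(as.data.frame(cohort$ground_truth), gt_path)
  invisible(c(ic = ic_path, trace = tr_path, ground_truth = gt_path))
}

#' Read IC measurements from CSV
#'
#' @param path Path to a CSV with columns patient_id, time_min, vo2_ml_min,
#'   vco2_ml_min.
#' @return A tibble.
#' @export
read_ic_measurements <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "time_min", "vo2_ml_min",
                                 "vco2_ml_min"))
  tibble::as_tibble(df)
}

#' Read ventilator traces from CSV
#'
#' @param path Path to a CSV with columns patient_id, time_min, vco2_ml_min.
#' @return A named list of [vent_trace()] objects.
#' @export
read_vent_traces <- function(path) {
  df <- read_csv_checked(path, c("patient_id", "time_min", "vco2_ml_min"))
  traces_from_long(df)
}

#' Write a paired dataset to CSV
#'
#' @param ds A `paired_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_paired <- function(ds, path) {
  stopifnot(inherits(ds, "paired_dataset"))
  write_table_utf8(as.data.frame(ds), path)
}
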