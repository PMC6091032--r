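#' Ventilator VCO2 trace for one patient
#'
#' @param patient_id Patient identifier.
#' @param times Record timestamps, minutes since cohort epoch; strictly
#'   increasing. Duplicate timestamps keep the first occurrence.
#' @param vco2 VCO2 in mL/min, one value per record; non-negative.
#' @param step Nominal sampling interval in minutes; inferred as the median
#'   time difference when omitted. Used only to assess window coverage.
#' @return An object of class `vent_trace`.
#' @examples
#' vent_trace("P1", seq(0, 55, by = 5), rep(244.5, 12))
#' @export
vent_trace <- function(patient_id, times, vco2, step = NULL) {
  if (length(times) != length(vco2)) {
    stop("`times` and `vco2` must have equal length", call. = FALSE)
  }
  if (length(times) == 0L) stop("empty trace", call. = FALSE)
  keep <- !duplicated(times)
  times <- as.numeric(times[keep]); vco2 <- as.numeric(vco2[keep])
  o <- order(times)
  times <- times[o]; vco2 <- vco2[o]
  check_nonneg(vco2, "vco2")
  if (is.null(step)) {
    step <- if (length(times) > 1L) stats::median(diff(times)) else 1
  }
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id), times = times, vco2 = vco2,
         step = step),
    class = "vent_trace"
  )
}

#' @export
print.vent_trace <- function(x, ...) {
  cat(sprintf("Ventilator trace %s: %d records every %g min, t in [%g, %g]\n",
              x$patient_id, length(x$times), x$step,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Mean VCO2 over the block preceding a timepoint
#'
#' Averages the trace records whose timestamps fall in the half-open window
#' `[t - window, t)` -- strictly preceding the assessment, so a record at `t`
#' itself is never used. Coverage is the number of records present divided by
#' the number expected at the trace's nominal step (`window / step`), capped
#' at 1. When coverage falls below `min_coverage` (or the window is empty) the
#' mean is returned as `NA` so the caller can exclude the observation.
#'
#' @param trace A [vent_trace()].
#' @param t Assessment time, minutes.
#' @param window Window length in minutes (default 360, i.e. 6 h).
#' @param min_coverage Minimum acceptable coverage fraction in \[0, 1\]
#'   (default 0.8).
#' @return A list with `mean` (mL/min, `NA` if under-covered), `coverage` and
#'   `n` (records used).
#' @examples
#' tr <- vent_trace("P1", seq(0, 420, by = 5), rep(244.5, 85))
#' block_mean_vco2(tr, 420)$mean # 244.5
#' @export
block_mean_vco2 <- function(trace, t, window = 360, min_coverage = 0.8) {
  stopifnot(inherits(trace, "vent_trace"))
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (min_coverage < 0 || min_coverage > 1) {
    stop("`min_coverage` must lie in [0, 1]", call. = FALSE)
  }
  sel <- trace$times >= (t - window) & trace$times < t
  n <- sum(sel)
  expected <- window / trace$step
  coverage <- min(1, n / expected)
  mean_v <- if (n > 0L && coverage >= min_coverage) mean(trace$vco2[sel]) else NA_real_
  list(mean = mean_v, coverage = coverage, n = n)
}

#' Pair IC measurements with preceding ventilator VCO2 blocks
#'
#' Builds the analysis dataset: one row per indirect-calorimetry measurement
#' whose preceding ventilator window meets the coverage requirement. The
#' reference REE is computed from the IC gases by the Weir equation; the
#' VCO2-only estimates apply [ree_from_vco2()] to the block mean at every RQ
#' of the grid. Rows are sorted by patient then time. Measurements from
#' patients without a trace, or with an under-covered window, are dropped with
#' a warning; the excluded rows are kept in the `excluded` attribute.
#'
#' @param ic Data frame of IC measurements with columns `patient_id`,
#'   `time_min`, `vo2_ml_min`, `vco2_ml_min` (as written by [write_cohort()]).
#' @param traces Named list of [vent_trace()] objects (names = patient ids),
#'   or a data frame with columns `patient_id`, `time_min`, `vco2_ml_min`.
#' @param rq_grid An [rq_grid()].
#' @param window,min_coverage Block aggregation settings; see
#'   [block_mean_vco2()].
#' @param coeffs [weir_coefficients()].
#' @return A tibble of class `paired_dataset` with columns `patient_id`,
#'   `time_min`, `ree_ic`, `block_vco2`, `coverage` and one
#'   `ree_vco2_rq<value>` column per grid RQ. Attributes: `rq_grid`,
#'   `window_minutes`, `min_coverage`, `excluded`.
#' @export
build_paired_dataset <- function(ic, traces, rq_grid = vco2ree::rq_grid(),
                                 window = 360, min_coverage = 0.8,
                                 coeffs = weir_coefficients()) {
  ic <- as.data.frame(ic)
  need <- c("patient_id", "time_min", "vo2_ml_min", "vco2_ml_min")
  missing_cols <- setdiff(need, names(ic))
  if (length(missing_cols) > 0L) {
    stop("IC table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(traces)) traces <- traces_from_long(traces)
  stopifnot(is.list(traces))

  ic <- ic[order(ic$patient_id, ic$time_min), , drop = FALSE]
  n <- nrow(ic)
  block <- numeric(n); coverage <- numeric(n); reason <- character(n)
  for (j in seq_len(n)) {
    tr <- traces[[ic$patient_id[j]]]
    if (is.null(tr)) {
      block[j] <- NA_real_; coverage[j] <- 0; reason[j] <- "no_trace"
      next
    }
    bm <- block_mean_vco2(tr, ic$time_min[j], window = window,
                          min_coverage = min_coverage)
    block[j] <- bm$mean
    coverage[j] <- bm$coverage
    reason[j] <- if (is.na(bm$mean)) "low_coverage" else ""
  }

  keep <- !is.na(block)
  excluded <- tibble::tibble(
    patient_id = ic$patient_id[!keep], time_min = ic$time_min[!keep],
    reason = reason[!keep]
  )
  if (nrow(excluded) > 0L) {
    warning(sprintf("%d of %d IC measurements excluded (%s)",
                    nrow(excluded), n,
                    paste(sprintf("%s: %d", names(table(excluded$reason)),
                                  as.integer(table(excluded$reason))),
                          collapse = ", ")),
            call. = FALSE)
  }
  if (!any(keep)) stop("no IC measurement could be paired with a ventilator block",
                       call. = FALSE)

  out <- tibble::tibble(
    patient_id = ic$patient_id[keep],
    time_min = ic$time_min[keep],
    ree_ic = ree_weir(ic$vo2_ml_min[keep], ic$vco2_ml_min[keep], coeffs),
    block_vco2 = block[keep],
    coverage = coverage[keep]
  )
  for (rq in as.numeric(rq_grid)) {
    out[[sprintf("ree_vco2_rq%.2f", rq)]] <-
      ree_from_vco2(out$block_vco2, rq, coeffs)
  }
  structure(out,
            rq_grid = as.numeric(rq_grid),
            window_minutes = window,
            min_coverage = min_coverage,
            excluded = excluded,
            class = c("paired_dataset", class(out)))
}

# Long-format trace table (patient_id, time_min, vco2_ml_min) -> named list of
# vent_trace objects.
traces_from_long <- function(df) {
  need <- c("patient_id", "time_min", "vco2_ml_min")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("trace table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  parts <- split(df[c("time_min", "vco2_ml_min")], df$patient_id)
  out <- lapply(names(parts), function(pid) {
    vent_trace(pid, parts[[pid]]$time_min, parts[[pid]]$vco2_ml_min)
  })
  names(out) <- names(parts)
  out
}
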