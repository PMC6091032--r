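check_pair <- function(est, ref, min_n = 2L) {
  if (length(est) != length(ref)) {
    stop("`est` and `ref` must have equal length", call. = FALSE)
  }
  if (length(est) < min_n) {
    stop(sprintf("need at least %d paired observations", min_n), call. = FALSE)
  }
  if (any(!is.finite(est)) || any(!is.finite(ref))) {
    stop("`est` and `ref` must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Mean difference and SD of differences
#'
#' Bias of the estimate relative to the reference: mean and sample standard
#' deviation (n - 1 denominator) of `est - ref`.
#'
#' @param est,ref Paired estimates and reference values (kcal/day), equal
#'   length, n >= 2.
#' @return Named numeric vector: `mean_difference`, `sd_difference`.
#' @examples
#' bias_and_sd(c(1900, 2100, 2000), c(2000, 2000, 2000)) # 0, 100
#' @export
bias_and_sd <- function(est, ref) {
  check_pair(est, ref, 2L)
  d <- est - ref
  c(mean_difference = mean(d), sd_difference = stats::sd(d))
}

#' Fraction of estimates within a ratio band of the reference
#'
#' The agreement statistic used in calorimetry validation: the proportion of
#' pairs whose ratio est/ref falls in a closed interval, e.g. \[0.85, 1.15\]
#' ("within 85% and 115% of measured REE") or the tight band \[0.95, 1.05\].
#'
#' @param est,ref Paired values; `ref` must be strictly positive.
#' @param low,high Band limits as ratios, `low < high`.
#' @return Fraction in \[0, 1\].
#' @examples
#' ratio_band_agreement(c(0.8, 0.9, 1, 1.1, 1.2), rep(1, 5), 0.85, 1.15) # 0.6
#' @export
ratio_band_agreement <- function(est, ref, low = 0.85, high = 1.15) {
  check_pair(est, ref, 1L)
  if (any(ref <= 0)) stop("`ref` must be strictly positive", call. = FALSE)
  if (low >= high) stop("`low` must be below `high`", call. = FALSE)
  r <- est / ref
  mean(r >= low & r <= high)
}

# n-denominator moments used by Lin's CCC
ccc_point <- function(est, ref) {
  n <- length(est)
  mx <- mean(est); my <- mean(ref)
  sx2 <- mean((est - mx)^2); sy2 <- mean((ref - my)^2)
  sxy <- mean((est - mx) * (ref - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line:
#' ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with n-denominator
#' moments. Unlike Pearson's r it penalises both location and scale shifts, so
#' |ccc| <= |r| always. The confidence interval is a nonparametric bootstrap
#' percentile interval by default; Lin's asymptotic Fisher-z interval is
#' available as `ci_method = "fisher"`.
#'
#' @param est,ref Paired values, n >= 3, both with non-zero variance.
#' @param ci_method `"bootstrap"` (percentile) or `"fisher"` (asymptotic z).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector: `ccc`, `ci_low`, `ci_high`.
#' @examples
#' lin_ccc(c(1, 2, 3, 4), c(2, 3, 4, 6), ci_method = "fisher") # ccc = 0.65
#' @export
lin_ccc <- function(est, ref, ci_method = c("bootstrap", "fisher"),
                    n_boot = 2000L, seed = 1L, conf = 0.95) {
  ci_method <- match.arg(ci_method)
  check_pair(est, ref, 3L)
  if (stats::var(est) == 0) stop("`est` has zero variance", call. = FALSE)
  if (stats::var(ref) == 0) stop("`ref` has zero variance", call. = FALSE)
  n <- length(est)
  ccc <- ccc_point(est, ref)
  alpha <- 1 - conf

  if (ci_method == "bootstrap") {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    reps <- apply(idx, 2L, function(ii) ccc_point(est[ii], ref[ii]))
    ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          na.rm = TRUE)
  } else {
    # Lin (1989, correction 2000) asymptotic variance of atanh(ccc)
    r <- stats::cor(est, ref)
    sx <- sqrt(mean((est - mean(est))^2))
    sy <- sqrt(mean((ref - mean(ref))^2))
    u <- (mean(est) - mean(ref)) / sqrt(sx * sy)
    z <- atanh(ccc)
    se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    half <- stats::qnorm(1 - alpha / 2) * sqrt(se2)
    ci <- tanh(c(z - half, z + half))
  }
  c(ccc = ccc, ci_low = ci[1], ci_high = ci[2])
}

# Save/restore the global RNG state so seeded internals do not disturb the
# caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param est,ref Paired values, n >= 4, both with non-zero variance.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector: `r`, `ci_low`, `ci_high`.
#' @export
pearson_with_ci <- function(est, ref, conf = 0.95) {
  check_pair(est, ref, 4L)
  if (stats::var(est) == 0) stop("`est` has zero variance", call. = FALSE)
  if (stats::var(ref) == 0) stop("`ref` has zero variance", call. = FALSE)
  ct <- stats::cor.test(est, ref, method = "pearson", conf.level = conf)
  c(r = unname(ct$estimate), ci_low = ct$conf.int[1], ci_high = ct$conf.int[2])
}

#' Percentage error and percentage difference
#'
#' Relative-discrepancy summaries of an estimator against a reference. The
#' published validation literature prints "% error" and "% difference" without
#' defining them, so both are configurable:
#' * `error_mode = "mean_abs_relative"` (default): mean(|est - ref| / ref).
#' * `error_mode = "critchley"`: 1.96 * SD(est - ref) / mean(ref), the
#'   method-comparison percentage-error criterion.
#' * `difference_mode = "mean_abs_pair_relative"` (default):
#'   mean(|est - ref| / ((est + ref)/2)).
#' * `difference_mode = "mean_signed_relative"`: mean((est - ref) / ref).
#'
#' @param est,ref Paired values; `ref` strictly positive.
#' @param error_mode,difference_mode Mode names as above.
#' @return Named numeric vector of fractions: `pct_error`, `pct_difference`.
#' @examples
#' percentage_metrics(c(900, 1100), c(1000, 1000)) # pct_error = 0.10
#' @export
percentage_metrics <- function(est, ref,
                               error_mode = c("mean_abs_relative", "critchley"),
                               difference_mode = c("mean_abs_pair_relative",
                                                   "mean_signed_relative")) {
  error_mode <- match.arg(error_mode)
  difference_mode <- match.arg(difference_mode)
  check_pair(est, ref, 2L)
  if (any(ref <= 0)) stop("`ref` must be strictly positive", call. = FALSE)
  pe <- switch(error_mode,
    mean_abs_relative = mean(abs(est - ref) / ref),
    critchley = 1.96 * stats::sd(est - ref) / mean(ref)
  )
  pd <- switch(difference_mode,
    mean_abs_pair_relative = mean(abs(est - ref) / ((est + ref) / 2)),
    mean_signed_relative = mean((est - ref) / ref)
  )
  c(pct_error = pe, pct_difference = pd)
}

#' Bland-Altman analysis
#'
#' Differences against pair means, with bias and 95% limits of agreement
#' bias +/- 1.96 * SD of the differences (normal-quantile multiplier, not
#' t-adjusted; at the hundreds of pairs typical here the distinction is
#' negligible).
#'
#' @param est,ref Paired values, n >= 2.
#' @return An object of class `bland_altman`: list with `bias`, `sd`,
#'   `loa_low`, `loa_high`, `n` and `points` (tibble: `pair_mean`,
#'   `difference`).
#' @export
bland_altman <- function(est, ref) {
  check_pair(est, ref, 2L)
  d <- est - ref
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         n = length(d),
         points = tibble::tibble(pair_mean = (est + ref) / 2, difference = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f, 95%% LoA [%.2f, %.2f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

# Full battery for one estimate column. Degenerate variance yields NA
# correlation/concordance with a warning rather than an error, so an
# all-constant estimator can still be summarised.
agreement_battery <- function(est, ref,
                              bands = list(agreement = c(0.85, 1.15),
                                           tight = c(0.95, 1.05)),
                              error_mode = "mean_abs_relative",
                              difference_mode = "mean_abs_pair_relative",
                              ccc_ci = "bootstrap", n_boot = 2000L, seed = 1L) {
  bs <- bias_and_sd(est, ref)
  pm <- percentage_metrics(est, ref, error_mode, difference_mode)
  degenerate <- stats::var(est) == 0 || stats::var(ref) == 0
  if (degenerate) {
    warning("zero variance in est or ref: correlation and concordance are NA",
            call. = FALSE)
    pr <- c(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    cc <- c(ccc = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  } else {
    pr <- pearson_with_ci(est, ref)
    cc <- lin_ccc(est, ref, ci_method = ccc_ci, n_boot = n_boot, seed = seed)
  }
  tibble::tibble(
    n = length(est),
    mean_difference = unname(bs["mean_difference"]),
    sd_difference = unname(bs["sd_difference"]),
    pct_error = unname(pm["pct_error"]),
    pct_difference = unname(pm["pct_difference"]),
    pearson_r = unname(pr["r"]),
    pearson_ci_low = unname(pr["ci_low"]),
    pearson_ci_high = unname(pr["ci_high"]),
    ccc = unname(cc["ccc"]),
    ccc_ci_low = unname(cc["ci_low"]),
    ccc_ci_high = unname(cc["ci_high"]),
    agreement = ratio_band_agreement(est, ref, bands$agreement[1],
                                     bands$agreement[2]),
    tight_agreement = ratio_band_agreement(est, ref, bands$tight[1],
                                           bands$tight[2])
  )
}

#' Agreement battery per RQ of a paired dataset
#'
#' Computes, for each fixed-RQ estimator column of a [build_paired_dataset()]
#' result, the full method-comparison battery: bias (mean difference) and its
#' SD, percentage error and percentage difference, Pearson correlation with
#' Fisher-z CI, Lin's concordance correlation with CI, and the fraction of
#' estimates inside the agreement (85-115%) and tight-agreement (95-105%)
#' ratio bands.
#'
#' @param ds A `paired_dataset`.
#' @param bands List with `agreement` and `tight` (low, high) ratio pairs.
#' @param error_mode,difference_mode See [percentage_metrics()].
#' @param ccc_ci,n_boot,seed See [lin_ccc()].
#' @return A tibble with one row per grid RQ (in grid order), columns `rq`
#'   plus the battery columns.
#' @export
performance_table <- function(ds,
                              bands = list(agreement = c(0.85, 1.15),
                                           tight = c(0.95, 1.05)),
                              error_mode = "mean_abs_relative",
                              difference_mode = "mean_abs_pair_relative",
                              ccc_ci = "bootstrap", n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (nrow(ds) == 0L) stop("empty paired dataset", call. = FALSE)
  grid <- attr(ds, "rq_grid")
  rows <- lapply(grid, function(rq) {
    est <- ds[[sprintf("ree_vco2_rq%.2f", rq)]]
    cbind(tibble::tibble(rq = rq),
          agreement_battery(est, ds$ree_ic, bands = bands,
                            error_mode = error_mode,
                            difference_mode = difference_mode,
                            ccc_ci = ccc_ci, n_boot = n_boot, seed = seed))
  })
  tibble::as_tibble(do.call(rbind, rows))
}
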