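# Closed-form single-predictor ridge: minimises
#   sum((y - a - b * x_s)^2) + lambda * b^2
# on the standardized predictor x_s = (x - mean(x)) / sd(x) (n - 1 SD), with
# the intercept unpenalized, then maps (a, b) back to the mL/min scale.
ridge_closed <- function(x, y, lambda) {
  xbar <- mean(x); sx <- stats::sd(x)
  xs <- (x - xbar) / sx
  ybar <- mean(y)
  b_s <- sum(xs * (y - ybar)) / (sum(xs^2) + lambda)
  slope <- b_s / sx
  c(intercept = ybar - slope * xbar, slope = slope)
}

#' Ridge calibration of REE on VCO2
#'
#' Fits REE (kcal/day) on VCO2 (mL/min) by penalized linear regression. The
#' predictor is standardized (mean 0, SD 1) before penalization and the
#' intercept is left unpenalized; the solution per penalty is closed-form.
#' The penalty weight is selected by k-fold cross-validated squared error
#' (folds shuffled with `seed`; standardization is recomputed inside each
#' training fold). Coefficients are reported back on the original mL/min
#' scale, and R-squared is computed in-sample on the selected fit.
#'
#' With a single well-conditioned predictor the penalty matters little -- the
#' CV-selected lambda is typically near the bottom of the grid and the fit is
#' essentially ordinary least squares; the grid exists to keep the procedure
#' well-defined and to support sensitivity checks.
#'
#' @param vco2 Predictor, mL/min; non-degenerate.
#' @param ree Response, kcal/day.
#' @param lambda_grid Candidate penalty weights (on the standardized scale);
#'   non-empty, non-negative. Default log-spaced 1e-4..1e2.
#' @param cv_folds Number of CV folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @return An object of class `calibration_result`: `intercept`, `slope`,
#'   `lambda`, `r2`, `n`, plus the CV table (`lambda_grid`, `cv_mse`).
#' @examples
#' v <- seq(100, 400, length.out = 50)
#' fit_ridge(v, 135 + 8 * v, lambda_grid = 0, cv_folds = 5)
#' @export
fit_ridge <- function(vco2, ree, lambda_grid = 10^seq(-4, 2, length.out = 25),
                      cv_folds = 10L, seed = 1L) {
  if (length(vco2) != length(ree)) {
    stop("`vco2` and `ree` must have equal length", call. = FALSE)
  }
  n <- length(vco2)
  if (n < max(cv_folds, 3L)) {
    stop("too few observations for the requested folds", call. = FALSE)
  }
  if (stats::sd(vco2) == 0) stop("`vco2` has zero variance", call. = FALSE)
  if (length(lambda_grid) == 0L) stop("`lambda_grid` is empty", call. = FALSE)
  if (any(lambda_grid < 0)) stop("`lambda_grid` must be non-negative", call. = FALSE)
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))

  if (length(lambda_grid) > 1L) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv_folds), n))
    cv_mse <- vapply(lambda_grid, function(lam) {
      errs <- vapply(seq_len(cv_folds), function(k) {
        tr <- fold != k
        if (stats::sd(vco2[tr]) == 0) return(NA_real_)
        cf <- ridge_closed(vco2[tr], ree[tr], lam)
        mean((ree[!tr] - cf["intercept"] - cf["slope"] * vco2[!tr])^2)
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    lambda <- lambda_grid[which.min(cv_mse)]   # ties: smallest lambda
  } else {
    cv_mse <- NA_real_
    lambda <- lambda_grid
  }

  cf <- ridge_closed(vco2, ree, lambda)
  fitted <- cf["intercept"] + cf["slope"] * vco2
  rss <- sum((ree - fitted)^2)
  tss <- sum((ree - mean(ree))^2)
  r2 <- if (tss == 0) 1 else max(0, min(1, 1 - rss / tss))
  structure(
    list(intercept = unname(cf["intercept"]), slope = unname(cf["slope"]),
         lambda = lambda, r2 = r2, n = n,
         lambda_grid = lambda_grid, cv_mse = cv_mse, cv_folds = cv_folds),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Ridge calibration (n = %d): REE = %.2f + %.4f * VCO2, lambda = %g, R2 = %.3f\n",
    x$n, x$intercept, x$slope, x$lambda, x$r2
  ))
  invisible(x)
}

# Half-away-from-zero rounding (base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Round a fitted calibration to a bedside formula
#'
#' Rounds the fitted intercept and slope half-away-from-zero at the requested
#' precision (both to integers by default), producing a memorable linear
#' formula such as REE = 135 + 8 * VCO2.
#'
#' @param result A [fit_ridge()] result, or any list with numeric `intercept`
#'   and `slope`.
#' @param slope_decimals,intercept_decimals Decimal places kept (default 0).
#' @return A [simplified_formula()].
#' @examples
#' round_to_simplified(list(intercept = 135.4, slope = 7.96))
#' @export
round_to_simplified <- function(result, slope_decimals = 0L,
                                intercept_decimals = 0L) {
  if (!is.list(result) || is.null(result$intercept) || is.null(result$slope)) {
    stop("`result` must carry `intercept` and `slope`", call. = FALSE)
  }
  simplified_formula(
    intercept = round_half_away(result$intercept, intercept_decimals),
    slope = round_half_away(result$slope, slope_decimals)
  )
}

#' Evaluate a simplified formula on a paired dataset
#'
#' Applies the linear formula to each row's ventilator block VCO2 and runs the
#' full agreement battery against the IC reference REE.
#'
#' @param formula A [simplified_formula()], or any list with numeric
#'   `intercept` and `slope` (so degenerate formulas can be probed).
#' @param ds A `paired_dataset`.
#' @inheritParams performance_table
#' @return A one-row tibble with the battery columns (as in
#'   [performance_table()], without the `rq` column).
#' @export
evaluate_formula <- function(formula, ds,
                             bands = list(agreement = c(0.85, 1.15),
                                          tight = c(0.95, 1.05)),
                             error_mode = "mean_abs_relative",
                             difference_mode = "mean_abs_pair_relative",
                             ccc_ci = "bootstrap", n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (nrow(ds) == 0L) stop("empty paired dataset", call. = FALSE)
  if (!is.list(formula) || is.null(formula$intercept) || is.null(formula$slope)) {
    stop("`formula` must carry `intercept` and `slope`", call. = FALSE)
  }
  if (any(ds$ree_ic <= 0)) stop("reference REE must be strictly positive",
                                call. = FALSE)
  est <- formula$intercept + formula$slope * ds$block_vco2
  agreement_battery(est, ds$ree_ic, bands = bands, error_mode = error_mode,
                    difference_mode = difference_mode, ccc_ci = ccc_ci,
                    n_boot = n_boot, seed = seed)
}
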