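#' Weir equation coefficients
#'
#' Caloric equivalents used by the nitrogen-free (two-term) Weir equation:
#' REE (kcal/day) = (a_vo2 * VO2 + b_vco2 * VCO2) * 1440, with gas rates in
#' L/min. The defaults (3.941 kcal per L O2, 1.106 kcal per L CO2) are the
#' classical values used throughout the indirect-calorimetry literature; they
#' are configurable to support sensitivity analysis. The day scaling is fixed
#' at 1440 min/day.
#'
#' @param a_vo2 Caloric equivalent of oxygen, kcal per litre of O2. Default 3.941.
#' @param b_vco2 Caloric equivalent of carbon dioxide, kcal per litre of CO2.
#'   Default 1.106.
#'
#' @return An object of class `weir_coefficients`.
#' @examples
#' weir_coefficients()
#' @export
weir_coefficients <- function(a_vo2 = 3.941, b_vco2 = 1.106) {
  if (!is.numeric(a_vo2) || length(a_vo2) != 1L || !is.finite(a_vo2) || a_vo2 <= 0) {
    stop("`a_vo2` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(b_vco2) || length(b_vco2) != 1L || !is.finite(b_vco2) || b_vco2 <= 0) {
    stop("`b_vco2` must be a single positive number", call. = FALSE)
  }
  structure(
    list(a_vo2 = a_vo2, b_vco2 = b_vco2, minutes_per_day = 1440L),
    class = "weir_coefficients"
  )
}

#' @export
print.weir_coefficients <- function(x, ...) {
  cat(sprintf(
    "Weir coefficients: %.3f kcal/L O2, %.3f kcal/L CO2, x%d min/day\n",
    x$a_vo2, x$b_vco2, x$minutes_per_day
  ))
  invisible(x)
}

# RQ sanity bounds. The physiology gives ~0.7 (fat) to ~1.0 (carbohydrate);
# (0.3, 2.0) is a deliberately loose guard against unit errors, not a clinical
# range.
.rq_lower <- 0.3
.rq_upper <- 2.0

check_rq <- function(rq, what = "rq") {
  if (!is.numeric(rq) || any(!is.finite(rq)) ||
      any(rq <= .rq_lower) || any(rq >= .rq_upper)) {
    stop(sprintf("`%s` must lie in (%.1f, %.1f)", what, .rq_lower, .rq_upper),
         call. = FALSE)
  }
  invisible(rq)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and finite", what), call. = FALSE)
  }
  invisible(x)
}

#' Grid of fixed respiratory quotients
#'
#' The RQ values at which the VCO2-only estimator is evaluated. The default
#' grid {0.75, 0.80, 0.85, 0.89} spans the commonly assumed clinical values:
#' ~0.7 for predominantly fat oxidation up to ~0.9 for mixed/carbohydrate
#' substrate use.
#'
#' @param values Strictly increasing numeric vector of RQ values in (0.3, 2).
#' @return An object of class `rq_grid` (a numeric vector).
#' @examples
#' rq_grid()
#' rq_grid(c(0.8, 0.85))
#' @export
rq_grid <- function(values = c(0.75, 0.80, 0.85, 0.89)) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  check_rq(values, "values")
  if (is.unsorted(values, strictly = TRUE)) {
    stop("`values` must be strictly increasing", call. = FALSE)
  }
  structure(as.numeric(values), class = "rq_grid")
}

#' Resting energy expenditure by the Weir equation
#'
#' The nitrogen-free Weir equation. Gas rates are taken in mL/min (the unit in
#' which ventilators and calorimeters report them) and converted to L/min
#' internally before the caloric coefficients are applied.
#'
#' @param vo2 Oxygen consumption, mL/min. Vectorised.
#' @param vco2 Carbon dioxide production, mL/min. Vectorised.
#' @param coeffs A [weir_coefficients()] object.
#' @return REE in kcal/day.
#' @examples
#' ree_weir(250, 200) # approximately 1736 kcal/day
#' @export
ree_weir <- function(vo2, vco2, coeffs = weir_coefficients()) {
  check_nonneg(vo2, "vo2")
  check_nonneg(vco2, "vco2")
  (coeffs$a_vo2 * vo2 / 1000 + coeffs$b_vco2 * vco2 / 1000) * coeffs$minutes_per_day
}

#' Per-litre VCO2 multiplier at a fixed RQ
#'
#' Substituting VO2 = VCO2/RQ into the Weir equation collapses it to
#' REE = (a_vo2/RQ + b_vco2) * VCO2(L/min) * 1440. This returns the combined
#' coefficient a_vo2/RQ + b_vco2 (before the x1440 day scaling). At RQ 0.89 and
#' the default coefficients it equals 5.534, whose rounded presentation is the
#' familiar bedside form 5.5 x VCO2 x 1.44.
#'
#' @param rq Assumed respiratory quotient, in (0.3, 2). Vectorised.
#' @inheritParams ree_weir
#' @return kcal per litre of VCO2 per minute-equivalent. Strictly decreasing
#'   in `rq`.
#' @examples
#' round(vco2_multiplier(0.89), 3) # 5.534
#' @export
vco2_multiplier <- function(rq, coeffs = weir_coefficients()) {
  check_rq(rq)
  coeffs$a_vo2 / rq + coeffs$b_vco2
}

#' VCO2-only REE estimate at a fixed RQ
#'
#' Estimates REE from CO2 production alone by assuming a fixed respiratory
#' quotient and deriving VO2 = VCO2/RQ. Algebraically identical to
#' `ree_weir(vco2 / rq, vco2)`.
#'
#' @param vco2 Carbon dioxide production, mL/min. Vectorised.
#' @inheritParams vco2_multiplier
#' @return REE in kcal/day.
#' @examples
#' ree_from_vco2(250, rq = 0.89) # 5.534 * 0.250 * 1440
#' @export
ree_from_vco2 <- function(vco2, rq, coeffs = weir_coefficients()) {
  check_nonneg(vco2, "vco2")
  check_rq(rq)
  vco2_multiplier(rq, coeffs) * (vco2 / 1000) * coeffs$minutes_per_day
}

#' Respiratory quotient from measured gas exchange
#'
#' @param vo2 Oxygen consumption, mL/min; must be strictly positive.
#' @param vco2 Carbon dioxide production, mL/min.
#' @return RQ = VCO2/VO2, dimensionless.
#' @examples
#' compute_rq(250, 200) # 0.8
#' @export
compute_rq <- function(vo2, vco2) {
  if (!is.numeric(vo2) || any(!is.finite(vo2)) || any(vo2 <= 0)) {
    stop("`vo2` must be strictly positive", call. = FALSE)
  }
  check_nonneg(vco2, "vco2")
  vco2 / vo2
}

#' Simplified linear REE formula
#'
#' A bedside-usable linear formula REE = intercept + slope * VCO2 (mL/min),
#' typically obtained by rounding the coefficients of a regression calibration
#' (see [fit_ridge()] and [round_to_simplified()]). Defaults are the published
#' calibration REE = 135 + 8 * VCO2.
#'
#' @param intercept kcal/day.
#' @param slope kcal/day per mL/min of VCO2; must be positive.
#' @return An object of class `simplified_formula`.
#' @examples
#' simplified_formula()
#' @export
simplified_formula <- function(intercept = 135, slope = 8) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("`intercept` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    stop("`slope` must be a single positive number", call. = FALSE)
  }
  structure(list(intercept = intercept, slope = slope), class = "simplified_formula")
}

#' @export
print.simplified_formula <- function(x, ...) {
  cat(sprintf("REE (kcal/day) = %g + %g * VCO2 (mL/min)\n", x$intercept, x$slope))
  invisible(x)
}

#' Evaluate a simplified linear REE formula
#'
#' @param vco2 Carbon dioxide production, mL/min. Vectorised.
#' @param formula A [simplified_formula()] object.
#' @return REE in kcal/day.
#' @examples
#' simplified_ree(244.5) # 2091 with the default 135 + 8 * VCO2
#' @export
simplified_ree <- function(vco2, formula = simplified_formula()) {
  check_nonneg(vco2, "vco2")
  formula$intercept + formula$slope * vco2
}
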