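# Measurements-per-patient distribution on 1..15, coarse-fit so that the
# population quartiles are (2, 3, 7) -- median 3, IQR 2-7, matching the
# skewed per-patient measurement counts typical of retrospective ICU
# calorimetry cohorts. The exact distribution is unidentified from two
# quantiles; this is one fixed choice.
.meas_count_pmf <- c(0.12, 0.22, 0.20, 0.09, 0.06, 0.05, 0.06, 0.05,
                     0.04, 0.04, 0.03, 0.02, 0.01, 0.005, 0.005)

# Default relative SD of the per-record multiplicative ventilator-trace noise,
# frozen at the tune_vent_noise() output for a pooled estimator-reference
# Pearson correlation of 0.51 (the level reported for ventilator-block VCO2
# against calorimetry in adult ICU validation work). A correlation this low
# requires heavy trace noise relative to the between-measurement REE spread.
.default_vent_noise_sd <- 1.289

#' Configuration of the synthetic ICU cohort
#'
#' Describes the generative model for a synthetic cohort of mechanically
#' ventilated patients with repeated indirect-calorimetry (IC) measurements
#' and a continuous ventilator VCO2 trace. Defaults emulate the marginal
#' statistics of published adult ICU validation cohorts: 80 patients, a median
#' of 3 (IQR 2-7) IC measurements per patient, REE 2059.5 +/- 491.7 kcal/day,
#' measured RQ 0.75 +/- 0.07.
#'
#' The generative chain per measurement is: true REE = patient random effect
#' (Normal, between-patient SD) + measurement deviation (Normal, within-patient
#' SD), truncated above `ree_floor`; true RQ drawn from a truncated Normal;
#' true VCO2 solved from the Weir relation (so IC-observed gases reproduce the
#' true REE exactly -- IC is the reference method); the ventilator trace is the
#' true VCO2 times `vent_bias` times stationary lognormal AR(1) multiplicative
#' noise with unit mean, sampled every `trace_step` minutes.
#'
#' @param n_patients Number of patients (default 80).
#' @param meas_pmf Probability vector over 1..length(meas_pmf) IC measurements
#'   per patient. The default targets median 3, IQR 2-7.
#' @param ree_mean,ree_sd Marginal mean and SD of true REE, kcal/day.
#' @param ree_between_frac Fraction of total REE variance assigned to the
#'   between-patient random effect (default 0.6; the remainder is
#'   within-patient).
#' @param ree_floor Lower truncation of true REE, kcal/day (default 500).
#' @param rq_mean,rq_sd Marginal (post-truncation) mean and SD of the true RQ.
#'   The latent normal's location and scale are solved internally so the
#'   truncated draw reproduces these moments exactly.
#' @param rq_bounds Truncation interval for RQ (default c(0.60, 1.10)); must
#'   contain `rq_mean`.
#' @param vent_bias Multiplicative bias of the ventilator VCO2 trace relative
#'   to true VCO2 (default 1: unbiased device).
#' @param vent_noise_sd Relative SD of the per-record multiplicative trace
#'   noise (lognormal, unit mean). Default tuned so the pooled correlation
#'   between the fixed-RQ estimator and the IC reference is about 0.51; see
#'   [tune_vent_noise()].
#' @param ar_coef AR(1) coefficient of the log-noise process (default 0.8).
#' @param trace_step Minutes between ventilator records (default 5).
#' @param meas_spacing Minutes between successive IC measurements of one
#'   patient (default 720, so 6-h aggregation windows never overlap).
#' @param first_meas_time Minutes from cohort epoch to each patient's first
#'   measurement (default 420, leaving a full 6-h window of trace before it).
#' @param seed Integer root seed. Per-patient child streams are derived from
#'   it, so extending the cohort never perturbs earlier patients.
#' @param coeffs [weir_coefficients()] used to invert the Weir relation.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n_patients = 10, seed = 42)
#' @export
cohort_config <- function(n_patients = 80,
                          meas_pmf = .meas_count_pmf,
                          ree_mean = 2059.5,
                          ree_sd = 491.7,
                          ree_between_frac = 0.6,
                          ree_floor = 500,
                          rq_mean = 0.75,
                          rq_sd = 0.07,
                          rq_bounds = c(0.60, 1.10),
                          vent_bias = 1.0,
                          vent_noise_sd = .default_vent_noise_sd,
                          ar_coef = 0.8,
                          trace_step = 5,
                          meas_spacing = 720,
                          first_meas_time = 420,
                          seed = 1L,
                          coeffs = weir_coefficients()) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("`n_patients` must be at least 1", call. = FALSE)
  }
  if (any(meas_pmf < 0) || sum(meas_pmf) <= 0) {
    stop("`meas_pmf` must be a non-negative probability vector", call. = FALSE)
  }
  if (ree_sd < 0) stop("`ree_sd` must be non-negative", call. = FALSE)
  if (ree_between_frac < 0 || ree_between_frac > 1) {
    stop("`ree_between_frac` must lie in [0, 1]", call. = FALSE)
  }
  if (ree_mean <= ree_floor) {
    stop("`ree_mean` must exceed `ree_floor`: truncation would be degenerate",
         call. = FALSE)
  }
  if (rq_sd < 0) stop("`rq_sd` must be non-negative", call. = FALSE)
  if (length(rq_bounds) != 2L || rq_bounds[1] >= rq_bounds[2] ||
      rq_mean < rq_bounds[1] || rq_mean > rq_bounds[2]) {
    stop("`rq_bounds` must be an interval containing `rq_mean`", call. = FALSE)
  }
  check_rq(rq_bounds, "rq_bounds")
  if (vent_bias <= 0) stop("`vent_bias` must be positive", call. = FALSE)
  if (vent_noise_sd < 0) stop("`vent_noise_sd` must be non-negative", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("`ar_coef` must lie in (-1, 1)", call. = FALSE)
  if (trace_step <= 0) stop("`trace_step` must be positive", call. = FALSE)
  if (meas_spacing <= 0) stop("`meas_spacing` must be positive", call. = FALSE)
  if (first_meas_time <= 0) stop("`first_meas_time` must be positive", call. = FALSE)
  structure(
    list(
      n_patients = as.integer(n_patients),
      meas_pmf = meas_pmf / sum(meas_pmf),
      ree_mean = ree_mean, ree_sd = ree_sd,
      ree_between_frac = ree_between_frac, ree_floor = ree_floor,
      rq_mean = rq_mean, rq_sd = rq_sd, rq_bounds = rq_bounds,
      vent_bias = vent_bias, vent_noise_sd = vent_noise_sd,
      ar_coef = ar_coef, trace_step = trace_step,
      meas_spacing = meas_spacing, first_meas_time = first_meas_time,
      seed = as.integer(seed), coeffs = coeffs
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic cohort config: %d patients, REE %.1f +/- %.1f kcal/d ",
           "(between-patient fraction %.2f), RQ %.2f +/- %.2f on [%.2f, %.2f],\n",
           "  ventilator bias %.3f, trace noise rel-SD %.3f (AR1 %.2f), ",
           "step %g min, seed %d\n"),
    x$n_patients, x$ree_mean, x$ree_sd, x$ree_between_frac,
    x$rq_mean, x$rq_sd, x$rq_bounds[1], x$rq_bounds[2],
    x$vent_bias, x$vent_noise_sd, x$ar_coef, x$trace_step, x$seed
  ))
  invisible(x)
}

# Moments of a Normal(mu, sigma) truncated to [lower, upper].
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma; b <- (upper - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# Latent-normal parameters whose truncation to [lower, upper] has the
# requested marginal mean and SD. Asymmetric truncation otherwise biases the
# realized moments away from the configured ones.
truncnorm_params <- function(mean, sd, lower, upper) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lower, upper)
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-8) {
    stop("cannot match truncated-normal moments inside the given bounds",
         call. = FALSE)
  }
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Truncated-normal draw by rejection; exact and fast far from the tails.
rtruncnorm_reject <- function(n, mean, sd, lower = -Inf, upper = Inf,
                              max_iter = 10000L) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncated normal: mean outside bounds", call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  iter <- 0L
  while (length(bad) > 0L) {
    iter <- iter + 1L
    if (iter > max_iter) stop("truncated-normal rejection failed to converge",
                              call. = FALSE)
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# Stationary AR(1) log-noise, returned as a unit-mean multiplicative factor.
# `rel_sd` is the marginal relative SD of the factor.
lognormal_ar1_factor <- function(n, rel_sd, phi) {
  if (rel_sd == 0 || n == 0L) return(rep(1, n))
  s <- sqrt(log(1 + rel_sd^2))           # marginal SD on the log scale
  z0 <- stats::rnorm(1, 0, s)
  innov <- stats::rnorm(n, 0, s * sqrt(1 - phi^2))
  z <- as.numeric(stats::filter(innov, phi, method = "recursive", init = z0))
  exp(z - s^2 / 2)
}

#' Generate a synthetic ICU cohort
#'
#' Draws a cohort under the generative model described in [cohort_config()].
#' Deterministic given the config's seed: each patient has an independent
#' child random stream derived from the root seed, so the first k patients of
#' an n-patient cohort are identical to a k-patient cohort.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: a list with
#'   `ic_samples` (tibble: patient_id, time_min, vo2_ml_min, vco2_ml_min,
#'   ree_kcal_d, rq), `traces` (named list of [vent_trace()] objects),
#'   `ground_truth` (tibble: patient_id, time_min, true_ree_kcal_d,
#'   true_vco2_ml_min, true_rq) and the `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 7))
#' nrow(coh$ic_samples)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  sd_b <- cf$ree_sd * sqrt(cf$ree_between_frac)
  sd_w <- cf$ree_sd * sqrt(1 - cf$ree_between_frac)

  # latent RQ-normal parameters matching the configured marginal moments
  if (cf$rq_sd > 0) {
    rq_par <- truncnorm_params(cf$rq_mean, cf$rq_sd,
                               cf$rq_bounds[1], cf$rq_bounds[2])
  } else {
    rq_par <- c(mu = cf$rq_mean, sigma = 0)
  }

  set.seed(cf$seed)
  child_seeds <- sample.int(.Machine$integer.max, cf$n_patients, replace = TRUE)

  ic_list <- vector("list", cf$n_patients)
  gt_list <- vector("list", cf$n_patients)
  traces <- vector("list", cf$n_patients)
  k_max <- length(cf$meas_pmf)

  for (i in seq_len(cf$n_patients)) {
    set.seed(child_seeds[i])
    pid <- sprintf("P%04d", i)
    n_meas <- sample.int(k_max, 1L, prob = cf$meas_pmf)

    # patient-level REE effect; redrawn if it leaves no room above the floor
    # in the degenerate sd_w = 0 case
    u <- stats::rnorm(1, 0, sd_b)
    if (sd_w == 0) {
      iter <- 0L
      while (cf$ree_mean + u <= cf$ree_floor) {
        iter <- iter + 1L
        if (iter > 10000L) stop("REE truncation failed to converge", call. = FALSE)
        u <- stats::rnorm(1, 0, sd_b)
      }
      true_ree <- rep(cf$ree_mean + u, n_meas)
    } else {
      true_ree <- rtruncnorm_reject(n_meas, cf$ree_mean + u, sd_w,
                                    lower = cf$ree_floor)
    }

    true_rq <- rtruncnorm_reject(n_meas, rq_par[["mu"]], rq_par[["sigma"]],
                                 lower = cf$rq_bounds[1], upper = cf$rq_bounds[2])

    times <- cf$first_meas_time + (seq_len(n_meas) - 1) * cf$meas_spacing
    mult <- vco2_multiplier(true_rq, cf$coeffs)             # kcal per L per min-equiv
    true_vco2 <- true_ree * 1000 / (cf$coeffs$minutes_per_day * mult)  # mL/min
    true_vo2 <- true_vco2 / true_rq

    # ventilator trace: step function of the per-measurement true VCO2,
    # times device bias and autocorrelated lognormal noise
    tr_times <- seq(0, max(times), by = cf$trace_step)
    idx <- pmin(findInterval(tr_times, times) + 1L, n_meas)
    factor <- lognormal_ar1_factor(length(tr_times), cf$vent_noise_sd, cf$ar_coef)
    tr_vco2 <- true_vco2[idx] * cf$vent_bias * factor

    ic_list[[i]] <- data.frame(
      patient_id = pid, time_min = times,
      vo2_ml_min = true_vo2, vco2_ml_min = true_vco2,
      ree_kcal_d = true_ree, rq = true_rq,
      stringsAsFactors = FALSE
    )
    gt_list[[i]] <- data.frame(
      patient_id = pid, time_min = times,
      true_ree_kcal_d = true_ree, true_vco2_ml_min = true_vco2,
      true_rq = true_rq, stringsAsFactors = FALSE
    )
    traces[[i]] <- vent_trace(pid, tr_times, tr_vco2, step = cf$trace_step)
  }

  names(traces) <- vapply(traces, function(tr) tr$patient_id, character(1))
  structure(
    list(
      ic_samples = tibble::as_tibble(do.call(rbind, ic_list)),
      traces = traces,
      ground_truth = tibble::as_tibble(do.call(rbind, gt_list)),
      config = cf
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_rec <- sum(vapply(x$traces, function(tr) length(tr$times), integer(1)))
  cat(sprintf(
    "Synthetic cohort: %d patients, %d IC measurements, %d ventilator records (seed %d)\n",
    length(x$traces), nrow(x$ic_samples), n_rec, x$config$seed
  ))
  invisible(x)
}

#' Summary moments of a synthetic cohort
#'
#' Computes the marginal statistics the generator is configured to emulate:
#' REE and RQ mean/SD over all IC measurements, 6-h ventilator block VCO2
#' mean/SD (using the same preceding-window aggregation as the pairing stage),
#' and the median and IQR of measurements per patient (linear-interpolation
#' quantiles).
#'
#' @param cohort A [generate_cohort()] result.
#' @param window,min_coverage Block aggregation settings, as in
#'   [build_paired_dataset()].
#' @return A tibble with columns `metric` and `value`.
#' @export
summarize_cohort <- function(cohort, window = 360, min_coverage = 0.8) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ic <- cohort$ic_samples
  if (nrow(ic) == 0L) stop("empty cohort", call. = FALSE)

  blocks <- mapply(function(pid, t) {
    bm <- block_mean_vco2(cohort$traces[[pid]], t, window = window,
                          min_coverage = min_coverage)
    bm$mean
  }, ic$patient_id, ic$time_min)
  blocks <- blocks[!is.na(blocks)]

  per_patient <- as.numeric(table(ic$patient_id))
  q <- stats::quantile(per_patient, c(0.25, 0.5, 0.75), type = 7, names = FALSE)

  tibble::tibble(
    metric = c("ree_mean", "ree_sd", "rq_mean", "rq_sd",
               "block_vco2_mean", "block_vco2_sd",
               "meas_per_patient_median", "meas_per_patient_q25",
               "meas_per_patient_q75", "n_measurements", "n_patients"),
    value = c(mean(ic$ree_kcal_d), stats::sd(ic$ree_kcal_d),
              mean(ic$rq), stats::sd(ic$rq),
              mean(blocks), stats::sd(blocks),
              q[2], q[1], q[3],
              nrow(ic), length(unique(ic$patient_id)))
  )
}

#' Tune the ventilator trace noise to a target estimator-reference correlation
#'
#' Finds, by bisection, the `vent_noise_sd` at which the pooled Pearson
#' correlation between the fixed-RQ VCO2-only estimator and the IC reference
#' REE reaches a requested value. The correlation is monotonically decreasing
#' in the trace noise, so bisection on a simulated cohort converges quickly.
#' The correlation is evaluated at one RQ only; it is invariant to the choice
#' because a fixed RQ rescales the estimator by a positive constant.
#'
#' @param target_r Target Pearson correlation (default 0.51).
#' @param config Base [cohort_config()]; its `vent_noise_sd` is ignored and
#'   its `n_patients` is replaced by `n_patients`.
#' @param n_patients Cohort size used for each bisection evaluation
#'   (default 500; about 2200 measurements).
#' @param rq Fixed RQ at which the estimator is evaluated (default 0.85).
#' @param interval Search interval for the relative noise SD.
#' @param tol Bisection tolerance on the realized correlation.
#' @param max_iter Maximum bisection steps.
#' @param seed Seed for the evaluation cohorts (held fixed across steps so the
#'   bisection target function is deterministic).
#' @return The tuned `vent_noise_sd` (numeric scalar), with the realized
#'   correlation attached as attribute `realized_r`.
#' @export
tune_vent_noise <- function(target_r = 0.51, config = cohort_config(),
                            n_patients = 500, rq = 0.85,
                            interval = c(0, 5), tol = 0.005,
                            max_iter = 30L, seed = config$seed) {
  stopifnot(target_r > 0, target_r < 1)
  eval_r <- function(noise) {
    cf <- config
    cf$n_patients <- as.integer(n_patients)
    cf$vent_noise_sd <- noise
    cf$seed <- as.integer(seed)
    coh <- generate_cohort(cf)
    ds <- build_paired_dataset(coh$ic_samples, coh$traces,
                               rq_grid = rq_grid(rq), coeffs = cf$coeffs)
    stats::cor(ds[[sprintf("ree_vco2_rq%.2f", rq)]], ds$ree_ic)
  }
  lo <- interval[1]; hi <- interval[2]
  r_lo <- eval_r(lo)
  if (r_lo < target_r) {
    stop("target correlation unreachable: even noise-free cohort falls below it",
         call. = FALSE)
  }
  r_hi <- eval_r(hi)
  if (r_hi > target_r) {
    stop("target correlation unreachable within the search interval", call. = FALSE)
  }
  r_mid <- r_lo; mid <- lo
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- eval_r(mid)
    if (abs(r_mid - target_r) < tol) break
    if (r_mid > target_r) lo <- mid else hi <- mid
  }
  structure(mid, realized_r = r_mid)
}
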