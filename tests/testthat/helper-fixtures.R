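# Shared fixtures and independent brute-force oracles. The oracle functions
# below are written from the defining formulas only and never call package
# internals, so they can serve as cross-checks for the implementation path.

const_trace <- function(pid = "P1", value = 244.5, t_max = 420, step = 5) {
  vent_trace(pid, seq(0, t_max, by = step), rep(value, t_max / step + 1),
             step = step)
}

degenerate_config <- function(n_patients = 20, seed = 101) {
  cohort_config(n_patients = n_patients, rq_sd = 0, vent_noise_sd = 0,
                vent_bias = 1, seed = seed)
}

# --- independent oracles ----------------------------------------------------

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_pearson_ci <- function(r, n, conf = 0.95) {
  z <- 0.5 * log((1 + r) / (1 - r))
  half <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  (exp(2 * c(z - half, z + half)) - 1) / (exp(2 * c(z - half, z + half)) + 1)
}

# Lin (1989) asymptotic CI on the z-transformed concordance coefficient
oracle_ccc_fisher_ci <- function(x, y, conf = 0.95) {
  n <- length(x)
  ccc <- oracle_ccc(x, y)
  r <- oracle_pearson(x, y)
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  z <- atanh(ccc)
  half <- qnorm(1 - (1 - conf) / 2) * sqrt(se2)
  tanh(c(z - half, z + half))
}

oracle_band <- function(est, ref, low, high) {
  sum(est / ref >= low & est / ref <= high) / length(est)
}

oracle_battery <- function(est, ref) {
  d <- est - ref
  list(
    mean_difference = oracle_mean(d),
    sd_difference = oracle_sd(d),
    pct_error = oracle_mean(abs(d) / ref),
    pct_difference = oracle_mean(abs(d) / ((est + ref) / 2)),
    pearson_r = oracle_pearson(est, ref),
    pearson_ci = oracle_pearson_ci(oracle_pearson(est, ref), length(est)),
    ccc = oracle_ccc(est, ref),
    ccc_ci = oracle_ccc_fisher_ci(est, ref),
    agreement = oracle_band(est, ref, 0.85, 1.15),
    tight_agreement = oracle_band(est, ref, 0.95, 1.05)
  )
}
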