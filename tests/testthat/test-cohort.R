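test_that("generation is deterministic and patient streams are stable", {
  cfg <- cohort_config(n_patients = 8, seed = 303)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$ic_samples, c2$ic_samples)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(lapply(c1$traces, `[[`, "vco2"),
                   lapply(c2$traces, `[[`, "vco2"))

  # adding patients never perturbs earlier ones
  c3 <- generate_cohort(cohort_config(n_patients = 12, seed = 303))
  expect_identical(c1$ic_samples,
                   c3$ic_samples[c3$ic_samples$patient_id %in%
                                   c1$ic_samples$patient_id, ])
})

test_that("noise-free degenerate cohort reproduces the reference exactly", {
  coh <- generate_cohort(degenerate_config(n_patients = 10))
  ds <- build_paired_dataset(coh$ic_samples, coh$traces)
  expect_equal(ds$ree_vco2_rq0.75, ds$ree_ic, tolerance = 1e-12)
  # IC-observed gases reproduce the true REE (IC is the reference method)
  expect_equal(ree_weir(coh$ic_samples$vo2_ml_min, coh$ic_samples$vco2_ml_min),
               coh$ground_truth$true_ree_kcal_d, tolerance = 1e-12)
})

test_that("truncation bounds are respected", {
  coh <- generate_cohort(cohort_config(n_patients = 150, seed = 5))
  expect_true(all(coh$ic_samples$rq >= 0.60 & coh$ic_samples$rq <= 1.10))
  expect_true(all(coh$ic_samples$ree_kcal_d > 500))
  expect_true(all(vapply(coh$traces, function(tr) all(tr$vco2 >= 0), logical(1))))
  expect_true(all(vapply(coh$traces,
                         function(tr) !is.unsorted(tr$times, strictly = TRUE),
                         logical(1))))
})

test_that("every measurement has at least six hours of preceding trace", {
  coh <- generate_cohort(cohort_config(n_patients = 25, seed = 9))
  for (j in seq_len(nrow(coh$ic_samples))) {
    tr <- coh$traces[[coh$ic_samples$patient_id[j]]]
    expect_lte(min(tr$times), coh$ic_samples$time_min[j] - 360)
  }
})

test_that("configured REE and RQ moments are recovered at moderate scale", {
  coh <- generate_cohort(cohort_config(n_patients = 400, seed = 17))
  ic <- coh$ic_samples
  n <- nrow(ic)
  # RQ draws are iid across measurements: naive standard errors apply
  expect_lt(abs(mean(ic$rq) - 0.75), 4 * 0.07 / sqrt(n))
  expect_lt(abs(sd(ic$rq) - 0.07), 4 * 0.07 / sqrt(2 * n))
  # REE is clustered within patients: allow a generous band at this scale
  expect_lt(abs(mean(ic$ree_kcal_d) - 2059.5), 100)
  expect_lt(abs(sd(ic$ree_kcal_d) - 491.7), 60)
})

test_that("summarize_cohort reports the documented metrics", {
  coh <- generate_cohort(degenerate_config(n_patients = 6))
  s <- summarize_cohort(coh)
  expect_equal(s$value[s$metric == "rq_sd"], 0)
  expect_equal(s$value[s$metric == "rq_mean"], 0.75)

  one <- generate_cohort(cohort_config(n_patients = 1, meas_pmf = 1, seed = 2))
  s1 <- summarize_cohort(one)
  expect_equal(s1$value[s1$metric == "meas_per_patient_median"], 1)
  expect_equal(s1$value[s1$metric == "n_measurements"], 1)
})

test_that("measurements per patient hit median 3 with IQR 2-7", {
  coh <- generate_cohort(cohort_config(n_patients = 600, seed = 23))
  per <- as.numeric(table(coh$ic_samples$patient_id))
  q <- quantile(per, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_equal(q[2], 3)
  expect_lte(abs(q[1] - 2), 1)
  expect_lte(abs(q[3] - 7), 1)
})

test_that("trace noise can be tuned to a target estimator-reference correlation", {
  tuned <- tune_vent_noise(target_r = 0.51, n_patients = 300, seed = 11)
  cf <- cohort_config(n_patients = 1100, vent_noise_sd = as.numeric(tuned),
                      seed = 12)
  coh <- generate_cohort(cf)
  ds <- suppressWarnings(build_paired_dataset(coh$ic_samples, coh$traces))
  r <- cor(ds$ree_vco2_rq0.85, ds$ree_ic)
  expect_lt(abs(r - 0.51), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(rq_mean = 0.5), "rq_bounds")
  expect_error(cohort_config(ree_mean = 400), "ree_floor")
  expect_error(cohort_config(ree_between_frac = 1.2), "ree_between_frac")
  expect_error(cohort_config(trace_step = 0), "trace_step")
})
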