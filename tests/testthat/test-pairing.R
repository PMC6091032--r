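test_that("block mean averages the strictly preceding half-open window", {
  tr <- const_trace(value = 244.5)
  bm <- block_mean_vco2(tr, 420)
  expect_equal(bm$mean, 244.5)
  expect_equal(bm$coverage, 1)

  alt <- vent_trace("P1", seq(0, 415, by = 5),
                    rep(c(200, 300), length.out = 84), step = 5)
  expect_equal(block_mean_vco2(alt, 420)$mean, 250)

  # records at or after t contribute nothing
  late <- vent_trace("P1", seq(420, 900, by = 5), rep(250, 97), step = 5)
  bm_late <- block_mean_vco2(late, 420)
  expect_true(is.na(bm_late$mean))
  expect_equal(bm_late$coverage, 0)

  # boundary records: t - window is included, t itself is excluded
  two <- vent_trace("P1", c(60, 420), c(100, 900), step = 360)
  expect_equal(block_mean_vco2(two, 420, window = 360, min_coverage = 0)$mean, 100)
})

test_that("coverage gating flags under-covered windows", {
  sparse <- vent_trace("P1", seq(0, 415, by = 5)[1:30], rep(250, 30), step = 5)
  bm <- block_mean_vco2(sparse, 420, min_coverage = 0.8)
  expect_true(is.na(bm$mean))
  expect_lt(bm$coverage, 0.8)
  expect_false(is.na(block_mean_vco2(sparse, 420, min_coverage = 0.1)$mean))
})

test_that("pairing keeps covered rows, excludes gaps, and sorts deterministically", {
  ic <- data.frame(
    patient_id = c("B", "A", "A"),
    time_min = c(420, 1140, 420),
    vo2_ml_min = c(250, 260, 240),
    vco2_ml_min = c(200, 210, 190)
  )
  tr_a_times <- c(seq(60, 415, by = 5), seq(1100, 1135, by = 5)) # gap before 1140
  traces <- list(
    A = vent_trace("A", tr_a_times, rep(250, length(tr_a_times)), step = 5),
    B = vent_trace("B", seq(60, 415, by = 5), rep(300, 72), step = 5)
  )
  expect_warning(ds <- build_paired_dataset(ic, traces), "excluded")
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$patient_id, c("A", "B"))
  expect_equal(ds$block_vco2, c(250, 300))
  expect_equal(attr(ds, "excluded")$reason, "low_coverage")

  expect_equal(ds$ree_ic, ree_weir(c(240, 250), c(190, 200)))
})

test_that("patients without a trace are dropped with a warning", {
  ic <- data.frame(patient_id = c("A", "Z"), time_min = c(420, 420),
                   vo2_ml_min = c(250, 250), vco2_ml_min = c(200, 200))
  traces <- list(A = const_trace("A", 250))
  expect_warning(ds <- build_paired_dataset(ic, traces), "no_trace")
  expect_equal(ds$patient_id, "A")

  expect_error(
    suppressWarnings(build_paired_dataset(ic[2, ], traces)),
    "no IC measurement"
  )
})

test_that("full-coverage cohorts pair every measurement", {
  coh <- generate_cohort(cohort_config(n_patients = 15, seed = 31))
  ds <- build_paired_dataset(coh$ic_samples, coh$traces)
  expect_equal(nrow(ds), nrow(coh$ic_samples))
  expect_true(all(ds$coverage == 1))
})

test_that("changing the RQ grid changes estimates but not membership", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 37))
  ds1 <- build_paired_dataset(coh$ic_samples, coh$traces, rq_grid = rq_grid())
  ds2 <- build_paired_dataset(coh$ic_samples, coh$traces,
                              rq_grid = rq_grid(c(0.70, 0.95)))
  expect_identical(ds1$block_vco2, ds2$block_vco2)
  expect_identical(ds1$patient_id, ds2$patient_id)
  expect_named(ds2, c("patient_id", "time_min", "ree_ic", "block_vco2",
                      "coverage", "ree_vco2_rq0.70", "ree_vco2_rq0.95"))
})

test_that("every block mean is reproducible from the written trace CSV", {
  coh <- generate_cohort(cohort_config(n_patients = 8, seed = 41))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  tr_raw <- read.csv(file.path(dir, "vent_trace.csv"))
  ic_raw <- read.csv(file.path(dir, "ic_measurements.csv"))
  ds <- build_paired_dataset(read_ic_measurements(file.path(dir, "ic_measurements.csv")),
                             read_vent_traces(file.path(dir, "vent_trace.csv")))
  for (j in seq_len(nrow(ds))) {
    rows <- tr_raw[tr_raw$patient_id == ds$patient_id[j] &
                     tr_raw$time_min >= ds$time_min[j] - 360 &
                     tr_raw$time_min < ds$time_min[j], ]
    expect_equal(ds$block_vco2[j], sum(rows$vco2_ml_min) / nrow(rows),
                 tolerance = 1e-12)
  }
  expect_equal(nrow(ds), nrow(ic_raw))
})
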