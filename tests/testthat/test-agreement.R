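test_that("bias_and_sd matches hand arithmetic", {
  x <- c(1900, 2100, 2000); r <- rep(2000, 3)
  expect_equal(bias_and_sd(x, x), c(mean_difference = 0, sd_difference = 0))
  expect_equal(bias_and_sd(x + 100, x),
               c(mean_difference = 100, sd_difference = 0))
  expect_equal(bias_and_sd(x, r), c(mean_difference = 0, sd_difference = 100))
  expect_error(bias_and_sd(1:3, 1:4), "equal length")
  expect_error(bias_and_sd(1, 1), "at least 2")
})

test_that("ratio-band agreement counts closed-interval ratios", {
  ref <- rep(1000, 5)
  est <- c(800, 900, 1000, 1100, 1200)
  expect_equal(ratio_band_agreement(ref, ref, 0.85, 1.15), 1.0)
  expect_equal(ratio_band_agreement(est, ref, 0.85, 1.15), 0.6)
  expect_equal(ratio_band_agreement(est, ref, 0.95, 1.05), 0.2)
  # closed endpoints: exactly 85% counts
  expect_equal(ratio_band_agreement(c(850, 1150), c(1000, 1000), 0.85, 1.15), 1.0)
  expect_error(ratio_band_agreement(est, c(0, 1, 1, 1, 1), 0.85, 1.15),
               "positive")
})

test_that("Lin's CCC matches the moment formula and its known cases", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 6)
  out <- lin_ccc(x, y, ci_method = "fisher")
  expect_equal(unname(out["ccc"]), 0.65, tolerance = 1e-12)
  expect_equal(unname(out["ccc"]), oracle_ccc(x, y))

  z <- c(10, 20, 35, 40, 55)
  expect_equal(unname(lin_ccc(z, z, ci_method = "fisher")["ccc"]), 1.0)
  mirror <- -z + 2 * mean(z)
  expect_lte(unname(lin_ccc(mirror, z, ci_method = "fisher")["ccc"]), 0)

  expect_error(lin_ccc(rep(1, 5), z), "zero variance")
  expect_error(lin_ccc(z[1:2], z[1:2]), "at least 3")
})

test_that("CCC bootstrap CI is seeded, ordered and brackets the point estimate", {
  set.seed(55)
  ref <- rnorm(80, 2000, 400)
  est <- ref + rnorm(80, 50, 300)
  a <- lin_ccc(est, ref, n_boot = 500, seed = 9)
  b <- lin_ccc(est, ref, n_boot = 500, seed = 9)
  expect_identical(a, b)
  expect_lt(a["ci_low"], a["ccc"])
  expect_gt(a["ci_high"], a["ccc"])
})

test_that("Pearson correlation and Fisher CI match the textbook formulas", {
  set.seed(3)
  r <- rnorm(40, 2000, 300)
  expect_equal(unname(pearson_with_ci(2 * r + 5, r)["r"]), 1.0)

  x <- c(1, 4, 6, 7, 10); y <- c(2, 3, 7, 9, 12)
  out <- pearson_with_ci(x, y)
  expect_equal(unname(out["r"]), oracle_pearson(x, y), tolerance = 1e-12)
  ci <- oracle_pearson_ci(oracle_pearson(x, y), 5)
  expect_equal(unname(out[c("ci_low", "ci_high")]), ci, tolerance = 1e-9)

  set.seed(8)
  big <- rnorm(2000)
  expect_lt(abs(unname(pearson_with_ci(sample(big), big)["r"])), 3 / sqrt(2000))
})

test_that("percentage metrics follow their declared definitions", {
  ref <- c(1000, 1000); est <- c(900, 1100)
  pm <- percentage_metrics(est, ref)
  expect_equal(unname(pm["pct_error"]), 0.10)
  expect_equal(unname(pm["pct_difference"]),
               mean(c(100 / 950, 100 / 1050)))
  expect_equal(percentage_metrics(ref, ref),
               c(pct_error = 0, pct_difference = 0))
  expect_equal(unname(percentage_metrics(1.1 * ref, ref)["pct_error"]), 0.10)

  cr <- percentage_metrics(est, ref, error_mode = "critchley")
  expect_equal(unname(cr["pct_error"]), 1.96 * sd(est - ref) / mean(ref))
  expect_error(percentage_metrics(est, c(1000, -1)), "positive")
})

test_that("Bland-Altman bias and limits match hand arithmetic", {
  est <- c(10, 20, 30); ref <- c(12, 18, 33)
  ba <- bland_altman(est, ref)
  d <- est - ref
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$points$pair_mean, (est + ref) / 2)
  expect_equal(ba$points$difference, d)

  same <- bland_altman(ref, ref)
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
})

test_that("concordance never exceeds correlation and bands are nested", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    ref <- rnorm(n, 2000, 400)
    est <- runif(1, 0.5, 1.5) * ref + rnorm(n, runif(1, -300, 300), 250)
    ccc <- unname(lin_ccc(est, ref, ci_method = "fisher")["ccc"])
    r <- unname(pearson_with_ci(est, ref)["r"])
    expect_lte(abs(ccc), abs(r) + 1e-12)

    ref_pos <- abs(ref) + 1
    est_pos <- abs(est) + 1
    expect_lte(ratio_band_agreement(est_pos, ref_pos, 0.95, 1.05),
               ratio_band_agreement(est_pos, ref_pos, 0.85, 1.15))
  }
})

test_that("LoA cover about 95% of normal differences", {
  set.seed(123)
  ref <- rnorm(10000, 2000, 400)
  est <- ref + rnorm(10000, 0, 200)
  ba <- bland_altman(est, ref)
  inside <- mean(ba$points$difference >= ba$loa_low &
                   ba$points$difference <= ba$loa_high)
  expect_gte(inside, 0.94)
  expect_lte(inside, 0.96)
})

test_that("performance_table summarises each grid RQ consistently", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 61))
  ds <- build_paired_dataset(coh$ic_samples, coh$traces)
  pt <- performance_table(ds, n_boot = 200, seed = 4)
  expect_equal(pt$rq, c(0.75, 0.80, 0.85, 0.89))
  # the estimator shrinks as RQ grows, so bias decreases along the grid
  expect_true(all(diff(pt$mean_difference) < 0))
  # a fixed RQ rescales the estimator by a positive constant: Pearson invariant
  expect_true(all(abs(pt$pearson_r - pt$pearson_r[1]) < 1e-12))
  expect_true(all(pt$tight_agreement <= pt$agreement))
  expect_true(all(abs(pt$ccc) <= abs(pt$pearson_r) + 1e-12))
})

test_that("degenerate estimator yields NA correlations with a warning, not an error", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 71))
  ds <- build_paired_dataset(coh$ic_samples, coh$traces)
  expect_warning(row <- evaluate_formula(list(intercept = 0, slope = 0), ds),
                 "zero variance")
  expect_equal(row$agreement, 0)
  expect_true(is.na(row$pearson_r))
})
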