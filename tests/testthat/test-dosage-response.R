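test_that("noiseless dosage fits are exact", {
  meta <- data.frame(sample = sprintf("s%d", 1:12), nY = rep(0:3, 3))
  y <- 80 - 7 * meta$nY
  fit <- fit_dosage_response(meta, y, predictor = "nY")
  expect_equal(fit$slope, -7)
  expect_equal(fit$intercept, 80)
  expect_equal(fit$pearson_r, -1)
  expect_equal(fit$baseline, 73)   # fitted at nY = 1
  expect_equal(fit$delta_e, -7 / 73)

  expect_error(fit_dosage_response(meta[meta$nY == 1, ], y[meta$nY == 1],
                                   predictor = "nY"), "no dosage contrast")
  expect_warning(flat <- fit_dosage_response(meta, rep(5, 12), predictor = "nY"),
                 "constant response")
  expect_equal(flat$pearson_r, 0)
})

test_that("delta_e is slope over baseline expression", {
  expect_equal(delta_e(26, baseline = 100), 0.26)
  expect_equal(delta_e(0, baseline = 50), 0)
  expect_warning(bad <- delta_e(5, baseline = 0), "nonpositive")
  expect_true(is.na(bad))
  # grid agreement with a fresh noiseless refit
  for (s in c(-10, 5, 20)) for (b0 in c(40, 120)) {
    meta <- data.frame(sample = 1:6, nX = rep(1:3, 2))
    y <- (b0 - s) + s * meta$nX  # baseline at nX = 1 equals b0
    fit <- fit_dosage_response(meta, y, predictor = "nX")
    expect_equal(fit$delta_e, s / b0)
  }
})

test_that("generator ground truth is recovered and coupling flips slopes", {
  cfg <- sim_config(seed = 31, noise_cv = 0, coupling_k = 0,
                    delta_ex_true = 0.26)
  sim <- simulate_aneuploidy_expression(
    cfg, karyotypes = data.frame(nX = 1:4, nY = 1), n_per_karyotype = 4)
  fit <- fit_dosage_response(sim$metadata, sim$tpm, "homX", "nX")
  expect_equal(fit$delta_e, 0.26, tolerance = 1e-12)

  cfgk <- sim_config(seed = 32, noise_cv = 0.05, coupling_k = 0.3)
  simk <- simulate_aneuploidy_expression(cfgk)
  meta_x1 <- simk$metadata[simk$metadata$nX == 1, ]
  fx_on_y <- fit_dosage_response(meta_x1, simk$tpm, "homX", "nY")
  expect_lt(fx_on_y$slope, 0)
  meta_y <- simk$metadata[simk$metadata$nY >= 1, ]
  fy_on_x <- fit_dosage_response(meta_y, simk$tpm, "homY", "nX")
  expect_lt(fy_on_x$slope, 0)

  # uncoupled null, assessed at fixed nX so the design cannot confound
  cfg0 <- sim_config(seed = 33, noise_cv = 0.05, coupling_k = 0)
  sim0 <- simulate_aneuploidy_expression(
    cfg0, karyotypes = data.frame(nX = 1, nY = 0:4), n_per_karyotype = 8)
  f0 <- fit_dosage_response(sim0$metadata, sim0$tpm, "homX", "nY")
  expect_gt(f0$p_value, 0.01)
})

test_that("allelic ratio handles counts and degenerate denominators", {
  expect_equal(allelic_ratio(100, 100), 1)
  expect_equal(allelic_ratio(55, 100), 0.55)
  expect_warning(na <- allelic_ratio(3, 0), "undefined")
  expect_true(is.na(na))
  expect_error(allelic_ratio(-1, 10), "nonnegative")
})

test_that("AR versus delta_e one-sample t-test behaves at its edges", {
  expect_warning(eq <- compare_ar_delta_e(rep(0.26, 5), 0.26), "zero variance")
  expect_equal(eq$p_value, 1)
  expect_warning(ne <- compare_ar_delta_e(rep(0.5, 5), 0.26), "zero variance")
  expect_equal(ne$p_value, 0)
  set.seed(34)
  shifted <- rnorm(10, 0.56, 0.1)
  res <- compare_ar_delta_e(shifted, 0.26)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$mean_ar, mean(shifted))
  expect_error(compare_ar_delta_e(c(0.5, 0.6), 0.26), "at least 3")
})

test_that("XY line filter applies strict thresholds", {
  lines <- data.frame(
    DDX3Y = c(1.0, 1.0, 0.2, NA),
    RPS4Y1 = c(1.0, 1.0, 1.0, 1.0),
    XIST = c(0.5, 3.0, 0.5, 0.5),
    row.names = c("keep", "xist_high", "boundary", "missing")
  )
  expect_warning(keep <- classify_xy_lines(lines), "missing")
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(classify_xy_lines(data.frame(DDX3Y = 1)), "RPS4Y1")
})
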