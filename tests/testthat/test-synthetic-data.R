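test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(seed = 11)
  tr <- ape::rtree(8)
  expect_identical(simulate_gene_loss(tr, 0.01, 30, seed = 11),
                   simulate_gene_loss(tr, 0.01, 30, seed = 11))
  expect_identical(simulate_aneuploidy_expression(cfg),
                   simulate_aneuploidy_expression(cfg))
  expect_identical(simulate_allelic_counts(0.5, 100, 10, seed = 11),
                   simulate_allelic_counts(0.5, 100, 10, seed = 11))
  expect_identical(simulate_labeling_timecourse(cfg),
                   simulate_labeling_timecourse(cfg))
  expect_identical(simulate_knockdown(cfg), simulate_knockdown(cfg))
  expect_identical(simulate_qpcr(c(a = 1, b = 2), seed = 11),
                   simulate_qpcr(c(a = 1, b = 2), seed = 11))
})

test_that("Dollo loss respects the zero- and infinite-hazard limits", {
  tr <- ape::rtree(6)
  expect_true(all(simulate_gene_loss(tr, 0, 20, seed = 1)))
  expect_false(any(simulate_gene_loss(tr, Inf, 20, seed = 1)))
  expect_error(simulate_gene_loss(tr, -0.1, 5), "loss_rate")
})

test_that("Dollo leaf survival matches the closed-form probability", {
  # survival in a leaf is exp(-rate * root-to-leaf path length)
  tr <- read_species_tree(text = "((A:100,B:150):200,(C:250,D:50):100):0;")
  rate <- 0.001
  n <- 10000
  pres <- simulate_gene_loss(tr, rate, n, seed = 42)
  depths <- c(A = 300, B = 350, C = 350, D = 150)
  for (sp in names(depths)) {
    p <- exp(-rate * depths[[sp]])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(pres[, sp]) - p), 3 * se)
  }
})

test_that("aneuploidy means follow the linear-with-repression model", {
  cfg <- sim_config(noise_cv = 0, coupling_k = 0, delta_ex_true = 0.26,
                    e_xa = 100)
  sim <- simulate_aneuploidy_expression(
    cfg, karyotypes = data.frame(nX = c(1, 2), nY = c(0, 0)),
    n_per_karyotype = 2)
  x1 <- sim$tpm["homX", sim$metadata$nX == 1]
  x2 <- sim$tpm["homX", sim$metadata$nX == 2]
  expect_equal(unique(x2) / unique(x1), 1.26)
  expect_equal(unique(x2), 126)

  # coupling: X-homolog mean strictly decreases as nY rises at fixed nX
  cfg2 <- sim_config(noise_cv = 0, coupling_k = 0.3)
  sim2 <- simulate_aneuploidy_expression(
    cfg2, karyotypes = data.frame(nX = 1, nY = 0:4), n_per_karyotype = 1)
  mx <- sim2$tpm["homX", order(sim2$metadata$nY)]
  expect_true(all(diff(mx) < 0))
  expect_error(simulate_aneuploidy_expression(cfg2, karyotypes = data.frame()),
               "non-empty")
})

test_that("allelic count generator hits its binomial expectation", {
  expect_true(all(simulate_allelic_counts(0, 100, 20, seed = 1)$xi_reads == 0))
  ac <- simulate_allelic_counts(1, 1e5, 30, seed = 2)
  ar <- ac$xi_reads / ac$xa_reads
  expect_lt(abs(mean(ar) - 1), 3 * sd(ar) / sqrt(30))
  ac2 <- simulate_allelic_counts(0.55, 1e5, 50, seed = 3)
  expect_lt(abs(mean(ac2$xi_reads / ac2$xa_reads) - 0.55), 0.01 * 0.55)
  expect_error(simulate_allelic_counts(-0.1, 100, 5), "ar_true")
})

test_that("labeling generator encodes first-order saturation kinetics", {
  cfg <- sim_config(noise_cv = 0, beta_true = log(2) / 1.3,
                    timepoints = c(0, 1.3, 7, 100))
  tc <- simulate_labeling_timecourse(cfg)
  expect_equal(tc$y_true[1], 0)
  expect_equal(tc$y_true[2], 0.5)                    # y at one half-life
  expect_lt(abs(tc$y_true[4] - 1), 1e-20)            # saturation
  expect_error(sim_config(beta_true = 0), "beta_true")
})

test_that("knockdown generator implements targeted loss plus compensation", {
  # no knockdown: all conditions share the same means
  cfg0 <- sim_config(noise_cv = 0, kd_efficiency = 0)
  kd0 <- simulate_knockdown(cfg0)
  expect_equal(length(unique(round(kd0$tpm_x, 9))), 1L)
  expect_equal(length(unique(round(kd0$tpm_y, 9))), 1L)

  # full compensation, noiseless: summed TPM identical across conditions
  cfg1 <- sim_config(noise_cv = 0, compensation_c = 1, kd_efficiency = 0.8)
  kd1 <- simulate_knockdown(cfg1)
  expect_equal(length(unique(round(kd1$summed, 9))), 1L)

  # partial compensation: summed deficit in kdX = eff * (1 - c) * mean_x
  cfg2 <- sim_config(noise_cv = 0, compensation_c = 0.4, kd_efficiency = 0.8,
                     e_xa = 100, rel_y = 0.5)
  kd2 <- simulate_knockdown(cfg2)
  deficit <- mean(kd2$summed[kd2$condition == "control"]) -
    mean(kd2$summed[kd2$condition == "kdX"])
  expect_equal(deficit, 0.8 * 0.6 * 100)
})

test_that("qPCR generator maps fold changes onto Ct shifts", {
  rec <- simulate_qpcr(c(ctrl = 1, high = 2), noise_sd = 0, n_reps = 2,
                       seed = 1)
  dct <- rec$ct_target - rec$ct_ref
  ddct <- dct[rec$dose == "high"] - mean(dct[rec$dose == "ctrl"])
  expect_equal(unique(ddct), -1)   # doubling = one fewer cycle
  expect_equal(unique(dct[rec$dose == "ctrl"] - 5), c(0))
  expect_error(simulate_qpcr(c(1, 0)), "positive")
})
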