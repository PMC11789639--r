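test_that("summed pair expression is a guarded elementwise sum", {
  expect_equal(summed_pair_expression(120, 30), 150)
  expect_equal(summed_pair_expression(c(1, 2), c(0, 0)), c(1, 2))
  expect_error(summed_pair_expression(-1, 2), "nonnegative")
})

test_that("compensation ANOVA separates targeted and summed channels", {
  cfg <- sim_config(seed = 41, noise_cv = 0.05, compensation_c = 1,
                    kd_efficiency = 0.8)
  kd <- simulate_knockdown(cfg)
  res <- compensation_anova(kd)
  expect_setequal(res$channel, c("tpm_x", "tpm_y", "summed"))
  expect_lt(res$p_value[res$channel == "tpm_x"], 1e-4)
  expect_gt(res$p_value[res$channel == "summed"], 0.05)

  # incomplete compensation of a large knockdown shows up in the summed channel
  cfg2 <- sim_config(seed = 42, noise_cv = 0.05, compensation_c = 0.3,
                     kd_efficiency = 0.8)
  res2 <- compensation_anova(simulate_knockdown(cfg2))
  expect_lt(res2$p_value[res2$channel == "summed"], 0.001)

  # relabeling the homologs leaves the summed channel untouched
  kd_swap <- kd
  kd_swap$tpm_x <- kd$tpm_y
  kd_swap$tpm_y <- kd$tpm_x
  kd_swap$summed <- NULL
  expect_equal(compensation_anova(kd_swap, "summed")$f_statistic,
               res$f_statistic[res$channel == "summed"])

  one_rep <- kd[kd$condition != "kdX" | (kd$guide == "g1" & kd$replicate == 1), ]
  expect_error(compensation_anova(one_rep), "kdX")
})

test_that("two-group comparison matches exact Mann-Whitney enumeration", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)              # complete separation
  expect_equal(res$p_value, 0.1)              # minimal two-sided p at n = 3,3
  expect_equal(res$p_value, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  set.seed(43)
  for (i in 1:10) {
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    expect_equal(compare_groups(a, b)$p_value, mw_exact_oracle(a, b))
  }

  expect_warning(tied <- compare_groups(c(2, 2), c(2, 2)), "tied")
  expect_equal(tied$p_value, 1)
  set.seed(44)
  tt <- compare_groups(rnorm(10), rnorm(10, 3), test = "t_test")
  expect_lt(tt$p_value, 0.01)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("delta-delta-Ct pipeline exactly inverts its generator", {
  folds <- c(`0` = 1, `1` = 1.2, `2` = 1.5, `5` = 2, `10` = 2.5)
  rec <- simulate_qpcr(folds, noise_sd = 0, n_reps = 3, seed = 45)
  out <- suppressWarnings(qpcr_fold_change(rec, control_label = "0"))
  expect_equal(out$fold[match(names(folds), out$dose)], unname(folds))
  expect_equal(out$fold[out$dose == "0"], 1)
  expect_true(is.na(out$p_value[out$dose == "0"]))

  # noisy ladder recovered within 10% and monotone
  rec2 <- simulate_qpcr(folds, noise_sd = 0.05, n_reps = 3, seed = 46)
  out2 <- qpcr_fold_change(rec2, control_label = "0")
  rec_folds <- out2$fold[match(names(folds), out2$dose)]
  expect_true(all(abs(rec_folds / folds - 1) < 0.1))
  expect_true(all(diff(rec_folds) > 0))

  # one-sided direction: elevated expression gives small p at high dose
  expect_lt(out2$p_value[out2$dose == "10"], 0.01)
  rec_na <- rec2
  rec_na$ct_ref[1] <- NA
  expect_warning(qpcr_fold_change(rec_na, "0"), "dropped")
})

test_that("gene-set overlap matches the explicit hypergeometric tail", {
  a <- paste0("g", 1:10)
  b <- paste0("g", 9:18)  # overlap 2
  res <- gene_set_overlap(a, b, universe_size = 100)
  expect_equal(res$overlap, 2)
  expect_equal(res$p_value, hyper_tail_oracle(2, 10, 10, 100))

  disj <- gene_set_overlap(paste0("a", 1:5), paste0("b", 1:5), 50)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$p_value, 1)

  same <- gene_set_overlap(a, a, universe_size = 10)  # sets = universe
  expect_equal(same$overlap, 10)
  expect_equal(same$p_value, 1)

  expect_error(gene_set_overlap(a, b, universe_size = 10), "universe")
})
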