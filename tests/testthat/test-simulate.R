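test_that("config validation rejects malformed parameters", {
  expect_error(silac_config(class_proportions = c(substrate_rescued = 1)),
               "named over")
  props <- c(substrate_rescued = 0.3, substrate_partial = 0.3,
             off_target = 0.3, unaffected = 0.3,
             compensatory_up_rescued = 0.3)
  expect_error(silac_config(class_proportions = props), "sum to 1")
  expect_error(silac_config(delta = -1))
  expect_error(simulate_silac(silac_config()), "seed")
})

test_that("zero-noise effects are planted exactly", {
  sim <- simulate_silac(zero_noise_config(n_sites = 200, seed = 4))
  s <- log2_transform(sim$sites)
  tr <- sim$truth
  for (cls in unique(tr$class)) {
    idx <- tr$class == cls
    expect_equal(unname(ratio_matrix(s, "M/L")[idx, ]),
                 matrix(tr$delta_M[idx], sum(idx), 5), tolerance = 1e-12)
    expect_equal(unname(ratio_matrix(s, "H/L")[idx, ]),
                 matrix(tr$delta_H[idx], sum(idx), 5), tolerance = 1e-12)
  }
  # partial class: H channel restored by half of delta by default
  part <- tr$class == "substrate_partial"
  expect_true(all(abs(ratio_matrix(s, "H/L")[part, ] + 0.75) < 1e-12))
})

test_that("channel-consistency identity holds elementwise", {
  sim <- simulate_silac(silac_config(n_sites = 500, seed = 8))
  s <- log2_transform(sim$sites)
  ml <- ratio_matrix(s, "M/L"); hl <- ratio_matrix(s, "H/L")
  hm <- ratio_matrix(s, "H/M")
  all3 <- !is.na(ml) & !is.na(hl) & !is.na(hm)
  expect_gt(sum(all3), 0)
  expect_true(all(abs(hm[all3] - (hl[all3] - ml[all3])) < 1e-9))
  # a missing intensity voids both ratios involving that channel:
  # H/M observed whenever H/L and M/L are both observed
  expect_true(all(!is.na(hm[!is.na(ml) & !is.na(hl)])))
})

test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- silac_config(n_sites = 150, seed = 99)
  sim1 <- simulate_silac(cfg)
  sim2 <- simulate_silac(cfg)
  expect_identical(sim1$sites, sim2$sites)
  expect_identical(sim1$truth, sim2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_silac_dataset(sim1, d1)
  write_silac_dataset(sim2, d2)
  for (f in c("sites.txt", "proteins.txt", "ground_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the realization
  sim3 <- simulate_silac(cfg, seed = 100)
  expect_false(identical(sim1$sites, sim3$sites))
})

test_that("planted effect size is recovered from substrate records", {
  sim <- simulate_silac(silac_config(n_sites = 3000, seed = 17))
  s <- channel_stats(log2_transform(sim$sites))
  sub <- sim$truth$class %in% c("substrate_rescued", "substrate_partial",
                                "off_target")
  est <- mean(s$mean_ML[sub], na.rm = TRUE)
  se <- 0.3 * sqrt(2) / sqrt(5 * sum(sub))
  expect_lt(abs(est - (-1.5)), 5 * se)
})

test_that("recovery evaluation reports confusion, sensitivity and specificity", {
  sim <- simulate_silac(zero_noise_config(n_sites = 300, seed = 2))
  fit <- rescue_analysis(sim$sites, sim$proteins)
  rec <- evaluate_recovery(fit$sites, sim$truth)
  expect_equal(rec$accuracy, 1.0)
  off_diag <- sum(rec$confusion) - sum(diag_confusion(rec$confusion))
  expect_equal(off_diag, 0)
  expect_true(all(rec$sensitivity == 1, na.rm = TRUE))
  expect_true(all(rec$specificity == 1, na.rm = TRUE))

  # zero planted substrates: sensitivity undefined, reported as NA
  cfg <- silac_config(n_sites = 100, sigma = 0, missing_rate = 0,
                      class_proportions = c(substrate_rescued = 0,
                                            substrate_partial = 0,
                                            off_target = 0, unaffected = 1,
                                            compensatory_up_rescued = 0),
                      protein_driven_rate = 0, seed = 5)
  sim0 <- simulate_silac(cfg)
  fit0 <- rescue_analysis(sim0$sites, sim0$proteins)
  rec0 <- evaluate_recovery(fit0$sites, sim0$truth)
  expect_true(is.na(rec0$sensitivity[["substrate_rescued"]]))

  # id mismatch is an error
  bad <- fit$sites
  bad$site_id[1] <- "nonexistent"
  expect_error(evaluate_recovery(bad, sim$truth), "match")
})
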