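test_that("regulation calls combine direction, significance and relevance", {
  df <- rbind(stats_row(mean_ML = -1.0, q_ML = 0.001),
              stats_row(mean_ML = -0.3, q_ML = 0.001),
              stats_row(mean_ML = -1.0, q_ML = 0.20),
              stats_row(mean_ML = 0.9, q_ML = 0.01),
              stats_row(mean_ML = NA, q_ML = NA, n_ML = 0L))
  out <- call_regulation(df)
  expect_equal(out$direction,
               c("down", "down", "down", "up", "insufficient_data"))
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$biologically_relevant, c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("fold-change relevance is strict at the boundary", {
  out <- call_regulation(rbind(
    stats_row(mean_ML = -0.585, q_ML = 0.001),
    stats_row(mean_ML = -0.5851, q_ML = 0.001),
    stats_row(mean_ML = 0.585, q_ML = 0.001)))
  expect_equal(out$biologically_relevant, c(FALSE, TRUE, FALSE))
})

test_that("rescue calls follow the H/L interval and H/M test", {
  df <- rbind(
    stats_row(-1.5, 0.001, mean_HL = 0.10, mean_HM = 1.4, q_HM = 0.01),
    stats_row(-1.5, 0.001, mean_HL = -0.90, mean_HM = 0.60, q_HM = 0.01),
    stats_row(-1.5, 0.001, mean_HL = -1.0, mean_HM = 0.05, q_HM = 0.30),
    stats_row(-0.3, 0.001, mean_HL = 0.0, mean_HM = 0.3, q_HM = 0.01),
    stats_row(-1.5, 0.001, mean_HL = NA, mean_HM = NA, q_HM = NA))
  out <- call_rescue(call_regulation(df))
  expect_equal(out$rescue, c("rescued", "partially_rescued", "not_rescued",
                             "not_applicable", "not_rescued"))
  expect_match(out$rescue_note[5], "undefined")
})

test_that("upregulated records use the mirrored rescue criteria", {
  df <- rbind(
    stats_row(1.5, 0.001, mean_HL = -0.10, mean_HM = -1.4, q_HM = 0.01),
    stats_row(1.5, 0.001, mean_HL = 0.90, mean_HM = -0.60, q_HM = 0.01),
    stats_row(1.5, 0.001, mean_HL = 0.90, mean_HM = 0.60, q_HM = 0.01))
  out <- call_rescue(call_regulation(df))
  expect_equal(out$rescue, c("rescued", "partially_rescued", "not_rescued"))
})

test_that("H/L interval is strict and the H/M significance is strict", {
  df <- rbind(
    stats_row(-1.5, 0.001, mean_HL = 0.585, mean_HM = 2.0, q_HM = 0.01),
    stats_row(-1.5, 0.001, mean_HL = 0.584, mean_HM = 2.0, q_HM = 0.05),
    stats_row(-1.5, 0.001, mean_HL = 0.584, mean_HM = 2.0, q_HM = 0.049))
  out <- call_rescue(call_regulation(df))
  expect_equal(out$rescue[1], "partially_rescued")  # boundary H/L not inside
  expect_equal(out$rescue[2], "not_rescued")        # q == alpha not significant
  expect_equal(out$rescue[3], "rescued")
})

test_that("proteome cross-reference flags exactly the planted protein-driven sites", {
  sim <- simulate_silac(silac_config(n_sites = 400, sigma = 0,
                                     missing_rate = 0, contaminant_rate = 0,
                                     reverse_rate = 0, seed = 12))
  expect_gt(sum(sim$truth$protein_driven), 0)
  fit <- rescue_analysis(sim$sites, sim$proteins)
  tr <- sim$truth[match(fit$sites$site_id, sim$truth$site_id), ]
  expect_equal(fit$sites$protein_confounded, tr$protein_driven)
})

test_that("cross-reference requires matching direction and handles orphans", {
  sites <- stats_row(-1.5, 0.001, mean_HL = 0.1, mean_HM = 1.4, q_HM = 0.01)
  sites <- cbind(sites, protein_ids = "A1;A2", stringsAsFactors = FALSE)
  sites <- call_rescue(call_regulation(sites))
  prot_down <- call_rescue(call_regulation(
    cbind(stats_row(-1.2, 0.001, mean_HL = 0, mean_HM = 1, q_HM = 0.5),
          protein_ids = "A2", stringsAsFactors = FALSE)))
  prot_up <- call_rescue(call_regulation(
    cbind(stats_row(1.2, 0.001, mean_HL = 0, mean_HM = 1, q_HM = 0.5),
          protein_ids = "A2", stringsAsFactors = FALSE)))
  prot_other <- call_rescue(call_regulation(
    cbind(stats_row(-1.2, 0.001, mean_HL = 0, mean_HM = 1, q_HM = 0.5),
          protein_ids = "ZZ", stringsAsFactors = FALSE)))
  expect_true(cross_reference_proteome(sites, prot_down)$protein_confounded)
  expect_false(cross_reference_proteome(sites, prot_up)$protein_confounded)
  expect_false(cross_reference_proteome(sites, prot_other)$protein_confounded)
  expect_false(cross_reference_proteome(sites, NULL)$protein_confounded)
})

test_that("funnel distinctness follows the peptide/site/protein definitions", {
  base <- rbind(
    stats_row(-1.5, 0.001, mean_HL = 0.1, mean_HM = 1.4, q_HM = 0.01),
    stats_row(-1.5, 0.001, mean_HL = 0.1, mean_HM = 1.4, q_HM = 0.01))
  base$protein_ids <- "P1"
  base$position <- 42L
  base$sequence_window <- "AAAAASAAADE"
  base$multiplicity <- c(1L, 2L)
  calls <- call_rescue(call_regulation(base))
  fun <- summarize_funnel(calls)
  expect_equal(fun$n_rescued_peptides, 2L)  # two multiplicity states
  expect_equal(fun$n_rescued_sites, 1L)     # one protein position
  expect_equal(fun$n_rescued_proteins, 1L)
  expect_equal(fun$n_multiplicity1_rescued, 1L)

  none <- call_rescue(call_regulation(
    cbind(stats_row(-0.1, 0.9, mean_HL = 0, mean_HM = 0, q_HM = 0.9),
          protein_ids = "P1", position = 1L, sequence_window = "AAAAASAAAAA",
          multiplicity = 1L, stringsAsFactors = FALSE)))
  fun0 <- summarize_funnel(none)
  expect_equal(fun0$n_rescued_peptides, 0L)
  expect_equal(fun0$n_partial_peptides, 0L)
})

test_that("rescued records satisfy the partial-rescue criteria (nesting)", {
  for (seed in 1:5) {
    sim <- simulate_silac(silac_config(n_sites = 500, seed = seed))
    fit <- rescue_analysis(sim$sites, sim$proteins)
    s <- fit$sites
    resc <- s$rescue == "rescued"
    down <- resc & s$direction == "down"
    up <- resc & s$direction == "up"
    expect_true(all(s$mean_HM[down] > 0 & s$q_HM[down] < 0.05))
    expect_true(all(s$mean_HM[up] < 0 & s$q_HM[up] < 0.05))
  }
})
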