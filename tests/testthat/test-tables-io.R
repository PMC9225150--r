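test_that("multiplicity expansion yields one record per populated ___ block", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_site_fixture(list(
    list(id = "a", ml1 = c(1.2, 1.1)),
    list(id = "b", ml1 = c(0.8, NA), ml2 = c(0.5, 0.6)),
    list(id = "c", ml1 = c(2.0, 2.2))
  ), path)
  rec <- read_site_table(path, small_dialect())
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$site_id, c("a", "b", "b", "c"))
  expect_equal(rec$multiplicity[rec$site_id == "b"], c(1L, 2L))
  # expansion conserves non-missing ratio cells
  expect_equal(sum(!is.na(ratio_matrix(rec, "M/L"))), 7L)
})

test_that("reverse and contaminant '+' markers set the flags", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_site_fixture(list(
    list(id = "a", reverse = "+", ml1 = c(1, 1)),
    list(id = "b", contam = "+", ml1 = c(1, 1)),
    list(id = "c", ml1 = c(1, 1))
  ), path)
  rec <- read_site_table(path, small_dialect())
  expect_equal(rec$is_reverse, c(TRUE, FALSE, FALSE))
  expect_equal(rec$is_contaminant, c(FALSE, TRUE, FALSE))
})

test_that("missing mandatory columns and malformed ratios are reported", {
  path <- withr::local_tempfile(fileext = ".txt")
  write.table(data.frame(x = 1), path, sep = "\t", row.names = FALSE)
  expect_error(read_site_table(path, small_dialect()),
               "Localization prob|Proteins")
  expect_error(read_site_table(tempfile(), small_dialect()), "not found")

  path2 <- withr::local_tempfile(fileext = ".txt")
  write_site_fixture(list(list(id = "a", ml1 = c("oops", 1))), path2)
  expect_error(read_site_table(path2, small_dialect()), "row 1")
})

test_that("empty and NaN cells parse as missing", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_site_fixture(list(list(id = "a", ml1 = c("NaN", "1.5"))), path)
  rec <- read_site_table(path, small_dialect())
  ml <- ratio_matrix(rec, "M/L")
  expect_true(is.na(ml[1, 1]))
  expect_equal(unname(ml[1, 2]), 1.5)
})

test_that("synthetic dataset round-trips through the MaxQuant dialect", {
  sim <- simulate_silac(silac_config(n_sites = 120, seed = 42))
  dir <- withr::local_tempdir()
  paths <- write_silac_dataset(sim, dir)
  dialect <- maxquant_dialect()
  sites <- read_site_table(paths[["sites"]], dialect)
  prot <- read_protein_table(paths[["proteins"]], dialect)
  expect_equal(nrow(sites), nrow(sim$sites))
  for (col in names(sim$sites)) {
    expect_equal(sites[[col]], sim$sites[[col]], tolerance = 1e-10,
                 info = col)
  }
  for (col in names(sim$proteins)) {
    expect_equal(prot[[col]], sim$proteins[[col]], tolerance = 1e-10,
                 info = col)
  }
})

test_that("protein table reader handles flags and row counts", {
  dir <- withr::local_tempdir()
  tab <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    `Proteins` = c("P1", "CON_P2"),
                    `Gene names` = c("G1", "G2"),
                    `Reverse` = c("", ""),
                    `Potential contaminant` = c("", "+"))
  tab[[protein_ratio_column_for_test("M/L", "R1")]] <- c(1.1, 0.9)
  path <- file.path(dir, "prot.txt")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_protein_table(path, small_dialect())
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$is_contaminant, c(FALSE, TRUE))
})

test_that("result tables round-trip and carry class labels verbatim", {
  sim <- simulate_silac(zero_noise_config(n_sites = 80, seed = 5))
  fit <- rescue_analysis(sim$sites, sim$proteins)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(fit, path)
  back <- read_results(path)
  expect_equal(nrow(back), nrow(fit$sites))
  expect_equal(back$rescue, fit$sites$rescue)
  expect_equal(back$mean_ML, fit$sites$mean_ML, tolerance = 1e-10)
  expect_true(any(grepl("\trescued\t", readLines(path), fixed = TRUE)))

  # empty record list -> header-only file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(fit$sites[0, ], path2)
  expect_equal(length(readLines(path2)), 1L)
})
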