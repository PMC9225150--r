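# Small in-code fixtures shared across tests.

# two-replicate dialect keeps hand-written fixtures compact
small_dialect <- function() maxquant_dialect(replicates = c("R1", "R2"))

# Write a MaxQuant-dialect site table from a list of row lists.
# Each row: list(Proteins=, window=, loc=, reverse=, contam=,
#                ml1 = c(rep1, rep2) ratios for multiplicity 1, ml2 = ...)
write_site_fixture <- function(rows, path, dialect = small_dialect()) {
  cols <- c("id", "Proteins", "Gene names", "Position", "Amino acid",
            "Localization prob", "Sequence window", "Reverse",
            "Potential contaminant")
  for (ch in dialect$channels) {
    for (r in dialect$replicates) {
      for (m in dialect$multiplicities) {
        cols <- c(cols, site_ratio_column_for_test(ch, r, m))
      }
    }
  }
  mat <- matrix("", nrow = length(rows), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    mat[i, "id"] <- r$id %||% sprintf("fix%02d", i)
    mat[i, "Proteins"] <- r$proteins %||% "P00001"
    mat[i, "Gene names"] <- r$genes %||% "GENE1"
    mat[i, "Position"] <- as.character(r$position %||% 10L)
    mat[i, "Amino acid"] <- r$aa %||% "S"
    mat[i, "Localization prob"] <- as.character(r$loc %||% 0.99)
    mat[i, "Sequence window"] <- r$window %||% "AAAAAAASAAAAAAA"
    mat[i, "Reverse"] <- r$reverse %||% ""
    mat[i, "Potential contaminant"] <- r$contam %||% ""
    for (m in 1:3) {
      vals <- r[[paste0("ml", m)]]
      if (is.null(vals)) next
      for (j in seq_along(vals)) {
        if (!is.na(vals[j])) {
          mat[i, site_ratio_column_for_test("M/L", dialect$replicates[j], m)] <-
            as.character(vals[j])
        }
      }
    }
  }
  df <- as.data.frame(mat, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# mirrors the package's ratio column naming without touching internals
site_ratio_column_for_test <- function(channel, replicate, multiplicity) {
  sprintf("Ratio %s normalized %s___%d", channel, replicate, multiplicity)
}
protein_ratio_column_for_test <- function(channel, replicate) {
  sprintf("Ratio %s normalized %s", channel, replicate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal classified-stats row builder for classification tests
stats_row <- function(mean_ML = NA, q_ML = NA, mean_HL = NA, mean_HM = NA,
                      q_HM = NA, n_ML = 5L) {
  data.frame(mean_ML = mean_ML, q_ML = q_ML, mean_HL = mean_HL,
             mean_HM = mean_HM, q_HM = q_HM, n_ML = n_ML,
             stringsAsFactors = FALSE)
}

# standard benchmark configs used across tests
zero_noise_config <- function(n_sites = 300L, seed = 1L) {
  silac_config(n_sites = n_sites, sigma = 0, missing_rate = 0, seed = seed)
}

# cells of the confusion table where the call matches the planted class
diag_confusion <- function(conf) {
  expected <- c(substrate_rescued = "rescued",
                substrate_partial = "partially_rescued",
                off_target = "not_rescued",
                unaffected = "not_applicable",
                compensatory_up_rescued = "rescued")
  vapply(rownames(conf), function(k) conf[k, expected[[k]]], numeric(1))
}
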