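SILAC_CLASSES <- c("substrate_rescued", "substrate_partial", "off_target",
                   "unaffected", "compensatory_up_rescued")

# Approximate human proteome amino-acid composition used as the background
# for sequence-window simulation (fixed built-in table, not estimated).
BACKGROUND_AA_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
  W = 0.012, Y = 0.027
)
BACKGROUND_AA_FREQ <- BACKGROUND_AA_FREQ / sum(BACKGROUND_AA_FREQ)

#' Configuration of the synthetic triple-SILAC generator
#'
#' Collects the generative parameters for [simulate_silac()]. Defaults encode
#' the study design the generator emulates: three SILAC channels
#' (L = wild-type kinase + vehicle, M = wild-type + inhibitor, H =
#' inhibitor-resistant mutant + inhibitor), five biological replicates, a
#' 1.5-fold (log2 1.5 = 0.585-crossing) planted inhibition effect of
#' magnitude `delta = 1.5`, and five effect classes: direct substrates fully
#' rescued by the mutant, partially rescued substrates, inhibitor off-target
#' sites (inhibited in both M and H), unaffected sites, and compensatorily
#' upregulated sites that return to baseline under the mutant.
#'
#' @param n_sites Number of phosphosites to simulate.
#' @param n_replicates Biological replicates per channel, default 5.
#' @param class_proportions Named fractions over the five effect classes
#'   (must sum to 1).
#' @param delta Magnitude of the planted log2 inhibition effect, default 1.5.
#' @param partial_fraction_restored Fraction of the inhibition restored in
#'   the H channel for the partial class, default 0.5 (mean H/L at
#'   `-delta/2`, outside the rescue interval for `delta = 1.5`).
#' @param sigma Per-channel log2 intensity noise SD, default 0.3.
#' @param missing_rate Per intensity-cell missing probability, default 0.05;
#'   a missing intensity voids both ratios involving that channel.
#' @param p_motif Probability that a substrate-class window carries D/E at
#'   +3, default 0.83 (the adherence proportion the design targets).
#' @param background_acidic_rate Same probability for non-substrate classes,
#'   default 0.12 (about the background D+E frequency).
#' @param localization_beta_params Shape parameters of the Beta distribution
#'   of localization probabilities, default `c(8, 1)` (about 10% of sites
#'   below the 0.75 class-I cutoff).
#' @param contaminant_rate,reverse_rate Fractions of contaminant / reverse
#'   decoy records, default 0.01 each.
#' @param protein_driven_rate Fraction of sites whose parent protein carries
#'   the same planted regulation (phospho change explained by protein
#'   abundance), default 0.02; drawn from the rescued-substrate class.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `silac_config`.
#' @export
silac_config <- function(n_sites = 2000L,
                         n_replicates = 5L,
                         class_proportions = c(substrate_rescued = 0.05,
                                               substrate_partial = 0.10,
                                               off_target = 0.05,
                                               unaffected = 0.78,
                                               compensatory_up_rescued = 0.02),
                         delta = 1.5,
                         partial_fraction_restored = 0.5,
                         sigma = 0.3,
                         missing_rate = 0.05,
                         p_motif = 0.83,
                         background_acidic_rate = 0.12,
                         localization_beta_params = c(8, 1),
                         contaminant_rate = 0.01,
                         reverse_rate = 0.01,
                         protein_driven_rate = 0.02,
                         seed = NULL) {
  if (!setequal(names(class_proportions), SILAC_CLASSES)) {
    stop("class_proportions must be named over: ",
         paste(SILAC_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  rates <- c(missing_rate, p_motif, background_acidic_rate,
             contaminant_rate, reverse_rate, protein_driven_rate)
  stopifnot(all(rates >= 0 & rates <= 1), delta > 0,
            partial_fraction_restored > 0, partial_fraction_restored < 1,
            sigma >= 0, n_sites >= 1, n_replicates >= 2)
  structure(list(
    n_sites = as.integer(n_sites), n_replicates = as.integer(n_replicates),
    class_proportions = class_proportions[SILAC_CLASSES],
    delta = delta, partial_fraction_restored = partial_fraction_restored,
    sigma = sigma, missing_rate = missing_rate, p_motif = p_motif,
    background_acidic_rate = background_acidic_rate,
    localization_beta_params = localization_beta_params,
    contaminant_rate = contaminant_rate, reverse_rate = reverse_rate,
    protein_driven_rate = protein_driven_rate, seed = seed
  ), class = "silac_config")
}

class_deltas <- function(config) {
  d <- config$delta
  dh_partial <- -d * (1 - config$partial_fraction_restored)
  data.frame(
    class = SILAC_CLASSES,
    delta_M = c(-d, -d, -d, 0, d),
    delta_H = c(0, dh_partial, -d, 0, 0),
    stringsAsFactors = FALSE
  )
}

sample_windows <- function(n, center_aa, acidic_prob, width = 31L) {
  half <- (width - 1L) %/% 2L
  aa <- names(BACKGROUND_AA_FREQ)
  chars <- matrix(sample(aa, n * width, replace = TRUE,
                         prob = BACKGROUND_AA_FREQ),
                  nrow = n, ncol = width)
  chars[, half + 1L] <- center_aa
  # +3 position: acidic with the class-dependent probability, otherwise from
  # the background restricted to non-acidic residues
  acidic <- runif(n) < acidic_prob
  non_de <- setdiff(aa, c("D", "E"))
  p_non <- BACKGROUND_AA_FREQ[non_de] / sum(BACKGROUND_AA_FREQ[non_de])
  plus3 <- ifelse(acidic, sample(c("D", "E"), n, replace = TRUE),
                  sample(non_de, n, replace = TRUE, prob = p_non))
  chars[, half + 4L] <- plus3
  apply(chars, 1, paste, collapse = "")
}

# simulate ratio-scale per-replicate ratio columns from per-record planted
# log2 effects; returns the three ratio blocks as a data frame
simulate_ratio_block <- function(n, reps, delta_M, delta_H, sigma, missing_rate) {
  base <- rnorm(n, mean = 20, sd = 2)
  out <- list()
  eL <- matrix(rnorm(n * reps, 0, sigma), n, reps)
  eM <- matrix(rnorm(n * reps, 0, sigma), n, reps)
  eH <- matrix(rnorm(n * reps, 0, sigma), n, reps)
  L <- base + eL
  M <- base + delta_M + eM
  H <- base + delta_H + eH
  missL <- matrix(runif(n * reps) < missing_rate, n, reps)
  missM <- matrix(runif(n * reps) < missing_rate, n, reps)
  missH <- matrix(runif(n * reps) < missing_rate, n, reps)
  blocks <- list(ML = list(num = M, den = L, miss = missM | missL),
                 HL = list(num = H, den = L, miss = missH | missL),
                 HM = list(num = H, den = M, miss = missH | missM))
  for (tag in names(blocks)) {
    b <- blocks[[tag]]
    r <- 2^(b$num - b$den)
    r[b$miss] <- NA_real_
    for (j in seq_len(reps)) out[[sprintf("ratio_%s_r%d", tag, j)]] <- r[, j]
  }
  as.data.frame(out)
}

#' Simulate a triple-SILAC phosphoproteomics dataset with known ground truth
#'
#' Generates a phosphosite table, a paired protein-group table and a
#' ground-truth table under the chemical-genetic rescue design. Per site and
#' replicate, log2 channel intensities are `L = b + e_L`,
#' `M = b + delta_M + e_M`, `H = b + delta_H + e_H` with independent
#' `e ~ N(0, sigma^2)` per channel, so the emitted ratios satisfy the
#' channel-consistency identity `log2(H/M) = log2(H/L) - log2(M/L)`
#' elementwise wherever all three are observed. Noise lives on intensities,
#' not ratios, so the three channels are correlated exactly as in a real
#' triple-labeling design.
#'
#' @param config A [silac_config()] object.
#' @param seed Integer seed; overrides `config$seed` if given.
#' @return Object of class `silac_sim`: `sites` and `proteins`
#'   (standardized ratio-scale tables as returned by the readers), `truth`
#'   (site_id, class, delta_M, delta_H, motif_planted, protein_driven) and
#'   `config`.
#' @examples
#' sim <- simulate_silac(silac_config(n_sites = 100, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_silac <- function(config = silac_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required (config$seed or seed argument)",
                          call. = FALSE)
  set.seed(as.integer(seed))
  n <- config$n_sites
  reps <- config$n_replicates

  cls <- sample(SILAC_CLASSES, n, replace = TRUE,
                prob = config$class_proportions)
  cd <- class_deltas(config)
  delta_M <- cd$delta_M[match(cls, cd$class)]
  delta_H <- cd$delta_H[match(cls, cd$class)]

  # protein assignment: about three sites per protein group
  n_prot <- max(1L, ceiling(n / 3))
  prot_idx <- sample.int(n_prot, n, replace = TRUE)

  # protein-driven sites: rescued-substrate sites moved to dedicated
  # proteins that carry the same planted regulation
  n_driven <- round(config$protein_driven_rate * n)
  driven <- rep(FALSE, n)
  cand <- which(cls == "substrate_rescued")
  if (n_driven > 0 && length(cand) > 0) {
    pick <- cand[seq_len(min(n_driven, length(cand)))]
    driven[pick] <- TRUE
    prot_idx[pick] <- n_prot + seq_along(pick)
  }
  n_prot_total <- n_prot + sum(driven)
  accession <- sprintf("SYNP%05d", prot_idx)
  genes <- sprintf("GENE%05d", prot_idx)

  center_aa <- sample(c("S", "T"), n, replace = TRUE, prob = c(0.8, 0.2))
  substrate <- cls %in% c("substrate_rescued", "substrate_partial",
                          "compensatory_up_rescued")
  acidic_prob <- ifelse(substrate, config$p_motif, config$background_acidic_rate)
  windows <- sample_windows(n, center_aa, acidic_prob)

  sites <- data.frame(
    site_id = sprintf("site%05d", seq_len(n)),
    protein_ids = accession,
    gene_names = genes,
    position = sample.int(1000L, n, replace = TRUE),
    amino_acid = center_aa,
    localization_prob = rbeta(n, config$localization_beta_params[1],
                              config$localization_beta_params[2]),
    sequence_window = windows,
    is_reverse = runif(n) < config$reverse_rate,
    is_contaminant = runif(n) < config$contaminant_rate,
    multiplicity = sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    stringsAsFactors = FALSE
  )
  sites <- cbind(sites, simulate_ratio_block(n, reps, delta_M, delta_H,
                                             config$sigma, config$missing_rate))
  attr(sites, "log2_transformed") <- FALSE

  # protein table: null effects except the protein-driven subset
  p_delta_M <- rep(0, n_prot_total)
  p_delta_H <- rep(0, n_prot_total)
  if (any(driven)) {
    drv_prot <- prot_idx[driven]
    p_delta_M[drv_prot] <- delta_M[driven]
    p_delta_H[drv_prot] <- delta_H[driven]
  }
  proteins <- data.frame(
    protein_ids = sprintf("SYNP%05d", seq_len(n_prot_total)),
    gene_names = sprintf("GENE%05d", seq_len(n_prot_total)),
    is_reverse = runif(n_prot_total) < config$reverse_rate,
    is_contaminant = runif(n_prot_total) < config$contaminant_rate,
    stringsAsFactors = FALSE
  )
  proteins <- cbind(proteins,
                    simulate_ratio_block(n_prot_total, reps, p_delta_M,
                                         p_delta_H, config$sigma,
                                         config$missing_rate))
  attr(proteins, "log2_transformed") <- FALSE

  truth <- data.frame(
    site_id = sites$site_id,
    class = cls,
    delta_M = delta_M,
    delta_H = delta_H,
    motif_planted = adheres_to_motif(windows),
    protein_driven = driven,
    stringsAsFactors = FALSE
  )
  structure(list(sites = sites, proteins = proteins, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "silac_sim")
}

#' @export
print.silac_sim <- function(x, ...) {
  cat(sprintf("Synthetic triple-SILAC dataset: %d sites, %d proteins, %d replicates (seed %d)\n",
              nrow(x$sites), nrow(x$proteins), x$config$n_replicates, x$seed))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a synthetic dataset as MaxQuant-dialect tables
#'
#' Emits `sites.txt` and `proteins.txt` in the tab-delimited dialect that
#' [read_site_table()] / [read_protein_table()] read (each site's ratios in
#' the column block of its multiplicity), plus `ground_truth.tsv` and
#' `config.json`.
#'
#' @param sim A `silac_sim` object.
#' @param dir Output directory (created if needed).
#' @param dialect Column dialect, defaulting to the simulated replicate count.
#' @return Invisibly, the paths written.
#' @export
write_silac_dataset <- function(sim, dir,
                                dialect = maxquant_dialect(
                                  replicates = paste0("R", seq_len(sim$config$n_replicates)))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- dialect$replicates
  sites <- sim$sites
  n <- nrow(sites)

  tab <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    id = sites$site_id
  )
  tab[[dialect$proteins]] <- sites$protein_ids
  tab[[dialect$gene_names]] <- sites$gene_names
  tab[[dialect$position]] <- sites$position
  tab[[dialect$amino_acid]] <- sites$amino_acid
  tab[[dialect$localization_prob]] <- format_number(sites$localization_prob)
  tab[[dialect$sequence_window]] <- sites$sequence_window
  tab[[dialect$reverse]] <- ifelse(sites$is_reverse, "+", "")
  tab[[dialect$contaminant]] <- ifelse(sites$is_contaminant, "+", "")
  for (ch in dialect$channels) {
    for (ri in seq_along(reps)) {
      std <- std_ratio_name(ch, ri)
      for (m in dialect$multiplicities) {
        col <- site_ratio_column(dialect, ch, reps[ri], m)
        v <- rep(NA_real_, n)
        sel <- sites$multiplicity == m
        v[sel] <- sites[[std]][sel]
        tab[[col]] <- format_number(v)
      }
    }
  }
  site_path <- file.path(dir, "sites.txt")
  write.table(tab, site_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")

  prot <- sim$proteins
  ptab <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                     row.names = seq_len(nrow(prot)))
  ptab[[dialect$proteins]] <- prot$protein_ids
  ptab[[dialect$gene_names]] <- prot$gene_names
  ptab[[dialect$reverse]] <- ifelse(prot$is_reverse, "+", "")
  ptab[[dialect$contaminant]] <- ifelse(prot$is_contaminant, "+", "")
  for (ch in dialect$channels) {
    for (ri in seq_along(reps)) {
      ptab[[protein_ratio_column(dialect, ch, reps[ri])]] <-
        format_number(prot[[std_ratio_name(ch, ri)]])
    }
  }
  prot_path <- file.path(dir, "proteins.txt")
  write.table(ptab, prot_path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")

  truth_path <- file.path(dir, "ground_truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  config_path <- file.path(dir, "config.json")
  cfg <- sim$config
  cfg$seed <- sim$seed
  jsonlite::write_json(unclass(cfg), config_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(sites = site_path, proteins = prot_path, truth = truth_path,
              config = config_path))
}

#' Compare classifier output against planted ground truth
#'
#' Each planted class has an expected rescue call: rescued substrates and
#' compensatory upregulated sites should be called `rescued`, partial
#' substrates `partially_rescued`, off-target sites `not_rescued`, and
#' unaffected sites `not_applicable`. Sensitivity per planted class is the
#' fraction of its records receiving the expected call; specificity per call
#' is the fraction of records NOT expecting that call that did not receive
#' it.
#'
#' @param site_calls Classified site table (must carry `site_id` and
#'   `rescue`); typically `fit$sites` from [rescue_analysis()]. Records
#'   absent from the truth are an error; truth records filtered out upstream
#'   are ignored.
#' @param truth Ground-truth table from [simulate_silac()].
#' @return List with `confusion` (planted class x call contingency table),
#'   `sensitivity` (per class, `NA` when the class was not planted),
#'   `specificity` (per call level) and `accuracy`.
#' @export
evaluate_recovery <- function(site_calls, truth) {
  if (!all(site_calls$site_id %in% truth$site_id)) {
    stop("site ids in calls do not all match the ground truth", call. = FALSE)
  }
  tr <- truth[match(site_calls$site_id, truth$site_id), ]
  expected_map <- c(substrate_rescued = "rescued",
                    substrate_partial = "partially_rescued",
                    off_target = "not_rescued",
                    unaffected = "not_applicable",
                    compensatory_up_rescued = "rescued")
  expected <- expected_map[tr$class]
  call <- site_calls$rescue
  levels_call <- c("rescued", "partially_rescued", "not_rescued", "not_applicable")
  confusion <- table(planted = factor(tr$class, levels = SILAC_CLASSES),
                     called = factor(call, levels = levels_call))
  sensitivity <- vapply(SILAC_CLASSES, function(k) {
    idx <- tr$class == k
    if (!any(idx)) return(NA_real_)
    mean(call[idx] == expected_map[[k]])
  }, numeric(1))
  specificity <- vapply(levels_call, function(v) {
    idx <- expected != v
    if (!any(idx)) return(NA_real_)
    mean(call[idx] != v)
  }, numeric(1))
  list(confusion = confusion, sensitivity = sensitivity,
       specificity = specificity, accuracy = mean(call == expected))
}
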