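#' Direction, significance and biological relevance of regulation
#'
#' Classifies each record from its M/L channel statistics: the direction of
#' regulation is the sign of the mean log2 M/L ratio (`down` = inhibited by
#' the drug, `up` = increased); a record is `significant` when its BH q value
#' is strictly below `alpha`; it is `biologically_relevant` when the mean
#' log2 M/L exceeds the fold-change cutoff in the called direction (strictly,
#' so a mean of exactly `-fc_threshold` is not relevant). Records whose M/L
#' statistics are undefined get direction `insufficient_data`.
#'
#' @param records Table with channel statistics from [channel_stats()].
#' @param alpha FDR significance level, default 0.05.
#' @param fc_threshold Absolute log2 fold-change cutoff, default 0.585
#'   (1.5-fold regulation: `log2(1.5)` to 3 decimals).
#' @return The table with added `direction`, `significant` and
#'   `biologically_relevant` columns (rescue status not yet set).
#' @export
call_regulation <- function(records, alpha = 0.05, fc_threshold = 0.585) {
  mu <- records$mean_ML
  q <- records$q_ML
  direction <- rep("none", nrow(records))
  direction[!is.na(mu) & mu < 0] <- "down"
  direction[!is.na(mu) & mu > 0] <- "up"
  direction[is.na(mu) | records$n_ML < 2L] <- "insufficient_data"
  significant <- !is.na(q) & q < alpha & direction %in% c("down", "up")
  relevant <- !is.na(mu) & (mu < -fc_threshold | mu > fc_threshold)
  records$direction <- direction
  records$significant <- significant
  records$biologically_relevant <- relevant
  records
}

#' Rescue status of inhibited or upregulated records
#'
#' The core chemical-genetic inference: among records that are significantly
#' regulated to a biologically relevant level in the inhibitor-treated
#' wild-type channel (M/L), decide whether expression of the
#' inhibitor-resistant kinase mutant (H channel) restores the phosphosite.
#'
#' For a downregulated record: `rescued` when the mean log2 H/L lies strictly
#' inside `(-fc_threshold, fc_threshold)` (phosphorylation back at control
#' level) and the one-sample H/M test is significant (`q < alpha`);
#' `partially_rescued` when not rescued but the mean log2 H/M is positive
#' with a significant H/M test; otherwise `not_rescued`. Upregulated records
#' use the mirrored criteria (H/L inside the same interval; partial rescue
#' requires a significantly negative H/M). Records that were not both
#' significant and relevant get `not_applicable`; undefined H/L or H/M
#' statistics yield `not_rescued` with the reason recorded in `rescue_note`.
#'
#' @inheritParams call_regulation
#' @param records Table produced by [call_regulation()].
#' @return The table with added `rescue` and `rescue_note` columns.
#' @export
call_rescue <- function(records, alpha = 0.05, fc_threshold = 0.585) {
  n <- nrow(records)
  rescue <- rep("not_applicable", n)
  note <- rep(NA_character_, n)
  eligible <- records$significant & records$biologically_relevant &
    records$direction %in% c("down", "up")
  mu_hl <- records$mean_HL
  mu_hm <- records$mean_HM
  q_hm <- records$q_HM

  undef <- eligible & (is.na(mu_hl) | is.na(q_hm))
  rescue[undef] <- "not_rescued"
  note[undef] <- "undefined H/L or H/M statistics"

  ok <- eligible & !undef
  in_interval <- ok & mu_hl > -fc_threshold & mu_hl < fc_threshold
  hm_sig <- ok & q_hm < alpha
  resc <- in_interval & hm_sig
  rescue[resc] <- "rescued"

  rest <- ok & !resc
  down_part <- rest & records$direction == "down" &
    !is.na(mu_hm) & mu_hm > 0 & hm_sig
  up_part <- rest & records$direction == "up" &
    !is.na(mu_hm) & mu_hm < 0 & hm_sig
  rescue[down_part | up_part] <- "partially_rescued"
  rescue[rest & !(down_part | up_part)] <- "not_rescued"

  records$rescue <- rescue
  records$rescue_note <- note
  records
}

leading_accession <- function(protein_ids) {
  vapply(strsplit(protein_ids, ";", fixed = TRUE),
         function(p) if (length(p) > 0) trimws(p[[1L]]) else NA_character_,
         character(1))
}

#' Flag sites whose change is explained by protein abundance
#'
#' A rescued phosphopeptide is only informative about kinase activity when
#' the change is not driven by differential expression of the parent
#' protein. This cross-references every classified site against the
#' classified protein-group table: a site is flagged `protein_confounded`
#' when any of its accessions matches a protein record that is itself
#' significantly regulated to a biologically relevant level in the same
#' direction. Sites with no matching protein record are not flagged.
#' Confounded sites are flagged, not removed, so funnel counts stay
#' comparable.
#'
#' @param site_calls Classified site table (after [call_rescue()]).
#' @param protein_calls Classified protein table produced with identical
#'   thresholds, or `NULL` to skip (all flags `FALSE`).
#' @return The site table with a `protein_confounded` column.
#' @export
cross_reference_proteome <- function(site_calls, protein_calls) {
  site_calls$protein_confounded <- FALSE
  if (is.null(protein_calls) || nrow(protein_calls) == 0L) return(site_calls)
  prot_acc <- strsplit(protein_calls$protein_ids, ";", fixed = TRUE)
  reg <- protein_calls$significant & protein_calls$biologically_relevant
  dir_by_acc <- list()
  for (i in which(reg)) {
    for (a in trimws(prot_acc[[i]])) dir_by_acc[[a]] <- protein_calls$direction[i]
  }
  if (length(dir_by_acc) == 0L) return(site_calls)
  site_acc <- strsplit(site_calls$protein_ids, ";", fixed = TRUE)
  site_calls$protein_confounded <- mapply(function(accs, dir) {
    any(vapply(trimws(accs),
               function(a) identical(dir_by_acc[[a]], dir), logical(1)))
  }, site_acc, site_calls$direction)
  site_calls
}

distinct_peptide_key <- function(records) {
  paste(records$sequence_window, records$multiplicity, sep = "|")
}
distinct_site_key <- function(records) {
  paste(leading_accession(records$protein_ids), records$position, sep = "|")
}

count_distinct <- function(records, idx, keyfun) {
  length(unique(keyfun(records[idx, , drop = FALSE])))
}

#' Summarize the classification funnel
#'
#' Counts distinct phosphopeptides, phosphosites and proteins in each class
#' of the filtering funnel. A distinct phosphopeptide is a unique
#' (sequence window, multiplicity) pair; a distinct phosphosite a unique
#' (leading accession, position) pair; a distinct protein a unique leading
#' accession. The partially-rescued counts are cumulative (they include the
#' rescued records, as the less stringent criterion nests the stricter one).
#'
#' @param site_calls Classified site table.
#' @param protein_calls Classified protein table or `NULL`.
#' @return A `funnel_summary` list of counts.
#' @export
summarize_funnel <- function(site_calls, protein_calls = NULL) {
  s <- site_calls
  down <- s$direction == "down" & s$significant & s$biologically_relevant
  up <- s$direction == "up" & s$significant & s$biologically_relevant
  resc_down <- down & s$rescue == "rescued"
  part_down <- down & s$rescue %in% c("rescued", "partially_rescued")
  resc_up <- up & s$rescue == "rescued"

  prot_of <- function(idx) length(unique(leading_accession(s$protein_ids[idx])))

  out <- list(
    n_down_significant_relevant = count_distinct(s, down, distinct_peptide_key),
    n_down_sites = count_distinct(s, down, distinct_site_key),
    n_rescued_peptides = count_distinct(s, resc_down, distinct_peptide_key),
    n_rescued_sites = count_distinct(s, resc_down, distinct_site_key),
    n_rescued_proteins = prot_of(resc_down),
    n_partial_peptides = count_distinct(s, part_down, distinct_peptide_key),
    n_partial_sites = count_distinct(s, part_down, distinct_site_key),
    n_partial_proteins = prot_of(part_down),
    n_up_significant_relevant = count_distinct(s, up, distinct_peptide_key),
    n_up_rescued = count_distinct(s, resc_up, distinct_peptide_key),
    n_multiplicity1_rescued = count_distinct(
      s, resc_down & s$multiplicity == 1L, distinct_peptide_key)
  )
  if (!is.null(protein_calls)) {
    p <- protein_calls
    p_down <- p$direction == "down" & p$significant & p$biologically_relevant
    p_up <- p$direction == "up" & p$significant & p$biologically_relevant
    out$n_proteins_down <- sum(p_down)
    out$n_proteins_down_rescued <- sum(p_down & p$rescue == "rescued")
    out$n_proteins_up <- sum(p_up)
    out$n_proteins_up_rescued <- sum(p_up & p$rescue == "rescued")
  }
  structure(out, class = "funnel_summary")
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat("Classification funnel (distinct phosphopeptides unless noted):\n")
  cat(sprintf("  inhibited (down, significant, >1.5-fold): %d peptides (%d sites)\n",
              x$n_down_significant_relevant, x$n_down_sites))
  cat(sprintf("  partially rescued (incl. rescued):        %d peptides (%d sites, %d proteins)\n",
              x$n_partial_peptides, x$n_partial_sites, x$n_partial_proteins))
  cat(sprintf("  rescued:                                  %d peptides (%d sites, %d proteins)\n",
              x$n_rescued_peptides, x$n_rescued_sites, x$n_rescued_proteins))
  cat(sprintf("  rescued at multiplicity 1:                %d peptides\n",
              x$n_multiplicity1_rescued))
  cat(sprintf("  upregulated / up-rescued:                 %d / %d peptides\n",
              x$n_up_significant_relevant, x$n_up_rescued))
  if (!is.null(x$n_proteins_down)) {
    cat(sprintf("  proteins down / down-rescued:             %d / %d\n",
                x$n_proteins_down, x$n_proteins_down_rescued))
    cat(sprintf("  proteins up / up-rescued:                 %d / %d\n",
                x$n_proteins_up, x$n_proteins_up_rescued))
  }
  invisible(x)
}
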