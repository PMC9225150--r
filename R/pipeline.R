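#' Run the full pipeline and write its artifacts
#'
#' Orchestrates read -> filter -> statistics -> classification -> motif
#' profiling and writes, under `out_dir`: the classified site and protein
#' tables, a JSON summary (QC funnel, classification funnel, thresholds),
#' per-class motif-profile matrices for the nested record sets (all input
#' sites before filtering, inhibited, partially rescued, rescued), and a
#' volcano export table. Every filter count and threshold is logged via
#' [message()].
#'
#' @inheritParams rescue_analysis
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the `rescue_analysis` fit.
#' @export
run_pipeline <- function(sites, proteins = NULL, out_dir,
                         alpha = 0.05, fc_threshold = 0.585,
                         min_localization = 0.75, min_valid = 3L,
                         dialect = maxquant_dialect()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(sites)) {
    message("reading site table: ", sites)
    sites <- read_site_table(sites, dialect)
  }
  raw_windows <- sites$sequence_window
  if (is.character(proteins)) {
    message("reading protein table: ", proteins)
    proteins <- read_protein_table(proteins, dialect)
  }
  message(sprintf("thresholds: alpha=%g fc_threshold=%g min_localization=%g min_valid=%d",
                  alpha, fc_threshold, min_localization, min_valid))
  fit <- rescue_analysis(sites, proteins, alpha = alpha,
                         fc_threshold = fc_threshold,
                         min_localization = min_localization,
                         min_valid = min_valid)
  fr <- fit$filter_report
  message(sprintf("QC funnel: %d -> %d (reverse/contaminant) -> %d (localization >= %g)",
                  fr$n_input, fr$n_after_reverse_contaminant,
                  fr$n_after_localization, fr$threshold_localization))
  message(sprintf("inhibited: %d peptides; rescued: %d peptides; partial: %d peptides",
                  fit$funnel$n_down_significant_relevant,
                  fit$funnel$n_rescued_peptides, fit$funnel$n_partial_peptides))

  write_results(fit$sites, file.path(out_dir, "classified_sites.tsv"))
  if (!is.null(fit$proteins)) {
    write_results(fit$proteins, file.path(out_dir, "classified_proteins.tsv"))
  }
  jsonlite::write_json(
    list(thresholds = fit$thresholds,
         filter_report = unclass(fit$filter_report),
         protein_report = fit$protein_report,
         funnel = unclass(fit$funnel)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")

  for (prof in names(profile_sets <- motif_profile_sets(fit, raw_windows))) {
    write_motif_profile(profile_sets[[prof]],
                        file.path(out_dir, sprintf("motif_profile_%s.tsv", prof)))
  }
  write.table(volcano_export(fit), file.path(out_dir, "volcano_export.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(fit)
}

#' Motif profiles of the nested classification sets
#'
#' Builds position-frequency/information-content profiles for the four
#' nested record sets a logo is typically drawn for: all input windows
#' before any filtering, inhibited sites (down, significant, beyond the
#' fold-change cutoff), partially rescued sites (including rescued), and
#' rescued sites. Within each classified set one window per distinct
#' phosphosite is used.
#'
#' @param fit A `rescue_analysis` object.
#' @param prefilter_windows Optional character vector of all windows before
#'   QC filtering (defaults to the analysed windows).
#' @return Named list of `motif_profile` objects:
#'   `all`, `inhibited`, `partial`, `rescued`.
#' @export
motif_profile_sets <- function(fit, prefilter_windows = NULL) {
  s <- fit$sites
  if (is.null(prefilter_windows)) prefilter_windows <- s$sequence_window
  key <- distinct_site_key(s)
  per_site <- function(idx) {
    idx <- which(idx)
    s$sequence_window[idx[!duplicated(key[idx])]]
  }
  down <- s$direction == "down" & s$significant & s$biologically_relevant
  list(
    all = build_motif_profile(prefilter_windows),
    inhibited = build_motif_profile(per_site(down)),
    partial = build_motif_profile(
      per_site(down & s$rescue %in% c("rescued", "partially_rescued"))),
    rescued = build_motif_profile(per_site(down & s$rescue == "rescued"))
  )
}
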