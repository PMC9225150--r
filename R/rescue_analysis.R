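#' Chemical-genetic rescue analysis of a triple-SILAC experiment
#'
#' The main entry point: runs the full inference on a phosphosite table and
#' (optionally) its paired protein-group table. The stages are (i) QC
#' filtering — removal of reverse decoys and contaminants, then of sites with
#' localization probability below `min_localization`; (ii) log2
#' transformation of the normalized M/L, H/L and H/M ratios; (iii) per
#' channel, a one-sample t test of the replicate log2 ratios against zero
#' with Benjamini-Hochberg FDR control across all records (sites and
#' proteins as separate families); (iv) regulation calls — direction,
#' significance (`q < alpha`), biological relevance
#' (`|mean log2 M/L| > fc_threshold`); (v) rescue calls from the H/L
#' interval and the H/M test; (vi) cross-referencing of site calls against
#' protein-level regulation; (vii) recognition-motif annotation and funnel
#' summary.
#'
#' @param sites Site table from [read_site_table()] or [simulate_silac()],
#'   or a path to a MaxQuant-dialect site table.
#' @param proteins Protein table, a path, or `NULL` to skip the proteome
#'   cross-reference (a warning is issued and `protein_confounded` is all
#'   `FALSE`).
#' @param alpha FDR significance level, default 0.05 (strict inequality).
#' @param fc_threshold Log2 fold-change cutoff for biological relevance,
#'   default 0.585, i.e. 1.5-fold regulation (strict inequality).
#' @param min_localization Minimum phosphosite localization probability,
#'   default 0.75 (inclusive).
#' @param min_valid Minimum non-missing replicates per channel for a test,
#'   default 3 of 5.
#' @param dialect Column dialect used when `sites`/`proteins` are paths.
#' @return An object of class `rescue_analysis` with components `sites`
#'   (classified site table), `proteins` (classified protein table or
#'   `NULL`), `filter_report`, `funnel` (a [summarize_funnel()] result),
#'   and `thresholds`.
#' @examples
#' sim <- simulate_silac(silac_config(n_sites = 300, seed = 11))
#' fit <- rescue_analysis(sim$sites, sim$proteins)
#' fit
#' summary(fit)
#' @seealso [summarize_funnel()], [evaluate_recovery()], [run_pipeline()]
#' @export
rescue_analysis <- function(sites, proteins = NULL,
                            alpha = 0.05, fc_threshold = 0.585,
                            min_localization = 0.75, min_valid = 3L,
                            dialect = maxquant_dialect()) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold > 0)
  if (is.character(sites)) sites <- read_site_table(sites, dialect)
  if (is.character(proteins)) proteins <- read_protein_table(proteins, dialect)

  flt <- filter_sites(sites, min_localization = min_localization)
  s <- log2_transform(flt$records)
  s <- channel_stats(s, min_valid = min_valid)
  s <- call_regulation(s, alpha = alpha, fc_threshold = fc_threshold)
  s <- call_rescue(s, alpha = alpha, fc_threshold = fc_threshold)
  s$motif_adherent <- adheres_to_motif(s$sequence_window)

  p <- NULL
  protein_report <- NULL
  if (!is.null(proteins)) {
    keep <- !(proteins$is_reverse | proteins$is_contaminant)
    protein_report <- list(n_input = nrow(proteins), n_kept = sum(keep))
    p <- proteins[keep, , drop = FALSE]
    attr(p, "log2_transformed") <- attr(proteins, "log2_transformed")
    p <- log2_transform(p)
    p <- channel_stats(p, min_valid = min_valid)
    p <- call_regulation(p, alpha = alpha, fc_threshold = fc_threshold)
    p <- call_rescue(p, alpha = alpha, fc_threshold = fc_threshold)
  } else {
    warning("no protein table supplied; proteome cross-reference skipped",
            call. = FALSE)
  }
  s <- cross_reference_proteome(s, p)

  structure(list(
    sites = s,
    proteins = p,
    filter_report = flt$report,
    protein_report = protein_report,
    funnel = summarize_funnel(s, p),
    thresholds = list(alpha = alpha, fc_threshold = fc_threshold,
                      min_localization = min_localization,
                      min_valid = as.integer(min_valid)),
    call = match.call()
  ), class = "rescue_analysis")
}

#' @export
print.rescue_analysis <- function(x, ...) {
  cat("Triple-SILAC chemical-genetic rescue analysis\n")
  th <- x$thresholds
  cat(sprintf("  thresholds: q < %g, |log2 FC| > %g, localization >= %g, >= %d valid replicates\n",
              th$alpha, th$fc_threshold, th$min_localization, th$min_valid))
  cat(sprintf("  records analysed: %d sites", nrow(x$sites)))
  if (!is.null(x$proteins)) cat(sprintf(", %d proteins", nrow(x$proteins)))
  cat("\n")
  print(x$funnel)
  invisible(x)
}

#' @export
summary.rescue_analysis <- function(object, ...) {
  resc <- which(object$sites$rescue == "rescued" &
                  object$sites$direction == "down")
  site_key <- distinct_site_key(object$sites)
  resc_sites <- resc[!duplicated(site_key[resc])]
  adh <- motif_adherence_rate(object$sites$sequence_window[resc_sites])
  structure(list(
    filter_report = object$filter_report,
    funnel = object$funnel,
    thresholds = object$thresholds,
    n_confounded = sum(object$sites$protein_confounded),
    rescued_motif_adherent = adh$adherent,
    rescued_motif_rate = adh$rate,
    n_rescued_distinct_sites = length(resc_sites)
  ), class = "summary.rescue_analysis")
}

#' @export
print.summary.rescue_analysis <- function(x, ...) {
  print(x$filter_report)
  print(x$funnel)
  cat(sprintf("  rescued sites adhering to [S/T]-x-x-[D/E]: %d of %d (%.0f%%)\n",
              x$rescued_motif_adherent, x$n_rescued_distinct_sites,
              100 * x$rescued_motif_rate))
  cat(sprintf("  sites confounded by protein-level change:  %d\n",
              x$n_confounded))
  invisible(x)
}

#' Volcano plot of the site-level analysis
#'
#' Mean log2 M/L against -log10 q, with the conventional annotation:
#' records significantly regulated beyond the fold-change cutoff in gold,
#' rescued records in purple, dashed vertical lines at the +/- fold-change
#' cutoff and a dashed horizontal line at the significance level.
#'
#' @param x A `rescue_analysis` object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame (`volcano_export()` output).
#' @export
plot.rescue_analysis <- function(x, ...) {
  v <- volcano_export(x)
  col <- c(background = "grey70", regulated = "goldenrod2",
           rescued = "purple3")[v$class]
  graphics::plot(v$mean_log2_ML, v$neg_log10_q, pch = 16, cex = 0.5,
                 col = col,
                 xlab = expression(log[2] ~ "M/L (inhibitor / vehicle)"),
                 ylab = expression(-log[10] ~ "q"), ...)
  graphics::abline(v = c(-1, 1) * x$thresholds$fc_threshold, lty = 2)
  graphics::abline(h = -log10(x$thresholds$alpha), lty = 2)
  invisible(v)
}

#' Plot-ready volcano export table
#'
#' @param fit A `rescue_analysis` object.
#' @return Data frame with `site_id`, `mean_log2_ML`, `neg_log10_q` and
#'   `class` (`background`, `regulated`, `rescued`).
#' @export
volcano_export <- function(fit) {
  s <- fit$sites
  cls <- rep("background", nrow(s))
  cls[s$significant & s$biologically_relevant] <- "regulated"
  cls[s$rescue == "rescued"] <- "rescued"
  data.frame(site_id = s$site_id,
             mean_log2_ML = s$mean_ML,
             neg_log10_q = -log10(s$q_ML),
             class = cls,
             stringsAsFactors = FALSE)
}
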