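#' Quality-control filtering of phosphosite records
#'
#' Applies the two site-level filters used before differential analysis:
#' removal of reverse-decoy and contaminant records, then removal of records
#' whose phosphosite localization probability falls below `min_localization`
#' (inclusive threshold: a record exactly at the threshold is kept). The
#' returned report records the funnel count after each stage.
#'
#' @param records Site table from [read_site_table()] or [simulate_silac()].
#' @param min_localization Minimum localization probability, default 0.75
#'   (the class-I site convention).
#' @return A list with `records` (surviving rows) and `report`, a
#'   `filter_report` list with `n_input`, `n_after_reverse_contaminant`,
#'   `n_after_localization` and `threshold_localization`.
#' @examples
#' sim <- simulate_silac(silac_config(n_sites = 50, seed = 1))
#' filter_sites(sim$sites)$report
#' @export
filter_sites <- function(records, min_localization = 0.75) {
  stopifnot(min_localization >= 0, min_localization <= 1)
  n_input <- nrow(records)
  keep1 <- !(records$is_reverse | records$is_contaminant)
  records <- records[keep1, , drop = FALSE]
  n_rc <- nrow(records)
  keep2 <- !is.na(records$localization_prob) &
    records$localization_prob >= min_localization
  records <- records[keep2, , drop = FALSE]
  rownames(records) <- NULL
  report <- structure(list(
    n_input = n_input,
    n_after_reverse_contaminant = n_rc,
    n_after_localization = nrow(records),
    threshold_localization = min_localization
  ), class = "filter_report")
  list(records = records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Site-level QC funnel:\n")
  cat(sprintf("  input records:                %d\n", x$n_input))
  cat(sprintf("  after reverse/contaminant:    %d\n", x$n_after_reverse_contaminant))
  cat(sprintf("  after localization >= %.2f:   %d\n",
              x$threshold_localization, x$n_after_localization))
  invisible(x)
}

#' Log2-transform SILAC ratios
#'
#' Replaces every non-missing normalized ratio by its base-2 logarithm;
#' missing values stay missing. Ratios must be positive.
#'
#' @param records Site or protein table with ratio-scale `ratio_*` columns.
#' @return The same table with log2 ratio values (attribute
#'   `log2_transformed` set, so downstream statistics can assert their
#'   precondition).
#' @export
log2_transform <- function(records) {
  if (isTRUE(attr(records, "log2_transformed"))) {
    stop("records are already log2-transformed", call. = FALSE)
  }
  for (ch in c("M/L", "H/L", "H/M")) {
    for (col in ratio_columns(records, ch)) {
      v <- records[[col]]
      bad <- which(!is.na(v) & v <= 0)
      if (length(bad) > 0L) {
        id <- if ("site_id" %in% names(records)) records$site_id[bad[1L]] else
          records$protein_ids[bad[1L]]
        stop(sprintf("non-positive ratio in record '%s', channel %s", id, ch),
             call. = FALSE)
      }
      records[[col]] <- log2(v)
    }
  }
  attr(records, "log2_transformed") <- TRUE
  records
}
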