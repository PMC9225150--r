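#' Column-name dialect for MaxQuant-style tables
#'
#' MaxQuant writes one wide row per phosphosite (or protein group), with
#' normalized SILAC ratio columns named per channel, per experiment and -- in
#' the site table -- per phosphopeptide multiplicity (suffixes `___1`,
#' `___2`, `___3`). A dialect maps the logical fields this package needs onto
#' the column names of a particular table, so simplified fixtures need not
#' reproduce every MaxQuant column.
#'
#' @param replicates Character vector of experiment (biological replicate)
#'   names as they appear inside ratio column names. Default `R1`..`R5`,
#'   matching a five-replicate design.
#' @param multiplicities Integer vector of multiplicity states carried by the
#'   site table (MaxQuant emits 1--3).
#' @param channels Character vector of SILAC ratio channels.
#' @return A list of class `silac_dialect` mapping logical fields to column
#'   names, with `site_ratio_column()`/`protein_ratio_column()` templates.
#' @examples
#' d <- maxquant_dialect(replicates = c("R1", "R2", "R3"))
#' d$sequence_window
#' @export
maxquant_dialect <- function(replicates = paste0("R", 1:5),
                             multiplicities = 1:3,
                             channels = c("M/L", "H/L", "H/M")) {
  structure(list(
    id                = "id",
    proteins          = "Proteins",
    gene_names        = "Gene names",
    position          = "Position",
    amino_acid        = "Amino acid",
    localization_prob = "Localization prob",
    sequence_window   = "Sequence window",
    multiplicity      = NULL,  # encoded in ___ suffixes, not a column
    reverse           = "Reverse",
    contaminant       = "Potential contaminant",
    replicates        = replicates,
    multiplicities    = as.integer(multiplicities),
    channels          = channels
  ), class = "silac_dialect")
}

# "Ratio M/L normalized R1___2"
site_ratio_column <- function(dialect, channel, replicate, multiplicity) {
  sprintf("Ratio %s normalized %s___%d", channel, replicate, multiplicity)
}

# "Ratio M/L normalized R1"
protein_ratio_column <- function(dialect, channel, replicate) {
  sprintf("Ratio %s normalized %s", channel, replicate)
}

# internal canonical channel tags used in standardized column names
channel_tag <- function(channel) gsub("/", "", channel, fixed = TRUE)

#' @export
print.silac_dialect <- function(x, ...) {
  cat("MaxQuant-style column dialect\n")
  cat("  replicates:     ", paste(x$replicates, collapse = ", "), "\n")
  cat("  multiplicities: ", paste(x$multiplicities, collapse = ", "), "\n")
  cat("  channels:       ", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}
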