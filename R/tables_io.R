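#' @importFrom utils read.delim write.table
NULL

MISSING_TOKENS <- c("", "NaN", "nan", "NA")

# Parse a character/numeric ratio column; unrecognized text is a parse error
# naming the offending row.
parse_ratio_column <- function(x, colname) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  keep <- !(x %in% MISSING_TOKENS) & !is.na(x)
  vals <- suppressWarnings(as.numeric(x[keep]))
  bad <- which(keep)[is.na(vals)]
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric ratio value '%s' in column '%s', row %d",
                 x[bad[1L]], colname, bad[1L]), call. = FALSE)
  }
  out[keep] <- vals
  out
}

require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("mandatory column '%s' not found in '%s'",
                 missing[1L], path), call. = FALSE)
  }
}

std_ratio_name <- function(channel, replicate_index) {
  sprintf("ratio_%s_r%d", channel_tag(channel), replicate_index)
}

#' Standardized ratio column names for a channel
#'
#' Helper to locate the per-replicate ratio columns of one SILAC channel in a
#' standardized site or protein table.
#'
#' @param x A data frame produced by [read_site_table()],
#'   [read_protein_table()] or [simulate_silac()].
#' @param channel One of `"M/L"`, `"H/L"`, `"H/M"`.
#' @return Character vector of column names, in replicate order.
#' @export
ratio_columns <- function(x, channel) {
  tag <- channel_tag(channel)
  nm <- grep(sprintf("^ratio_%s_r[0-9]+$", tag), names(x), value = TRUE)
  nm[order(as.integer(sub(sprintf("^ratio_%s_r", tag), "", nm)))]
}

#' Extract a channel's ratio values as a matrix
#'
#' @inheritParams ratio_columns
#' @return Numeric matrix, one row per record, one column per replicate.
#' @export
ratio_matrix <- function(x, channel) {
  as.matrix(x[, ratio_columns(x, channel), drop = FALSE])
}

#' Read a MaxQuant-style phosphosite table
#'
#' Reads a tab-delimited `Phospho (STY)Sites.txt`-dialect table and expands
#' the wide per-multiplicity layout (`___1`/`___2`/`___3` ratio column
#' suffixes) into one record per site x multiplicity state that carries at
#' least one non-missing ratio. Empty cells, `NaN`/`nan` and `NA` parse as
#' missing; a `+` in the Reverse / Potential contaminant columns sets the
#' corresponding flag.
#'
#' @param path Path to the tab-delimited table (UTF-8, header row).
#' @param dialect Column-name mapping, see [maxquant_dialect()].
#' @return A data frame with one row per site x multiplicity record:
#'   identifier and annotation columns (`site_id`, `protein_ids`,
#'   `gene_names`, `position`, `amino_acid`, `localization_prob`,
#'   `multiplicity`, `sequence_window`, `is_reverse`, `is_contaminant`) and
#'   per-replicate ratio columns `ratio_ML_r1` ... for each channel. Ratios
#'   are on the ratio (not log) scale.
#' @seealso [read_protein_table()], [filter_sites()], [log2_transform()]
#' @export
read_site_table <- function(path, dialect = maxquant_dialect()) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  tab <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, quote = "")
  meta_cols <- c(dialect$proteins, dialect$gene_names, dialect$position,
                 dialect$amino_acid, dialect$localization_prob,
                 dialect$sequence_window, dialect$reverse, dialect$contaminant)
  require_columns(tab, meta_cols, path)
  reps <- dialect$replicates
  mults <- dialect$multiplicities

  n <- nrow(tab)
  ids <- if (!is.null(dialect$id) && dialect$id %in% names(tab)) {
    as.character(tab[[dialect$id]])
  } else sprintf("site%05d", seq_len(n))

  base <- data.frame(
    site_id           = ids,
    protein_ids       = as.character(tab[[dialect$proteins]]),
    gene_names        = as.character(tab[[dialect$gene_names]]),
    position          = as.integer(parse_ratio_column(tab[[dialect$position]], dialect$position)),
    amino_acid        = as.character(tab[[dialect$amino_acid]]),
    localization_prob = parse_ratio_column(tab[[dialect$localization_prob]], dialect$localization_prob),
    sequence_window   = as.character(tab[[dialect$sequence_window]]),
    is_reverse        = trimws(as.character(tab[[dialect$reverse]])) == "+",
    is_contaminant    = trimws(as.character(tab[[dialect$contaminant]])) == "+",
    stringsAsFactors  = FALSE
  )

  # ratio cube: [row, channel x replicate, multiplicity]
  pieces <- vector("list", length(mults))
  for (mi in seq_along(mults)) {
    m <- mults[mi]
    rat <- matrix(NA_real_, nrow = n, ncol = length(dialect$channels) * length(reps))
    k <- 0L
    std_names <- character(0)
    for (ch in dialect$channels) {
      for (ri in seq_along(reps)) {
        k <- k + 1L
        col <- site_ratio_column(dialect, ch, reps[ri], m)
        if (col %in% names(tab)) rat[, k] <- parse_ratio_column(tab[[col]], col)
        std_names[k] <- std_ratio_name(ch, ri)
      }
    }
    colnames(rat) <- std_names
    pieces[[mi]] <- rat
  }

  out <- vector("list", length(mults))
  for (mi in seq_along(mults)) {
    has_data <- rowSums(!is.na(pieces[[mi]])) > 0L
    if (!any(has_data)) next
    rec <- base[has_data, , drop = FALSE]
    rec$multiplicity <- mults[mi]
    out[[mi]] <- cbind(rec, as.data.frame(pieces[[mi]][has_data, , drop = FALSE]))
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- cbind(base[0, , drop = FALSE], multiplicity = integer(0))
  }
  ord <- order(match(out$site_id, ids), out$multiplicity)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log2_transformed") <- FALSE
  out
}

#' Read a MaxQuant-style protein-group table
#'
#' As [read_site_table()] but for `proteinGroups.txt`-dialect tables: no
#' multiplicity expansion and no site-level annotation columns.
#'
#' @inheritParams read_site_table
#' @return Data frame with `protein_ids`, `gene_names`, `is_reverse`,
#'   `is_contaminant` and per-replicate `ratio_*` columns.
#' @export
read_protein_table <- function(path, dialect = maxquant_dialect()) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  tab <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = NULL, quote = "")
  meta_cols <- c(dialect$proteins, dialect$gene_names, dialect$reverse,
                 dialect$contaminant)
  require_columns(tab, meta_cols, path)
  out <- data.frame(
    protein_ids      = as.character(tab[[dialect$proteins]]),
    gene_names       = as.character(tab[[dialect$gene_names]]),
    is_reverse       = trimws(as.character(tab[[dialect$reverse]])) == "+",
    is_contaminant   = trimws(as.character(tab[[dialect$contaminant]])) == "+",
    stringsAsFactors = FALSE
  )
  for (ch in dialect$channels) {
    for (ri in seq_along(dialect$replicates)) {
      col <- protein_ratio_column(dialect, ch, dialect$replicates[ri])
      out[[std_ratio_name(ch, ri)]] <-
        if (col %in% names(tab)) parse_ratio_column(tab[[col]], col) else NA_real_
    }
  }
  rownames(out) <- NULL
  attr(out, "log2_transformed") <- FALSE
  out
}

#' Write a classified result table
#'
#' Writes any standardized record table (classified sites or proteins) as
#' tab-delimited text with a stable column order; missing values are rendered
#' as empty strings.
#'
#' @param records Data frame of (classified) site or protein records, or a
#'   [rescue_analysis] object (its site table is written).
#' @param path Output file path.
#' @return Invisibly, the written data frame.
#' @export
write_results <- function(records, path) {
  if (inherits(records, "rescue_analysis")) records <- records$sites
  df <- as.data.frame(records)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- format_number(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(records)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a tab-delimited result table.
#' @return Data frame with empty cells as `NA` and numeric columns restored.
#' @export
read_results <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                   stringsAsFactors = FALSE, quote = "")
  rownames(df) <- NULL
  df
}

# deterministic, round-trip-safe numeric formatting
format_number <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.12g", x[ok])
  out
}
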