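AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PLACEHOLDER <- "_"

#' Minimal acidophilic kinase recognition motif
#'
#' Tests whether a phosphosite sequence window adheres to the minimal
#' CSNK2-type recognition motif `[S/T]-x-x-[D/E]`: a serine or threonine
#' phosphoacceptor with an acidic residue (Asp or Glu) at position +3.
#' Position +1 is never penalized (proline there is common and reported
#' faithfully by the profile, but plays no role in adherence). A placeholder
#' (`_`, terminus padding) at +3 and tyrosine-centered windows give `FALSE`.
#'
#' @param sequence_window Character vector of odd-length windows centered on
#'   the phosphoacceptor (MaxQuant convention: 31-mers padded with `_`).
#' @return Logical vector.
#' @examples
#' adheres_to_motif("ARVLGSEGEEE")  # LIG1-type window, +3 = E
#' @export
adheres_to_motif <- function(sequence_window) {
  len <- nchar(sequence_window)
  if (any(len %% 2 == 0)) {
    stop("sequence windows must have odd length (centered on the phosphoacceptor)",
         call. = FALSE)
  }
  center_pos <- (len + 1L) %/% 2L
  center <- substr(sequence_window, center_pos, center_pos)
  plus3 <- ifelse(center_pos + 3L <= len,
                  substr(sequence_window, center_pos + 3L, center_pos + 3L),
                  PLACEHOLDER)
  center %in% c("S", "T") & plus3 %in% c("D", "E")
}

#' Motif adherence count and rate
#'
#' @param windows Character vector of sequence windows (at least one).
#' @return List with `adherent` (count) and `rate` (fraction of windows).
#' @export
motif_adherence_rate <- function(windows) {
  if (length(windows) == 0L) return(list(adherent = 0L, rate = 0))
  adh <- sum(adheres_to_motif(windows))
  list(adherent = adh, rate = adh / length(windows))
}

pad_or_trim_window <- function(w, width) {
  len <- nchar(w)
  center <- (len + 1L) %/% 2L
  half <- (width - 1L) %/% 2L
  if (len >= width) {
    substr(w, center - half, center + half)
  } else {
    pad <- strrep(PLACEHOLDER, half - (center - 1L))
    paste0(pad, w, strrep(PLACEHOLDER, half - (len - center)))
  }
}

#' Position frequency matrix and information content of sequence windows
#'
#' The matrix behind a sequence logo: per-position residue counts over a set
#' of aligned windows (position 0 = phosphoacceptor), column-normalized
#' frequencies over the 20 standard residues (terminus placeholders are
#' excluded from counting), and per-position information content in bits,
#' `IC = log2(20) - H` with `H` the Shannon entropy of the column, against a
#' uniform background. No small-sample correction is applied.
#'
#' @param windows Character vector of odd-length windows; windows longer than
#'   `2 * halfwidth + 1` are trimmed around the center, shorter ones padded
#'   with placeholders.
#' @param halfwidth Number of positions on each side of the phosphoacceptor,
#'   default 15 (the MaxQuant 31-mer window).
#' @return Object of class `motif_profile`: `counts` and `frequencies`
#'   (residue x position matrices, positions `-halfwidth..+halfwidth`),
#'   `information_content` (bits per position, `NA` where no residue was
#'   observed), `n_windows`, `halfwidth`.
#' @export
build_motif_profile <- function(windows, halfwidth = 15L) {
  if (any(nchar(windows) %% 2 == 0)) {
    stop("sequence windows must have odd length", call. = FALSE)
  }
  width <- 2L * as.integer(halfwidth) + 1L
  ww <- vapply(windows, pad_or_trim_window, character(1), width = width,
               USE.NAMES = FALSE)
  chars <- matrix(unlist(strsplit(ww, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(ww), ncol = width, byrow = TRUE)
  known <- c(AA_ALPHABET, PLACEHOLDER)
  bad <- setdiff(unique(as.vector(chars)), known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue character '%s' in sequence window", bad[1L]),
         call. = FALSE)
  }
  positions <- seq(-halfwidth, halfwidth)
  counts <- matrix(0L, nrow = length(AA_ALPHABET), ncol = width,
                   dimnames = list(AA_ALPHABET, as.character(positions)))
  for (j in seq_len(width)) {
    tab <- table(factor(chars[, j], levels = AA_ALPHABET))
    counts[, j] <- as.integer(tab)
  }
  colsum <- colSums(counts)
  freq <- sweep(counts, 2, pmax(colsum, 1L), "/")
  freq[, colsum == 0] <- NA_real_
  ic <- apply(freq, 2, function(f) {
    if (anyNA(f)) return(NA_real_)
    f <- f[f > 0]
    log2(length(AA_ALPHABET)) + sum(f * log2(f))
  })
  structure(list(counts = counts, frequencies = freq,
                 information_content = ic,
                 n_windows = length(windows),
                 halfwidth = as.integer(halfwidth)),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("Motif profile over %d windows (positions -%d..+%d)\n",
              x$n_windows, x$halfwidth, x$halfwidth))
  ic <- x$information_content
  top <- sort(ic, decreasing = TRUE)
  top <- top[!is.na(top)][seq_len(min(5, sum(!is.na(ic))))]
  cat("  highest information content (bits):\n")
  for (p in names(top)) {
    j <- which(colnames(x$frequencies) == p)
    best <- rownames(x$frequencies)[which.max(x$frequencies[, j])]
    cat(sprintf("    position %3s: %.2f (top residue %s, %.0f%%)\n",
                p, ic[[p]], best, 100 * max(x$frequencies[, j])))
  }
  invisible(x)
}

#' Write a motif profile as plain-text matrices
#'
#' Emits the position frequency matrix as a tab-delimited table (residues as
#' rows, positions as columns) plus a JSON file with the per-position
#' information content, suitable for any logo renderer.
#'
#' @param profile A `motif_profile` object.
#' @param path Output path for the frequency matrix; the information-content
#'   JSON is written alongside with suffix `.ic.json`.
#' @return Invisibly, `profile`.
#' @export
write_motif_profile <- function(profile, path) {
  df <- data.frame(residue = rownames(profile$frequencies),
                   profile$frequencies, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(n_windows = profile$n_windows,
         positions = as.integer(colnames(profile$frequencies)),
         information_content = unname(profile$information_content)),
    paste0(path, ".ic.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(profile)
}
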