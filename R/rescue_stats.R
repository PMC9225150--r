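#' @importFrom stats pt p.adjust rnorm rbeta runif setNames
NULL

#' One-sample t test of log2 ratios against zero
#'
#' The per-record test of the differential workflow: for one channel's
#' replicate log2 ratios, tests the null hypothesis that the mean log2 ratio
#' is zero. The statistic is `t = mean / (sd / sqrt(n))` with `n - 1` degrees
#' of freedom and a two-sided p value. Degenerate inputs are not errors:
#' fewer than `min_valid` non-missing values yields an undefined result, and
#' zero sample variance yields the limiting case (`t = +/-Inf`, `p = 0` for a
#' nonzero mean; undefined for an all-zero vector).
#'
#' @param values Numeric vector of per-replicate log2 ratios; `NA` = missing.
#' @param min_valid Minimum number of non-missing values required, default 2.
#' @return List with `n_valid`, `mean`, `sd`, `t_stat`, `p_value`, `df` and
#'   `reason` (`NA` when the test was performed, otherwise why not).
#' @examples
#' one_sample_ttest(c(0.5, 1.0, 1.5))
#' @export
one_sample_ttest <- function(values, min_valid = 2L) {
  v <- values[!is.na(values)]
  n <- length(v)
  res <- list(n_valid = n, mean = if (n > 0) mean(v) else NA_real_,
              sd = if (n > 1) stats::sd(v) else NA_real_,
              t_stat = NA_real_, p_value = NA_real_, df = NA_real_,
              reason = NA_character_)
  if (n < max(2L, min_valid)) {
    res$reason <- "too few valid values"
    return(res)
  }
  if (res$sd == 0) {
    if (res$mean == 0) {
      res$reason <- "zero variance, zero mean"
      return(res)
    }
    res$t_stat <- sign(res$mean) * Inf
    res$p_value <- 0
    res$df <- n - 1
    return(res)
  }
  res$t_stat <- res$mean / (res$sd / sqrt(n))
  res$df <- n - 1
  res$p_value <- 2 * stats::pt(-abs(res$t_stat), df = n - 1)
  res
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment across a test family. Undefined (`NA`) entries are
#' excluded from the family and returned undefined; input order is preserved.
#'
#' @param p_values Numeric vector of p values in `[0, 1]` (`0` arises only as
#'   the zero-variance limiting case of [one_sample_ttest()]).
#' @return Numeric vector of q values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

# Vectorized per-channel moments and t statistics over a record table.
# Returns a data frame of n/mean/sd/t/p columns for one channel.
channel_moments <- function(x, channel, min_valid) {
  m <- ratio_matrix(x, channel)
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  ss <- rowSums(m * m, na.rm = TRUE) - n * mu * mu
  ss[ss < 0] <- 0  # numerical guard
  sd <- ifelse(n > 1, sqrt(ss / pmax(n - 1, 1)), NA_real_)
  testable <- n >= max(2L, min_valid)
  t <- rep(NA_real_, nrow(m))
  p <- rep(NA_real_, nrow(m))
  pos <- testable & !is.na(sd) & sd > 0
  t[pos] <- mu[pos] / (sd[pos] / sqrt(n[pos]))
  p[pos] <- 2 * stats::pt(-abs(t[pos]), df = n[pos] - 1)
  degen <- testable & !is.na(sd) & sd == 0 & mu != 0
  t[degen] <- sign(mu[degen]) * Inf
  p[degen] <- 0
  data.frame(n_valid = n, mean_log2 = mu, sd_log2 = sd, t_stat = t, p_value = p)
}

#' Per-channel summary statistics with family-wide FDR control
#'
#' Computes, for every record and every SILAC ratio channel, the number of
#' valid replicates, the mean and standard deviation of the log2 ratios, the
#' one-sample t statistic and two-sided p value, and the
#' Benjamini-Hochberg q value. The FDR family for each channel is the full
#' set of records passed in (sites and proteins therefore form separate
#' families when processed separately, mirroring a column-wise Perseus test).
#'
#' @param records Log2-transformed site or protein table (see
#'   [log2_transform()]).
#' @param min_valid Minimum non-missing replicates per channel for the test
#'   to be performed, default 3 of 5.
#' @return The input table with added columns `n_<ch>`, `mean_<ch>`,
#'   `sd_<ch>`, `t_<ch>`, `p_<ch>`, `q_<ch>` for `<ch>` in `ML`, `HL`, `HM`.
#' @export
channel_stats <- function(records, min_valid = 3L) {
  if (!isTRUE(attr(records, "log2_transformed"))) {
    stop("channel_stats() requires log2-transformed records; see log2_transform()",
         call. = FALSE)
  }
  for (ch in c("M/L", "H/L", "H/M")) {
    tag <- channel_tag(ch)
    mom <- channel_moments(records, ch, min_valid)
    records[[paste0("n_", tag)]] <- mom$n_valid
    records[[paste0("mean_", tag)]] <- mom$mean_log2
    records[[paste0("sd_", tag)]] <- mom$sd_log2
    records[[paste0("t_", tag)]] <- mom$t_stat
    records[[paste0("p_", tag)]] <- mom$p_value
    records[[paste0("q_", tag)]] <- bh_adjust(mom$p_value)
  }
  records
}
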