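# Independent brute-force oracle for the Benjamini-Hochberg step-up rule:
# q_i = min over all j with p_j >= p_i of (m * p_j / rank_j), clipped to 1,
# with rank_j = number of p values <= p_j. Written literally from the
# definition, independent of the package's implementation.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi], function(pj) m * pj / sum(p <= pj), numeric(1))
    min(c(cand, 1))
  }, numeric(1))
}
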