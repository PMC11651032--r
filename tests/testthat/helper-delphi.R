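# Shared builders for vote tables and tiny simulated studies.

make_votes <- function(code, scores, round = 1L,
                       panelists = sprintf("P%02d", seq_along(scores))) {
  data.frame(round = round, code = code, panelist = panelists,
             score = scores, stringsAsFactors = FALSE)
}

# One vote table for several codes, each with its own score vector.
make_round <- function(scores_by_code, round = 1L) {
  do.call(rbind, lapply(names(scores_by_code), function(cd) {
    make_votes(cd, scores_by_code[[cd]], round = round)
  }))
}

# A small, fully concordant study configuration (every panel endorses a
# correct proposal; nothing contested).
concordant_config <- function(n_codes = 200L, ...) {
  sim_config(n_codes = n_codes, reviewer_error_rate = 0,
             concordance = 1, controversy_fraction = 0, n_covid = 0L, ...)
}

# Literal, independent transcription of the agreement rule used as the
# brute-force oracle: stats::quantile (type 7) for the quartiles, the
# enumerated median/IPRAS rules applied verbatim.
oracle_status <- function(scores) {
  q <- unname(stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  ipras_val <- 2.35 + 1.5 * abs(5 - (q[1] + q[3]) / 2)
  med <- q[2]
  if (med < 4) "AGREE_LOW"
  else if (med < 7) "NO_AGREEMENT"
  else if (iqr > ipras_val) "NO_AGREEMENT"
  else "AGREE_HIGH"
}
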