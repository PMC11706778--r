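# Independent oracles and shared toy fixtures.

# direct transcription of the ssGSEA score definition: position-by-position
# sum of the weighted in-set ECDF minus the unweighted out-of-set ECDF
ssgsea_oracle <- function(x, set, alpha = 0.25) {
  rnk <- rank(x, ties.method = "average")
  ord <- order(rnk, decreasing = TRUE)
  ids <- names(x)[ord]
  denom_in <- sum(rnk[ord][ids %in% set]^alpha)
  n_out <- sum(!ids %in% set)
  score <- 0; cum_in <- 0; cum_out <- 0
  for (i in seq_along(ids)) {
    if (ids[i] %in% set) cum_in <- cum_in + rnk[ord][i]^alpha
    else cum_out <- cum_out + 1
    score <- score + (cum_in / denom_in - cum_out / n_out)
  }
  unname(score)
}

# 2 donors x fractions 1/4/7; 5 proteins with varied missingness patterns
make_cls_toy <- function() {
  des <- tiny_design(n_donors = 2, fractions = c(1, 4, 7))
  vals <- rbind(
    P1 = c(16, 16,   NA, NA, 15, 15),  # absent from fraction 4
    P2 = c(13, NA,   16, 16, 16, 16),  # low mean in fraction 1
    P3 = c(15, NA,   16, 16, 16, 16),  # high mean in fraction 1
    P4 = c(13.0, NA, 16, 16, 16, 16),  # fraction-1 mean below cutoff
    P5 = c(16, 16,   16, 16, 16, 16))  # complete
  colnames(vals) <- des$sample
  toy_lfq(vals, des)
}
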