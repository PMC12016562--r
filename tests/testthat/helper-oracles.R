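# Independent oracles and small fixture builders shared across test files.

# All-pairs Mann-Whitney AUROC: P(score_pos > score_neg) + 0.5 P(tie).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Hand-built annotation table (transcript coordinates, 5'->3').
mk_annotation <- function(lengths, utr5 = 100L, utr3 = 100L,
                          expression = 1) {
  n <- length(lengths)
  data.frame(transcript_id = sprintf("TX%03d", seq_len(n)),
             gene_id = sprintf("G%03d", seq_len(n)),
             strand = rep("+", n),
             utr5_len = rep_len(utr5, n),
             cds_len = lengths - rep_len(utr5, n) - rep_len(utr3, n),
             utr3_len = rep_len(utr3, n),
             length = lengths,
             expression = rep_len(expression, n),
             stringsAsFactors = FALSE)
}

# Dot-product oracle for planted m6A levels (no noise, no clipping applied
# when levels stay positive): per-site affine function of log1p expression.
m6a_oracle <- function(expr, net) {
  lx <- log1p(expr)
  t(vapply(seq_along(net$site_ids), function(s) {
    net$intercept[s] + as.vector(lx[, net$regulators[[s]], drop = FALSE] %*%
                                   net$coefficients[[s]])
  }, numeric(nrow(expr))))
}
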