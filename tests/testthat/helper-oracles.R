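# Independent oracles used by several test files.

# Five-hypothesis posterior by explicit enumeration over causal-variant
# configurations, on the natural (non-log) scale.
enumerate_pps <- function(l1, l2, p1, p2, p12) {
  L1 <- exp(l1)
  L2 <- exp(l2)
  v <- length(l1)
  S0 <- 1
  S1 <- p1 * sum(L1)
  S2 <- p2 * sum(L2)
  S3 <- 0
  for (i in seq_len(v)) for (j in seq_len(v)) {
    if (i != j) S3 <- S3 + L1[i] * L2[j]
  }
  S3 <- p1 * p2 * S3
  S4 <- p12 * sum(L1 * L2)
  s <- c(S0, S1, S2, S3, S4)
  s / sum(s)
}

# closed-form Wakefield log-ABF, written out independently
wakefield <- function(beta, se, sd0) {
  v <- se^2
  w <- sd0^2
  log(sqrt(v / (v + w))) + (beta / se)^2 * w / (2 * (v + w))
}
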