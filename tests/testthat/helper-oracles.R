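# Independent oracles used across the suite.

# Brute-force Benjamini-Hochberg step-up, mapped back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Weighted circular mean by direct complex-vector summation.
circ_mean_oracle <- function(phases, weights = rep(1, length(phases))) {
  z <- sum(weights * exp(1i * 2 * pi * phases / 24))
  (Arg(z) * 24 / (2 * pi)) %% 24
}

# Smallest data set usable by most bulk helpers.
tiny_dataset <- function() {
  t <- c(3, 9, 15, 21)
  m <- rbind(gA = c(10, 8, 2, 4), gB = c(1, 1, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  meta <- data.frame(sample_id = paste0("s", 1:4), zt = t,
                     age_group = "young", sex = "M",
                     replicate = paste0("r", 1:4))
  expression_dataset(m, meta)
}
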