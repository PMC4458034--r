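# Independent oracles used by both unit and acceptance tests.

# Brute-force exact Fisher p for a 2 x c table: enumerate every first row
# compatible with the margins and accumulate multivariate hypergeometric
# probabilities of tables no more probable than the observed one.
fisher_oracle_2xc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(t1) {
    t2 <- cs - t1
    if (any(t2 < 0)) return(NA_real_)
    exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
          sum(lfactorial(c(t1, t2))))
  }
  cells <- expand.grid(purrr::map(cs, ~0:.x))
  cells <- cells[rowSums(cells) == rs[1], , drop = FALSE]
  ps <- apply(cells, 1, function(t1) prob(as.numeric(t1)))
  p_obs <- prob(tab[1, ])
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Direct step-up definition of the Benjamini-Hochberg adjustment.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)
    adj[i] <- min(1, min(p[o][seq(r, m)] * m / seq(r, m)))
  }
  adj
}
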