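# Independent oracles, kept deliberately naive and separate from the
# package's code paths.

# Step-up FDR adjustment straight from the definition:
# q_i = min_{j >= i} (n * p_(j) / j), clipped at 1, in input order.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(n), function(i) min(n * ps[i:n] / (i:n)), numeric(1))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# Exact two-sided Wilcoxon p by full enumeration of all assignments of the
# pooled midranks to the first group.
wilcox_exact_oracle <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  sums <- colSums(combn(r, nx))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}

# Fisher combination via numerical integration of the chi-square density
# with 2k degrees of freedom (upper tail beyond X2 = -2 sum log p).
fisher_oracle <- function(p) {
  k <- length(p)
  x2 <- -2 * sum(log(p))
  dens <- function(u) u^(k - 1) * exp(-u / 2) / (2^k * gamma(k))
  stats::integrate(dens, lower = x2, upper = Inf, rel.tol = 1e-13)$value
}
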