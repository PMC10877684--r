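# Independent oracles used to check the statistical paths.

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (with the same relative
# slack R uses to absorb floating-point noise).
fisher_two_sided_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  dens <- dhyper(lo:hi, r1, r2, c1)
  sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)])
}

# One-sided (over-representation) Fisher p: P(X >= a) by enumeration.
fisher_greater_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  xs <- lo:hi
  sum(dhyper(xs[xs >= a], r1, r2, c1))
}

# Exact Wilcoxon signed-rank p by enumeration of all 2^n sign assignments
# (valid for untied, non-zero differences).
wilcoxon_signed_oracle <- function(x, y,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  w_obs <- sum(r[d > 0])
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Pearson correlation from the covariance formula.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Plug-in Shannon entropy by direct summation over counts.
shannon_oracle <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log(p))
}
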