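# Independent oracles, kept deliberately naive: each re-derives its quantity
# with plain loops / closed forms, never through the package's own code path.

# connectivity KS statistic by an explicit scan over every list position,
# tracking the tag ECDF against the uniform reference
ks_oracle <- function(positions, n_total) {
  n <- length(positions)
  cnt <- 0
  a <- -Inf
  b <- -Inf
  for (i in seq_len(n_total)) {
    if (i %in% positions) {
      b <- max(b, i / n_total - cnt / n)
      cnt <- cnt + 1
      a <- max(a, cnt / n - i / n_total)
    }
  }
  if (a > b) a else -b
}

# textbook Welch-Satterthwaite two-sample test
welch_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a) / n1; v2 <- var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# closed-form type-7 quantile (linear interpolation between order statistics)
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# exact hypergeometric upper tail by direct combinatorial evaluation
hyper_oracle <- function(k, m, x, u) {
  i <- x:min(k, m)
  sum(choose(m, i) * choose(u - m, k - i)) / choose(u, k)
}
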