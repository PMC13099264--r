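# Independent enumeration oracles for the statistical tests.

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration: sum the probabilities of all tables with the observed
# margins whose probability does not exceed the observed table's.
fisher_enum_p <- function(d1, n1, d2, n2) {
  K <- d1 + d2                       # total detected (column margin)
  support <- max(0, K - n2):min(n1, K)
  probs <- vapply(support, function(x)
    exp(lchoose(n1, x) + lchoose(n2, K - x) - lchoose(n1 + n2, K)),
    numeric(1))
  p_obs <- probs[match(d1, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact Wilcoxon rank-sum p by full enumeration of the
# C(n1+n2, n1) group assignments (assumes no ties across groups).
wilcox_enum_p <- function(x, y) {
  v <- c(x, y)
  stopifnot(!anyDuplicated(v))
  n1 <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(v), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(v) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up by hand.
bh_enum <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pseudo-F for a distance matrix and grouping, computed independently from
# first principles (direct double loop over pairs).
pseudo_f_direct <- function(d, groups) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  n <- nrow(d)
  a <- nlevels(groups)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    acc <- 0
    if (ng > 1)
      for (i in idx) for (j in idx) if (i < j) acc <- acc + d[i, j]^2
    ss_w <- ss_w + acc / ng
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}
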