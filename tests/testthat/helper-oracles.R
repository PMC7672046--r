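# Independent brute-force oracles used to check the statistical kernels.
# Each is written from the textbook definition (log-choose enumeration),
# never via the code path it checks.

# Two-sided Fisher exact by full margin-fixed enumeration.
oracle_fisher <- function(a, b, c, d) {
  alt <- a + c; ref <- b + d; case <- a + b; pan <- c + d
  if (alt == 0 || ref == 0 || case == 0 || pan == 0) return(1)
  N <- alt + ref
  xs <- max(0, alt - pan):min(alt, case)
  lp <- lchoose(case, xs) + lchoose(pan, alt - xs) - lchoose(N, alt)
  lobs <- lp[xs == a]
  min(1, sum(exp(lp)[lp <= lobs + log1p(1e-7)]))
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} m p_(j) / j, clipped to 1, in input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (no ties assumed).
oracle_wilcoxon <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(na + nb, na)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  p <- if (u_obs <= mu) 2 * mean(us <= u_obs) else 2 * mean(us >= u_obs)
  min(1, p)
}

# Venn region counts by direct set algebra.
oracle_venn_regions <- function(sets) {
  union_all <- unique(unlist(sets))
  sig <- vapply(union_all, function(el)
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&"), character(1))
  table(sig)
}
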