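# Independent brute-force oracles used to validate the package's statistics.
# These are deliberately naive (enumeration / direct definitions) and share
# no code with the implementation.

# Benjamini-Hochberg step-up by direct definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][i:m] * m / (i:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the observed margins and summing the probabilities <= the observed one
# (with the customary relative tolerance).
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_range, function(a)
    stats::dhyper(a, c1, n - c1, r1), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact Mann-Whitney p by enumerating all group assignments.
oracle_mannwhitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  combs <- utils::combn(n1 + n2, n1)
  u_of <- function(idx) {
    x <- vals[idx]; y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  u_null <- apply(combs, 2, u_of)
  p_low <- mean(u_null <= u_obs)
  p_high <- mean(u_null >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Upper-tail hypergeometric over-representation p by full enumeration of
# all possible query lists of the given size.
oracle_hypergeom_enum <- function(universe_size, set_size, list_size, overlap) {
  universe <- seq_len(universe_size)
  gene_set <- seq_len(set_size)
  combs <- utils::combn(universe_size, list_size)
  hits <- apply(combs, 2, function(idx) sum(idx %in% gene_set))
  mean(hits >= overlap)
}

# ssGSEA running sum straight from its definition, with explicit loops.
oracle_ssgsea <- function(expr, gene_set, alpha = 0.25) {
  n <- length(expr)
  ord <- names(sort(expr, decreasing = TRUE))
  r <- rank(expr)
  es <- 0
  sum_w_in <- 0
  for (g in ord) if (g %in% gene_set) sum_w_in <- sum_w_in + r[g]^alpha
  n_out <- n - sum(names(expr) %in% gene_set)
  p_in <- 0; p_out <- 0
  for (g in ord) {
    if (g %in% gene_set) p_in <- p_in + r[[g]]^alpha / sum_w_in
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Weighted GSEA ES for a single-gene set: the running sum attains its
# extreme either at the hit (hit mass minus misses before it) or just
# before the hit (negative miss mass). On an exact magnitude tie the
# earlier extreme (the pre-hit trough) is reported, matching the
# first-extreme convention of the running-sum scan.
oracle_gsea_single <- function(stat_sorted_desc, hit_position) {
  n <- length(stat_sorted_desc)
  miss_step <- 1 / (n - 1)
  at_hit <- 1 - (hit_position - 1) * miss_step
  before_hit <- -(hit_position - 1) * miss_step
  if (abs(before_hit) >= abs(at_hit)) before_hit else at_hit
}
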