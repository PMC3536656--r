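# Independent brute-force oracles, written against the definitions and
# deliberately kept apart from the package's code paths.

# Step-up BH by literal rank scan: q_(i) = min over j >= i of
# min(1, m * p_(j) / j), returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric tails by exhaustive enumeration of all nA-subsets of a
# universe of size n containing nB marked elements.
oracle_hyper_tails <- function(n, na, nb, obs) {
  marked <- seq_len(nb)
  subsets <- utils::combn(n, na)
  overlaps <- apply(subsets, 2, function(s) sum(s %in% marked))
  c(p_over = mean(overlaps >= obs), p_under = mean(overlaps <= obs))
}

# geNorm stability M by direct all-pairs double loop on a counts matrix.
oracle_genorm_m <- function(x) {
  l <- log2(x)
  n <- nrow(x)
  m <- numeric(n)
  for (j in seq_len(n)) {
    acc <- c()
    for (k in seq_len(n)) {
      if (k != j) acc <- c(acc, stats::sd(l[j, ] - l[k, ]))
    }
    m[j] <- mean(acc)
  }
  names(m) <- rownames(x)
  m
}

# Full geNorm exclusion order by repeated direct recomputation; ties on
# M drop the lexicographically last id, matching the documented rule.
oracle_genorm_order <- function(x) {
  x <- x[order(rownames(x)), , drop = FALSE]
  out <- character(0)
  while (nrow(x) > 2) {
    m <- oracle_genorm_m(x)
    worst <- names(m)[m == max(m)]
    drop_id <- max(worst)
    out <- c(out, drop_id)
    x <- x[setdiff(rownames(x), drop_id), , drop = FALSE]
  }
  c(out, sort(rownames(x)))
}

# Scan-based root of the trigamma moment equation trigamma(d0/2) = y.
oracle_trigamma_root <- function(y, lo = 1e-6, hi = 1e6) {
  f <- function(d0) trigamma(d0 / 2) - y
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Ordinary two-sample pooled-variance t-test from group summaries.
oracle_pooled_t <- function(mean_a, mean_b, s2, n_a, n_b) {
  t <- (mean_b - mean_a) / sqrt(s2 * (1 / n_a + 1 / n_b))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n_a + n_b - 2))
}

# Small flagged DE table builder for program-construction tests.
toy_de_table <- function(probeset_id, log2_fc, is_de,
                         mean_a = 8, q_value = ifelse(is_de, 0.001, 0.5)) {
  data.frame(
    probeset_id = probeset_id,
    n_a = 3, n_b = 3,
    mean_a = mean_a, mean_b = mean_a + log2_fc,
    log2_fc = log2_fc, s2 = 0.05, df = 4, s2_post = 0.05,
    t = log2_fc / sqrt(0.05 * 2 / 3),
    p_value = q_value, q_value = q_value,
    passes_intensity = TRUE,
    passes_fc = abs(log2_fc) >= log2(1.5),
    passes_p = q_value <= 0.01,
    is_de = is_de,
    direction = ifelse(log2_fc > 0, "up", ifelse(log2_fc < 0, "down", NA)),
    stringsAsFactors = FALSE
  )
}
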