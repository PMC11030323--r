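# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (loops, explicit enumerations) and share no
# code with the package internals.

# recovery-curve AUC by explicit step-function integration
oracle_auc <- function(ranking, regulon_genes, window) {
  hits <- vapply(seq_len(window), function(k) {
    sum(ranking[seq_len(k)] %in% regulon_genes)
  }, numeric(1))
  m <- min(length(regulon_genes), window)
  max_hits <- vapply(seq_len(window), function(k) min(k, m), numeric(1))
  sum(hits) / sum(max_hits)
}

# ARI by exhaustive pair counting over all element pairs
oracle_ari <- function(p1, p2) {
  n <- length(p1)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
    if (s1 && s2) a <- a + 1
    else if (s1 && !s2) b <- b + 1
    else if (!s1 && s2) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  maxi <- ((a + b) + (a + c_)) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# one-sided enrichment p by direct hypergeometric tail summation
oracle_hyper_tail <- function(k, n_a, n_b, n_u) {
  kk <- k:min(n_a, n_b)
  sum(choose(n_a, kk) * choose(n_u - n_a, n_b - kk)) / choose(n_u, n_b)
}

# Lin's CCC from population (divisor-n) moments, written out directly
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n; sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# base-2 Jensen-Shannon divergence by direct KL summation
oracle_jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# small deterministic expression fixture: planted two-state counts
make_toy_expr <- function(n_cells = 60, n_genes = 40, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 2), n_cells, n_genes)
  state <- rep(1:2, length.out = n_cells)
  up <- seq_len(min(5, n_genes))
  counts[state == 2, up] <- counts[state == 2, up] + 20L
  meta <- data.frame(patient_id = rep(c("P1", "P2", "P3"), length.out = n_cells),
                     category = "toy")
  list(expr = expression_matrix(counts, sprintf("g%02d", 1:n_genes),
                                sprintf("c%02d", 1:n_cells), meta),
       state = state)
}
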