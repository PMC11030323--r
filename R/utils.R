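#' Derive a stage-specific seed from a global seed
#'
#' Expands one user-facing seed into independent per-stage substreams so that
#' adding or reordering pipeline stages does not perturb the randomness of the
#' others. The stage name is hashed to a small integer offset and combined
#' with the global seed modulo 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"activity"`.
#' @return an integer seed suitable for [set.seed()].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

# internal: stop() with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

# internal: check a scalar is a single finite number
.num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Shannon entropy of a frequency vector
#'
#' H = -sum p_i log p_i in nats over the nonzero frequencies. Counts are
#' normalized to probabilities internally.
#'
#' @param counts non-negative numeric vector of label counts or frequencies
#'   (e.g. number of cells per patient within a cluster); must sum to > 0.
#' @return entropy in nats, in `[0, log(length(counts))]`.
#' @examples
#' shannon_entropy(c(5, 5, 5, 5))  # log(4)
#' shannon_entropy(c(10, 0, 0))    # 0
#' @export
shannon_entropy <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0)) {
    .fail("shannon_entropy: counts must be non-negative numeric")
  }
  s <- sum(counts)
  if (s <= 0) .fail("shannon_entropy: counts sum to zero")
  p <- counts[counts > 0] / s
  -sum(p * log(p))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same elements,
#' computed from the contingency table under the Hubert-Arabie permutation
#' model. 1 means identical partitions (up to relabeling); values near 0 are
#' expected for independent partitions; negative values indicate less
#' agreement than chance.
#'
#' @param p1,p2 vectors of cluster labels over the same elements.
#' @return numeric ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (length(p1) != length(p2)) .fail("adjusted_rand_index: unequal lengths")
  n <- length(p1)
  if (n < 2L) return(1)
  tab <- table(p1, p2)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  nc2 <- choose(n, 2)
  expected <- a * b / nc2
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)  # both partitions trivial (all-one-cluster or all-singletons)
  (sum_ij - expected) / (max_index - expected)
}
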