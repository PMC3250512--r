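#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic child seed for replicate r of a run seeded with `seed`.
# Kept below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(seed, r) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + r) %% 2147483647)
}
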