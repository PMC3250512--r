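# Independent oracles used across tests. These deliberately re-derive results
# by brute force / enumeration and must stay independent of the package's own
# code paths.

# quick community matrix from a plain matrix
cm <- function(m, sites = NULL, species = NULL, ...) {
  if (is.null(rownames(m))) rownames(m) <- sites %||%
      paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- species %||%
      paste0("sp", seq_len(ncol(m)))
  community_matrix(m, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# within-group sum of squares around the centroid
ss_of <- function(y) {
  if (nrow(y) == 0) return(0)
  sum(sweep(y, 2, colMeans(y))^2)
}

# exhaustive best-split search: every variable, every midpoint between
# adjacent distinct sorted values; returns the maximal gain (ties share it)
brute_force_best_gain <- function(y, x, min_split = 2) {
  n <- nrow(y)
  parent <- ss_of(y)
  best <- -Inf
  if (n < min_split) return(best)
  for (v in seq_len(ncol(x))) {
    vals <- sort(unique(x[, v]))
    if (length(vals) < 2) next
    thr <- (vals[-1] + vals[-length(vals)]) / 2
    for (t in thr) {
      l <- x[, v] < t
      gain <- parent - ss_of(y[l, , drop = FALSE]) -
        ss_of(y[!l, , drop = FALSE])
      if (gain > best) best <- gain
    }
  }
  best
}

# gain actually realized by the split stored at a tree node
node_gain <- function(tree, node) {
  tree$ss[node] - tree$ss[tree$left[node]] - tree$ss[tree$right[node]]
}

# full-enumeration Raup-Crick tail: P(|A intersect B| >= s) over all
# choose(S, a) equiprobable draws of A, with B fixed as species 1..b
enum_tail <- function(S, a, b, s) {
  if (a == 0) return(as.numeric(s <= 0))
  draws <- combn(S, a)
  mean(apply(draws, 2, function(A) sum(A <= b) >= s))
}

# Monte-Carlo Raup-Crick tail
mc_tail <- function(S, a, b, s, draws = 10000) {
  mean(replicate(draws, {
    A <- sample.int(S, a); B <- sample.int(S, b)
    length(intersect(A, B)) >= s
  }))
}

# random small test instance for split-search checks
random_instance <- function(n_sites, n_species, n_vars) {
  y <- matrix(rbinom(n_sites * n_species, 1, 0.5), n_sites, n_species,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              paste0("sp", seq_len(n_species))))
  x <- matrix(round(runif(n_sites * n_vars, 0, 100), 1), n_sites, n_vars,
              dimnames = list(rownames(y), paste0("x", seq_len(n_vars))))
  list(y = y, x = x)
}
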