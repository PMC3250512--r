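#' Raup-Crick probabilistic similarity
#'
#' For two sites with richness `a` and `b` sharing `s` species out of a pool
#' of `S`, the dissimilarity is the probability of sharing at least `s`
#' species when the two species sets are drawn at random from the pool
#' (hypergeometric tail, symmetric in `a` and `b`):
#' \deqn{p = \sum_{i=s}^{\min(a,b)} \binom{b}{i} \binom{S-b}{a-i} / \binom{S}{a}}
#' and the similarity reported is `1 - p`. The classic null draws all species
#' equiprobably; `null = "frequency"` instead weights species by their
#' occurrence frequency across sites and estimates `p` by Monte Carlo.
#'
#' @param x a binary [community_matrix()].
#' @param null `"equiprobable"` (exact, default) or `"frequency"`
#'   (occurrence-frequency-weighted, Monte Carlo).
#' @param draws Monte Carlo draws per pair for the frequency null.
#' @param seed seed for the frequency null.
#' @return an object of class `raup_crick`: the site-by-site similarity matrix
#'   (diagonal 1) with attributes recording the convention and null model.
#' @export
raup_crick <- function(x, null = c("equiprobable", "frequency"),
                       draws = 10000, seed = 1) {
  stopifnot(inherits(x, "community_matrix"))
  if (!x$binary) stop("Raup-Crick requires a presence/absence matrix")
  null <- match.arg(null)
  occ <- x$occurrences
  n <- nrow(occ)
  S <- ncol(occ)
  sim <- diag(1, n)
  dimnames(sim) <- list(x$site_ids, x$site_ids)
  if (null == "frequency") {
    rng_state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(rng_state))
      assign(".Random.seed", rng_state, envir = globalenv()), add = TRUE)
    set.seed(seed)
    w <- colSums(occ) + 1  # +1 keeps never-observed species drawable
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- sum(occ[i, ]); b <- sum(occ[j, ])
      s <- sum(occ[i, ] * occ[j, ])
      p <- if (null == "equiprobable") {
        hypergeom_tail(S, a, b, s)
      } else {
        mean(replicate(draws, {
          A <- sample.int(S, a, prob = w)
          B <- sample.int(S, b, prob = w)
          length(intersect(A, B)) >= s
        }))
      }
      sim[i, j] <- sim[j, i] <- 1 - p
    }
  }
  structure(sim, class = c("raup_crick", "matrix"),
            convention = "similarity", null = null)
}

# P(X >= s) for X = |A intersect B|, A of size a and B of size b drawn
# without replacement from a pool of S species; log-space sum for stability.
hypergeom_tail <- function(S, a, b, s) {
  if (s <= max(0, a + b - S)) return(1)
  upper <- min(a, b)
  if (s > upper) return(0)
  i <- seq(s, upper)
  sum(exp(lchoose(b, i) + lchoose(S - b, a - i) - lchoose(S, a)))
}

#' @export
print.raup_crick <- function(x, ...) {
  cat(sprintf("Raup-Crick %s matrix (%s null), %d sites\n",
              attr(x, "convention"), attr(x, "null"), nrow(x)))
  print(unclass(x)[,], ...)
  invisible(x)
}

#' Agglomerative clustering of a Raup-Crick matrix
#'
#' Converts the similarity to dissimilarity `1 - similarity` and applies
#' standard hierarchical agglomerative clustering (UPGMA/average linkage by
#' default). The merge order and tie handling are those of [stats::hclust()],
#' which are deterministic for a given input.
#'
#' @param similarity a [raup_crick()] matrix.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return an object of class `rc_dendrogram` wrapping the `hclust` tree.
#' @export
agglomerate <- function(similarity, linkage = "average") {
  stopifnot(inherits(similarity, "raup_crick"))
  if (nrow(similarity) < 2) stop("need at least 2 sites to cluster")
  d <- as.dist(1 - unclass(similarity))
  h <- hclust(d, method = linkage)
  structure(list(hclust = h, linkage = linkage,
                 dissimilarity = "1 - Raup-Crick similarity"),
            class = "rc_dendrogram")
}

#' @export
print.rc_dendrogram <- function(x, ...) {
  cat(sprintf("agglomerative dendrogram (%s linkage) on %s\n",
              x$linkage, x$dissimilarity))
  print(x$hclust)
  invisible(x)
}

#' Cut an agglomerative dendrogram into k clusters
#'
#' @param dendrogram an [agglomerate()] result.
#' @param k number of clusters.
#' @return named integer vector of cluster labels.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "rc_dendrogram"))
  cutree(dendrogram$hclust, k = k)
}

#' Write a dendrogram as newick
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param dendrogram an [agglomerate()] result.
#' @param path output file.
#' @export
write_newick <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "rc_dendrogram"))
  phy <- ape::as.phylo(dendrogram$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
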