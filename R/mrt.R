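#' Hellinger transformation
#'
#' Per-row transform `y' = sqrt(y / row total)`, which makes Euclidean
#' distances between rows appropriate for composition data (including
#' presence/absence). All-zero rows are passed through unchanged with a
#' warning.
#'
#' @param x a [community_matrix()] or nonnegative numeric matrix.
#' @return numeric matrix of the same shape and dimnames, rows scaled so the
#'   squared entries of each nonempty row sum to 1.
#' @export
hellinger <- function(x) {
  m <- if (inherits(x, "community_matrix")) x$occurrences else as.matrix(x)
  if (any(m < 0)) stop("negative entries are not allowed")
  tot <- rowSums(m)
  if (any(tot == 0))
    warning("all-zero row(s) left as zeros: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
  scale <- ifelse(tot > 0, tot, 1)
  out <- sqrt(sweep(m, 1, scale, "/"))
  dimnames(out) <- dimnames(m)
  out
}

#' Grow a geographically constrained multivariate regression tree
#'
#' Recursive binary partitioning of the (transformed) species composition on
#' the constraint variables. At each node the split — a threshold at the
#' midpoint between adjacent distinct sorted values of one constraint column —
#' maximizing the drop in within-node sum of squares is chosen. Ties go to the
#' earlier constraint column, then to the smaller threshold. Growth is
#' best-first (largest gain next) and stops when no admissible split improves
#' the fit, when nodes fall below `min_node_size`, or at `max_leaves`.
#'
#' @param response numeric matrix, typically [hellinger()] output; rows are
#'   sites.
#' @param constraints numeric matrix of explanatory variables, row-aligned
#'   with `response` (see [build_constraints()]).
#' @param min_node_size smallest node that may still be split (default 2).
#' @param max_leaves maximum number of leaves (default: number of sites).
#' @return an object of class `mrt`: a flat node table (`left`, `right`,
#'   `split_var`, `threshold`, `n`, `ss`), per-node `centroids` and `members`,
#'   `leaf_of_site`, the variable names, and `root_ss`.
#' @export
grow_mrt <- function(response, constraints, min_node_size = 2,
                     max_leaves = nrow(response)) {
  response <- as.matrix(response)
  constraints <- as.matrix(constraints)
  if (nrow(response) != nrow(constraints))
    stop("response and constraints are misaligned: ",
         nrow(response), " vs ", nrow(constraints), " rows")
  if (!is.null(rownames(response)) && !is.null(rownames(constraints)) &&
      !identical(rownames(response), rownames(constraints)))
    stop("response and constraint row names disagree")
  if (min_node_size < 1) stop("min_node_size must be >= 1")
  if (nrow(response) < 1) stop("empty response")
  fit <- grow_tree_cpp(response, constraints, as.integer(max(min_node_size, 2)),
                       as.integer(max_leaves))
  n_leaves <- sum(fit$split_var == 0)
  if (n_leaves == 1 && nrow(unique(response)) > 1) {
    all_const <- all(apply(constraints, 2, function(v) length(unique(v)) <= 1))
    if (all_const)
      warning("constraints are constant; returning a single-leaf tree")
  }
  structure(
    c(fit,
      list(site_ids = rownames(response) %||% as.character(seq_len(nrow(response))),
           var_names = colnames(constraints) %||%
             paste0("x", seq_len(ncol(constraints))),
           root_ss = fit$ss[1])),
    class = "mrt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_leaves <- function(tree) sum(tree$split_var == 0)

#' @export
print.mrt <- function(x, ...) {
  cat(sprintf("constrained multivariate regression tree: %d sites, %d leaves, root SS %.4g\n",
              length(x$leaf_of_site), n_leaves(x), x$root_ss))
  cat(format_mrt(x), sep = "\n")
  invisible(x)
}

# indented text rendering of the tree
format_mrt <- function(tree) {
  out <- character(0)
  rec <- function(node, depth, label) {
    ind <- strrep("  ", depth)
    if (tree$split_var[node] == 0) {
      out[[length(out) + 1]] <<- sprintf(
        "%s%s leaf: n=%d ss=%.5g [%s]", ind, label, tree$n[node],
        tree$ss[node],
        paste(tree$site_ids[tree$members[[node]]], collapse = ", "))
    } else {
      v <- tree$var_names[tree$split_var[node]]
      out[[length(out) + 1]] <<- sprintf(
        "%s%s node: n=%d ss=%.5g split %s < %.6g", ind, label,
        tree$n[node], tree$ss[node], v, tree$threshold[node])
      rec(tree$left[node], depth + 1, "L")
      rec(tree$right[node], depth + 1, "R")
    }
  }
  rec(1, 0, "root")
  out
}

#' Cost-complexity pruning sequence
#'
#' Weakest-link pruning of a grown tree: repeatedly collapse the internal
#' branch with the smallest per-leaf gain `alpha`, producing a nested sequence
#' of subtrees from the full tree down to the root. The resubstitution
#' relative error of each subtree is its total leaf within-SS divided by the
#' root within-SS.
#'
#' @param tree an [grow_mrt()] result.
#' @return an object of class `mrt_pruning`: data frame `sequence` with
#'   columns `alpha` (strictly increasing), `size` (leaf count, strictly
#'   decreasing) and `rel_error`, plus per-node `prune_alpha` used to extract
#'   any subtree of the sequence.
#' @export
prune_mrt <- function(tree) {
  stopifnot(inherits(tree, "mrt"))
  pr <- prune_tree_cpp(tree$left, tree$right, tree$ss)
  structure(list(
    sequence = data.frame(alpha = pr$alpha, size = pr$size,
                          rel_error = pr$rel_error),
    prune_alpha = pr$prune_alpha), class = "mrt_pruning")
}

#' @export
print.mrt_pruning <- function(x, ...) {
  cat("pruning sequence:\n")
  print(x$sequence, row.names = FALSE)
  invisible(x)
}

# Is node `t` a leaf of the subtree obtained at complexity `alpha`?
# Internal nodes with prune_alpha <= alpha have been collapsed.
node_is_leaf_at <- function(tree, pruning, t, alpha) {
  tree$split_var[t] == 0 || pruning$prune_alpha[t] <= alpha
}

# Path of node ids from the root to the full-tree leaf reached by one
# constraint row.
drop_path <- function(tree, x) {
  path <- integer(0)
  t <- 1L
  repeat {
    path <- c(path, t)
    if (tree$split_var[t] == 0) return(path)
    v <- tree$split_var[t]
    t <- if (x[v] < tree$threshold[t]) tree$left[t] else tree$right[t]
  }
}

# leaf labels (1..size) for every site under the subtree at complexity alpha
leaves_at_alpha <- function(tree, pruning, alpha) {
  # depth-first left-to-right over the pruned subtree
  leaves <- integer(0)
  rec <- function(t) {
    if (node_is_leaf_at(tree, pruning, t, alpha)) {
      leaves <<- c(leaves, t)
    } else {
      rec(tree$left[t]); rec(tree$right[t])
    }
  }
  rec(1L)
  leaves
}

#' v-fold cross-validation of the pruned tree sequence
#'
#' Sites are shuffled into `v` near-equal folds; for each fold a tree is grown
#' and pruned on the training sites, each held-out site is dropped down the
#' fold tree by its constraint values, and its squared deviation from the
#' reached leaf centroid is pooled. Fold subtrees are matched to the full-data
#' pruning sequence through the geometric means of consecutive alpha values.
#' The cross-validated relative error (xerror) divides the pooled held-out
#' error by the full-data root sum of squares; its standard error is computed
#' across per-site contributions.
#'
#' @param response,constraints as in [grow_mrt()].
#' @param v number of folds (between 2 and the number of sites).
#' @param seed integer seed for the fold shuffle.
#' @param min_node_size,max_leaves passed to [grow_mrt()].
#' @param full optional precomputed `list(tree, pruning)` for the full data
#'   (reused by [multi_cv()]).
#' @return an object of class `mrt_cv`: data frame `cv` with columns `size`,
#'   `alpha`, `rel_error`, `xerror`, `se`, plus the full-data tree and pruning.
#' @export
cross_validate <- function(response, constraints, v = 10, seed = 1,
                           min_node_size = 2, max_leaves = nrow(response),
                           full = NULL) {
  response <- as.matrix(response)
  constraints <- as.matrix(constraints)
  n <- nrow(response)
  if (v < 2 || v > n) stop("v must be between 2 and the number of sites (", n, ")")
  if (is.null(full)) {
    tree <- grow_mrt(response, constraints, min_node_size, max_leaves)
    pruning <- prune_mrt(tree)
  } else {
    tree <- full$tree; pruning <- full$pruning
  }
  if (tree$root_ss <= 0)
    stop("root within-SS is zero (constant response); cross-validation undefined")
  seq_df <- pruning$sequence
  m <- nrow(seq_df)
  # representative complexity per subtree: geometric mean of consecutive alphas
  a <- seq_df$alpha
  beta <- c(if (m > 1) sqrt(a[-m] * a[-1]) else numeric(0), Inf)

  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()), add = TRUE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(v), n))

  err <- matrix(NA_real_, n, m)   # per-site held-out squared error, per size
  for (f in seq_len(v)) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(train) == 0) stop("fold with zero training sites")
    ftree <- grow_mrt(response[train, , drop = FALSE],
                      constraints[train, , drop = FALSE],
                      min_node_size, min(max_leaves, length(train)))
    fprune <- prune_mrt(ftree)
    for (i in test) {
      path <- drop_path(ftree, constraints[i, ])
      # squared error to each node centroid along the path
      perr <- vapply(path, function(t)
        sum((response[i, ] - ftree$centroids[t, ])^2), numeric(1))
      palpha <- fprune$prune_alpha[path]
      is_term <- ftree$split_var[path] == 0
      for (k in seq_len(m)) {
        hit <- which(is_term | palpha <= beta[k])[1]
        err[i, k] <- perr[hit]
      }
    }
  }
  xerror <- colSums(err) / tree$root_ss
  se <- apply(err, 2, stats::sd) * sqrt(n) / tree$root_ss
  structure(list(
    cv = data.frame(size = seq_df$size, alpha = seq_df$alpha,
                    rel_error = seq_df$rel_error, xerror = xerror, se = se),
    tree = tree, pruning = pruning, v = v, seed = seed), class = "mrt_cv")
}

#' @export
print.mrt_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d):\n", x$v, x$seed))
  print(x$cv, row.names = FALSE)
  invisible(x)
}

#' Multiple cross-validation of tree size
#'
#' Repeats [cross_validate()] with re-randomized folds and tabulates, per
#' replicate, the smallest tree size attaining the minimum cross-validated
#' relative error. The frequency table over replicates is the evidence used to
#' pick the number of provinces.
#'
#' @inheritParams cross_validate
#' @param replicates number of cross-validation replicates (the analysis that
#'   motivated this package used 1000).
#' @param seed integer master seed; replicate `r` runs with a seed derived
#'   deterministically from `(seed, r)`.
#' @return an object of class `mrt_multicv`: data frame `summary` with per-size
#'   mean `xerror` and mean `se`, `size_freq` (frequency table of per-replicate
#'   optimal sizes), `optimal_sizes`, the full-data `tree` and `pruning`,
#'   `replicates`, and the seeds used.
#' @export
multi_cv <- function(response, constraints, replicates = 1000, v = 10,
                     seed = 1, min_node_size = 2,
                     max_leaves = nrow(response)) {
  if (replicates < 1) stop("replicates must be >= 1")
  response <- as.matrix(response)
  constraints <- as.matrix(constraints)
  tree <- grow_mrt(response, constraints, min_node_size, max_leaves)
  pruning <- prune_mrt(tree)
  full <- list(tree = tree, pruning = pruning)
  sizes <- pruning$sequence$size
  m <- length(sizes)
  xerr <- matrix(NA_real_, replicates, m)
  ses <- matrix(NA_real_, replicates, m)
  optimal <- integer(replicates)
  seeds <- vapply(seq_len(replicates), function(r) derive_seed(seed, r),
                  integer(1))
  for (r in seq_len(replicates)) {
    cv <- cross_validate(response, constraints, v = v, seed = seeds[r],
                         min_node_size = min_node_size,
                         max_leaves = max_leaves, full = full)
    xerr[r, ] <- cv$cv$xerror
    ses[r, ] <- cv$cv$se
    best <- min(cv$cv$xerror)
    optimal[r] <- min(sizes[cv$cv$xerror == best])  # smallest minimizer
  }
  freq <- table(factor(optimal, levels = sort(unique(sizes))))
  structure(list(
    summary = data.frame(size = sizes, alpha = pruning$sequence$alpha,
                         rel_error = pruning$sequence$rel_error,
                         xerror = colMeans(xerr), se = colMeans(ses)),
    size_freq = freq, optimal_sizes = optimal,
    tree = tree, pruning = pruning,
    replicates = replicates, v = v, seed = seed, replicate_seeds = seeds),
    class = "mrt_multicv")
}

#' @export
print.mrt_multicv <- function(x, ...) {
  cat(sprintf("multiple cross-validation: %d replicates, %d folds\n",
              x$replicates, x$v))
  cat("optimal-size frequencies:\n")
  print(x$size_freq)
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select a tree size from a multiple-cross-validation summary
#'
#' `most_frequent_min` takes the modal per-replicate optimal size (ties to the
#' smaller size); `one_se` takes the smallest size whose mean xerror lies
#' within one standard error of the minimum mean xerror.
#'
#' @param summary an [multi_cv()] result.
#' @param rule `"most_frequent_min"` or `"one_se"`.
#' @return selected leaf count (integer).
#' @export
select_size <- function(summary, rule = c("most_frequent_min", "one_se")) {
  stopifnot(inherits(summary, "mrt_multicv"))
  rule <- match.arg(rule)
  if (rule == "most_frequent_min") {
    freq <- summary$size_freq[summary$size_freq > 0]
    sizes <- as.integer(names(freq))
    return(min(sizes[freq == max(freq)]))
  }
  s <- summary$summary
  imin <- which.min(s$xerror)
  cutoff <- s$xerror[imin] + s$se[imin]
  as.integer(min(s$size[s$xerror <= cutoff]))
}

#' Assign sites to provinces at a chosen tree size
#'
#' Labels every site by the leaf it belongs to in the pruning-sequence subtree
#' with the requested leaf count. Labels are leaf indices in left-to-right
#' tree order.
#'
#' @param tree an [grow_mrt()] result.
#' @param pruning the matching [prune_mrt()] result.
#' @param size leaf count; must be one of the sizes in the pruning sequence.
#' @return named integer vector, site id -> province label in `1:size`.
#' @export
assign_provinces <- function(tree, pruning, size) {
  stopifnot(inherits(tree, "mrt"), inherits(pruning, "mrt_pruning"))
  seq_df <- pruning$sequence
  k <- match(size, seq_df$size)
  if (is.na(k)) {
    avail <- seq_df$size
    nearest <- avail[order(abs(avail - size))][1:min(2, length(avail))]
    stop("size ", size, " not in the pruning sequence; nearest achievable: ",
         paste(sort(nearest), collapse = ", "))
  }
  alpha <- seq_df$alpha[k]
  leaves <- leaves_at_alpha(tree, pruning, alpha)
  lab <- integer(length(tree$leaf_of_site))
  for (j in seq_along(leaves)) lab[tree$members[[leaves[j]]]] <- j
  names(lab) <- tree$site_ids
  lab
}

#' Longitude-encoding sensitivity scan
#'
#' Runs the full multiple-cross-validation analysis once per longitude
#' encoding scheme and reports, per scheme, the optimal-size frequencies, the
#' sizes selected under both rules, and the province assignment at the
#' modal size. Used to demonstrate how the placement of the longitude cut
#' line changes the inferred provinces.
#'
#' @param matrix a [community_matrix()].
#' @param sites site-record data frame matching the matrix sites.
#' @param schemes character vector of scheme names (see [encoding_schemes()]).
#' @param replicates,v,seed,min_node_size passed to [multi_cv()].
#' @return named list (one element per scheme) with components `multicv`,
#'   `size_most_frequent`, `size_one_se`, `provinces`.
#' @export
encoding_sensitivity_scan <- function(matrix, sites,
                                      schemes = encoding_schemes(),
                                      replicates = 100, v = 10, seed = 1,
                                      min_node_size = 2) {
  stopifnot(length(schemes) >= 1)
  resp <- hellinger(matrix)
  out <- lapply(schemes, function(sc) {
    cons <- build_constraints(sites, sc, site_order = matrix$site_ids)
    mcv <- multi_cv(resp, cons, replicates = replicates, v = v, seed = seed,
                    min_node_size = min_node_size)
    smf <- select_size(mcv, "most_frequent_min")
    sse <- select_size(mcv, "one_se")
    list(multicv = mcv,
         size_most_frequent = smf,
         size_one_se = sse,
         provinces = assign_provinces(mcv$tree, mcv$pruning, smf))
  })
  names(out) <- schemes
  out
}
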