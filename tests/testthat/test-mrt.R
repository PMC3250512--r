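test_that("hellinger transform follows sqrt(y / row total)", {
  bin <- cm(matrix(c(rep(1, 4), rep(0, 6)), 1, 10))
  h <- hellinger(bin)
  expect_equal(unname(h[1, 1:4]), rep(0.5, 4))
  expect_equal(unname(h[1, 5:10]), rep(0, 6))

  ab <- cm(matrix(c(1, 3, 0), 1, 3), binary = FALSE)
  expect_equal(unname(hellinger(ab)[1, ]), c(0.5, sqrt(3) / 2, 0))

  # rows with positive totals have unit squared sums; matches vegan
  set.seed(5)
  m <- matrix(rpois(60, 2), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("p", 1:10)))
  h2 <- hellinger(m)
  expect_equal(unname(rowSums(h2^2)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unclass(h2), unclass(vegan::decostand(m, "hellinger")),
               ignore_attr = TRUE)

  z <- rbind(a = c(1, 1), b = c(0, 0))
  expect_warning(hz <- hellinger(z), "b")
  expect_equal(unname(hz["b", ]), c(0, 0))
  expect_error(hellinger(matrix(-1, 1, 1, dimnames = list("a", "x"))),
               "negative")
})

test_that("grow_mrt finds the optimal split and handles degenerate input", {
  # constant response: single leaf, zero SS
  y <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), paste0("p", 1:3)))
  x <- cbind(v = c(0, 1, 10, 11))
  t0 <- grow_mrt(y, x)
  expect_equal(sum(t0$split_var == 0), 1L)
  expect_equal(t0$root_ss, 0)

  # two identical response pairs at constraint values (0,1) and (10,11):
  # the only zero-error split of the three candidates is at 5.5
  y2 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  colnames(y2) <- c("p1", "p2")
  t2 <- grow_mrt(y2, x)
  expect_equal(t2$threshold[1], 5.5)
  expect_equal(t2$ss[t2$left[1]], 0)
  expect_equal(t2$ss[t2$right[1]], 0)
  expect_equal(sum(t2$split_var == 0), 2L)

  # first split equals the brute-force optimum on random 6-site data
  set.seed(101)
  for (rep in 1:10) {
    inst <- random_instance(6, 4, 2)
    tr <- grow_mrt(inst$y, inst$x)
    if (sum(tr$split_var == 0) == 1) next
    expect_equal(node_gain(tr, 1),
                 brute_force_best_gain(inst$y, inst$x),
                 tolerance = 1e-9)
  }

  # constant constraints with varying response: single leaf with warning
  expect_warning(
    t3 <- grow_mrt(y2, cbind(v = rep(1, 4))), "constant")
  expect_equal(sum(t3$split_var == 0), 1L)

  # misaligned rows are an error
  expect_error(grow_mrt(y2, cbind(v = 1:3)), "misaligned")
})

test_that("pruning sequence is nested, monotone, and variance-consistent", {
  # single-leaf tree
  y <- matrix(1, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  t1 <- grow_mrt(y, cbind(v = 1:3))
  p1 <- prune_mrt(t1)
  expect_equal(nrow(p1$sequence), 1L)
  expect_equal(p1$sequence$rel_error, 1)

  # 4-site perfect split: 2-leaf subtree with zero error, then the root
  y2 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  colnames(y2) <- c("p1", "p2")
  t2 <- grow_mrt(y2, cbind(v = c(0, 1, 10, 11)))
  p2 <- prune_mrt(t2)
  expect_equal(p2$sequence$size, c(2L, 1L))
  expect_equal(p2$sequence$rel_error, c(0, 1))
  expect_equal(p2$sequence$alpha[1], 0)

  # structural properties on random grown trees
  set.seed(77)
  for (rep in 1:10) {
    inst <- random_instance(12, 6, 2)
    tr <- grow_mrt(inst$y, inst$x)
    pr <- prune_mrt(tr)
    sq <- pr$sequence
    expect_true(all(diff(sq$size) < 0))
    expect_true(all(diff(sq$alpha) > 0))
    expect_true(all(diff(sq$rel_error) >= -1e-12))
    expect_equal(sq$rel_error[nrow(sq)], 1)
    # parent SS >= sum of child SS at every internal node
    internal <- which(tr$split_var > 0)
    for (nd in internal)
      expect_gte(tr$ss[nd] - tr$ss[tr$left[nd]] - tr$ss[tr$right[nd]], -1e-9)
    # variance decomposition at the full tree: root SS = between + within
    leaves <- which(tr$split_var == 0)
    within <- sum(tr$ss[leaves])
    between <- sum(vapply(leaves, function(l) {
      ctr <- tr$centroids[l, ]; tr$n[l] * sum((ctr - tr$centroids[1, ])^2)
    }, numeric(1)))
    expect_equal(within + between, tr$root_ss,
                 tolerance = 1e-9 * max(tr$root_ss, 1))
  }
})

test_that("cross_validate guards degenerate input and is seed-deterministic", {
  y <- matrix(1, 6, 2, dimnames = list(paste0("s", 1:6), c("a", "b")))
  x <- cbind(v = 1:6)
  expect_error(cross_validate(y, x, v = 3, seed = 1), "zero")
  inst <- local({set.seed(9); random_instance(12, 6, 2)})
  expect_error(cross_validate(inst$y, inst$x, v = 13), "between 2")

  cv1 <- cross_validate(inst$y, inst$x, v = 4, seed = 5)
  cv2 <- cross_validate(inst$y, inst$x, v = 4, seed = 5)
  expect_identical(cv1$cv, cv2$cv)
  expect_true(all(cv1$cv$xerror >= 0))
  expect_true(all(cv1$cv$se >= 0))
})

test_that("cross-validation error is minimized at the true cluster count", {
  meta <- generate_metacommunity(K = 3, seed = 21)
  resp <- hellinger(meta$matrix)
  cons <- build_constraints(meta$sites, site_order = meta$matrix$site_ids)
  cv <- cross_validate(resp, cons, v = 10, seed = 4)
  best <- cv$cv$size[which.min(cv$cv$xerror)]
  expect_equal(best, 3L)
})

test_that("multi_cv tabulates optimal sizes deterministically", {
  meta <- generate_metacommunity(K = 3, sites_per_province = 6,
                                 endemics_per_province = 8, seed = 2)
  resp <- hellinger(meta$matrix)
  cons <- build_constraints(meta$sites, site_order = meta$matrix$site_ids)

  one <- multi_cv(resp, cons, replicates = 1, v = 6, seed = 3)
  expect_equal(sum(one$size_freq), 1)
  expect_equal(length(one$optimal_sizes), 1L)

  m1 <- multi_cv(resp, cons, replicates = 25, v = 6, seed = 3)
  m2 <- multi_cv(resp, cons, replicates = 25, v = 6, seed = 3)
  expect_identical(m1$summary, m2$summary)
  expect_identical(m1$size_freq, m2$size_freq)
  expect_equal(sum(m1$size_freq), 25)
  expect_equal(select_size(m1, "most_frequent_min"), 3L)
})

test_that("select_size implements both rules", {
  meta <- generate_metacommunity(K = 3, sites_per_province = 6,
                                 endemics_per_province = 8, seed = 2)
  resp <- hellinger(meta$matrix)
  cons <- build_constraints(meta$sites, site_order = meta$matrix$site_ids)
  m <- multi_cv(resp, cons, replicates = 10, v = 6, seed = 3)

  # modal rule with a manual frequency table, ties to the smaller size
  m$size_freq <- table(factor(c(rep(3, 60), rep(5, 40)), levels = c(3, 5)))
  expect_equal(select_size(m, "most_frequent_min"), 3L)
  m$size_freq <- table(factor(c(rep(3, 50), rep(5, 50)), levels = c(3, 5)))
  expect_equal(select_size(m, "most_frequent_min"), 3L)

  # flat xerror curve within one SE: 1-SE picks the smallest size
  m$summary$xerror <- rep(0.5, nrow(m$summary))
  m$summary$se <- rep(0.05, nrow(m$summary))
  expect_equal(select_size(m, "one_se"), min(m$summary$size))

  # strong 5-province signal: both rules agree on 5
  meta5 <- generate_metacommunity(K = 5, seed = 8)
  resp5 <- hellinger(meta5$matrix)
  cons5 <- build_constraints(meta5$sites, site_order = meta5$matrix$site_ids)
  m5 <- multi_cv(resp5, cons5, replicates = 20, v = 10, seed = 6)
  expect_equal(select_size(m5, "most_frequent_min"), 5L)
  expect_equal(select_size(m5, "one_se"), 5L)
})

test_that("assign_provinces labels sites by pruned-subtree leaf", {
  y2 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  colnames(y2) <- c("p1", "p2")
  tr <- grow_mrt(y2, cbind(v = c(0, 1, 10, 11)))
  pr <- prune_mrt(tr)

  lab1 <- assign_provinces(tr, pr, 1)
  expect_equal(unname(lab1), rep(1L, 4))

  lab2 <- assign_provinces(tr, pr, 2)
  expect_equal(lab2[["a"]], lab2[["b"]])
  expect_equal(lab2[["c"]], lab2[["d"]])
  expect_true(lab2[["a"]] != lab2[["c"]])

  expect_error(assign_provinces(tr, pr, 3), "nearest achievable")

  meta <- generate_metacommunity(K = 3, seed = 13)
  resp <- hellinger(meta$matrix)
  cons <- build_constraints(meta$sites, site_order = meta$matrix$site_ids)
  tr3 <- grow_mrt(resp, cons)
  pr3 <- prune_mrt(tr3)
  expect_equal(
    adjusted_rand_index(assign_provinces(tr3, pr3, 3), meta$true_labels), 1)
})

test_that("encoding scan reduces to multi_cv for one scheme and reacts to the cut line", {
  meta <- generate_metacommunity(K = 3, sites_per_province = 6,
                                 endemics_per_province = 8, seed = 4)
  scan <- encoding_sensitivity_scan(meta$matrix, meta$sites,
                                    schemes = "greenwich_pm180",
                                    replicates = 10, v = 6, seed = 5)
  direct <- multi_cv(hellinger(meta$matrix),
                     build_constraints(meta$sites, "greenwich_pm180",
                                       meta$matrix$site_ids),
                     replicates = 10, v = 6, seed = 5)
  expect_identical(scan$greenwich_pm180$multicv$summary, direct$summary)
  expect_identical(scan$greenwich_pm180$multicv$size_freq, direct$size_freq)

  # all sites in one hemisphere, far from every cut: schemes agree
  meta_e <- generate_metacommunity(K = 3, sites_per_province = 6,
                                   endemics_per_province = 8,
                                   centroid_longitudes = c(40, 80, 120),
                                   seed = 6)
  scan_e <- encoding_sensitivity_scan(meta_e$matrix, meta_e$sites,
                                      replicates = 10, v = 6, seed = 7)
  provs <- lapply(scan_e, `[[`, "provinces")
  expect_identical(provs[[1]], provs[[2]])
  expect_identical(provs[[1]], provs[[3]])
})
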