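test_that("generate_metacommunity obeys its stated dimensions and determinism", {
  meta <- generate_metacommunity(K = 3, sites_per_province = 4,
                                 endemics_per_province = 6,
                                 cosmopolitan_species = 2, seed = 1)
  expect_equal(dim(meta$matrix), c(12L, 20L))
  expect_true(meta$matrix$binary)
  expect_equal(as.integer(table(meta$true_labels)), rep(4L, 3))
  expect_equal(meta$sites$site_id, meta$matrix$site_ids)

  # identical parameters + seed: bit-identical output
  meta2 <- generate_metacommunity(K = 3, sites_per_province = 4,
                                  endemics_per_province = 6,
                                  cosmopolitan_species = 2, seed = 1)
  expect_identical(meta$matrix$occurrences, meta2$matrix$occurrences)
  expect_identical(meta$sites, meta2$sites)

  # different seed: different draw
  meta3 <- generate_metacommunity(K = 3, sites_per_province = 4,
                                  endemics_per_province = 6,
                                  cosmopolitan_species = 2, seed = 2)
  expect_false(identical(meta$matrix$occurrences, meta3$matrix$occurrences))

  expect_error(generate_metacommunity(endemicity = 1.2), "endemicity")
  expect_error(generate_metacommunity(detection_prob = 0), "detection_prob")
  expect_error(generate_metacommunity(K = 1, sites_per_province = 1),
               "at least 2")
})

test_that("perfect endemicity yields disjoint province pools", {
  meta <- generate_metacommunity(K = 3, sites_per_province = 3,
                                 endemics_per_province = 8,
                                 cosmopolitan_species = 0,
                                 endemicity = 1, detection_prob = 1, seed = 5)
  occ <- meta$matrix$occurrences
  # block-diagonal: every site carries exactly its own province's endemics
  expect_equal(unname(rowSums(occ)), rep(8, 9))
  rc <- raup_crick(meta$matrix)
  between <- outer(meta$true_labels, meta$true_labels, "!=")
  expect_true(all(rc[between] == 0))
})

test_that("empirical presence rates match the generative model", {
  # average occupancy over replicates vs stated Bernoulli probabilities
  K <- 2; spp <- 3; end <- 4; cosmo <- 2
  endem <- 0.8; det <- 0.9
  reps <- 200
  own <- other <- cos_rate <- 0
  for (r in seq_len(reps)) {
    meta <- generate_metacommunity(K = K, sites_per_province = spp,
                                   endemics_per_province = end,
                                   cosmopolitan_species = cosmo,
                                   endemicity = endem, detection_prob = det,
                                   seed = 1000 + r)
    occ <- meta$matrix$occurrences
    own_cells <- other_cells <- matrix(FALSE, nrow(occ), ncol(occ))
    for (k in seq_len(K)) {
      cols <- (k - 1) * end + seq_len(end)
      own_cells[meta$true_labels == k, cols] <- TRUE
      other_cells[meta$true_labels != k, cols] <- TRUE
    }
    own <- own + mean(occ[own_cells])
    other <- other + mean(occ[other_cells])
    cos_rate <- cos_rate + mean(occ[, end * K + seq_len(cosmo)])
  }
  n_own <- reps * spp * end * K          # binomial cell counts per estimate
  tol <- function(p, n) 4 * sqrt(p * (1 - p) / n)
  expect_equal(own / reps, endem * det,
               tolerance = tol(endem * det, n_own) / (endem * det))
  expect_equal(other / reps, (1 - endem) * det,
               tolerance = tol((1 - endem) * det, n_own) /
                 ((1 - endem) * det))
  expect_equal(cos_rate / reps, det,
               tolerance = tol(det, reps * spp * K * cosmo) / det)
})

test_that("within-province similarity exceeds between when endemicity > 0.5", {
  for (s in 1:3) {
    meta <- generate_metacommunity(K = 3, sites_per_province = 4,
                                   endemics_per_province = 10,
                                   endemicity = 0.7, seed = 100 + s)
    rc <- raup_crick(meta$matrix)
    same <- outer(meta$true_labels, meta$true_labels, "==")
    diag(same) <- NA
    within <- mean(rc[same & !is.na(same)])
    between <- mean(rc[!same & !is.na(same)])
    expect_gt(within, between)
  }
})

test_that("generate_pair_alignment hits its target distance", {
  # target 0: identical sequences
  p0 <- generate_pair_alignment(200, 0, seed = 4)
  expect_identical(p0["anc", ], p0["der", ])

  # fixed seed reproducibility
  p1 <- generate_pair_alignment(500, 0.05, seed = 9)
  p2 <- generate_pair_alignment(500, 0.05, seed = 9)
  expect_identical(unclass(p1), unclass(p2))

  # estimator recovery within 3 SE at moderate length
  pair <- generate_pair_alignment(5000, 0.0645, seed = 12)
  est <- tamura_nei(pair)
  se <- est$value / sqrt(5000 * est$value)  # rough Poisson-scale SE
  expect_lt(abs(est$value - 0.0645), 3 * max(se, 0.004))

  expect_error(generate_pair_alignment(50, 0.1), "length")
  expect_error(generate_pair_alignment(200, -0.1), "target_distance")
  expect_error(generate_pair_alignment(200, 0.1, freq = c(A = 1, C = 0, G = 0, T = 0)),
               "frequencies")
})
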