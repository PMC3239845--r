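test_that("binary density counts edges over possible pairs", {
  clique3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(binary_density(clique3, 1:3), 1)
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  expect_equal(binary_density(W, 1:4), 2 / 6)
  # exhaustive pair enumeration oracle on random 8-node blocks
  for (seed in 1:5) {
    set.seed(seed)
    up <- matrix(0, 8, 8)
    up[upper.tri(up)] <- rbinom(28, 1, 0.4)
    W <- up + t(up)
    expect_equal(binary_density(W, 1:8), brute_density(W, 1:8))
  }
  expect_error(binary_density(matrix(0.5, 3, 3), 1:3), "binary")
  expect_error(binary_density(clique3, 1), "at least 2")
})

test_that("weighted density is the mean off-diagonal block weight", {
  W <- matrix(0.8, 4, 4)
  expect_equal(weighted_density(W, 1:4), 0.8)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.2
  W[1, 3] <- W[3, 1] <- 0.4
  W[2, 3] <- W[3, 2] <- 0.6
  expect_equal(weighted_density(W, 1:3), 0.4)
  # coincides with the binary count on 0/1 matrices
  for (seed in 1:5) {
    set.seed(seed)
    up <- matrix(0, 6, 6)
    up[upper.tri(up)] <- rbinom(15, 1, 0.5)
    W <- up + t(up)
    expect_equal(weighted_density(W, 1:6), binary_density(W, 1:6))
  }
})

test_that("cluster quality combines densities as ratio or difference", {
  pair <- network_pair(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 1, 1, 0), 2))
  cl <- cluster_candidate(1:2, "A")
  expect_equal(cluster_quality(pair, cl, combiner = "ratio")$c_value, 1)
  expect_equal(cluster_quality(pair, cl, combiner = "difference")$c_value, 0)

  # ratio on binary blocks equals the raw edge-count ratio (|s| cancels)
  pair <- make_binary_fixture(seed = 2)
  cl <- cluster_candidate(6:15, "A")
  q <- cluster_quality(pair, cl, combiner = "ratio")
  ec <- function(W, s) sum(W[s, s][upper.tri(W[s, s])])
  expect_equal(q$c_value, ec(pair$A, 6:15) / ec(pair$B, 6:15))

  # zero denominator yields the +Inf sentinel
  z <- matrix(0, 4, 4)
  o <- matrix(0, 4, 4); o[1, 2] <- o[2, 1] <- 1
  expect_equal(cluster_quality(network_pair(o, z), cluster_candidate(1:2, "A"),
                               combiner = "ratio")$c_value, Inf)
})

test_that("densifying the target block never decreases quality", {
  set.seed(11)
  for (rep in 1:10) {
    pair <- generate_binary_pair(seed = 500 + rep)
    cl <- cluster_candidate(6:15, "A")
    for (comb in c("ratio", "difference")) {
      q0 <- cluster_quality(pair, cl, combiner = comb)$c_value
      A2 <- pair$A
      off <- which(A2[6:15, 6:15] == 0 & upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
      if (nrow(off) == 0) next
      i <- 5 + off[1, 1]; j <- 5 + off[1, 2]
      A2[i, j] <- A2[j, i] <- 1
      q1 <- cluster_quality(network_pair(A2, pair$B), cl, combiner = comb)$c_value
      expect_gte(q1, q0)
    }
  }
})

test_that("candidate clusters are contiguous runs with the stated sizes", {
  pair <- make_binary_fixture()
  ord <- reordering_vector(suppressWarnings(compute_gsvd(pair)), 1, "last")
  cands <- candidate_clusters(ord, taus = c(10, 5))
  expect_equal(nrow(cands), 4)
  expect_equal(cands$tau, c(10, 10, 5, 5))
  expect_equal(cands$run, c("head", "tail", "head", "tail"))
  expect_equal(cands$candidate[[1]]$nodes, ord$permutation[1:10])
  expect_equal(cands$candidate[[2]]$nodes, ord$permutation[11:20])
  expect_equal(candidate_clusters(ord, taus = 20)$candidate[[1]]$nodes,
               ord$permutation)
  expect_error(candidate_clusters(ord, taus = integer(0)), "non-empty")
  expect_error(candidate_clusters(ord, taus = 25), "tau")

  # head-22 / tail-18 runs of a 98-node ordering are disjoint
  set.seed(1)
  big <- network_pair(random_spd(98), random_spd(98))
  bord <- reordering_vector(compute_gsvd(big), 1, "last")
  c22 <- candidate_clusters(bord, 22, ends = "head")$candidate[[1]]
  c18 <- candidate_clusters(bord, 18, ends = "tail")$candidate[[1]]
  expect_length(intersect(c22$nodes, c18$nodes), 0)
})

test_that("ordering_run extracts arbitrary positions of the sorted ordering", {
  pair <- make_binary_fixture()
  ord <- reordering_vector(suppressWarnings(compute_gsvd(pair)), 1, "last")
  cl <- ordering_run(ord, 12:18)
  expect_equal(cl$nodes, ord$permutation[12:18])
  expect_equal(cl$tau, 7)
  expect_error(ordering_run(ord, 15:25), "out of range")
})

test_that("permutation p-values are exact exceedance proportions, reproducible by seed", {
  pair <- make_binary_fixture(seed = 4)
  ord <- reordering_vector(suppressWarnings(compute_gsvd(pair)), 1, "last")
  cl <- candidate_clusters(ord, 10, ends = "head")$candidate[[1]]
  p1 <- permutation_pvalue(pair, cl, M = 300, seed = 99)
  p2 <- permutation_pvalue(pair, cl, M = 300, seed = 99)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$null_samples, p2$null_samples)
  x <- sum(is.nan(p1$null_samples) | p1$null_samples >= p1$observed$c_value)
  expect_equal(p1$p_value, x / 300)
  expect_equal(p1$p_value_corrected, (x + 1) / 301)
  expect_gte(p1$p_value, 0)
  expect_lte(p1$p_value, 1)
})

test_that("an unbeatable observed quality gives p = 0, reported below resolution", {
  # planted block is complete and the background empty: only the exact planted
  # subset ties the observed quality, and the seeded null draws never hit it
  A <- matrix(0, 40, 40); A[1:4, 1:4] <- 1; diag(A) <- 0
  B <- matrix(0, 40, 40)
  B[39, 40] <- B[40, 39] <- 1
  pair <- network_pair(A, B)
  cl <- cluster_candidate(1:4, "A")
  pt <- permutation_pvalue(pair, cl, M = 1000, seed = 1, combiner = "difference",
                           measure = "weighted")
  expect_equal(pt$p_value, 0)
  expect_equal(glance(pt)$p_label, "< 0.001")
})

test_that("graph-randomization schemes work on binary input and refuse weighted", {
  pair <- make_binary_fixture(seed = 5)
  ord <- reordering_vector(suppressWarnings(compute_gsvd(pair)), 1, "last")
  cl <- candidate_clusters(ord, 10, ends = "head")$candidate[[1]]
  for (scheme in c("erdos_renyi", "redistribution")) {
    pt <- suppressWarnings(permutation_pvalue(pair, cl, M = 20, scheme = scheme, seed = 1))
    expect_gte(pt$p_value, 0)
    expect_lte(pt$p_value, 1)
  }
  wpair <- network_pair(random_spd(6), random_spd(6))
  expect_error(permutation_pvalue(wpair, cluster_candidate(1:3, "A"),
                                  M = 10, scheme = "erdos_renyi"),
               "binary")
  expect_error(permutation_pvalue(pair, cl, M = 0), "M")
})

test_that("planted cluster is significant and a mid-ordering run is not", {
  pair <- make_binary_fixture(seed = 1)
  ord <- reordering_vector(suppressWarnings(compute_gsvd(pair)), 1, "last")
  planted <- candidate_clusters(ord, 10, ends = "head")$candidate[[1]]
  pt <- permutation_pvalue(pair, planted, M = 1000, seed = 1)
  expect_lt(pt$p_value, 0.05)
  ctrl <- ordering_run(ord, 12:18)
  pt2 <- permutation_pvalue(pair, ctrl, M = 1000, seed = 1)
  expect_gt(pt2$p_value, 0.05)
})
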