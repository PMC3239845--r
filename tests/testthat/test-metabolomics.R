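make_table <- function(...) simulate_intensity_table(...)

test_that("differential screen computes fold changes and Welch p-values", {
  # identical groups: ratio 1, p = 1 for zero-variance identical data
  tab <- tibble::tibble(sample_id = paste0("s", 1:6),
                        group = rep(c("c", "t"), each = 3),
                        m1 = rep(5, 6),
                        m2 = c(1, 2, 3, 3, 6, 9))
  res <- differential_metabolites(tab, log_transform = FALSE)
  expect_equal(res$ratio[res$metabolite == "m1"], 1)
  expect_equal(res$p_value[res$metabolite == "m1"], 1)
  # treated mean three times control mean
  expect_equal(res$ratio[res$metabolite == "m2"], 3)
  expect_error(differential_metabolites(tab[1:3, ]), "two groups")
})

test_that("significance rule applies the p and fold-change thresholds", {
  tab <- tibble::tibble(group = rep(c("c", "t"), each = 5),
                        m1 = c(rnorm(5, 100, 1e-6), rnorm(5, 300, 1e-6)))
  res <- differential_metabolites(tab, mode = "either")
  expect_true(res$significant)
  expect_equal(res$direction, "up")
  res_r <- differential_metabolites(tab, mode = "ratio_only", ratio_up = 5)
  expect_false(res_r$significant)
})

test_that("a 3-pooled-SD shift is detected in most replicates", {
  hits <- 0
  for (s in 1:200) {
    tab <- simulate_intensity_table(n_per_group = 5, n_metabolites = 1,
                                    block = integer(0), shifted = 1,
                                    shift_sd = 3, seed = 4000 + s)
    res <- differential_metabolites(tab, mode = "p_only")
    hits <- hits + res$significant
  }
  expect_gte(hits, 180)
})

test_that("fisher transform matches the closed form and is odd and monotone", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0.5), atanh(0.5))
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  # clipping keeps r = 1 finite and maximal
  z1 <- fisher_z(1)
  expect_true(is.finite(z1))
  expect_gt(z1, fisher_z(0.999999))
})

test_that("correlation pair is built per group with optional Fisher transform", {
  tab <- make_table(n_per_group = 8, n_metabolites = 10, seed = 2)
  pair_raw <- correlation_pair(tab, fisher = FALSE)
  expect_s3_class(pair_raw, "network_pair")
  off <- pair_raw$A[upper.tri(pair_raw$A)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(diag(pair_raw$A), rep(1, 10), ignore_attr = TRUE)
  pair_z <- correlation_pair(tab, fisher = TRUE)
  expect_equal(pair_z$A[1, 2], fisher_z(pair_raw$A[1, 2]))
  expect_equal(diag(pair_z$A), rep(1, 10), ignore_attr = TRUE)
  # duplicated metabolite columns give the clipped maximal z off-diagonally
  tab2 <- tab
  tab2$dup <- tab2$m1
  pz <- correlation_pair(tab2, fisher = TRUE)
  expect_true(is.finite(pz$A["m1", "dup"]))
  expect_equal(pz$A["m1", "dup"], fisher_z(1))
  # constant metabolite is reported by name
  tab3 <- tab
  tab3$m1 <- 7
  expect_error(correlation_pair(tab3), "m1")
  expect_error(correlation_pair(tab[c(1, 2, 9, 10), ]), "3 samples")
})

test_that("hypergeometric tail matches brute-force summation and the complement rule", {
  grid <- expand.grid(N = c(20, 98, 200), frac_n = c(0.1, 0.25), frac_m = c(0.05, 0.3))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]
    n <- max(2, round(grid$frac_n[i] * N))
    m <- max(1, round(grid$frac_m[i] * N))
    for (k in unique(pmin(c(0, 1, 2, min(n, m)), min(n, m)))) {
      p <- hypergeometric_tail(N, n, m, k)
      expect_equal(p, brute_hyper_tail(N, n, m, k), tolerance = 1e-12)
      if (k > 0) {
        lower <- stats::phyper(k - 1, m, N - m, n)
        expect_equal(p + lower, 1, tolerance = 1e-12)
      }
    }
  }
  expect_equal(hypergeometric_tail(98, 22, 5, 0), 1)
  expect_error(hypergeometric_tail(98, 22, 5, 6), "k <= min")
  expect_error(hypergeometric_tail(98, 99, 5, 1), "n, m <= N")
})

test_that("single-member pathways reduce to the n/N fraction", {
  expect_equal(hypergeometric_tail(98, 22, 1, 1), 22 / 98)
  expect_equal(round(hypergeometric_tail(98, 22, 1, 1), 3), 0.224)
  expect_equal(round(hypergeometric_tail(98, 18, 1, 1), 3), 0.184)
})

test_that("pathway enrichment counts cluster and universe memberships", {
  annot <- tibble::tibble(
    metabolite = c("a", "a", "b", "c", "d", "e", "f"),
    pathway = c("p1", "p2", "p1", "p1", "p2", NA, NA)
  )
  res <- pathway_enrichment(c("a", "b", "e"), annot)
  # universe: 6 metabolites (incl. unannotated), cluster of 3
  expect_equal(unique(res$N), 6)
  expect_equal(unique(res$n), 3)
  p1 <- res[res$pathway == "p1", ]
  expect_equal(p1$m, 3)
  expect_equal(p1$k, 2)
  expect_equal(p1$p_value, brute_hyper_tail(6, 3, 3, 2))
  # multi-membership: "a" counts in both p1 and p2
  expect_equal(res[res$pathway == "p2", ]$k, 1)
  # pathways fully outside the cluster are not reported
  annot2 <- dplyr::bind_rows(annot, tibble::tibble(metabolite = "g", pathway = "p3"))
  res2 <- pathway_enrichment(c("a", "b"), annot2)
  expect_false("p3" %in% res2$pathway)
  expect_error(pathway_enrichment(c("zz"), annot), "absent")
})

test_that("pipeline flags a planted group-specific block and its pathway", {
  hits <- 0
  n_seed <- 40
  for (s in seq_len(n_seed)) {
    tab <- simulate_intensity_table(n_per_group = 12, n_metabolites = 20,
                                    block = 1:8, block_strength = 2,
                                    seed = 5000 + s)
    annot <- tibble::tibble(
      metabolite = paste0("m", 1:20),
      pathway = c(rep("planted", 8), rep(NA, 12))
    )
    rep_ <- run_pipeline(tab, annotation = annot, taus = 8, M = 200,
                         seed = 5000 + s)
    if (!is.null(rep_$enrichment) && nrow(rep_$enrichment) > 0) {
      top <- rep_$enrichment[which.min(rep_$enrichment$p_value), ]
      if (top$pathway == "planted") hits <- hits + 1
    }
  }
  expect_gte(hits, 0.9 * n_seed)
})

test_that("identical groups yield no significant cluster", {
  for (s in 1:20) {
    tab <- simulate_intensity_table(n_per_group = 8, n_metabolites = 12,
                                    block = integer(0), seed = 6000 + s)
    # duplicate group 1's samples as group 2: the two networks are identical
    half <- tab[tab$group == "control", ]
    dup <- half
    dup$group <- "treated"
    dup$sample_id <- paste0(dup$sample_id, "_d")
    tab2 <- dplyr::bind_rows(half, dup)
    rep_ <- run_pipeline(tab2, taus = 6, M = 100, seed = s)
    expect_equal(sum(rep_$clusters$significant), 0)
  }
})

test_that("pipeline report carries positions of every metabolite", {
  tab <- make_table(n_per_group = 6, n_metabolites = 10, seed = 3)
  rep_ <- run_pipeline(tab, taus = 5, M = 50, seed = 1)
  pos <- rep_$positions
  expect_equal(nrow(pos), 10)
  expect_setequal(pos$position_first_1, 1:10)
  expect_setequal(pos$position_last_1, 1:10)
  expect_named(glance(rep_),
               c("n_metabolites", "n_differential", "n_candidates",
                 "n_significant_clusters", "n_enriched_pathways"))
})
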