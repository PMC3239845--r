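#' Planted-cluster binary network pair
#'
#' Generates the 20-node benchmark design: in both networks nodes 1-5 form a
#' well-connected shared cluster; network `A` additionally contains a cluster
#' on nodes 6-15 and network `B` one on nodes 15-20 (node 15 belongs to both
#' exclusive clusters). Within each designated cluster, edges are drawn
#' independently with probability `p_in`; all remaining pairs with probability
#' `p_out`, so the clusters contain missing edges (false negatives) and the
#' background contains spurious edges (false positives).
#'
#' @param n_nodes Number of nodes.
#' @param shared_cluster,a_cluster,b_cluster Node index sets of the planted
#'   clusters (shared; exclusive to `A`; exclusive to `B`).
#' @param p_in Within-cluster edge probability.
#' @param p_out Background edge probability (`0 <= p_out < p_in <= 1`).
#' @param seed Integer seed.
#' @return A [network_pair()] with attribute `"truth"`: a list with the
#'   planted cluster index sets.
#' @examples
#' pair <- generate_binary_pair(seed = 1)
#' binary_density(pair$A, attr(pair, "truth")$a_cluster)
#' @export
generate_binary_pair <- function(n_nodes = 20,
                                 shared_cluster = 1:5,
                                 a_cluster = 6:15,
                                 b_cluster = 15:20,
                                 p_in = 0.85, p_out = 0.08,
                                 seed = NULL) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("Need 0 <= p_out < p_in <= 1.", call. = FALSE)
  }
  for (cl in list(shared_cluster, a_cluster, b_cluster)) {
    if (any(cl < 1) || any(cl > n_nodes)) {
      stop("Cluster node sets must lie in 1..n_nodes.", call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(clusters) {
    P <- matrix(p_out, n_nodes, n_nodes)
    for (g in clusters) P[g, g] <- p_in
    up <- upper.tri(P)
    W <- matrix(0, n_nodes, n_nodes)
    W[up] <- as.numeric(stats::runif(sum(up)) < P[up])
    W + t(W)
  }
  A <- draw(list(shared_cluster, a_cluster))
  B <- draw(list(shared_cluster, b_cluster))
  pair <- network_pair(A, B)
  attr(pair, "truth") <- list(shared_cluster = shared_cluster,
                              a_cluster = a_cluster, b_cluster = b_cluster)
  pair
}

#' The nine source signals of the correlation benchmark
#'
#' Row vectors of length `n_samples`: seven sinusoids of distinct frequencies
#' and phases, a square wave, and a linear ramp. Correlated blocks of the
#' benchmark data matrices are built as positive linear combinations of
#' subsets of these signals.
#'
#' @param n_samples Signal length (number of samples).
#' @return A `9 x n_samples` numeric matrix with rownames `v1`..`v9`.
#' @export
mixing_signals <- function(n_samples = 50) {
  t <- seq(0, 1, length.out = n_samples)
  V <- rbind(
    v1 = sin(2 * pi * 1.0 * t),
    v2 = sin(2 * pi * 2.0 * t + 0.5),
    v3 = sin(2 * pi * 3.0 * t + 1.0),
    v4 = cos(2 * pi * 1.5 * t),
    v5 = cos(2 * pi * 2.5 * t + 0.3),
    v6 = sin(2 * pi * 4.0 * t + 2.0),
    v7 = cos(2 * pi * 3.5 * t + 1.2),
    v8 = sign(sin(2 * pi * 2.0 * t + 0.1)),
    v9 = 2 * t - 1
  )
  V
}

#' Signal-mixing correlation network pair
#'
#' Generates the weighted benchmark design: two `20 x n_samples` data
#' matrices `D_a` and `D_b` are built from the nine [mixing_signals()] and the
#' networks are their row-wise Pearson correlation matrices. Rows 1-5 of both
#' matrices mix signals v1..v7 (the shared cluster); rows 6-15 of `D_a` mix v7
#' and v8 (the `A`-exclusive cluster) while rows 6-14 of `D_b` are pure
#' Gaussian noise; rows 15-20 of `D_b` mix v4 and v9 (the `B`-exclusive
#' cluster) while rows 16-20 of `D_a` are pure noise. Mixing coefficients are
#' drawn from Uniform(0.5, 1.5) (strictly positive, so planted correlations
#' are positive) and signal rows receive additive Gaussian noise with standard
#' deviation `noise_sd`.
#'
#' @param n_samples Number of columns of the data matrices.
#' @param noise_sd Additive noise standard deviation on signal-bearing rows.
#' @param seed Integer seed.
#' @return A [network_pair()] of correlation matrices (unit diagonal, entries
#'   in `[-1, 1]`), with attribute `"truth"` (planted cluster index sets) and
#'   attribute `"data"` (list with `D_a`, `D_b`).
#' @examples
#' pair <- generate_correlation_pair(seed = 1)
#' range(pair$A)
#' @export
generate_correlation_pair <- function(n_samples = 50, noise_sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples
  V <- mixing_signals(n)
  mix <- function(rows) {
    colSums(stats::runif(length(rows), 0.5, 1.5) * V[rows, , drop = FALSE])
  }
  Da <- matrix(0, 20, n)
  Db <- matrix(0, 20, n)
  for (i in 1:5)   Da[i, ] <- mix(1:7) + stats::rnorm(n, 0, noise_sd)
  for (i in 6:15)  Da[i, ] <- mix(7:8) + stats::rnorm(n, 0, noise_sd)
  for (i in 16:20) Da[i, ] <- stats::rnorm(n)
  for (i in 1:5)   Db[i, ] <- mix(1:7) + stats::rnorm(n, 0, noise_sd)
  for (i in 6:14)  Db[i, ] <- stats::rnorm(n)
  for (i in 15:20) Db[i, ] <- mix(c(4, 9)) + stats::rnorm(n, 0, noise_sd)
  if (any(apply(Da, 1, stats::sd) == 0) || any(apply(Db, 1, stats::sd) == 0)) {
    stop("Zero-variance data row generated; increase noise_sd.", call. = FALSE)
  }
  A <- stats::cor(t(Da))
  B <- stats::cor(t(Db))
  # enforce exact symmetry and unit diagonal against floating point drift
  A <- (A + t(A)) / 2; diag(A) <- 1
  B <- (B + t(B)) / 2; diag(B) <- 1
  pair <- network_pair(A, B)
  attr(pair, "truth") <- list(shared_cluster = 1:5, a_cluster = 6:15,
                              b_cluster = 15:20)
  attr(pair, "data") <- list(D_a = Da, D_b = Db)
  pair
}

#' Synthetic two-group metabolite intensity table
#'
#' Emulates an LC-MS peak-intensity experiment with a planted group-specific
#' correlation block: in the first group, the metabolites of `block` share a
#' latent factor (hence correlate); in the second group all metabolites are
#' independent. Optionally a subset of metabolites is mean-shifted between
#' groups to exercise the differential screen. Intensities are log-normal and
#' strictly positive.
#'
#' @param n_per_group Samples per group.
#' @param n_metabolites Number of metabolite columns.
#' @param block Indices of the metabolites forming the group-specific
#'   correlated block (correlated in group 1 only).
#' @param block_strength Loading of the shared latent factor in group 1.
#' @param shifted Indices of metabolites whose mean differs between groups.
#' @param shift_sd Size of the mean shift, in units of the log-scale noise SD.
#' @param groups Length-2 character vector of group names.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `group`, and one numeric column
#'   per metabolite (named `m1`, `m2`, ...), plus attribute `"truth"`.
#' @export
simulate_intensity_table <- function(n_per_group = 10, n_metabolites = 30,
                                     block = 1:8, block_strength = 1.5,
                                     shifted = integer(0), shift_sd = 3,
                                     groups = c("control", "treated"),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(groups) == 2, n_per_group >= 3)
  n <- 2 * n_per_group
  met <- paste0("m", seq_len(n_metabolites))
  logI <- matrix(stats::rnorm(n * n_metabolites, mean = 5, sd = 1),
                 n, n_metabolites, dimnames = list(NULL, met))
  g1 <- seq_len(n_per_group)
  factor1 <- stats::rnorm(n_per_group)
  for (j in block) logI[g1, j] <- logI[g1, j] + block_strength * factor1
  for (j in shifted) logI[-g1, j] <- logI[-g1, j] + shift_sd * 1
  out <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    group = rep(groups, each = n_per_group)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(10^logI))
  attr(out, "truth") <- list(block = met[block], shifted = met[shifted])
  out
}
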