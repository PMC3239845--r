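#' Two-group screen for overtly altered metabolites
#'
#' Per metabolite, computes the fold change of average peak intensity
#' (second group over first) and a Welch two-sample p-value, then flags
#' metabolites by the conventional rule: p < `p_cutoff` and/or fold change
#' below `ratio_down` (down-regulated) or above `ratio_up` (up-regulated).
#'
#' @param table A samples-by-metabolites data frame with a group column; all
#'   other numeric columns are treated as metabolite intensities.
#' @param group Name of the two-level group column (default `"group"`).
#' @param log_transform Run the test on log10 intensities (fold changes are
#'   always computed on the raw scale).
#' @param mode `"either"` flags on p-value or ratio (the "and/or" rule);
#'   `"p_only"` / `"ratio_only"` restrict to one criterion; `"both"` requires
#'   both.
#' @param p_cutoff,ratio_down,ratio_up Thresholds of the significance rule.
#' @return A tibble with one row per metabolite: `metabolite`, `mean_1`,
#'   `mean_2`, `ratio`, `p_value`, `significant`, `direction`.
#' @examples
#' tab <- simulate_intensity_table(shifted = 1, seed = 1)
#' dplyr::filter(differential_metabolites(tab), significant)
#' @export
differential_metabolites <- function(table, group = "group",
                                     log_transform = TRUE,
                                     mode = c("either", "p_only", "ratio_only", "both"),
                                     p_cutoff = 0.05,
                                     ratio_down = 0.5, ratio_up = 2) {
  mode <- match.arg(mode)
  gv <- extract_groups(table, group)
  mets <- metabolite_columns(table, group)
  purrr::map_dfr(mets, function(m) {
    x <- table[[m]][gv$idx1]
    y <- table[[m]][gv$idx2]
    m1 <- mean(x)
    m2 <- mean(y)
    ratio <- m2 / m1
    tx <- if (log_transform) log10(x) else x
    ty <- if (log_transform) log10(y) else y
    p <- if (stats::sd(tx) == 0 && stats::sd(ty) == 0) {
      if (mean(tx) == mean(ty)) 1 else 0
    } else {
      stats::t.test(ty, tx)$p.value   # Welch by default
    }
    by_p <- p < p_cutoff
    by_ratio <- ratio < ratio_down || ratio > ratio_up
    sig <- switch(mode,
                  either = by_p || by_ratio,
                  p_only = by_p,
                  ratio_only = by_ratio,
                  both = by_p && by_ratio)
    tibble::tibble(metabolite = m, mean_1 = m1, mean_2 = m2, ratio = ratio,
                   p_value = p, significant = sig,
                   direction = if (ratio < 1) "down" else if (ratio > 1) "up" else "none")
  })
}

extract_groups <- function(table, group) {
  if (!group %in% names(table)) {
    stop(sprintf("Column '%s' not found in table.", group), call. = FALSE)
  }
  gv <- as.character(table[[group]])
  lev <- unique(gv)
  if (length(lev) != 2) {
    stop("Exactly two groups are required; found: ", paste(lev, collapse = ", "),
         call. = FALSE)
  }
  list(levels = lev, idx1 = which(gv == lev[1]), idx2 = which(gv == lev[2]))
}

metabolite_columns <- function(table, group) {
  num <- vapply(table, is.numeric, logical(1))
  mets <- setdiff(names(table)[num], group)
  if (length(mets) == 0) stop("No numeric metabolite columns found.", call. = FALSE)
  mets
}

#' Fisher z-transform of a correlation
#'
#' `z = arctanh(r)`, with `|r|` clipped to `1 - 1e-12` so that duplicated
#' variables (r = 1) map to a large finite value.
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmax(pmin(r, 1 - 1e-12), -1 + 1e-12))
}

#' Within-group correlation networks from an intensity table
#'
#' Builds the pair of all-pairs Pearson correlation matrices, one per
#' experimental group, across the samples of that group; this is the
#' functional-association network pair the differential clustering operates
#' on. Off-diagonal correlations are optionally Fisher z-transformed to
#' normalize their distribution (the diagonal stays at its raw value of 1).
#'
#' @inheritParams differential_metabolites
#' @param fisher Apply [fisher_z()] to the off-diagonal entries.
#' @param log_transform Correlate log10 intensities (the default) rather than
#'   raw ones.
#' @return A [network_pair()] with `A` the first group's network and `B` the
#'   second group's (group order = order of first appearance in the table).
#' @examples
#' tab <- simulate_intensity_table(seed = 1)
#' correlation_pair(tab)
#' @export
correlation_pair <- function(table, group = "group", fisher = TRUE,
                             log_transform = TRUE) {
  gv <- extract_groups(table, group)
  if (length(gv$idx1) < 3 || length(gv$idx2) < 3) {
    stop("Need at least 3 samples per group for correlation estimation.", call. = FALSE)
  }
  mets <- metabolite_columns(table, group)
  M <- as.matrix(table[, mets])
  if (log_transform) {
    if (any(M <= 0)) stop("Intensities must be positive for log transform.", call. = FALSE)
    M <- log10(M)
  }
  one_group <- function(idx, label) {
    X <- M[idx, , drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("Constant metabolite within group '", label, "': ",
           paste(mets[sds == 0], collapse = ", "), call. = FALSE)
    }
    R <- stats::cor(X)
    R <- (R + t(R)) / 2
    if (fisher) {
      z <- fisher_z(R)
      diag(z) <- diag(R)
      R <- z
    }
    R
  }
  A <- one_group(gv$idx1, gv$levels[1])
  B <- one_group(gv$idx2, gv$levels[2])
  pair <- network_pair(A, B, labels = mets)
  attr(pair, "groups") <- gv$levels
  pair
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` members of a pathway of size `m`
#' (among the `N` detected metabolites) inside a cluster of size `n`:
#' `P(X >= k)` for `X ~ Hypergeometric(N, m, n)`. Computed with
#' `stats::phyper` on the upper tail, which is exact at these scales.
#'
#' @param N Total number of detected metabolites (the universe).
#' @param n Cluster size.
#' @param m Number of detected metabolites annotated to the pathway.
#' @param k Number of those inside the cluster.
#' @return `P(X >= k)`, a probability in `(0, 1]`; `k = 0` gives 1.
#' @examples
#' hypergeometric_tail(N = 98, n = 22, m = 10, k = 7)  # 0.001
#' @export
hypergeometric_tail <- function(N, n, m, k) {
  if (any(c(N, n, m, k) < 0) || n > N || m > N || k > min(n, m)) {
    stop("Need 0 <= k <= min(n, m) and n, m <= N.", call. = FALSE)
  }
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' KEGG pathway over-representation in a cluster
#'
#' For every pathway with at least one member inside the cluster, counts `k`
#' (pathway metabolites in the cluster), `m` (pathway metabolites detected),
#' `n` (cluster size) and `N` (total detected metabolites, including
#' pathway-unannotated ones) and computes the upper-tail hypergeometric
#' probability. Metabolites annotated to several pathways count in each.
#'
#' @param cluster Character vector of metabolite identifiers in the cluster,
#'   or a `cluster_candidate` plus `labels`.
#' @param annotation A data frame with columns `metabolite` and `pathway`
#'   (one row per metabolite-pathway membership; see
#'   [read_pathway_annotation()]), optionally `pathway_name`.
#' @param N Size of the detection universe. Defaults to the number of
#'   distinct metabolites in `annotation` (which should then include
#'   unannotated metabolites with `NA` pathway).
#' @param labels Node labels used to resolve a `cluster_candidate`'s indices.
#' @return A tibble sorted by `p_value` with columns `pathway`
#'   (+`pathway_name` if present), `k`, `m`, `n`, `N`, `p_value`,
#'   `p_adjust_bh`, `significant` (`p_value < 0.05`, the plain threshold; the
#'   Benjamini-Hochberg column is informational).
#' @examples
#' annot <- tibble::tibble(metabolite = paste0("m", 1:20),
#'                         pathway = rep(c("ko1", "ko2", NA), length.out = 20))
#' pathway_enrichment(paste0("m", 1:5), annot)
#' @export
pathway_enrichment <- function(cluster, annotation, N = NULL, labels = NULL) {
  if (inherits(cluster, "cluster_candidate")) {
    if (is.null(labels)) stop("Provide `labels` to resolve cluster indices.", call. = FALSE)
    cluster <- labels[cluster$nodes]
  }
  cluster <- as.character(cluster)
  stopifnot(is.data.frame(annotation),
            all(c("metabolite", "pathway") %in% names(annotation)))
  universe <- unique(annotation$metabolite)
  if (is.null(N)) N <- length(universe)
  n <- length(unique(cluster))
  if (N < n) stop("Universe size N is smaller than the cluster.", call. = FALSE)
  missing <- setdiff(cluster, universe)
  if (length(missing) > 0) {
    stop("Cluster metabolites absent from annotation universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ann <- annotation[!is.na(annotation$pathway), , drop = FALSE]
  ann <- dplyr::distinct(ann, .data$metabolite, .data$pathway,
                         .keep_all = TRUE)
  per_path <- dplyr::group_by(ann, .data$pathway)
  res <- dplyr::summarise(
    per_path,
    pathway_name = if ("pathway_name" %in% names(ann)) dplyr::first(.data$pathway_name) else NA_character_,
    m = dplyr::n_distinct(.data$metabolite),
    k = dplyr::n_distinct(intersect(.data$metabolite, cluster)),
    .groups = "drop"
  )
  res <- dplyr::filter(res, .data$k >= 1)
  res$n <- n
  res$N <- N
  res$p_value <- purrr::pmap_dbl(list(res$m, res$k),
                                 function(m, k) hypergeometric_tail(N, n, m, k))
  res$p_adjust_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < 0.05
  if (all(is.na(res$pathway_name))) res$pathway_name <- NULL
  dplyr::arrange(res, .data$p_value, .data$pathway)
}
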