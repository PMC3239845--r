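#' End-to-end differential clustering of a network pair
#'
#' Runs the full discovery chain on a prepared [network_pair()]: GSVD, node
#' orderings from the outermost `n_columns` columns of each end of `X^-T`,
#' contiguous candidate clusters at the requested sizes, and Monte-Carlo
#' p-values. This is the network-level core shared by the synthetic benchmarks
#' and the metabolomics pipeline.
#'
#' @param pair A [network_pair()].
#' @param taus Candidate cluster sizes (head runs of each ordering).
#' @param n_columns How many columns to inspect from each end of the spectrum.
#' @param M,scheme,seed,measure,combiner Passed to [permutation_pvalue()].
#' @return An object of class `netdiff_scan`: a list with `pair`, `gsvd`,
#'   `orderings` (list of `node_ordering`), and `results`, a tibble with one
#'   row per (ordering, tau) candidate holding the candidate, densities,
#'   quality and p-values.
#' @examples
#' scan <- scan_network_pair(generate_binary_pair(seed = 1), taus = 10,
#'                           M = 200, seed = 1)
#' tidy(scan)
#' @export
scan_network_pair <- function(pair, taus, n_columns = 1, M = 1000,
                              scheme = "permutation", seed = NULL,
                              measure = "auto", combiner = "auto") {
  stopifnot(inherits(pair, "network_pair"))
  fact <- compute_gsvd(pair)
  grid <- tidyr::expand_grid(end = c("first", "last"), column = seq_len(n_columns))
  orderings <- purrr::pmap(grid, function(end, column) {
    reordering_vector(fact, column = column, end = end)
  })
  names(orderings) <- paste0(grid$end, "_", grid$column)
  results <- purrr::map2_dfr(orderings, names(orderings), function(ord, nm) {
    cands <- candidate_clusters(ord, taus = taus)
    tests <- purrr::map(cands$candidate, function(cl) {
      permutation_pvalue(pair, cl, M = M, scheme = scheme, seed = seed,
                        measure = measure, combiner = combiner)
    })
    out <- purrr::map_dfr(tests, glance)
    out$ordering <- nm
    out$run <- cands$run
    out$column <- cands$candidate[[1]]$source$column
    out$end <- ord$end
    out$candidate <- cands$candidate
    out$test <- tests
    out
  })
  structure(list(pair = pair, gsvd = fact, orderings = orderings,
                 results = results, taus = taus, M = M, scheme = scheme,
                 seed = seed),
            class = "netdiff_scan")
}

#' @export
print.netdiff_scan <- function(x, ...) {
  cat(sprintf("<netdiff_scan> %d nodes, taus = %s, M = %d (%s)\n",
              n_nodes(x$pair), paste(x$taus, collapse = ","), x$M, x$scheme))
  print(tidy.netdiff_scan(x), n = Inf)
  invisible(x)
}

#' @describeIn scan_network_pair Candidate-level results as a tibble (one row
#'   per ordering/tau combination, without the list-columns).
#' @param x A `netdiff_scan`.
#' @param ... Unused.
#' @export
tidy.netdiff_scan <- function(x, ...) {
  dplyr::select(x$results, "ordering", "end", "column", "run", "tau", "target",
                "f_target", "f_other", "c_value", "p_value", "p_label",
                "significant")
}

#' @describeIn scan_network_pair One-row summary: nodes, candidates tested,
#'   number significant.
#' @export
glance.netdiff_scan <- function(x, ...) {
  tibble::tibble(n_nodes = n_nodes(x$pair),
                 n_candidates = nrow(x$results),
                 n_significant = sum(x$results$significant),
                 M = x$M, scheme = x$scheme)
}

#' Node positions in the original and reordered networks
#'
#' @param scan A `netdiff_scan`.
#' @return A tibble with `original_position`, `label`, and one
#'   `position_<ordering>` column per computed ordering (mirrors the layout of
#'   a reordering lookup table).
#' @export
position_table <- function(scan) {
  stopifnot(inherits(scan, "netdiff_scan"))
  labs <- scan$pair$labels
  out <- tibble::tibble(original_position = seq_along(labs), label = labs)
  for (nm in names(scan$orderings)) {
    perm <- scan$orderings[[nm]]$permutation
    pos <- integer(length(labs))
    pos[perm] <- seq_along(perm)
    out[[paste0("position_", nm)]] <- pos
  }
  out
}

#' Two-group metabolomics differential-network pipeline
#'
#' Composes the full metabolomics analysis: per-metabolite differential
#' screen, within-group (Fisher-transformed) correlation networks, GSVD
#' reordering, permutation-tested candidate clusters at the configured sizes,
#' and hypergeometric pathway over-representation for every cluster passing
#' the significance threshold.
#'
#' @inheritParams differential_metabolites
#' @inheritParams correlation_pair
#' @param annotation Optional pathway annotation data frame (see
#'   [pathway_enrichment()]); without it the enrichment stage is skipped.
#' @param taus Candidate cluster sizes.
#' @param n_columns Columns inspected per spectrum end.
#' @param M,scheme,seed,measure,combiner Passed to [permutation_pvalue()].
#' @param alpha Cluster significance threshold gating the enrichment stage.
#' @return An object of class `netdiff_report`: list with `differential`
#'   (tibble), `scan` (`netdiff_scan`), `clusters` (tidy scan results),
#'   `enrichment` (tibble, one row per pathway per significant cluster),
#'   `positions` (the [position_table()]), and `config`.
#' @examples
#' tab <- simulate_intensity_table(n_metabolites = 20, seed = 1)
#' rep <- run_pipeline(tab, taus = c(8, 5), M = 100, seed = 1)
#' rep$clusters
#' @export
run_pipeline <- function(table, annotation = NULL, group = "group",
                         taus = c(22, 18), n_columns = 1, M = 1000,
                         scheme = "permutation", seed = NULL,
                         fisher = TRUE, log_transform = TRUE,
                         measure = "auto", combiner = "auto", alpha = 0.05) {
  differential <- differential_metabolites(table, group = group,
                                           log_transform = log_transform)
  pair <- correlation_pair(table, group = group, fisher = fisher,
                           log_transform = log_transform)
  taus <- taus[taus <= n_nodes(pair)]
  if (length(taus) == 0) stop("All taus exceed the number of metabolites.", call. = FALSE)
  scan <- scan_network_pair(pair, taus = taus, n_columns = n_columns, M = M,
                            scheme = scheme, seed = seed, measure = measure,
                            combiner = combiner)
  clusters <- tidy.netdiff_scan(scan)
  enrichment <- NULL
  if (!is.null(annotation)) {
    sig <- scan$results[scan$results$p_value < alpha, , drop = FALSE]
    if (nrow(sig) > 0) {
      enrichment <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
        cl <- sig$candidate[[i]]
        er <- pathway_enrichment(cl, annotation, labels = pair$labels)
        er$ordering <- sig$ordering[i]
        er$run <- sig$run[i]
        er$tau <- sig$tau[i]
        dplyr::relocate(er, "ordering", "run", "tau")
      })
    } else {
      enrichment <- tibble::tibble()
    }
  }
  structure(list(differential = differential, scan = scan, clusters = clusters,
                 enrichment = enrichment, positions = position_table(scan),
                 config = list(group = group, taus = taus, n_columns = n_columns,
                               M = M, scheme = scheme, seed = seed,
                               fisher = fisher, log_transform = log_transform,
                               measure = measure, combiner = combiner,
                               alpha = alpha)),
            class = "netdiff_report")
}

#' @export
print.netdiff_report <- function(x, ...) {
  cat("<netdiff_report>\n")
  cat(sprintf("  differential screen: %d metabolites, %d flagged\n",
              nrow(x$differential), sum(x$differential$significant)))
  cat("  clusters:\n")
  print(x$clusters, n = Inf)
  if (!is.null(x$enrichment) && nrow(x$enrichment) > 0) {
    cat("  enrichment (top rows):\n")
    print(utils::head(x$enrichment, 10))
  }
  invisible(x)
}

#' @describeIn run_pipeline Cluster-level results of the report.
#' @param x A `netdiff_report`.
#' @param ... Unused.
#' @export
tidy.netdiff_report <- function(x, ...) x$clusters

#' @describeIn run_pipeline One-row pipeline summary.
#' @export
glance.netdiff_report <- function(x, ...) {
  tibble::tibble(
    n_metabolites = nrow(x$differential),
    n_differential = sum(x$differential$significant),
    n_candidates = nrow(x$clusters),
    n_significant_clusters = sum(x$clusters$significant),
    n_enriched_pathways = if (is.null(x$enrichment)) NA_integer_ else sum(x$enrichment$significant)
  )
}
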