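#' Pair of weighted networks on a common node set
#'
#' Bundles two square symmetric weight matrices `A` and `B` defined on the same
#' ordered set of nodes. This is the sole required input of the differential
#' clustering pipeline: `A` and `B` typically hold within-group correlation
#' coefficients (possibly Fisher z-transformed, possibly negative) or binary
#' adjacencies.
#'
#' @param A,B Square numeric matrices of identical dimension. Each must be
#'   symmetric to within `tol` (or pass `symmetrize = TRUE`).
#' @param labels Character vector of node labels, one per row. Defaults to the
#'   dimnames of `A`, else `"n1"`, `"n2"`, ...
#' @param tol Absolute tolerance for the symmetry check.
#' @param symmetrize If `TRUE`, replace each matrix by `(W + t(W))/2` (with a
#'   warning) instead of erroring on asymmetry.
#' @param zero_diagonal If `TRUE`, set both diagonals to zero. Diagonals are
#'   retained as given by default.
#'
#' @return An object of class `network_pair`: a list with elements `A`, `B`
#'   (labelled matrices) and `labels`.
#' @examples
#' pair <- generate_binary_pair(seed = 1)
#' pair
#' @export
network_pair <- function(A, B, labels = NULL, tol = 1e-8,
                         symmetrize = FALSE, zero_diagonal = FALSE) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!is.numeric(A) || !is.numeric(B)) {
    stop("`A` and `B` must be numeric matrices.", call. = FALSE)
  }
  if (nrow(A) != ncol(A) || nrow(B) != ncol(B)) {
    stop("`A` and `B` must be square.", call. = FALSE)
  }
  if (!all(dim(A) == dim(B))) {
    stop("`A` and `B` must have identical dimensions.", call. = FALSE)
  }
  if (anyNA(A) || anyNA(B) || any(is.infinite(A)) || any(is.infinite(B))) {
    stop("`A` and `B` must be finite (no NA/NaN/Inf entries).", call. = FALSE)
  }
  N <- nrow(A)
  if (N < 2) stop("Need at least 2 nodes.", call. = FALSE)
  for (nm in c("A", "B")) {
    W <- get(nm)
    asym <- max(abs(W - t(W)))
    if (asym > tol) {
      if (symmetrize) {
        warning(sprintf("`%s` asymmetric (max |W - t(W)| = %.3g); averaging with its transpose.",
                        nm, asym), call. = FALSE)
        assign(nm, (W + t(W)) / 2)
      } else {
        stop(sprintf("`%s` is not symmetric (max |W - t(W)| = %.3g > tol). Use symmetrize = TRUE to average.",
                     nm, asym), call. = FALSE)
      }
    }
  }
  if (is.null(labels)) labels <- rownames(A)
  if (is.null(labels)) labels <- paste0("n", seq_len(N))
  labels <- as.character(labels)
  if (length(labels) != N) stop("`labels` must have one entry per node.", call. = FALSE)
  if (anyDuplicated(labels)) stop("`labels` must not contain duplicates.", call. = FALSE)
  if (zero_diagonal) {
    diag(A) <- 0
    diag(B) <- 0
  }
  dimnames(A) <- dimnames(B) <- list(labels, labels)
  structure(list(A = A, B = B, labels = labels), class = "network_pair")
}

#' @export
print.network_pair <- function(x, ...) {
  cat(sprintf("<network_pair> %d nodes\n", length(x$labels)))
  cat(sprintf("  A: range [%.3g, %.3g]%s\n", min(x$A), max(x$A),
              if (is_binary_matrix(x$A)) " (binary)" else ""))
  cat(sprintf("  B: range [%.3g, %.3g]%s\n", min(x$B), max(x$B),
              if (is_binary_matrix(x$B)) " (binary)" else ""))
  cat("  labels: ", paste(utils::head(x$labels, 5), collapse = ", "),
      if (length(x$labels) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

n_nodes <- function(pair) length(pair$labels)

is_binary_matrix <- function(W) all(W %in% c(0, 1))

#' Symmetrically permute both networks of a pair
#'
#' Applies the same node permutation to rows and columns of `A` and `B`,
#' carrying node labels along. Typically called with a [reordering_vector()]
#' result so that latent block structure becomes contiguous in heat maps.
#'
#' @param pair A [network_pair()].
#' @param ordering A `node_ordering` (from [reordering_vector()]) or a bare
#'   integer permutation of `1:N`.
#' @return A new `network_pair` with rows/columns of both matrices in the new
#'   order.
#' @examples
#' pair <- generate_binary_pair(seed = 1)
#' ord <- reordering_vector(compute_gsvd(pair), column = 1, end = "last")
#' reorder_pair(pair, ord)
#' @export
reorder_pair <- function(pair, ordering) {
  stopifnot(inherits(pair, "network_pair"))
  perm <- if (inherits(ordering, "node_ordering")) ordering$permutation else as.integer(ordering)
  N <- n_nodes(pair)
  if (length(perm) != N || !setequal(perm, seq_len(N))) {
    stop("`ordering` must be a permutation of 1:", N, call. = FALSE)
  }
  network_pair(pair$A[perm, perm], pair$B[perm, perm], labels = pair$labels[perm])
}

#' Randomly relabel a network pair
#'
#' Draws one uniform random node permutation and applies it identically to both
#' matrices (and the labels). Used to verify that the reordering pipeline is
#' invariant to the arbitrary input labelling.
#'
#' @param pair A [network_pair()].
#' @param seed Integer seed for the permutation draw.
#' @return A list with elements `pair` (the relabelled `network_pair`) and
#'   `permutation` (the integer permutation applied), so callers can invert it.
#' @examples
#' sh <- shuffle_pair(generate_binary_pair(seed = 1), seed = 2)
#' sh$permutation
#' @export
shuffle_pair <- function(pair, seed = NULL) {
  stopifnot(inherits(pair, "network_pair"))
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_nodes(pair))
  list(pair = reorder_pair(pair, perm), permutation = perm)
}

#' Tidy a network pair into long edge form
#'
#' @param x A `network_pair`.
#' @param ... Unused.
#' @return A tibble with one row per ordered node pair and columns `from`,
#'   `to`, `weight_a`, `weight_b`.
#' @export
tidy.network_pair <- function(x, ...) {
  labs <- x$labels
  tibble::tibble(
    from = rep(labs, times = length(labs)),
    to = rep(labs, each = length(labs)),
    weight_a = as.vector(x$A),
    weight_b = as.vector(x$B)
  )
}

#' Heat-map display of the two networks of a pair
#'
#' @param object A `network_pair`.
#' @param ... Unused.
#' @return A ggplot with one facet per network, diverging fill centred at 0,
#'   nodes in matrix order.
#' @export
autoplot.network_pair <- function(object, ...) {
  labs <- object$labels
  df <- tidy.network_pair(object)
  df <- tidyr::pivot_longer(df, cols = c("weight_a", "weight_b"),
                            names_to = "network", values_to = "weight")
  df$network <- ifelse(df$network == "weight_a", "A", "B")
  df$from <- factor(df$from, levels = labs)
  df$to <- factor(df$to, levels = rev(labs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~network) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  midpoint = 0) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL)
}
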