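#' Generalized Singular Value Decomposition of a network pair
#'
#' Jointly factorizes the two weight matrices as `A = U C X^-1` and
#' `B = V S X^-1`, with `U`, `V` orthogonal and `C = diag(c)`, `S = diag(s)`
#' nonnegative diagonal, normalized so that `c^2 + s^2 = 1` componentwise and
#' ordered with `c` nondecreasing and `s` nonincreasing. The generalized
#' singular values `lambda_i = c_i / s_i` are the stationary values of
#' `||A x|| / ||B x||`: directions with large `lambda` carry structure much
#' stronger in `A` than in `B`, and vice versa. Sorting the components of the
#' extreme columns of `X^-T` therefore reorders the node set so that
#' condition-exclusive clusters become contiguous (see
#' [reordering_vector()]).
#'
#' The factorization is computed without forming any matrix inverse: the
#' stacked matrix `rbind(A, B)` is QR-factorized and the orthonormal factor's
#' top block is resolved by a CS decomposition (SVD), which remains defined
#' when `A` or `B` (or both) are singular. When one matrix is rank-deficient a
#' whole block of generalized singular values is exactly infinite (or zero)
#' and the corresponding columns of `X^-T` are determined only up to rotation;
#' such numerically tied end blocks are made deterministic by rotating them
#' onto the eigenvectors of the block-projected target matrix, so that the
#' outermost column is the strongest cluster direction the tied subspace
#' contains. This leaves the factorization exact and makes orderings
#' reproducible across platforms.
#'
#' @param pair A [network_pair()].
#' @param tol Tolerance used to detect tied (numerically zero) entries of `c`
#'   and `s`, relative to 1.
#' @return An object of class `net_gsvd` with elements `U`, `V`, `X_inv`
#'   (`X^-1`), `X_invT` (`X^-T`, i.e. `t(X_inv)`), `c`, `s`, `lam`
#'   (`c/s`, `Inf` where `s` is numerically zero), and `labels`.
#' @examples
#' f <- compute_gsvd(generate_binary_pair(seed = 1))
#' glance(f)
#' @export
compute_gsvd <- function(pair, tol = 1e-7) {
  stopifnot(inherits(pair, "network_pair"))
  A <- pair$A
  B <- pair$B
  N <- n_nodes(pair)

  qrM <- qr(rbind(A, B))
  rd <- abs(diag(qr.R(qrM)))
  if (min(rd) < max(rd) * 1e-12) {
    warning("Stacked pair rbind(A, B) is numerically rank-deficient; ",
            "X is ill-conditioned and orderings from the affected columns may be unstable.",
            call. = FALSE)
  }
  Q <- qr.Q(qrM)
  R <- qr.R(qrM)
  Q1 <- Q[seq_len(N), , drop = FALSE]
  Q2 <- Q[N + seq_len(N), , drop = FALSE]

  # CS decomposition of (Q1, Q2): Q1 = U diag(c) W^T with c in [0, 1]
  sv <- svd(Q1)
  ord <- order(sv$d)                    # enforce c ascending / s descending
  cvec <- pmin(sv$d[ord], 1)
  W <- sv$v[, ord, drop = FALSE]
  svec <- sqrt(pmax(0, 1 - cvec^2))

  # Disambiguate numerically tied end blocks by rotating the shared basis W
  # (see Details). The per-column factors below are recomputed from the
  # rotated W, so U diag(c) W^T = Q1 and V diag(s) W^T = Q2 hold exactly for
  # any block rotation.
  trail <- which(svec < tol)
  if (length(trail) > 1) {
    W[, trail] <- W[, trail, drop = FALSE] %*%
      tied_block_rotation(crossprod(W[, trail, drop = FALSE], R), A,
                          largest_last = TRUE)
  }
  lead <- which(cvec < tol)
  if (length(lead) > 1) {
    W[, lead] <- W[, lead, drop = FALSE] %*%
      tied_block_rotation(crossprod(W[, lead, drop = FALSE], R), B,
                          largest_last = FALSE)
  }

  T1 <- Q1 %*% W
  T2 <- Q2 %*% W
  cvec <- sqrt(colSums(T1^2))
  svec <- sqrt(colSums(T2^2))
  U <- normalize_columns(T1, cvec)
  V <- normalize_columns(T2, svec)

  X_inv <- crossprod(W, R)              # X^-1 = W^T R
  X_invT <- t(X_inv)

  lam <- ifelse(svec < tol, Inf, cvec / svec)
  structure(list(U = U, V = V, X_inv = X_inv, X_invT = X_invT,
                 c = cvec, s = svec, lam = lam, labels = pair$labels),
            class = "net_gsvd")
}

# Orthogonal rotation aligning a tied block with the eigenvectors of the
# block-projected matrix `target`; `Kt` holds the block's rows of X^-1
# (t(Kt) = the block's columns of X^-T). The strongest cluster direction goes
# to the outer end of the spectrum.
tied_block_rotation <- function(Kt, target, largest_last) {
  K <- t(Kt)
  e <- eigen(crossprod(K, target %*% K), symmetric = TRUE)
  G <- e$vectors                         # eigenvalues descending
  if (largest_last) G <- G[, rev(seq_len(ncol(G))), drop = FALSE]
  G
}

# Divide columns by their norms; numerically zero columns are replaced by a
# deterministic orthonormal completion of the remaining ones.
normalize_columns <- function(M, norms, tiny = 1e-12) {
  ok <- norms > tiny
  M[, ok] <- sweep(M[, ok, drop = FALSE], 2, norms[ok], "/")
  if (any(!ok)) {
    M[, !ok] <- complete_orthonormal(M[, ok, drop = FALSE], sum(!ok))
  }
  M
}

# Deterministic orthonormal completion: Gram-Schmidt of the identity columns
# against `basis`, keeping the first k independent directions.
complete_orthonormal <- function(basis, k) {
  N <- nrow(basis)
  out <- matrix(0, N, k)
  got <- 0
  B <- basis
  for (j in seq_len(N)) {
    if (got == k) break
    v <- numeric(N)
    v[j] <- 1
    if (ncol(B) > 0) v <- v - B %*% crossprod(B, v)
    nrm <- sqrt(sum(v^2))
    if (nrm > 1e-6) {
      v <- v / nrm
      got <- got + 1
      out[, got] <- v
      B <- cbind(B, v)
    }
  }
  out
}

#' @export
print.net_gsvd <- function(x, ...) {
  N <- length(x$c)
  cat(sprintf("<net_gsvd> %d nodes\n", N))
  cat("  generalized singular values (c/s), smallest and largest:\n")
  cat("   ", paste(signif(utils::head(x$lam, 3), 4), collapse = ", "), "...",
      paste(signif(utils::tail(x$lam, 3), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn compute_gsvd One row per factorization component: `index`, `c`,
#'   `s`, `lam`.
#' @param x A `net_gsvd` object.
#' @param ... Unused.
#' @export
tidy.net_gsvd <- function(x, ...) {
  tibble::tibble(index = seq_along(x$c), c = x$c, s = x$s, lam = x$lam)
}

#' @describeIn compute_gsvd One-row summary with node count, rank estimates and
#'   the extreme generalized singular values.
#' @export
glance.net_gsvd <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$c),
    n_infinite = sum(is.infinite(x$lam)),
    n_zero = sum(x$lam == 0),
    lam_min = min(x$lam),
    lam_max = max(x$lam)
  )
}

#' Node ordering from a column of X^-T
#'
#' Extracts one column of `X^-T` from a GSVD factorization and sorts its
#' components to produce a node permutation. The first few columns (`end =
#' "first"`) order nodes so that clusters exclusive to network `B` move to the
#' head; the last few columns (`end = "last"`) do the same for clusters
#' exclusive to `A`. Each column is sign-normalized so its largest-magnitude
#' component is positive, then sorted in decreasing order (ties broken by
#' original node index), so results are deterministic; a cluster may still
#' appear at either end of the ordering, and both ends are offered as
#' candidates by [candidate_clusters()].
#'
#' @param fact A `net_gsvd` from [compute_gsvd()].
#' @param column Column number counted from the chosen end (1 = outermost).
#' @param end `"first"` (columns 1, 2, ...; favors clusters in `B`) or
#'   `"last"` (columns N, N-1, ...; favors clusters in `A`).
#' @return An object of class `node_ordering`: list with `permutation`
#'   (original node indices in new order), `values` (sorted components),
#'   `source_column` (absolute column index into `X^-T`), `end`, `labels`
#'   (labels in new order), and `target` (`"A"` or `"B"`, which network this
#'   ordering favors clusters in).
#' @examples
#' f <- compute_gsvd(generate_binary_pair(seed = 1))
#' reordering_vector(f, column = 1, end = "last")
#' @export
reordering_vector <- function(fact, column = 1, end = c("first", "last")) {
  stopifnot(inherits(fact, "net_gsvd"))
  end <- match.arg(end)
  N <- length(fact$c)
  if (!is.numeric(column) || length(column) != 1 || column < 1 || column > N) {
    stop("`column` must be a single integer in 1..", N, call. = FALSE)
  }
  col_abs <- if (end == "first") as.integer(column) else as.integer(N + 1 - column)
  x <- unname(fact$X_invT[, col_abs])
  if (x[which.max(abs(x))] < 0) x <- -x   # sign normalization
  perm <- order(x, seq_along(x), decreasing = c(TRUE, FALSE), method = "radix")
  structure(list(permutation = perm,
                 values = x[perm],
                 source_column = col_abs,
                 end = end,
                 labels = fact$labels[perm],
                 target = if (end == "first") "B" else "A"),
            class = "node_ordering")
}

#' @export
print.node_ordering <- function(x, ...) {
  cat(sprintf("<node_ordering> column %d (%s end; favors clusters in %s)\n",
              x$source_column, x$end, x$target))
  cat("  head:", paste(utils::head(x$labels, 8), collapse = ", "), "...\n")
  invisible(x)
}

#' Tidy a node ordering
#'
#' @param x A `node_ordering`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `node` (original index), `label`,
#'   `value` (the sorted component of the reordering vector).
#' @export
tidy.node_ordering <- function(x, ...) {
  tibble::tibble(position = seq_along(x$permutation),
                 node = x$permutation,
                 label = x$labels,
                 value = x$values)
}
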