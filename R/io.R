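#' Read a labelled square matrix from TSV/CSV
#'
#' Expects a header row of node labels and a first column of identical labels;
#' tab-separated by default, comma accepted (sniffed from the header line).
#'
#' @param path File path.
#' @param symmetrize Average `(W + t(W)) / 2` (with a warning) instead of
#'   erroring when the matrix is asymmetric beyond `tol`.
#' @param tol Symmetry tolerance.
#' @return A list with `labels` (character) and `matrix` (numeric, with
#'   dimnames).
#' @export
read_labeled_matrix <- function(path, symmetrize = FALSE, tol = 1e-8) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) stop("Duplicate labels in ", path, call. = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(W)) stop("Non-numeric cells in matrix file: ", path, call. = FALSE)
  if (nrow(W) != ncol(W)) {
    stop(sprintf("Matrix in %s is not square (%d x %d).", path, nrow(W), ncol(W)),
         call. = FALSE)
  }
  if (!identical(labels, colnames(W))) {
    stop("Row and column labels differ in ", path, call. = FALSE)
  }
  rownames(W) <- labels
  asym <- max(abs(W - t(W)))
  if (asym > tol) {
    if (symmetrize) {
      warning(sprintf("Matrix in %s asymmetric (max diff %.3g); symmetrizing.",
                      path, asym), call. = FALSE)
      W <- (W + t(W)) / 2
    } else {
      stop(sprintf("Matrix in %s is not symmetric (max diff %.3g). Use symmetrize = TRUE.",
                   path, asym), call. = FALSE)
    }
  }
  list(labels = labels, matrix = W)
}

#' Write a labelled square matrix as TSV
#'
#' @param matrix Numeric matrix.
#' @param labels Node labels (defaults to rownames).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(matrix, path, labels = rownames(matrix)) {
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(matrix)))
  dimnames(matrix) <- list(labels, labels)
  df <- as.data.frame(matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a network pair from two matrix files
#'
#' @param path_a,path_b Paths of the two matrices.
#' @param align_labels Reorder the second matrix's nodes to match the first
#'   (by label) instead of requiring identical order.
#' @inheritParams read_labeled_matrix
#' @inheritParams network_pair
#' @return A [network_pair()].
#' @export
read_network_pair <- function(path_a, path_b, align_labels = FALSE,
                              symmetrize = FALSE, zero_diagonal = FALSE) {
  a <- read_labeled_matrix(path_a, symmetrize = symmetrize)
  b <- read_labeled_matrix(path_b, symmetrize = symmetrize)
  if (!identical(a$labels, b$labels)) {
    if (align_labels && setequal(a$labels, b$labels)) {
      idx <- match(a$labels, b$labels)
      b$matrix <- b$matrix[idx, idx]
      b$labels <- a$labels
    } else {
      stop("Label sets/order differ between the two matrices",
           if (!align_labels) " (use align_labels = TRUE if they are the same set)",
           ".", call. = FALSE)
    }
  }
  network_pair(a$matrix, b$matrix, labels = a$labels,
               zero_diagonal = zero_diagonal)
}

#' Read a metabolite-to-pathway annotation table
#'
#' Two-column TSV/CSV: metabolite identifier and a comma-separated list of
#' pathway identifiers (`NA` for unannotated metabolites, which stay in the
#' enrichment universe with no pathway membership).
#'
#' @param path File path.
#' @return A tibble with columns `metabolite` and `pathway` (one row per
#'   membership; unannotated metabolites get one row with `NA` pathway).
#' @export
read_pathway_annotation <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 2) stop("Annotation needs two columns.", call. = FALSE)
  names(df)[1:2] <- c("metabolite", "pathway")
  out <- tibble::as_tibble(df[, 1:2])
  out <- tidyr::separate_rows(out, "pathway", sep = ",")
  out$pathway <- trimws(out$pathway)
  out$pathway[out$pathway %in% c("", "NA")] <- NA_character_
  dplyr::distinct(out)
}

#' Read a samples-by-metabolites intensity table
#'
#' TSV/CSV with a sample identifier column, a `group` column and one numeric
#' column per metabolite.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Export a matrix heat map as a PNG image
#'
#' Renders the matrix with a diverging blue-white-red colour map centred at 0
#' and writes the pixel array directly (no graphics device), so the output is
#' byte-identical across runs and platforms.
#'
#' @param matrix Numeric matrix.
#' @param path Output `.png` path.
#' @param pixel_size Square pixels per matrix cell.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(matrix, path, pixel_size = 8) {
  W <- as.matrix(matrix)
  lim <- max(abs(W))
  if (lim == 0) lim <- 1
  v <- W / lim                        # in [-1, 1]
  # diverging map: -1 -> blue (#2166AC), 0 -> white, +1 -> red (#B2182B)
  lo <- c(0x21, 0x66, 0xAC) / 255
  hi <- c(0xB2, 0x18, 0x2B) / 255
  chan <- function(i) {
    out <- matrix(1, nrow(W), ncol(W))
    neg <- v < 0
    out[neg] <- 1 + (-v[neg]) * (lo[i] - 1)
    out[!neg] <- 1 + v[!neg] * (hi[i] - 1)
    out
  }
  img <- array(0, dim = c(nrow(W) * pixel_size, ncol(W) * pixel_size, 3))
  for (i in 1:3) {
    img[, , i] <- chan(i)[rep(seq_len(nrow(W)), each = pixel_size),
                          rep(seq_len(ncol(W)), each = pixel_size)]
  }
  png::writePNG(img, path)
  invisible(path)
}
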