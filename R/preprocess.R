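#' Extract the non-zero genes of one cell
#'
#' A cell enters the encoder only through its non-zero expressed genes,
#' stored as parallel lists of 0-based gene indices and expression values in
#' ascending index order.
#'
#' @param cell_expression numeric vector of length \code{vocab$n} (one cell's
#'   counts in vocabulary order), entries >= 0.
#' @param vocab a \code{GeneVocabulary}.
#' @param cell_id optional identifier carried into the all-zero error message.
#' @return A \code{SparseCell}: list with \code{g_index} (0-based integer),
#'   \code{g_value} (positive numeric), both the same length.
#' @export
extract_nonzero <- function(cell_expression, vocab, cell_id = NULL) {
  if (length(cell_expression) != vocab$n)
    stop("expression vector length ", length(cell_expression),
         " != vocabulary size ", vocab$n)
  nz <- which(cell_expression != 0)
  if (length(nz) == 0)
    stop("cell ", if (is.null(cell_id)) "<unnamed>" else cell_id,
         " has no non-zero genes")
  structure(list(g_index = as.integer(nz - 1L),
                 g_value = as.numeric(cell_expression[nz])),
            class = "SparseCell")
}

#' Mean-scale a cell's non-zero expression values
#'
#' Divides each non-zero value by the mean of the cell's non-zero values, so
#' the scaled values average exactly 1. This removes per-cell depth while
#' keeping relative expression, and is applied to every cell (reference and
#' query) before encoding.
#'
#' @param cell a \code{SparseCell}.
#' @return The \code{SparseCell} with scaled values.
#' @export
mean_scale <- function(cell) {
  m <- mean(cell$g_value)
  cell$g_value <- cell$g_value / m
  cell
}

#' Convert an expression matrix into per-cell sparse gene lists
#'
#' Runs [extract_nonzero()] and [mean_scale()] over all rows. All-zero cells
#' are dropped with a warning (they cannot be encoded); the kept row indices
#' are returned so callers can subset labels accordingly.
#'
#' @param x an \code{ExpressionMatrix} whose columns follow \code{vocab}.
#' @param vocab a \code{GeneVocabulary}.
#' @param scale apply mean scaling (default TRUE).
#' @return list with \code{cells} (list of \code{SparseCell}), \code{kept}
#'   (integer row indices of x that survived), \code{cell_ids}.
#' @export
prepare_cells <- function(x, vocab, scale = TRUE) {
  m <- x$counts
  if (inherits(m, "sparseMatrix")) {
    mt <- methods::as(methods::as(Matrix::t(m), "generalMatrix"), "CsparseMatrix")
    p <- mt@p
    nnz_of <- function(i) p[i + 1L] - p[i]
    cell_list <- function(i) {
      if (nnz_of(i) == 0L) return(NULL)
      sel <- (p[i] + 1L):p[i + 1L]
      structure(list(g_index = as.integer(mt@i[sel]),
                     g_value = as.numeric(mt@x[sel])), class = "SparseCell")
    }
    cells <- lapply(seq_len(ncol(mt)), cell_list)
  } else {
    cells <- lapply(seq_len(nrow(m)), function(i) {
      nz <- which(m[i, ] != 0)
      if (length(nz) == 0) return(NULL)
      structure(list(g_index = as.integer(nz - 1L),
                     g_value = as.numeric(m[i, nz])), class = "SparseCell")
    })
  }
  kept <- which(!vapply(cells, is.null, logical(1)))
  if (length(kept) < length(cells))
    warning(length(cells) - length(kept),
            " all-zero cell(s) dropped during preprocessing")
  cells <- cells[kept]
  if (scale) cells <- lapply(cells, mean_scale)
  list(cells = cells, kept = kept, cell_ids = x$cell_ids[kept])
}

#' Pad a list of sparse cells into a batch
#'
#' Cells have varying numbers of non-zero genes, so a batch is padded to the
#' longest cell: padded slots carry the vocabulary pad index and value 0, and
#' a key mask records which slots are real genes.
#'
#' @param cells non-empty list of \code{SparseCell}.
#' @param vocab a \code{GeneVocabulary} (supplies the pad index).
#' @return A \code{PaddedBatch}: list with \code{G_index} (B x M, 0-based),
#'   \code{G_value} (B x M), \code{key_mask} (B x M logical), \code{B},
#'   \code{M}, \code{lengths}.
#' @export
collate <- function(cells, vocab) {
  B <- length(cells)
  if (B == 0) stop("cannot collate an empty list of cells")
  lens <- vapply(cells, function(c) length(c$g_index), integer(1))
  M <- max(lens)
  G_index <- matrix(as.integer(vocab$pad_index), B, M)
  G_value <- matrix(0, B, M)
  key_mask <- matrix(FALSE, B, M)
  for (b in seq_len(B)) {
    L <- lens[b]
    G_index[b, seq_len(L)] <- cells[[b]]$g_index
    G_value[b, seq_len(L)] <- cells[[b]]$g_value
    key_mask[b, seq_len(L)] <- TRUE
  }
  structure(list(G_index = G_index, G_value = G_value, key_mask = key_mask,
                 B = B, M = M, lengths = lens),
            class = "PaddedBatch")
}

#' Randomly mask a cell's genes (contrastive augmentation)
#'
#' Each (index, value) pair is removed independently with probability
#' \code{rate}. Should every pair be removed, one uniformly chosen pair is
#' retained, because an empty cell cannot be encoded. Values of surviving
#' genes are unchanged.
#'
#' @param cell a \code{SparseCell}.
#' @param rate masking probability in [0, 1).
#' @return A \code{SparseCell} whose gene set is a subset of the input's.
#' @export
random_mask <- function(cell, rate = 0.15) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(cell)
  L <- length(cell$g_index)
  keep <- stats::runif(L) >= rate
  if (!any(keep)) keep[sample.int(L, 1L)] <- TRUE
  structure(list(g_index = cell$g_index[keep], g_value = cell$g_value[keep]),
            class = "SparseCell")
}
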