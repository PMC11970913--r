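#' Expression matrix container
#'
#' Bundles a cells-by-genes count matrix with gene symbols, cell barcodes and
#' optional per-cell labels and batch identifiers. Counts may be a base
#' matrix or a sparse \code{Matrix::dgCMatrix}; rows are cells, columns are
#' genes, everywhere in this package.
#'
#' @param counts cells-by-genes non-negative numeric matrix (dense or sparse).
#' @param gene_symbols character vector of unique gene symbols, one per column.
#' @param cell_ids character vector of unique cell barcodes, one per row.
#' @param labels optional per-cell cell-type labels (character).
#' @param batches optional per-cell batch identifiers (character).
#' @return An object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(counts, gene_symbols, cell_ids,
                              labels = NULL, batches = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (nrow(counts) != length(cell_ids))
    stop("counts has ", nrow(counts), " rows but ", length(cell_ids), " cell ids")
  if (ncol(counts) != length(gene_symbols))
    stop("counts has ", ncol(counts), " columns but ", length(gene_symbols),
         " gene symbols")
  if (anyDuplicated(gene_symbols))
    stop("duplicate gene symbols: ",
         paste(unique(gene_symbols[duplicated(gene_symbols)]), collapse = ", "))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (length(counts) > 0) {
    mn <- if (inherits(counts, "sparseMatrix")) min(counts@x, 0)
          else min(counts)
    if (is.na(mn) || mn < 0) stop("counts must be non-negative and finite")
  }
  if (!is.null(labels) && length(labels) != length(cell_ids))
    stop("labels length != number of cells")
  if (!is.null(batches) && length(batches) != length(cell_ids))
    stop("batches length != number of cells")
  dimnames(counts) <- list(cell_ids, gene_symbols)
  structure(list(counts = counts,
                 gene_symbols = as.character(gene_symbols),
                 cell_ids = as.character(cell_ids),
                 labels = if (is.null(labels)) NULL else as.character(labels),
                 batches = if (is.null(batches)) NULL else as.character(batches)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$cell_ids), "cells x",
      length(x$gene_symbols), "genes\n")
  if (!is.null(x$labels))
    cat("  labels:", length(unique(x$labels)), "cell types\n")
  if (!is.null(x$batches))
    cat("  batches:", length(unique(x$batches)), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read an expression matrix from disk
#'
#' Supported formats: \code{"mtx_triplet"}, the CellRanger-style triplet of
#' \code{matrix.mtx} (genes in rows, transposed to cells-by-genes on load),
#' \code{genes.tsv} and \code{barcodes.tsv} in one directory; and
#' \code{"delimited"}, a header-ed text table whose first column is the cell
#' id and remaining columns are gene counts.
#'
#' @param path directory (mtx_triplet) or file (delimited).
#' @param format one of \code{"mtx_triplet"}, \code{"delimited"}.
#' @param sep field separator for delimited files (default tab; automatic
#'   comma detection for \code{.csv}).
#' @return An \code{ExpressionMatrix}.
#' @export
read_expression <- function(path, format = c("mtx_triplet", "delimited"),
                            sep = NULL) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    barcodes <- file.path(path, "barcodes.tsv")
    missing <- c(mtx, genes, barcodes)[!file.exists(c(mtx, genes, barcodes))]
    if (length(missing))
      stop("missing mtx triplet file(s): ", paste(missing, collapse = ", "))
    m <- Matrix::readMM(mtx)
    gs <- data.table::fread(genes, header = FALSE, sep = "\t")[[1]]
    bc <- data.table::fread(barcodes, header = FALSE, sep = "\t")[[1]]
    if (nrow(m) != length(gs))
      stop("matrix.mtx has ", nrow(m), " gene rows but genes.tsv lists ",
           length(gs))
    if (ncol(m) != length(bc))
      stop("matrix.mtx has ", ncol(m), " cell columns but barcodes.tsv lists ",
           length(bc))
    expression_matrix(methods::as(Matrix::t(m), "CsparseMatrix"), gs, bc)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, with = FALSE])
    storage.mode(m) <- "double"
    expression_matrix(m, colnames(m), ids)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: writes either the MTX triplet directory or
#' a single delimited file. Integer counts round-trip exactly.
#'
#' @param x an \code{ExpressionMatrix}.
#' @param path output directory (mtx_triplet) or file (delimited).
#' @param format output format.
#' @param sep field separator for delimited output.
#' @export
write_expression <- function(x, path, format = c("mtx_triplet", "delimited"),
                             sep = "\t") {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(x$counts, sparse = TRUE)),
                                 "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(x$gene_symbols, file.path(path, "genes.tsv"))
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    m <- as.matrix(x$counts)
    dt <- data.table::data.table(cell_id = x$cell_ids)
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::setnames(dt, c("cell_id", x$gene_symbols))
    data.table::fwrite(dt, path, sep = sep)
  }
  invisible(path)
}

#' Read or write per-cell annotations (labels or batches)
#'
#' Two-column delimited text: \code{cell_id} and a value column. On read the
#' values are matched to the matrix' cell order.
#'
#' @param x an \code{ExpressionMatrix}.
#' @param path file path.
#' @param what which slot to fill: \code{"labels"} or \code{"batches"}.
#' @return \code{read_annotations}: the updated \code{ExpressionMatrix}.
#' @export
read_annotations <- function(x, path, what = c("labels", "batches")) {
  what <- match.arg(what)
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 2) stop("annotation file needs two columns (cell_id, value)")
  val <- as.character(dt[[2]])
  names(val) <- as.character(dt[[1]])
  miss <- setdiff(x$cell_ids, names(val))
  if (length(miss))
    stop(length(miss), " cells missing from annotation file, e.g. ", miss[1])
  x[[what]] <- unname(val[x$cell_ids])
  x
}

#' @rdname read_annotations
#' @param values character vector aligned to \code{x$cell_ids} (only for write).
#' @export
write_annotations <- function(x, values, path, what = c("labels", "batches")) {
  what <- match.arg(what)
  stopifnot(length(values) == length(x$cell_ids))
  dt <- data.table::data.table(cell_id = x$cell_ids, value = values)
  data.table::setnames(dt, c("cell_id", sub("es$", "", what)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Build a gene vocabulary from a reference matrix
#'
#' The vocabulary fixes the gene-symbol-to-index map used by the embedding
#' table. Indices are 0-based and follow the reference column order; the
#' padding index is \code{n} (one past the last gene) and maps to no symbol.
#'
#' @param ref an \code{ExpressionMatrix}.
#' @return A \code{GeneVocabulary}: list with \code{symbols},
#'   \code{symbol_to_index} (0-based named integer vector), \code{n},
#'   \code{pad_index}.
#' @export
build_vocabulary <- function(ref) {
  symbols <- ref$gene_symbols
  if (length(symbols) == 0) stop("cannot build a vocabulary from 0 genes")
  idx <- seq_along(symbols) - 1L
  names(idx) <- symbols
  structure(list(symbols = symbols, symbol_to_index = idx,
                 n = length(symbols), pad_index = length(symbols)),
            class = "GeneVocabulary")
}

#' Align a query matrix to a reference vocabulary
#'
#' Columns are reordered to vocabulary order. Query genes absent from the
#' vocabulary are dropped (they have no embedding); vocabulary genes absent
#' from the query become all-zero columns, so they never enter a cell's
#' non-zero gene list. Matching is exact and case-sensitive on gene symbols.
#'
#' @param query an \code{ExpressionMatrix}.
#' @param vocab a \code{GeneVocabulary}.
#' @param verbose log a drop/zero-fill report via \code{message()}.
#' @return The aligned \code{ExpressionMatrix} with \code{ncol == vocab$n}.
#' @export
align_query <- function(query, vocab, verbose = TRUE) {
  shared <- intersect(vocab$symbols, query$gene_symbols)
  if (length(shared) == 0)
    stop("no overlap between query genes and the vocabulary (overlap count 0)")
  n_dropped <- length(setdiff(query$gene_symbols, vocab$symbols))
  n_zero <- vocab$n - length(shared)
  if (verbose && (n_dropped > 0 || n_zero > 0))
    message("align_query: dropped ", n_dropped,
            " query-only gene(s); zero-filled ", n_zero,
            " vocabulary gene(s) absent from the query")
  nc <- length(query$cell_ids)
  out <- Matrix::Matrix(0, nrow = nc, ncol = vocab$n, sparse = TRUE)
  pos <- match(shared, query$gene_symbols)
  out[, vocab$symbol_to_index[shared] + 1L] <-
    Matrix::Matrix(query$counts[, pos, drop = FALSE], sparse = TRUE)
  expression_matrix(methods::as(out, "CsparseMatrix"), vocab$symbols,
                    query$cell_ids, labels = query$labels,
                    batches = query$batches)
}

#' Build a label map from cell-type labels
#'
#' @param labels character vector of cell-type labels.
#' @return A \code{LabelMap}: list with \code{classes} (sorted unique labels)
#'   and \code{label_to_id} (0-based named integer vector).
#' @export
build_label_map <- function(labels) {
  if (length(labels) == 0) stop("no labels")
  classes <- sort(unique(as.character(labels)))
  ids <- seq_along(classes) - 1L
  names(ids) <- classes
  structure(list(classes = classes, label_to_id = ids, C = length(classes)),
            class = "LabelMap")
}

#' Write annotation predictions
#'
#' Delimited text with header \code{cell_id, predicted_label,
#' max_probability}.
#'
#' @param cell_ids,labels,probabilities equal-length vectors.
#' @param path output file.
#' @export
write_predictions <- function(cell_ids, labels, probabilities, path) {
  if (length(cell_ids) != length(labels) ||
      length(labels) != length(probabilities))
    stop("cell_ids, labels and probabilities must have equal length")
  dt <- data.table::data.table(cell_id = cell_ids, predicted_label = labels,
                               max_probability = probabilities)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read back a predictions file written by [write_predictions()]
#' @param path file path.
#' @return data.frame with cell_id, predicted_label, max_probability.
#' @export
read_predictions <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Write / read a latent matrix
#'
#' Delimited text with header \code{cell_id, z_1..z_D}. Values are written
#' with full double precision so a read-back reproduces them exactly.
#'
#' @param z cells-by-D numeric matrix.
#' @param cell_ids row identifiers, length \code{nrow(z)}.
#' @param path output file.
#' @export
write_latent <- function(z, cell_ids, path) {
  if (nrow(z) != length(cell_ids)) stop("nrow(z) != length(cell_ids)")
  dt <- data.table::data.table(cell_id = cell_ids)
  zd <- data.table::as.data.table(as.matrix(z))
  data.table::setnames(zd, paste0("z_", seq_len(ncol(z))))
  data.table::fwrite(cbind(dt, zd), path, sep = "\t")
  invisible(path)
}

#' @rdname write_latent
#' @return \code{read_latent}: list with \code{z} (matrix) and \code{cell_ids}.
#' @export
read_latent <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  z <- as.matrix(dt[, -1, with = FALSE])
  list(z = z, cell_ids = as.character(dt[[1]]))
}
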