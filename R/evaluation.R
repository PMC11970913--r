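#' Annotation accuracy and macro F1
#'
#' Accuracy is the fraction of cells with the correct predicted label.
#' Macro F1 is the unweighted mean of per-class F1 scores over the classes
#' present in the true labels; a class with zero true positives and no
#' predictions contributes F1 = 0, so never-predicted classes pull the
#' macro average down.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return list with \code{accuracy} and \code{f1_macro}.
#' @export
accuracy_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  acc <- mean(y_true == y_pred)
  f1 <- vapply(unique(y_true), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(accuracy = acc, f1_macro = mean(f1))
}

#' Adjusted Rand index between two partitions
#' @param a,b equal-length cluster label vectors.
#' @return scalar in [-1, 1]; 1 for identical partitions up to relabeling.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  mclust::adjustedRandIndex(a, b)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the label contingency table normalized by the
#' arithmetic mean of the two label entropies (0 when either partition is
#' a single cluster and the other is not informative).
#'
#' @param a,b equal-length cluster label vectors.
#' @return scalar in [0, 1].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nzero <- pij > 0
  mi <- sum(pij[nzero] * log(pij[nzero] / outer(pi, pj)[nzero]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi) + h(pj)) / 2
  if (denom == 0) return(if (mi == 0) 1 else 0)
  mi / denom
}

#' Average silhouette width
#'
#' Mean silhouette width of points under their labels, Euclidean distance.
#'
#' @param points n x D numeric matrix.
#' @param labels length-n labels (at least 2 distinct values).
#' @return scalar in [-1, 1].
#' @export
asw <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    stop("silhouette needs at least two distinct labels")
  if (length(labels) != nrow(points)) stop("length mismatch")
  sil <- cluster::silhouette(labels, stats::dist(points))
  mean(sil[, "sil_width"])
}

#' Cell-type ASW (biological conservation)
#'
#' Rescales the average silhouette width on cell-type labels from [-1, 1]
#' to [0, 1]: \code{(ASW + 1) / 2}. Higher is better conservation.
#'
#' @inheritParams asw
#' @param cell_labels per-cell type labels.
#' @return scalar in [0, 1].
#' @export
celltype_asw <- function(points, cell_labels) {
  (asw(points, cell_labels) + 1) / 2
}

#' Batch ASW (batch mixing)
#'
#' Within every cell-type group, silhouettes are computed on the batch
#' labels and folded to absolute values; a perfectly mixed group has
#' near-zero absolute widths. The score averages \code{1 - |s|} per group,
#' then across groups, so 1 means batches are indistinguishable within each
#' cell type and 0 means fully separated. Cell-type groups containing a
#' single batch (or too few cells for a silhouette) are skipped with a
#' message.
#'
#' @param points n x D latent matrix.
#' @param cell_labels per-cell type labels.
#' @param batch_labels per-cell batch labels (>= 2 batches overall).
#' @return scalar in [0, 1].
#' @export
batch_asw <- function(points, cell_labels, batch_labels) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == length(cell_labels),
            length(cell_labels) == length(batch_labels))
  if (length(unique(batch_labels)) < 2)
    stop("batch ASW needs at least two batches")
  groups <- unique(as.character(cell_labels))
  scores <- c()
  for (g in groups) {
    idx <- which(cell_labels == g)
    bl <- as.integer(factor(batch_labels[idx]))
    nb <- length(unique(bl))
    if (nb < 2 || nb >= length(idx)) {
      message("batch_asw: skipping cell type '", g,
              "' (single batch or too few cells)")
      next
    }
    sil <- cluster::silhouette(bl, stats::dist(points[idx, , drop = FALSE]))
    scores <- c(scores, mean(1 - abs(sil[, "sil_width"])))
  }
  if (length(scores) == 0)
    stop("no cell-type group had at least two batches")
  mean(scores)
}

#' Assemble a metric report
#'
#' Computes the metrics that apply to the supplied inputs: accuracy and
#' macro F1 when true and predicted labels are given; ARI and NMI when true
#' labels and cluster assignments are given; ASW variants when a latent
#' matrix is given.
#'
#' @param y_true true labels (optional).
#' @param y_pred predicted labels (optional).
#' @param clusters cluster assignments (optional).
#' @param latent latent matrix (optional).
#' @param batches batch labels (optional).
#' @return named list of computed metrics.
#' @export
metric_report <- function(y_true = NULL, y_pred = NULL, clusters = NULL,
                          latent = NULL, batches = NULL) {
  rep <- list()
  if (!is.null(y_true) && !is.null(y_pred)) {
    af <- accuracy_f1(y_true, y_pred)
    rep$accuracy <- af$accuracy
    rep$f1_macro <- af$f1_macro
  }
  if (!is.null(y_true) && !is.null(clusters)) {
    rep$ari <- ari(y_true, clusters)
    rep$nmi <- nmi(y_true, clusters)
  }
  if (!is.null(latent) && !is.null(clusters))
    rep$asw <- asw(latent, clusters)
  if (!is.null(latent) && !is.null(y_true))
    rep$celltype_asw <- celltype_asw(latent, y_true)
  if (!is.null(latent) && !is.null(y_true) && !is.null(batches))
    rep$batch_asw <- batch_asw(latent, y_true, batches)
  rep
}

#' Write a metric report as two-column delimited text
#' @param report named list from [metric_report()].
#' @param path output file.
#' @export
write_metric_report <- function(report, path) {
  dt <- data.table::data.table(metric = names(report),
                               value = unlist(report, use.names = FALSE))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
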