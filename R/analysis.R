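batched_encode <- function(model, x, batch_size = 64L,
                           capture_attention = FALSE) {
  prep <- prepare_cells(x, model$vocab)
  n <- length(prep$cells)
  Z <- matrix(0, n, model$config$D)
  attn <- if (capture_attention) vector("list", n) else NULL
  if (n > 0) {
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      e <- min(s + batch_size - 1L, n)
      batch <- collate(prep$cells[s:e], model$vocab)
      enc <- encode_cells(batch, model, capture_attention = capture_attention)
      Z[s:e, ] <- enc$Z
      if (capture_attention) attn[s:e] <- enc$attention
    }
  }
  list(Z = Z, kept = prep$kept, cell_ids = prep$cell_ids, attention = attn)
}

#' Annotate a query dataset
#'
#' Aligns the query to the model vocabulary (if needed), encodes every cell
#' and assigns the cell type with the highest classifier probability; ties
#' go to the lowest class id. Cells dropped in preprocessing (all-zero after
#' alignment) are reported with \code{NA} predictions.
#'
#' @param model a fine-tuned \code{scattn_model}.
#' @param query an \code{ExpressionMatrix}.
#' @param batch_size encoder batch size (does not change the results).
#' @param capture_attention also return per-cell attention records for
#'   critical-gene analysis.
#' @return list with \code{predictions} (data.frame: cell_id,
#'   predicted_label, max_probability; NA rows for unannotated cells),
#'   \code{probabilities} (annotated cells x C), \code{attention} (optional),
#'   \code{kept} (row indices of query that were annotated).
#' @export
annotate <- function(model, query, batch_size = 64L,
                     capture_attention = FALSE) {
  if (is.null(model$params$clf) || is.null(model$label_map))
    stop("model is not fine-tuned")
  if (!identical(query$gene_symbols, model$vocab$symbols))
    query <- align_query(query, model$vocab)
  enc <- batched_encode(model, query, batch_size, capture_attention)
  p <- classify(model, enc$Z)
  hit <- max.col(p, ties.method = "first")
  labels <- rep(NA_character_, length(query$cell_ids))
  probs <- rep(NA_real_, length(query$cell_ids))
  labels[enc$kept] <- model$label_map$classes[hit]
  probs[enc$kept] <- p[cbind(seq_along(hit), hit)]
  list(predictions = data.frame(cell_id = query$cell_ids,
                                predicted_label = labels,
                                max_probability = probs,
                                stringsAsFactors = FALSE),
       probabilities = p,
       attention = enc$attention,
       kept = enc$kept)
}

#' Extract latent representations
#'
#' Deterministic evaluation-mode encoding (no dropout); batching width does
#' not affect the values because padded keys are masked out of the attention
#' softmax.
#'
#' @param model an \code{scattn_model}.
#' @param data an \code{ExpressionMatrix}.
#' @param batch_size encoder batch size.
#' @return list with \code{z} (cells x D), \code{cell_ids}, \code{kept}.
#' @export
extract_latent <- function(model, data, batch_size = 64L) {
  if (!identical(data$gene_symbols, model$vocab$symbols))
    data <- align_query(data, model$vocab)
  enc <- batched_encode(model, data, batch_size)
  list(z = enc$Z, cell_ids = enc$cell_ids, kept = enc$kept)
}

#' Rank critical genes per cluster from attention weights
#'
#' For every cluster the per-cell attention weights are summed gene-wise:
#' \code{w_jk = sum over cells i in cluster k of attn_ij} (genes absent
#' from a cell contribute 0). Because each cell's weights sum to 1, the
#' weights of cluster k sum to the cluster size. Genes are ranked by
#' descending weight, ties broken by ascending gene index.
#'
#' @param attention list of per-cell attention records (\code{g_index},
#'   \code{weights}), e.g. from [annotate()] with
#'   \code{capture_attention = TRUE}.
#' @param clusters per-cell cluster labels, aligned to \code{attention}.
#' @param vocab a \code{GeneVocabulary}.
#' @param top_k optional cut-off per cluster (e.g. 10 for heatmaps, 100 for
#'   enrichment export); all genes with non-zero weight otherwise.
#' @return data.frame with columns cluster, rank, gene_symbol, weight.
#' @export
critical_genes <- function(attention, clusters, vocab, top_k = NULL) {
  if (length(attention) != length(clusters))
    stop("attention records and clusters must be aligned")
  out <- list()
  for (cl in sort(unique(as.character(clusters)))) {
    idx <- which(as.character(clusters) == cl)
    if (length(idx) == 0) stop("empty cluster: ", cl)
    w <- numeric(vocab$n)
    for (i in idx) {
      gi <- attention[[i]]$g_index + 1L
      w[gi] <- w[gi] + attention[[i]]$weights
    }
    ord <- order(-w, seq_along(w))
    keep <- if (is.null(top_k)) which(w[ord] > 0) else seq_len(min(top_k, vocab$n))
    ord <- ord[keep]
    out[[cl]] <- data.frame(cluster = cl, rank = seq_along(ord),
                            gene_symbol = vocab$symbols[ord],
                            weight = w[ord], stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a critical-gene table
#' @param table data.frame from [critical_genes()].
#' @param path output file (tab-delimited).
#' @export
write_critical_genes <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' Marker randomization test on critical-gene weights
#'
#' Scores how close a marker set sits to the top of a cluster's
#' attention-weight ranking. The ranking score of a gene at descending rank
#' r among n scored genes is \code{1 - (r - 1) / (n - 1)} (1 = top, 0 =
#' bottom); the set score is the mean over markers. The null distribution
#' draws \code{length(markers)} genes uniformly without replacement
#' \code{n_perm} times; the p-value is \code{(1 + #(null >= observed)) /
#' (n_perm + 1)}.
#'
#' @param cluster_weights named numeric vector, gene symbol to weight, for
#'   one cluster (all scored genes).
#' @param markers character vector of marker gene symbols (must be scored).
#' @param n_perm number of null draws (>= 99).
#' @param seed integer seed.
#' @return list with \code{score}, \code{p_value}, \code{n_perm},
#'   \code{null_scores}.
#' @export
marker_rank_test <- function(cluster_weights, markers, n_perm = 999L,
                             seed = 1L) {
  if (length(markers) == 0) stop("empty marker set")
  if (n_perm < 99) stop("n_perm must be >= 99")
  genes <- names(cluster_weights)
  missing <- setdiff(markers, genes)
  if (length(missing))
    stop("marker(s) not scored: ", paste(missing, collapse = ", "))
  n <- length(genes)
  if (n < 2) stop("need at least two scored genes")
  r <- rank(-cluster_weights, ties.method = "average")
  score_frac <- 1 - (r - 1) / (n - 1)
  names(score_frac) <- genes
  observed <- mean(score_frac[markers])
  set.seed(seed)
  k <- length(markers)
  null_scores <- vapply(seq_len(n_perm), function(i)
    mean(score_frac[sample.int(n, k)]), numeric(1))
  p <- (1 + sum(null_scores >= observed)) / (n_perm + 1)
  list(score = observed, p_value = p, n_perm = as.integer(n_perm),
       null_scores = null_scores)
}

#' Write a marker randomization test report
#'
#' One row per tested cluster: cluster, score, p_value, n_perm.
#'
#' @param results data.frame with those columns (e.g. assembled from
#'   repeated [marker_rank_test()] calls).
#' @param path output file (tab-delimited).
#' @export
write_marker_test_report <- function(results, path) {
  needed <- c("cluster", "score", "p_value", "n_perm")
  if (!all(needed %in% names(results)))
    stop("report needs columns: ", paste(needed, collapse = ", "))
  data.table::fwrite(results[, needed], path, sep = "\t")
  invisible(path)
}

#' K-Means clustering with silhouette grid search
#'
#' Runs K-Means for every k in \code{k_range} (skipping k >= number of
#' cells) and keeps the clustering with the highest average silhouette
#' width; ties go to the smaller k.
#'
#' @param latent cells x D matrix.
#' @param k_range candidate cluster counts (default 2:15).
#' @param seed integer seed.
#' @param nstart K-Means restarts per k.
#' @return list with \code{clusters} (integer vector), \code{k},
#'   \code{asw}, \code{asw_by_k}.
#' @export
kmeans_grid <- function(latent, k_range = 2:15, seed = 1L, nstart = 5L) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (n < 2) stop("clustering needs at least 2 cells")
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (length(k_range) == 0) {
    # n == 2: each point its own cluster; silhouette undefined
    return(list(clusters = seq_len(n), k = n, asw = NA_real_,
                asw_by_k = stats::setNames(NA_real_, n)))
  }
  d <- stats::dist(latent)
  best <- NULL
  asw_by_k <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    km <- stats::kmeans(latent, centers = k, nstart = nstart,
                        iter.max = 50L)
    sil <- cluster::silhouette(km$cluster, d)
    asw_k <- mean(sil[, "sil_width"])
    asw_by_k[i] <- asw_k
    if (is.null(best) || asw_k > best$asw)
      best <- list(clusters = km$cluster, k = k, asw = asw_k)
  }
  best$asw_by_k <- asw_by_k
  best
}
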