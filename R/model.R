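#' Model configuration defaults
#'
#' Architecture hyperparameters of the sparse-attention encoder.
#'
#' @param D gene/CLS embedding width.
#' @param H number of attention heads (must divide D).
#' @param N number of attention blocks.
#' @param F_hidden feed-forward hidden width.
#' @param P projection-head output width (contrastive features).
#' @param attn_scale attention logit divisor: \code{"d"} divides the raw
#'   query-key dot products by the embedding length D; \code{"sqrt_d"} uses
#'   the conventional \code{sqrt(D)}.
#' @param norm_style \code{"residual_ln"} computes X + LayerNorm(sublayer(X));
#'   \code{"pre_residual"} the conventional LayerNorm(X + sublayer(X)).
#' @param emb_dropout dropout rate on encoded gene embeddings during
#'   training; keep 0 unless integrating data with strong batch effects.
#' @return list of configuration values.
#' @export
model_config <- function(D = 64L, H = 4L, N = 2L, F_hidden = 256L, P = 64L,
                         attn_scale = c("d", "sqrt_d"),
                         norm_style = c("residual_ln", "pre_residual"),
                         emb_dropout = 0) {
  attn_scale <- match.arg(attn_scale)
  norm_style <- match.arg(norm_style)
  if (D %% H != 0) stop("D must be divisible by H")
  if (N < 1) stop("need at least one attention block")
  list(D = as.integer(D), H = as.integer(H), N = as.integer(N),
       F = as.integer(F_hidden), P = as.integer(P),
       attn_scale = attn_scale, norm_style = norm_style,
       emb_dropout = emb_dropout)
}

xavier <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_block_params <- function(D, F_hidden) {
  # Inner-product-preserving start: queries and keys share one projection
  # (E[W W^T] = I for Xavier draws), and the value/output path begins at
  # the identity, so an untrained block already computes an attention-
  # weighted mean of the value-scaled gene embeddings, with cells attending
  # to genes aligned with their own aggregate profile. Training departs
  # from this interpretable starting point.
  Wqk <- xavier(D, D)
  list(Wq = Wqk, Wk = Wqk, Wv = diag(D),
       Wo = diag(D), bo = numeric(D),
       ln1_g = rep(1, D), ln1_b = numeric(D),
       W1 = xavier(D, F_hidden), b1 = numeric(F_hidden),
       W2 = xavier(F_hidden, D), b2 = numeric(D),
       ln2_g = rep(1, D), ln2_b = numeric(D))
}

#' Initialize a sparse-attention annotation model
#'
#' Builds the parameter set: an (n+1) x D gene embedding table whose last
#' row is the frozen all-zero padding embedding, a CLS query vector drawn
#' from a standard normal, N attention blocks, a two-layer projection head
#' for contrastive features and a softmax classifier head (attached at
#' fine-tuning time once the label set is known).
#'
#' @param vocab a \code{GeneVocabulary}.
#' @param config from [model_config()].
#' @param embedding optional (n+1) x D matrix, e.g. from [pca_init()];
#'   random normal (sd 0.02) if omitted.
#' @param seed integer seed controlling all random initialization.
#' @return An object of class \code{scattn_model}.
#' @export
init_model <- function(vocab, config = model_config(), embedding = NULL,
                       seed = 1L) {
  set.seed(seed)
  D <- config$D
  if (is.null(embedding)) {
    embedding <- matrix(stats::rnorm((vocab$n + 1L) * D, sd = 0.02),
                        vocab$n + 1L, D)
    embedding[vocab$n + 1L, ] <- 0
  } else {
    if (!all(dim(embedding) == c(vocab$n + 1L, D)))
      stop("embedding must be (n+1) x D = ", vocab$n + 1L, " x ", D)
    if (any(embedding[vocab$n + 1L, ] != 0))
      stop("padding row of the embedding table must be all-zero")
  }
  params <- list(
    embedding = embedding,
    cls = stats::rnorm(D),
    blocks = lapply(seq_len(config$N),
                    function(i) init_block_params(D, config$F)),
    proj = list(W1 = xavier(D, D), b1 = numeric(D),
                W2 = xavier(D, config$P), b2 = numeric(config$P)),
    clf = NULL)
  structure(list(vocab = vocab, label_map = NULL, config = config,
                 params = params, pretrained = FALSE, finetuned = FALSE),
            class = "scattn_model")
}

#' @export
print.scattn_model <- function(x, ...) {
  cfg <- x$config
  cat("scattn_model: D =", cfg$D, "| heads =", cfg$H, "| blocks =", cfg$N,
      "| FFN =", cfg$F, "\n")
  cat("  vocabulary:", x$vocab$n, "genes (+1 pad)\n")
  if (!is.null(x$label_map))
    cat("  classifier:", x$label_map$C, "cell types\n")
  cat("  pretrained:", x$pretrained, "| finetuned:", x$finetuned, "\n")
  invisible(x)
}

#' PCA initialization of the gene embedding table
#'
#' Normalizes the reference matrix per cell (see \code{normalization}),
#' transposes it to genes-by-cells, and runs PCA across cells; each gene's
#' embedding row is its score on the top D principal components. For large
#' references a random subsample of cells is used. The padding row is zero.
#'
#' @param ref an \code{ExpressionMatrix} (columns in vocabulary order).
#' @param vocab a \code{GeneVocabulary} built from \code{ref}.
#' @param D embedding width.
#' @param n_sample number of cells used for the PCA (subsampled without
#'   replacement when the reference is larger).
#' @param seed integer seed for the subsample.
#' @param normalization \code{"lognorm"} (default) library-size-normalizes
#'   each cell to the median depth then applies log1p -- the field's
#'   standard normalization, which keeps on/off contrasts prominent while
#'   compressing the magnitude of ubiquitously high genes;
#'   \code{"mean_scale"} divides each cell's counts by the mean of its
#'   non-zero counts (the same scaling the encoder applies to values).
#' @param row_normalize scale every gene's embedding row to unit length
#'   (default TRUE). Attention logits then rank a cell's genes by
#'   expression value times directional alignment with the query instead of
#'   being dominated by the embedding-norm spread of high-variance genes;
#'   set FALSE to keep raw principal-component scores.
#' @return (n+1) x D embedding matrix suitable for [init_model()].
#' @export
pca_init <- function(ref, vocab, D = 64L, n_sample = 1000L, seed = 1L,
                     normalization = c("lognorm", "mean_scale"),
                     row_normalize = TRUE) {
  normalization <- match.arg(normalization)
  m <- as.matrix(ref$counts)
  set.seed(seed)
  if (nrow(m) > n_sample) m <- m[sample.int(nrow(m), n_sample), , drop = FALSE]
  if (D > min(ncol(m), nrow(m)))
    stop("D = ", D, " exceeds min(n_genes, n_sampled_cells) = ",
         min(ncol(m), nrow(m)))
  if (normalization == "mean_scale") {
    sc <- apply(m, 1, function(r) {
      nz <- r[r != 0]
      if (length(nz) == 0) 1 else mean(nz)
    })
    m <- m / sc
  } else {
    depth <- rowSums(m)
    depth[depth == 0] <- 1
    m <- log1p(m / depth * stats::median(depth))
  }
  g <- t(m)  # genes x cells
  if (all(apply(g, 2, stats::sd) == 0))
    stop("degenerate all-constant matrix: PCA undefined")
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE, rank. = D)
  scores <- pc$x
  if (ncol(scores) < D)
    stop("reference has rank ", ncol(scores), " < D = ", D)
  emb <- scores[, seq_len(D), drop = FALSE]
  if (row_normalize) {
    nrm <- sqrt(rowSums(emb^2))
    nrm[nrm == 0] <- 1
    emb <- emb / nrm
  }
  emb <- rbind(emb, 0)
  dimnames(emb) <- NULL
  emb
}

#' Encode gene values into embedding space
#'
#' Each batch slot receives its gene's embedding row scaled by the cell's
#' (mean-scaled) expression value; padded slots are zero vectors because the
#' padding embedding row is zero and the padded value is 0.
#'
#' @param batch a \code{PaddedBatch}.
#' @param embedding (n+1) x D embedding table.
#' @return B x M x D array.
#' @export
encode_values <- function(batch, embedding) {
  idx <- flatten_rows(batch$G_index) + 1L
  if (any(idx > nrow(embedding))) stop("gene index out of embedding range")
  flat <- embedding[idx, , drop = FALSE] * flatten_rows(batch$G_value)
  D <- ncol(embedding)
  out <- array(0, c(batch$B, batch$M, D))
  for (b in seq_len(batch$B))
    out[b, , ] <- flat[((b - 1L) * batch$M + 1L):(b * batch$M), ]
  out
}

#' One cross-attention block (forward only)
#'
#' Exposed for inspection and testing; training uses the internal fused
#' forward/backward path. Computes per-head attention of the query states
#' over the unmasked key/value slots, concatenates heads through the output
#' projection, then applies the residual LayerNorm and feed-forward
#' sublayers.
#'
#' @param query_states B x D matrix.
#' @param keys_values B x M x D array (from [encode_values()]).
#' @param key_mask B x M logical, TRUE = real gene.
#' @param block_params one element of \code{model$params$blocks}.
#' @param config from [model_config()].
#' @param return_attention also return the B x H x M attention weights.
#' @return list with \code{Z} (B x D) and optionally \code{attention}.
#' @export
attention_block <- function(query_states, keys_values, key_mask, block_params,
                            config, return_attention = FALSE) {
  B <- dim(keys_values)[1]; M <- dim(keys_values)[2]; D <- dim(keys_values)[3]
  if (!all(rowSums(key_mask) >= 1)) stop("every row needs >= 1 unmasked key")
  E <- matrix(0, B * M, D)
  for (b in seq_len(B))
    E[((b - 1L) * M + 1L):(b * M), ] <- keys_values[b, , ]
  out <- block_forward(query_states, E, flatten_rows(key_mask), M,
                       block_params, config)
  res <- list(Z = out$Z)
  if (return_attention) {
    att <- array(0, c(B, config$H, M))
    for (h in seq_len(config$H)) att[, h, ] <- t(out$cache$heads[[h]]$aM)
    res$attention <- att
  }
  res
}

#' Encode a padded batch of cells into latent vectors
#'
#' Block 1 uses the CLS embedding as the query; blocks 2..N use the previous
#' block's output, all attending over the same encoded gene embeddings. The
#' final block's output rows are the per-cell latent representations.
#'
#' @param batch a \code{PaddedBatch}.
#' @param model an \code{scattn_model}.
#' @param capture_attention also return per-cell attention weights (final
#'   block, averaged over heads, renormalized over the cell's real genes).
#' @return list with \code{Z} (B x D) and, if requested, \code{attention}
#'   (list per cell of \code{g_index} and \code{weights}).
#' @export
encode_cells <- function(batch, model, capture_attention = FALSE) {
  fwd <- encoder_forward(model$params, batch, model$config,
                         training = FALSE,
                         capture_attention = capture_attention)
  list(Z = fwd$Z, attention = fwd$attn)
}

#' Projection head: nonlinear contrastive features
#' @param model an \code{scattn_model}.
#' @param z cells x D latent matrix.
#' @return cells x P feature matrix.
#' @export
project <- function(model, z) project_forward(model$params$proj, z)$S

#' Classifier head: cell-type probabilities
#' @param model a fine-tuned \code{scattn_model}.
#' @param z cells x D latent matrix.
#' @return cells x C matrix of softmax probabilities (rows sum to 1).
#' @export
classify <- function(model, z) {
  if (is.null(model$params$clf))
    stop("model has no classifier head; run finetune() first")
  classify_forward(model$params$clf, z)$p
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the vocabulary, label
#' map, embedding table, encoder and head parameters and the configuration;
#' save then load round-trips bit-exactly.
#'
#' @param model an \code{scattn_model}.
#' @param path checkpoint file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @return \code{load_model}: the restored \code{scattn_model}.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "scattn_model"))
    stop("file is not an scattn model checkpoint: ", path)
  model
}
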