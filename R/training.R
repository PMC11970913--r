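#' Cosine similarity between two vectors
#' @param u,v non-zero numeric vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  sum(u * v) / (nu * nv)
}

# NT-Xent forward (+ optional gradient wrt the raw feature rows).
# features: 2B x P; rows i and i+B are a positive pair.
nt_xent <- function(features, tau, grad = FALSE) {
  n <- nrow(features)
  if (n %% 2 != 0) stop("feature matrix must have 2B rows")
  B <- n %/% 2
  if (B < 2) stop("contrastive loss needs batch size >= 2 (no negatives)")
  norms <- sqrt(rowSums(features^2))
  if (any(norms == 0)) stop("zero feature row in contrastive batch")
  U <- features / norms
  S <- tcrossprod(U) / tau
  diag(S) <- -Inf
  pos <- c((B + 1):n, 1:B)
  mx <- apply(S, 1, max)
  ex <- exp(S - mx)
  den <- rowSums(ex)
  logp <- S[cbind(1:n, pos)] - mx - log(den)
  loss <- -mean(logp)
  if (!grad) return(list(loss = loss))
  P <- ex / den
  G <- P
  G[cbind(1:n, pos)] <- G[cbind(1:n, pos)] - 1
  G <- G / (n * tau)
  dU <- (G + t(G)) %*% U
  dF <- (dU - U * rowSums(dU * U)) / norms
  list(loss = loss, dF = dF)
}

#' Normalized-temperature cross-entropy (InfoNCE) contrastive loss
#'
#' Rows i and i+B of \code{features} are the two augmented views of cell i
#' (a positive pair); all other rows in the doubled batch act as negatives.
#' Each anchor's loss is \code{-log} of the softmax (over the 2B-1 other
#' rows, at temperature \code{tau}) of its positive's cosine similarity;
#' the total is the mean over all 2B anchors, which symmetrizes the pair
#' directions.
#'
#' @param features 2B x P numeric matrix of projection-head outputs.
#' @param tau temperature (> 0), default 0.1.
#' @return scalar loss >= 0 (up to numerical rounding at the optimum).
#' @export
info_nce_loss <- function(features, tau = 0.1) {
  nt_xent(as.matrix(features), tau)$loss
}

#' Cross-entropy loss of predicted class probabilities
#'
#' @param p B x C matrix of probabilities, rows summing to 1.
#' @param y integer class ids in [0, C).
#' @return scalar mean negative log-likelihood.
#' @export
cross_entropy_loss <- function(p, y) {
  p <- as.matrix(p)
  if (nrow(p) != length(y)) stop("nrow(p) != length(y)")
  if (any(y < 0 | y >= ncol(p))) stop("label outside [0, C)")
  -mean(log(p[cbind(seq_len(nrow(p)), y + 1L)]))
}

#' Stratified train/test split
#'
#' Samples \code{max(1, round(fraction * class_size))} cells from every
#' class into the training set; the remainder is the test set. The two index
#' sets are disjoint and exhaustive.
#'
#' @param labels per-cell labels.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer vectors \code{train} and \code{test} (1-based).
#' @export
stratified_split <- function(labels, fraction, seed = 1L) {
  if (length(labels) == 0) stop("empty labels")
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- max(1L, round(fraction * length(idx)))
    train <- c(train, if (length(idx) == 1L) idx else
      sample(idx, min(k, length(idx))))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Contrastive pre-training configuration
#' @param mask_rate gene masking probability for the augmented view.
#' @param tau NT-Xent temperature.
#' @param batch_size,epochs,lr,seed optimization settings.
#' @return list of settings.
#' @export
contrastive_config <- function(mask_rate = 0.15, tau = 0.1, batch_size = 32L,
                               epochs = 5L, lr = 1e-3, seed = 1L) {
  stopifnot(mask_rate >= 0, mask_rate < 1, tau > 0)
  list(mask_rate = mask_rate, tau = tau, batch_size = as.integer(batch_size),
       epochs = as.integer(epochs), lr = lr, seed = as.integer(seed))
}

#' Fine-tuning configuration
#' @param epochs,batch_size,lr,seed optimization settings.
#' @param preset \code{"short"} fixes one pre-training epoch and ten
#'   fine-tuning epochs (the fast budget); \code{"default"} leaves epochs
#'   as given.
#' @return list of settings.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, lr = 1e-3,
                         seed = 1L, preset = c("default", "short")) {
  preset <- match.arg(preset)
  if (preset == "short") epochs <- 10L
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, seed = as.integer(seed), preset = preset)
}

# ---- Adam over a nested parameter list -------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) {
      if (is.null(names(v))) names(v) <- seq_along(v)
      out <- c(out, flatten_params(v, key))
    } else if (!is.null(v)) out[[key]] <- v
  }
  out
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    flat[[k]] <- flat[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

unflatten_params <- function(flat, skeleton, prefix = "") {
  for (nm in names(skeleton)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    v <- skeleton[[nm]]
    if (is.list(v)) {
      if (is.null(names(v))) names(v) <- seq_along(v)
      skeleton[[nm]] <- unflatten_params(flat, v, key)
      if (is.null(names(v)) || all(names(v) == seq_along(v)))
        names(skeleton[[nm]]) <- NULL
    } else if (!is.null(v)) skeleton[[nm]] <- flat[[key]]
  }
  skeleton
}

# ---- training loops --------------------------------------------------------

make_batches <- function(n, batch_size, shuffle = TRUE) {
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Contrastive pre-training
#'
#' For every batch, an augmented view of each cell is built by randomly
#' masking its non-zero genes; both views pass through the shared encoder
#' and projection head, and the NT-Xent loss pulls the two views of a cell
#' together against the other cells in the batch. All parameters, including
#' the gene embeddings, are updated with Adam. Batches of size 1 are
#' skipped (they have no negatives).
#'
#' @param model an \code{scattn_model}.
#' @param data an \code{ExpressionMatrix} aligned to the model vocabulary
#'   (labels not required).
#' @param cfg from [contrastive_config()].
#' @param verbose log per-epoch losses via \code{message()}.
#' @return The updated model, with a \code{pretrain_log} attribute holding
#'   per-epoch mean losses.
#' @export
pretrain <- function(model, data, cfg = contrastive_config(),
                     verbose = FALSE) {
  prep <- prepare_cells(data, model$vocab)
  cells <- prep$cells
  if (length(cells) == 0) stop("no usable cells for pre-training")
  set.seed(cfg$seed)
  params <- model$params
  params$clf <- NULL
  flat <- flatten_params(params)
  state <- adam_init(flat)
  pad_key <- "embedding"
  epoch_losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    batches <- make_batches(length(cells), cfg$batch_size)
    losses <- c()
    for (bi in batches) {
      if (length(bi) < 2) next
      orig <- cells[bi]
      masked <- lapply(orig, random_mask, rate = cfg$mask_rate)
      params <- unflatten_params(flat, params)
      b1 <- collate(orig, model$vocab)
      b2 <- collate(masked, model$vocab)
      f1 <- encoder_forward(params, b1, model$config, training = TRUE)
      f2 <- encoder_forward(params, b2, model$config, training = TRUE)
      p1 <- project_forward(params$proj, f1$Z)
      p2 <- project_forward(params$proj, f2$Z)
      feats <- rbind(p1$S, p2$S)
      nx <- nt_xent(feats, cfg$tau, grad = TRUE)
      losses <- c(losses, nx$loss)
      B <- length(bi)
      pb1 <- project_backward(params$proj, p1, nx$dF[seq_len(B), , drop = FALSE])
      pb2 <- project_backward(params$proj, p2,
                              nx$dF[(B + 1):(2 * B), , drop = FALSE])
      e1 <- encoder_backward(params, f1, pb1$dZ, model$config)
      e2 <- encoder_backward(params, f2, pb2$dZ, model$config)
      grads <- list(
        embedding = e1$embedding + e2$embedding,
        cls = e1$cls + e2$cls,
        blocks = lapply(seq_len(model$config$N), function(k)
          mapply(`+`, e1$blocks[[k]], e2$blocks[[k]], SIMPLIFY = FALSE)),
        proj = mapply(`+`, pb1$grads, pb2$grads, SIMPLIFY = FALSE))
      gflat <- flatten_params(grads)
      upd <- adam_step(flat, gflat, state, cfg$lr)
      flat <- upd$flat
      state <- upd$state
      flat[[pad_key]][nrow(flat[[pad_key]]), ] <- 0
    }
    epoch_losses[ep] <- mean(losses)
    if (verbose)
      message(sprintf("pretrain epoch %d/%d: loss %.4f", ep, cfg$epochs,
                      epoch_losses[ep]))
  }
  clf <- model$params$clf
  model$params <- unflatten_params(flat, params)
  model$params$clf <- clf
  model$pretrained <- TRUE
  attr(model, "pretrain_log") <- epoch_losses
  model
}

#' Supervised fine-tuning
#'
#' Attaches (or reuses) a softmax classifier head and minimizes the
#' cross-entropy of the predicted cell-type probabilities over the labeled
#' cells. All encoder parameters and the embeddings are updated; the
#' projection head is kept in the checkpoint but not touched.
#'
#' @param model an \code{scattn_model}.
#' @param data a labeled \code{ExpressionMatrix} aligned to the vocabulary.
#' @param cfg from [train_config()].
#' @param label_map optional pre-built \code{LabelMap}; built from the data
#'   labels otherwise.
#' @param verbose log per-epoch loss/accuracy.
#' @return The updated model with a \code{finetune_log} attribute (matrix of
#'   per-epoch loss and training accuracy).
#' @export
finetune <- function(model, data, cfg = train_config(), label_map = NULL,
                     verbose = FALSE) {
  if (is.null(data$labels)) stop("fine-tuning requires labeled cells")
  if (is.null(label_map)) label_map <- build_label_map(data$labels)
  unseen <- setdiff(unique(data$labels), label_map$classes)
  if (length(unseen))
    stop("label(s) not in the label map: ", paste(unseen, collapse = ", "))
  prep <- prepare_cells(data, model$vocab)
  cells <- prep$cells
  y <- unname(label_map$label_to_id[data$labels[prep$kept]])
  set.seed(cfg$seed)
  D <- model$config$D; C <- label_map$C
  params <- model$params
  if (is.null(params$clf) || ncol(params$clf$W) != C)
    params$clf <- list(W = xavier(D, C), b = numeric(C))
  proj <- params$proj
  params$proj <- NULL  # frozen during fine-tuning
  flat <- flatten_params(params)
  state <- adam_init(flat)
  log <- matrix(NA_real_, cfg$epochs, 2,
                dimnames = list(NULL, c("loss", "accuracy")))
  if (cfg$epochs > 0) for (ep in seq_len(cfg$epochs)) {
    batches <- make_batches(length(cells), cfg$batch_size)
    tot_loss <- 0; tot_correct <- 0; tot_n <- 0
    for (bi in batches) {
      params <- unflatten_params(flat, params)
      batch <- collate(cells[bi], model$vocab)
      fwd <- encoder_forward(params, batch, model$config, training = TRUE)
      cf <- classify_forward(params$clf, fwd$Z)
      yi <- y[bi]
      loss <- cross_entropy_loss(cf$p, yi)
      onehot <- matrix(0, length(bi), C)
      onehot[cbind(seq_along(bi), yi + 1L)] <- 1
      dlogits <- (cf$p - onehot) / length(bi)
      cb <- classify_backward(params$clf, cf, dlogits)
      eb <- encoder_backward(params, fwd, cb$dZ, model$config)
      grads <- list(embedding = eb$embedding, cls = eb$cls,
                    blocks = eb$blocks, clf = cb$grads)
      upd <- adam_step(flat, flatten_params(grads), state, cfg$lr)
      flat <- upd$flat
      state <- upd$state
      flat$embedding[nrow(flat$embedding), ] <- 0
      tot_loss <- tot_loss + loss * length(bi)
      tot_correct <- tot_correct + sum(max.col(cf$p, "first") == yi + 1L)
      tot_n <- tot_n + length(bi)
    }
    log[ep, ] <- c(tot_loss / tot_n, tot_correct / tot_n)
    if (verbose)
      message(sprintf("finetune epoch %d/%d: loss %.4f acc %.4f",
                      ep, cfg$epochs, log[ep, 1], log[ep, 2]))
  }
  model$params <- unflatten_params(flat, params)
  model$params$proj <- proj
  model$label_map <- label_map
  model$finetuned <- cfg$epochs > 0 || model$finetuned
  attr(model, "finetune_log") <- log
  model
}
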