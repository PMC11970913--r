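# Low-level neural network layers: forward passes with caches and matching
# hand-derived backward passes. Everything operates on plain base-R matrices.
#
# Flat layout convention: a padded batch of B cells with M key slots each is
# flattened to a (B*M) x D matrix whose rows are ordered cell-major, slot
# fastest: flat row (b-1)*M + m is slot m of cell b. Under this ordering
# matrix(v, M, B) reshapes a flat vector into one column per cell.

.ln_eps <- 1e-5

flatten_rows <- function(m) as.vector(t(m))

ln_forward <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  s2 <- rowMeans(xc * xc)
  inv <- 1 / sqrt(s2 + .ln_eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, gamma, "*")
  y <- sweep(y, 2, beta, "+")
  list(y = y, xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Masked per-cell softmax over flattened logits (length B*M). Returns the
# attention matrix in M x B orientation (one column per cell).
masked_softmax <- function(logits, maskv, M, B) {
  lm <- matrix(logits, M, B)
  lm[matrix(!maskv, M, B)] <- -Inf
  mx <- apply(lm, 2, max)
  w <- exp(sweep(lm, 2, mx))
  w[!is.finite(w)] <- 0
  sweep(w, 2, colSums(w), "/")
}

# One cross-attention block. Xq: B x D query states. E: (B*M) x D encoded
# key/value gene embeddings. maskv: flat logical, TRUE = real gene.
# cfg: list(D, H, attn_scale, norm_style). Returns Z (B x D) and a cache.
block_forward <- function(Xq, E, maskv, M, prm, cfg) {
  B <- nrow(Xq); D <- cfg$D; H <- cfg$H; dh <- D %/% H
  scale <- if (identical(cfg$attn_scale, "sqrt_d")) sqrt(D) else D
  cg <- rep(seq_len(B), each = M)
  heads <- vector("list", H)
  A <- matrix(0, B, D)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Q <- Xq %*% prm$Wq[, cols, drop = FALSE]
    K <- E %*% prm$Wk[, cols, drop = FALSE]
    V <- E %*% prm$Wv[, cols, drop = FALSE]
    logits <- rowSums(K * Q[cg, , drop = FALSE]) / scale
    aM <- masked_softmax(logits, maskv, M, B)
    af <- as.vector(aM)
    hout <- rowsum(V * af, cg)
    A[, cols] <- hout
    heads[[h]] <- list(Q = Q, K = K, V = V, aM = aM, af = af)
  }
  Oatt <- sweep(A %*% prm$Wo, 2, prm$bo, "+")
  if (identical(cfg$norm_style, "pre_residual")) {
    # conventional post-norm: O = LayerNorm(Xq + Oatt)
    ln1 <- ln_forward(Xq + Oatt, prm$ln1_g, prm$ln1_b)
    O <- ln1$y
  } else {
    # paper-literal: O = Xq + LayerNorm(Oatt)
    ln1 <- ln_forward(Oatt, prm$ln1_g, prm$ln1_b)
    O <- Xq + ln1$y
  }
  H1 <- sweep(O %*% prm$W1, 2, prm$b1, "+")
  Hr <- pmax(H1, 0)
  Z2 <- sweep(Hr %*% prm$W2, 2, prm$b2, "+")
  if (identical(cfg$norm_style, "pre_residual")) {
    ln2 <- ln_forward(O + Z2, prm$ln2_g, prm$ln2_b)
    Z <- ln2$y
  } else {
    ln2 <- ln_forward(Z2, prm$ln2_g, prm$ln2_b)
    Z <- O + ln2$y
  }
  list(Z = Z,
       cache = list(Xq = Xq, E = E, maskv = maskv, M = M, B = B, cg = cg,
                    heads = heads, A = A, ln1 = ln1, O = O, H1 = H1, Hr = Hr,
                    ln2 = ln2, scale = scale))
}

block_backward <- function(dZ, cache, prm, cfg) {
  D <- cfg$D; H <- cfg$H; dh <- D %/% H
  B <- cache$B; M <- cache$M; cg <- cache$cg
  pre <- identical(cfg$norm_style, "pre_residual")
  if (pre) {
    l2 <- ln_backward(dZ, cache$ln2, prm$ln2_g)
    dO <- l2$dx; dZ2 <- l2$dx
  } else {
    l2 <- ln_backward(dZ, cache$ln2, prm$ln2_g)
    dO <- dZ; dZ2 <- l2$dx
  }
  dW2 <- crossprod(cache$Hr, dZ2)
  db2 <- colSums(dZ2)
  dHr <- tcrossprod(dZ2, prm$W2)
  dH1 <- dHr * (cache$H1 > 0)
  dW1 <- crossprod(cache$O, dH1)
  db1 <- colSums(dH1)
  dO <- dO + tcrossprod(dH1, prm$W1)
  if (pre) {
    l1 <- ln_backward(dO, cache$ln1, prm$ln1_g)
    dXq <- l1$dx; dOatt <- l1$dx
  } else {
    l1 <- ln_backward(dO, cache$ln1, prm$ln1_g)
    dXq <- dO; dOatt <- l1$dx
  }
  dWo <- crossprod(cache$A, dOatt)
  dbo <- colSums(dOatt)
  dA <- tcrossprod(dOatt, prm$Wo)
  dWq <- matrix(0, D, D); dWk <- matrix(0, D, D); dWv <- matrix(0, D, D)
  dE <- matrix(0, nrow(cache$E), D)
  Xq <- cache$Xq; E <- cache$E
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    hd <- cache$heads[[h]]
    dhout <- dA[, cols, drop = FALSE]
    dhout_f <- dhout[cg, , drop = FALSE]
    dV <- hd$af * dhout_f
    da <- rowSums(hd$V * dhout_f)
    daM <- matrix(da, M, B)
    s <- colSums(hd$aM * daM)
    dlog <- hd$aM * sweep(daM, 2, s)
    dlogf <- as.vector(dlog) / cache$scale
    dQ <- rowsum(hd$K * dlogf, cg)
    dK <- hd$Q[cg, , drop = FALSE] * dlogf
    dWq[, cols] <- crossprod(Xq, dQ)
    dWk[, cols] <- crossprod(E, dK)
    dWv[, cols] <- crossprod(E, dV)
    dXq <- dXq + tcrossprod(dQ, prm$Wq[, cols, drop = FALSE])
    dE <- dE + tcrossprod(dK, prm$Wk[, cols, drop = FALSE]) +
      tcrossprod(dV, prm$Wv[, cols, drop = FALSE])
  }
  grads <- list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo, bo = dbo,
                ln1_g = l1$dgamma, ln1_b = l1$dbeta,
                W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                ln2_g = l2$dgamma, ln2_b = l2$dbeta)
  list(dXq = dXq, dE = dE, grads = grads)
}

# Full encoder forward over a PaddedBatch. Block 1 queries with the CLS
# embedding; later blocks query with the previous block's output; all blocks
# attend over the same encoded gene embeddings E.
encoder_forward <- function(params, batch, cfg, training = FALSE,
                            capture_attention = FALSE, dropout_mask = NULL) {
  B <- batch$B; M <- batch$M; D <- cfg$D
  idx <- flatten_rows(batch$G_index) + 1L
  val <- flatten_rows(batch$G_value)
  E <- params$embedding[idx, , drop = FALSE] * val
  drop_mask <- NULL
  if (training && cfg$emb_dropout > 0) {
    if (is.null(dropout_mask)) {
      drop_mask <- matrix(
        (stats::runif(length(E)) >= cfg$emb_dropout) / (1 - cfg$emb_dropout),
        nrow(E), ncol(E))
    } else drop_mask <- dropout_mask
    E <- E * drop_mask
  }
  maskv <- flatten_rows(batch$key_mask)
  Xq <- matrix(params$cls, B, D, byrow = TRUE)
  caches <- vector("list", cfg$N)
  for (k in seq_len(cfg$N)) {
    out <- block_forward(Xq, E, maskv, M, params$blocks[[k]], cfg)
    caches[[k]] <- out$cache
    Xq <- out$Z
  }
  attn <- NULL
  if (capture_attention) {
    hb <- caches[[cfg$N]]$heads
    aMean <- Reduce(`+`, lapply(hb, `[[`, "aM")) / cfg$H
    attn <- lapply(seq_len(B), function(b) {
      L <- batch$lengths[b]
      w <- aMean[seq_len(L), b]
      w <- w / sum(w)
      list(g_index = batch$G_index[b, seq_len(L)], weights = w)
    })
  }
  list(Z = Xq, caches = caches, E = E, idx = idx, val = val,
       drop_mask = drop_mask, attn = attn)
}

# Backward through the encoder. dZ: gradient at the final latent matrix.
# Returns gradients for the embedding table (pad row zeroed), CLS vector and
# every block.
encoder_backward <- function(params, fwd, dZ, cfg) {
  dE_total <- matrix(0, nrow(fwd$E), cfg$D)
  block_grads <- vector("list", cfg$N)
  dX <- dZ
  for (k in rev(seq_len(cfg$N))) {
    bk <- block_backward(dX, fwd$caches[[k]], params$blocks[[k]], cfg)
    block_grads[[k]] <- bk$grads
    dE_total <- dE_total + bk$dE
    dX <- bk$dXq
  }
  dcls <- colSums(dX)
  if (!is.null(fwd$drop_mask)) dE_total <- dE_total * fwd$drop_mask
  demb <- matrix(0, nrow(params$embedding), cfg$D)
  contrib <- dE_total * fwd$val
  agg <- rowsum(contrib, fwd$idx)
  rows <- as.integer(rownames(agg))
  demb[rows, ] <- agg
  demb[nrow(demb), ] <- 0  # pad row stays frozen at zero
  list(embedding = demb, cls = dcls, blocks = block_grads)
}

relu <- function(x) pmax(x, 0)

project_forward <- function(prm, Z) {
  S1 <- sweep(Z %*% prm$W1, 2, prm$b1, "+")
  Sr <- relu(S1)
  S <- sweep(Sr %*% prm$W2, 2, prm$b2, "+")
  list(S = S, S1 = S1, Sr = Sr, Z = Z)
}

project_backward <- function(prm, cache, dS) {
  dW2 <- crossprod(cache$Sr, dS)
  db2 <- colSums(dS)
  dSr <- tcrossprod(dS, prm$W2)
  dS1 <- dSr * (cache$S1 > 0)
  dW1 <- crossprod(cache$Z, dS1)
  db1 <- colSums(dS1)
  dZ <- tcrossprod(dS1, prm$W1)
  list(dZ = dZ, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

softmax_rows <- function(x) {
  mx <- apply(x, 1, max)
  e <- exp(x - mx)
  e / rowSums(e)
}

classify_forward <- function(prm, Z) {
  logits <- sweep(Z %*% prm$W, 2, prm$b, "+")
  list(p = softmax_rows(logits), logits = logits, Z = Z)
}

# dlogits is supplied by the loss (softmax+CE fuse); returns dZ and grads.
classify_backward <- function(prm, cache, dlogits) {
  dW <- crossprod(cache$Z, dlogits)
  db <- colSums(dlogits)
  dZ <- tcrossprod(dlogits, prm$W)
  list(dZ = dZ, grads = list(W = dW, b = db))
}
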