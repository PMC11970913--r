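# Shared fixtures and independent straight-line oracles for the test suite.
# Expensive objects (simulated datasets, trained models) are memoised in
# .fixture_cache so multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

make_cell <- function(idx, val) {
  structure(list(g_index = as.integer(idx), g_value = as.numeric(val)),
            class = "SparseCell")
}

toy_vocab <- function(n) {
  n <- as.integer(n)
  syms <- paste0("g", seq_len(n))
  idx <- seq_len(n) - 1L
  names(idx) <- syms
  structure(list(symbols = syms, symbol_to_index = idx, n = n,
                 pad_index = n), class = "GeneVocabulary")
}

random_expression <- function(n_cells, n_genes, seed = 1, max_count = 9L) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, 2), n_cells, n_genes)
  m[1, ] <- pmax(m[1, ], 1L)  # guarantee no all-zero cell
  expression_matrix(m, paste0("g", seq_len(n_genes)),
                    paste0("c", seq_len(n_cells)))
}

tiny_sim <- function() cache_get("tiny_sim", function() make_fixture("tiny"))

# A small trained model on the tiny fixture, shared by analysis/cli tests.
tiny_trained <- function() cache_get("tiny_trained", function() {
  sim <- tiny_sim()
  x <- sim$data
  vocab <- build_vocabulary(x)
  emb <- pca_init(x, vocab, D = 16L, n_sample = 40L, seed = 1L)
  model <- init_model(vocab, model_config(D = 16L, H = 2L, N = 2L,
                                          F_hidden = 32L, P = 16L),
                      embedding = emb, seed = 1L)
  model <- pretrain(model, x, contrastive_config(epochs = 1L, batch_size = 16L,
                                                 seed = 1L))
  finetune(model, x, train_config(epochs = 15L, batch_size = 16L, seed = 1L))
})

# Full study pipeline on a simulated dataset: PCA-initialized embeddings,
# one-epoch contrastive pre-training, short fine-tuning on a 10% stratified
# split, annotation of the held-out cells.
run_benchmark <- function(sim, seed, pretrain_epochs = 1L,
                          preset = "short", capture_attention = FALSE) {
  x <- sim$data
  vocab <- build_vocabulary(x)
  emb <- pca_init(x, vocab, D = 64L, n_sample = 1000L, seed = seed)
  model <- init_model(vocab, model_config(), embedding = emb, seed = seed)
  model <- pretrain(model, x,
                    contrastive_config(epochs = pretrain_epochs, seed = seed))
  sp <- stratified_split(x$labels, 0.1, seed = seed)
  tr <- expression_matrix(x$counts[sp$train, ], x$gene_symbols,
                          x$cell_ids[sp$train], labels = x$labels[sp$train])
  te <- expression_matrix(x$counts[sp$test, ], x$gene_symbols,
                          x$cell_ids[sp$test], labels = x$labels[sp$test])
  model <- finetune(model, tr, train_config(preset = preset, seed = seed))
  ann <- annotate(model, te, capture_attention = capture_attention)
  list(model = model, sim = sim, train = tr, test = te, ann = ann,
       split = sp)
}

separable5_run <- function(seed) {
  cache_get(paste0("sep5_run_", seed), function() {
    run_benchmark(make_fixture("separable5", seed = seed), seed = seed,
                  capture_attention = (seed == 1L))
  })
}

# ---- independent oracles ---------------------------------------------------

# Straight-line dense implementation of one attention block, written
# directly from the per-head equations with explicit loops.
oracle_block <- function(Xq, KV, mask, prm, cfg) {
  B <- dim(KV)[1]; M <- dim(KV)[2]; D <- dim(KV)[3]
  H <- cfg$H; dh <- D / H
  scale <- if (identical(cfg$attn_scale, "sqrt_d")) sqrt(D) else D
  eps <- 1e-5
  ln <- function(x, g, b) {
    mu <- mean(x); s2 <- mean((x - mu)^2)
    ((x - mu) / sqrt(s2 + eps)) * g + b
  }
  Z <- matrix(0, B, D)
  for (b in seq_len(B)) {
    concat <- numeric(0)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      q <- as.numeric(Xq[b, ] %*% prm$Wq[, cols])
      logits <- rep(-Inf, M)
      for (m in seq_len(M)) if (mask[b, m]) {
        k <- as.numeric(KV[b, m, ] %*% prm$Wk[, cols])
        logits[m] <- sum(q * k) / scale
      }
      a <- exp(logits - max(logits))
      a <- a / sum(a)
      head_out <- numeric(dh)
      for (m in seq_len(M)) if (mask[b, m]) {
        v <- as.numeric(KV[b, m, ] %*% prm$Wv[, cols])
        head_out <- head_out + a[m] * v
      }
      concat <- c(concat, head_out)
    }
    Oatt <- as.numeric(concat %*% prm$Wo) + prm$bo
    O <- Xq[b, ] + ln(Oatt, prm$ln1_g, prm$ln1_b)
    H1 <- pmax(as.numeric(O %*% prm$W1) + prm$b1, 0)
    Z2 <- as.numeric(H1 %*% prm$W2) + prm$b2
    Z[b, ] <- O + ln(Z2, prm$ln2_g, prm$ln2_b)
  }
  Z
}

# Straight-line batch ASW: silhouettes on batch labels within each cell
# type, absolute widths, averaged as 1 - |s| per group then across groups.
oracle_batch_asw <- function(points, cell_labels, batch_labels) {
  dmat <- as.matrix(dist(points))
  scores <- c()
  for (g in unique(cell_labels)) {
    idx <- which(cell_labels == g)
    bl <- batch_labels[idx]
    if (length(unique(bl)) < 2 || length(unique(bl)) >= length(idx)) next
    s <- numeric(length(idx))
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      own <- idx[bl == bl[ii] & idx != i]
      if (length(idx[bl == bl[ii]]) == 1) { s[ii] <- 0; next }
      a <- mean(dmat[i, own])
      b <- min(vapply(setdiff(unique(bl), bl[ii]), function(ob)
        mean(dmat[i, idx[bl == ob]]), numeric(1)))
      s[ii] <- (b - a) / max(a, b)
    }
    scores <- c(scores, mean(1 - abs(s)))
  }
  mean(scores)
}

# Covariance eigendecomposition oracle for the PCA embedding: normalize the
# cell matrix the same declared way, transpose to genes x cells, center the
# cell dimension, project onto covariance eigenvectors.
oracle_pca_scores <- function(m, D, normalization = "mean_scale") {
  if (normalization == "mean_scale") {
    sc <- apply(m, 1, function(r) { nz <- r[r != 0]
      if (length(nz) == 0) 1 else mean(nz) })
    m <- m / sc
  } else {
    depth <- rowSums(m); depth[depth == 0] <- 1
    m <- log1p(m / depth * median(depth))
  }
  g <- t(m)
  gc <- sweep(g, 2, colMeans(g))
  cv <- crossprod(gc) / (nrow(gc) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  gc %*% ev$vectors[, seq_len(D), drop = FALSE]
}

expect_same_up_to_sign <- function(a, b, tol = 1e-6) {
  expect_equal(dim(a), dim(b))
  for (j in seq_len(ncol(a))) {
    d1 <- max(abs(a[, j] - b[, j]))
    d2 <- max(abs(a[, j] + b[, j]))
    expect_lt(min(d1, d2), tol)
  }
}
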