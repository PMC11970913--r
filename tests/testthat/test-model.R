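test_that("pca_init embeddings match the covariance eigendecomposition", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(rpois(20 * 10, 4) + 1, 20, 10)
    x <- expression_matrix(m, paste0("g", 1:10), paste0("c", 1:20))
    vocab <- build_vocabulary(x)
    for (norm in c("mean_scale", "lognorm")) {
      emb <- pca_init(x, vocab, D = 5L, n_sample = 20L, seed = seed,
                      normalization = norm, row_normalize = FALSE)
      ref <- oracle_pca_scores(m, 5L, normalization = norm)
      expect_same_up_to_sign(emb[1:10, ], ref, tol = 1e-6)
      expect_equal(emb[11, ], rep(0, 5))
    }
  }
})

test_that("pca_init on a rank-1 matrix concentrates variance on PC1", {
  u <- c(1, 2, 3, 4, 5, 6)
  w <- c(2, 1, 3, 1)
  m <- outer(w, u)  # 4 cells x 6 genes, rank 1
  x <- expression_matrix(m, paste0("g", 1:6), paste0("c", 1:4))
  vocab <- build_vocabulary(x)
  emb <- pca_init(x, vocab, D = 2L, n_sample = 4L, seed = 1,
                  normalization = "mean_scale", row_normalize = FALSE)
  # all variance on component 1; component 2 numerically zero
  expect_gt(sum(emb[1:6, 1]^2), 1e-6)
  expect_lt(sum(emb[1:6, 2]^2), 1e-12 * sum(emb[1:6, 1]^2))
})

test_that("pca_init is deterministic given a seed and validates D", {
  x <- random_expression(30, 12, seed = 3)
  vocab <- build_vocabulary(x)
  e1 <- pca_init(x, vocab, D = 6L, n_sample = 20L, seed = 5)
  e2 <- pca_init(x, vocab, D = 6L, n_sample = 20L, seed = 5)
  expect_identical(e1, e2)
  expect_error(pca_init(x, vocab, D = 40L, seed = 1), "exceeds")
  const <- expression_matrix(matrix(2, 5, 4), paste0("g", 1:4), paste0("c", 1:5))
  expect_error(pca_init(const, build_vocabulary(const), D = 2L,
                        normalization = "mean_scale"), "degenerate")
})

test_that("row-normalized embeddings have unit gene rows", {
  x <- random_expression(30, 12, seed = 3)
  vocab <- build_vocabulary(x)
  emb <- pca_init(x, vocab, D = 6L, seed = 1, row_normalize = TRUE)
  expect_equal(sqrt(rowSums(emb[1:12, ]^2)), rep(1, 12), tolerance = 1e-8)
  expect_equal(emb[13, ], rep(0, 6))
})

test_that("encode_values scales embedding rows by expression value", {
  vocab <- toy_vocab(3)
  set.seed(2)
  emb <- rbind(matrix(rnorm(12), 3, 4), 0)
  b <- collate(list(make_cell(c(0, 2), c(1, 2)), make_cell(1, 1)), vocab)
  enc <- encode_values(b, emb)
  expect_equal(enc[1, 1, ], emb[1, ])          # value 1: row unchanged
  expect_equal(enc[1, 2, ], 2 * emb[3, ])      # value 2: doubled
  expect_equal(enc[2, 2, ], rep(0, 4))         # padded slot: zero vector
  bad <- b; bad$G_index[1, 1] <- 99L
  expect_error(encode_values(bad, emb), "range")
})

test_that("attention softmax handles singleton and symmetric keys", {
  cfg <- model_config(D = 4L, H = 1L, N = 1L, F_hidden = 8L, P = 4L)
  set.seed(3)
  prm <- scattn:::init_block_params(4L, 8L)
  q <- matrix(rnorm(4), 1, 4)
  kv <- array(rnorm(1 * 3 * 4), c(1, 3, 4))
  # single unmasked key: weight exactly 1
  mask1 <- matrix(c(TRUE, FALSE, FALSE), 1)
  out <- attention_block(q, kv, mask1, prm, cfg, return_attention = TRUE)
  expect_equal(out$attention[1, 1, 1], 1)
  # identical unmasked keys: uniform weights
  kv2 <- kv; kv2[1, 2, ] <- kv2[1, 1, ]; kv2[1, 3, ] <- kv2[1, 1, ]
  out2 <- attention_block(q, kv2, matrix(TRUE, 1, 3), prm, cfg,
                          return_attention = TRUE)
  expect_equal(as.numeric(out2$attention[1, 1, ]), rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_error(attention_block(q, kv, matrix(FALSE, 1, 3), prm, cfg),
               "unmasked")
})

test_that("attention_block matches the straight-line dense oracle", {
  for (i in 1:20) {
    set.seed(100 + i)
    D <- 4L; H <- sample(c(1L, 2L), 1); M <- sample(2:5, 1); B <- sample(1:3, 1)
    cfg <- model_config(D = D, H = H, N = 1L, F_hidden = 8L, P = 4L,
                        attn_scale = sample(c("d", "sqrt_d"), 1))
    prm <- scattn:::init_block_params(D, 8L)
    prm$bo <- rnorm(D); prm$ln1_b <- rnorm(D) * 0.1
    q <- matrix(rnorm(B * D), B, D)
    kv <- array(rnorm(B * M * D), c(B, M, D))
    mask <- matrix(runif(B * M) < 0.7, B, M)
    mask[, 1] <- TRUE
    got <- attention_block(q, kv, mask, prm, cfg)$Z
    want <- oracle_block(q, kv, mask, prm, cfg)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("latent vectors are invariant to gene order and padding width", {
  vocab <- toy_vocab(30)
  set.seed(11)
  emb <- rbind(matrix(rnorm(30 * 8, sd = 0.5), 30, 8), 0)
  cfg <- model_config(D = 8L, H = 2L, N = 2L, F_hidden = 16L, P = 8L)
  model <- init_model(vocab, cfg, embedding = emb, seed = 2)
  for (i in 1:20) {
    L <- sample(2:10, 1)
    idx <- sort(sample(0:29, L))
    val <- runif(L, 0.2, 3)
    cell <- make_cell(idx, val)
    perm <- sample(L)
    cell_perm <- make_cell(idx[perm], val[perm])
    z1 <- encode_cells(collate(list(cell), vocab), model)$Z
    z2 <- encode_cells(collate(list(cell_perm), vocab), model)$Z
    expect_equal(z1, z2, tolerance = 1e-6)
    # batch with a longer companion changes M but not the latent
    comp <- make_cell(0:14, rep(1, 15))
    z3 <- encode_cells(collate(list(cell, comp), vocab), model)$Z[1, , drop = FALSE]
    expect_equal(z1, z3, tolerance = 1e-10)
  }
})

test_that("block depth changes the representation", {
  vocab <- toy_vocab(10)
  set.seed(5)
  emb <- rbind(matrix(rnorm(80), 10, 8), 0)
  cell <- list(make_cell(c(0, 3, 7), c(1, 2, 1)))
  z1 <- encode_cells(collate(cell, vocab),
                     init_model(vocab, model_config(D = 8L, H = 2L, N = 1L,
                                                    F_hidden = 16L, P = 8L),
                                embedding = emb, seed = 3))$Z
  z2 <- encode_cells(collate(cell, vocab),
                     init_model(vocab, model_config(D = 8L, H = 2L, N = 2L,
                                                    F_hidden = 16L, P = 8L),
                                embedding = emb, seed = 3))$Z
  expect_gt(max(abs(z1 - z2)), 1e-8)
})

test_that("captured attention weights are a distribution over real genes", {
  model <- tiny_trained()
  sim <- tiny_sim()
  prep <- prepare_cells(sim$data, model$vocab)
  batch <- collate(prep$cells[1:10], model$vocab)
  enc <- encode_cells(batch, model, capture_attention = TRUE)
  for (i in 1:10) {
    a <- enc$attention[[i]]
    expect_identical(length(a$weights), length(prep$cells[[i]]$g_index))
    expect_true(all(a$weights >= 0))
    expect_equal(sum(a$weights), 1, tolerance = 1e-5)
  }
})

test_that("classifier probabilities are softmax-normalized with tie rules", {
  set.seed(8)
  z <- matrix(rnorm(12), 3, 4)
  prm <- list(W = matrix(rnorm(8), 4, 2), b = rnorm(2))
  p <- scattn:::classify_forward(prm, z)$p
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  zero <- scattn:::classify_forward(list(W = matrix(0, 4, 3), b = rep(0, 3)), z)$p
  expect_equal(zero, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # project is deterministic in eval mode
  model <- tiny_trained()
  expect_identical(project(model, z[, 1:4] %*% matrix(1, 4, 16)),
                   project(model, z[, 1:4] %*% matrix(1, 4, 16)))
})

test_that("checkpoints round-trip bit-exactly", {
  model <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  expect_identical(back$vocab, model$vocab)
  expect_identical(back$label_map, model$label_map)
  expect_identical(back$config, model$config)
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), junk)
  expect_error(load_model(junk), "checkpoint")
})
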