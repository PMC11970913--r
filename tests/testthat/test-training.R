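test_that("cosine similarity endpoints", {
  expect_equal(cosine_similarity(c(1, 2), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 2), -c(1, 2)), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 3)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("contrastive loss has its analytic values", {
  # all four rows identical: every similarity is 1, loss = log(2B - 1) = log 3
  f <- matrix(1, 4, 8)
  expect_equal(info_nce_loss(f, tau = 0.1), log(3), tolerance = 1e-9)
  expect_equal(info_nce_loss(f, tau = 2), log(3), tolerance = 1e-9)
  # perfectly separated pairs: positives at cosine 1, negatives at -1
  u <- c(1, rep(0, 7)); v <- -u
  f2 <- rbind(u, v, u, v)
  expect_lt(info_nce_loss(f2, tau = 0.1), 1e-6)
  # cosine scale invariance
  set.seed(3)
  f3 <- matrix(rnorm(6 * 5), 6, 5)
  expect_equal(info_nce_loss(f3 * 10, 0.1), info_nce_loss(f3, 0.1),
               tolerance = 1e-9)
  expect_gte(info_nce_loss(f3, 0.1), 0)
  expect_error(info_nce_loss(matrix(1, 2, 3), 0.1), "batch size")
})

test_that("contrastive loss decreases as the positive pair aligns", {
  # rotate the positive partner away from its anchor while every
  # anchor-negative similarity stays fixed at 0 (negatives orthogonal to
  # the rotation plane): loss must rise strictly with the angle
  losses <- vapply(seq(0.1, 3, length.out = 12), function(theta) {
    f <- rbind(c(1, 0, 0), c(0, 1, 0),
               c(cos(theta), 0, sin(theta)), c(0, 1, 0))
    info_nce_loss(f, tau = 0.5)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("cross entropy matches closed forms", {
  p1 <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy_loss(p1, 0:2), 0)
  expect_equal(cross_entropy_loss(matrix(0.25, 2, 4), c(1L, 3L)), log(4),
               tolerance = 1e-9)
  p2 <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(cross_entropy_loss(p2, c(0L, 1L)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-9)
  expect_error(cross_entropy_loss(p2, c(0L, 5L)), "label")
})

test_that("analytic gradients match numerical gradients on a small instance", {
  fl <- scattn:::flatten_params
  ufl <- scattn:::unflatten_params
  vocab <- toy_vocab(6)
  cfg <- model_config(D = 4L, H = 2L, N = 2L, F_hidden = 8L, P = 4L)
  model <- init_model(vocab, cfg, seed = 7)
  cells <- list(make_cell(c(0, 2, 4), c(1.2, 0.5, 1.3)),
                make_cell(c(1, 3), c(0.8, 1.2)),
                make_cell(c(0, 1, 2, 5), c(1, 1, 1, 1)),
                make_cell(5, 1))
  cells2 <- list(make_cell(c(0, 2), c(1.2, 0.5)), make_cell(3, 1.2),
                 make_cell(c(1, 2, 5), c(1, 1, 1)), make_cell(5, 1))
  b1 <- collate(cells, vocab); b2 <- collate(cells2, vocab)
  tau <- 0.1; eps <- 1e-6

  check_grads <- function(flat, gflat, loss_fn, skip_pad_of = "embedding") {
    worst <- 0
    for (k in names(flat)) {
      g_num <- flat[[k]] * 0
      for (i in seq_along(flat[[k]])) {
        f <- flat
        f[[k]][i] <- f[[k]][i] + eps; lp <- loss_fn(f)
        f[[k]][i] <- f[[k]][i] - 2 * eps; lm <- loss_fn(f)
        g_num[i] <- (lp - lm) / (2 * eps)
      }
      if (k == skip_pad_of) g_num[nrow(flat[[k]]), ] <- 0
      worst <- max(worst, max(abs(gflat[[k]] - g_num) /
                                pmax(abs(gflat[[k]]), 1e-4)))
    }
    worst
  }

  # contrastive path
  params0 <- model$params; params0$clf <- NULL
  nce_fn <- function(flat) {
    p <- ufl(flat, params0)
    s1 <- scattn:::project_forward(p$proj,
            scattn:::encoder_forward(p, b1, cfg)$Z)$S
    s2 <- scattn:::project_forward(p$proj,
            scattn:::encoder_forward(p, b2, cfg)$Z)$S
    info_nce_loss(rbind(s1, s2), tau)
  }
  f1 <- scattn:::encoder_forward(params0, b1, cfg)
  f2 <- scattn:::encoder_forward(params0, b2, cfg)
  p1 <- scattn:::project_forward(params0$proj, f1$Z)
  p2 <- scattn:::project_forward(params0$proj, f2$Z)
  nx <- scattn:::nt_xent(rbind(p1$S, p2$S), tau, grad = TRUE)
  pb1 <- scattn:::project_backward(params0$proj, p1, nx$dF[1:4, , drop = FALSE])
  pb2 <- scattn:::project_backward(params0$proj, p2, nx$dF[5:8, , drop = FALSE])
  e1 <- scattn:::encoder_backward(params0, f1, pb1$dZ, cfg)
  e2 <- scattn:::encoder_backward(params0, f2, pb2$dZ, cfg)
  grads <- list(embedding = e1$embedding + e2$embedding, cls = e1$cls + e2$cls,
                blocks = lapply(1:2, function(k)
                  mapply(`+`, e1$blocks[[k]], e2$blocks[[k]], SIMPLIFY = FALSE)),
                proj = mapply(`+`, pb1$grads, pb2$grads, SIMPLIFY = FALSE))
  expect_lt(check_grads(fl(params0), fl(grads), nce_fn), 1e-4)

  # supervised path
  set.seed(1)
  y <- c(0L, 1L, 0L, 1L)
  params1 <- model$params
  params1$clf <- list(W = matrix(rnorm(8, sd = 0.3), 4, 2), b = rnorm(2))
  params1$proj <- NULL
  ce_fn <- function(flat) {
    pp <- ufl(flat, params1)
    fw <- scattn:::encoder_forward(pp, b1, cfg)
    cross_entropy_loss(scattn:::classify_forward(pp$clf, fw$Z)$p, y)
  }
  fw <- scattn:::encoder_forward(params1, b1, cfg)
  cf <- scattn:::classify_forward(params1$clf, fw$Z)
  onehot <- matrix(0, 4, 2); onehot[cbind(1:4, y + 1L)] <- 1
  cb <- scattn:::classify_backward(params1$clf, cf, (cf$p - onehot) / 4)
  eb <- scattn:::encoder_backward(params1, fw, cb$dZ, cfg)
  g1 <- fl(list(embedding = eb$embedding, cls = eb$cls, blocks = eb$blocks,
                clf = cb$grads))
  expect_lt(check_grads(fl(params1), g1, ce_fn), 1e-4)
})

test_that("pretraining reduces the contrastive loss for most seeds", {
  sim <- tiny_sim()
  x64 <- expression_matrix(sim$data$counts[rep(1:40, length.out = 64), ],
                           sim$data$gene_symbols, paste0("cc", 1:64))
  wins <- 0
  for (seed in 1:10) {
    model <- init_model(build_vocabulary(x64),
                        model_config(D = 16L, H = 2L, N = 2L,
                                     F_hidden = 32L, P = 16L),
                        embedding = NULL, seed = seed)
    model <- pretrain(model, x64,
                      contrastive_config(epochs = 2L, batch_size = 32L,
                                         seed = seed))
    log <- attr(model, "pretrain_log")
    if (log[2] < log[1]) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("pretraining is deterministic given the seed", {
  sim <- tiny_sim()
  x <- sim$data
  run <- function() {
    model <- init_model(build_vocabulary(x),
                        model_config(D = 16L, H = 2L, N = 1L,
                                     F_hidden = 16L, P = 8L), seed = 4)
    pretrain(model, x, contrastive_config(epochs = 1L, batch_size = 16L,
                                          seed = 4))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$params, m2$params)
})

test_that("fine-tuning fits separable data and honors the epoch budget", {
  sim <- tiny_sim()
  model <- tiny_trained()
  log <- attr(model, "finetune_log")
  ann <- annotate(model, sim$data)
  expect_gte(accuracy_f1(sim$data$labels,
                         ann$predictions$predicted_label)$accuracy, 0.99)
  # preset short runs exactly 10 epochs
  m0 <- init_model(build_vocabulary(sim$data),
                   model_config(D = 16L, H = 2L, N = 1L, F_hidden = 16L,
                                P = 8L), seed = 2)
  ms <- finetune(m0, sim$data, train_config(preset = "short", seed = 2))
  expect_identical(nrow(attr(ms, "finetune_log")), 10L)
  # zero epochs leave encoder parameters untouched
  mz <- finetune(m0, sim$data, train_config(epochs = 0L, seed = 2))
  expect_identical(mz$params$blocks, m0$params$blocks)
  expect_identical(mz$params$embedding, m0$params$embedding)
  expect_error(finetune(m0, expression_matrix(matrix(1, 1, 1), "gA", "c1"),
                        train_config()), "label")
})

test_that("stratified split samples max(1, round(fraction * size)) per class", {
  labels <- rep(c("a", "b"), each = 10)
  sp <- stratified_split(labels, 0.1, seed = 1)
  expect_identical(length(sp$train), 2L)
  expect_identical(sum(labels[sp$train] == "a"), 1L)
  expect_identical(sort(c(sp$train, sp$test)), 1:20)

  labels2 <- c(rep("a", 4), rep("b", 6))
  sp2 <- stratified_split(labels2, 0.5, seed = 2)
  expect_identical(sum(labels2[sp2$train] == "a"), 2L)
  expect_identical(sum(labels2[sp2$train] == "b"), 3L)

  labels3 <- c("solo", rep("big", 9))
  sp3 <- stratified_split(labels3, 0.1, seed = 3)
  expect_true(1L %in% sp3$train)  # size-1 class goes to train
  expect_error(stratified_split(character(0), 0.5), "empty")
})
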