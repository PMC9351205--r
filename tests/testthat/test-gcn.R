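# The GraphSAGE survival network: analytic gradients vs finite differences,
# forward-pass contracts, determinism, and the training loop mechanics.

relist_params <- function(flat, skeleton) {
  p <- utils::relist(flat, skeleton)
  lungraph:::param_map2(function(a, s) { attributes(a) <- attributes(s); a },
                        p, skeleton)
}

test_that("analytic gradients match central finite differences", {
  mc <- model_config(n_blocks = 2, hidden_dim = 4, dropout_p = 0, input_dim = 5)
  gs <- toy_graphs(3, dim = 5, seed = 42)
  gs[[1]]$label <- 1L; gs[[2]]$label <- 0L; gs[[3]]$label <- 1L
  batch <- lungraph:::prepare_batch(gs)
  params <- lungraph:::init_gcn_params(mc, seed = 7)
  loss_of <- function(p) {
    fwd <- lungraph:::gcn_batch_forward(p, batch, mc, train = FALSE)
    lungraph:::bce_loss(fwd$logit, batch$labels)
  }
  fwd <- lungraph:::gcn_batch_forward(params, batch, mc, train = TRUE)
  grads <- lungraph:::gcn_batch_backward(params, batch, fwd, mc)
  flat_p <- unlist(params)
  flat_g <- unlist(grads)
  expect_identical(length(flat_p), length(flat_g))
  set.seed(1)
  idx <- sample(length(flat_p), 60)
  eps <- 1e-5
  for (j in idx) {
    up <- flat_p; up[j] <- up[j] + eps
    dn <- flat_p; dn[j] <- dn[j] - eps
    num <- (loss_of(relist_params(up, params)) -
            loss_of(relist_params(dn, params))) / (2 * eps)
    expect_equal(unname(flat_g[j]), num, tolerance = 1e-4,
                 info = sprintf("param %s", names(flat_p)[j]))
  }
})

test_that("inference is deterministic and dropout-free", {
  mc <- model_config(n_blocks = 2, hidden_dim = 8, dropout_p = 0.5, input_dim = 6)
  g <- toy_graphs(1, dim = 6, seed = 3)[[1]]
  model <- list(params = lungraph:::init_gcn_params(mc, 5), model_config = mc)
  s1 <- predict_risk(model, list(g))
  s2 <- predict_risk(model, list(g))
  expect_identical(s1, s2)
  expect_true(s1 >= 0 && s1 <= 1)
})

test_that("a zero head yields score 0.5; identical graphs score identically", {
  mc <- model_config(n_blocks = 1, hidden_dim = 6, dropout_p = 0, input_dim = 4)
  params <- lungraph:::init_gcn_params(mc, 2)
  params$head$w[] <- 0; params$head$b <- 0
  model <- list(params = params, model_config = mc)
  gs <- toy_graphs(2, dim = 4, seed = 9)
  expect_equal(unname(predict_risk(model, gs[1])), 0.5)
  g2 <- gs[[1]]; g2$patient_id <- "copy"
  scores <- predict_risk(list(params = lungraph:::init_gcn_params(mc, 2),
                              model_config = mc), list(gs[[1]], g2))
  expect_equal(unname(scores[1]), unname(scores[2]))
})

test_that("scores are invariant to feature storage order (canonicalization)", {
  mc <- model_config(n_blocks = 1, hidden_dim = 6, dropout_p = 0, input_dim = 4)
  model <- list(params = lungraph:::init_gcn_params(mc, 2), model_config = mc)
  f <- matrix(rnorm(40), 10, 4); rownames(f) <- node_roles()
  perm <- sample(10)
  g1 <- build_graph(f, "LUL", "a")
  g2 <- build_graph(f[perm, , drop = FALSE], "LUL", "a")
  expect_equal(predict_risk(model, list(g1)), predict_risk(model, list(g2)))
})

test_that("layer-norm output rows are standardized before the affine rescale", {
  mc <- model_config(n_blocks = 1, hidden_dim = 16, dropout_p = 0, input_dim = 6)
  params <- lungraph:::init_gcn_params(mc, 11)
  params$blocks[[1]]$gamma[] <- 1; params$blocks[[1]]$beta[] <- 0
  gs <- toy_graphs(2, dim = 6, seed = 13)
  batch <- lungraph:::prepare_batch(gs)
  out <- sage_block(params$blocks[[1]], batch$H, batch$nbr_idx, batch$deg)
  expect_true(all(abs(rowMeans(out)) < 1e-10))
  expect_true(all(abs(apply(out, 1, function(r) mean(r^2)) - 1) < 1e-2))
})

test_that("single-neighbor aggregation equals one hand-computed LSTM step", {
  mc <- model_config(n_blocks = 1, hidden_dim = 3, dropout_p = 0, input_dim = 4)
  p <- lungraph:::init_gcn_params(mc, 4)$blocks[[1]]
  H <- matrix(rnorm(8), 2, 4)
  nbr_idx <- matrix(c(2L, 1L), 2, 1)
  out <- sage_block(p, H, nbr_idx, deg = c(1L, 1L))
  # manual single LSTM step for node 1 (its neighbor is node 2)
  sig <- function(x) 1 / (1 + exp(-x))
  gates <- as.numeric(p$Wx %*% H[2, ] + p$b)
  h <- 3
  i <- sig(gates[1:h]); f <- sig(gates[(h + 1):(2 * h)])
  g <- tanh(gates[(2 * h + 1):(3 * h)]); o <- sig(gates[(3 * h + 1):(4 * h)])
  a <- o * tanh(i * g)
  s <- as.numeric(p$Wself %*% H[1, ] + p$bself)
  z <- as.numeric(p$Wcomb %*% c(s, a) + p$bcomb)
  r <- pmax(z, 0)
  xc <- r - mean(r)
  manual <- (xc / sqrt(mean(xc^2) + 1e-5)) * p$gamma + p$beta
  expect_equal(as.numeric(out[1, ]), manual, tolerance = 1e-12)
})

test_that("training follows the learning-rate contract and is reproducible", {
  sets <- toy_graph_sets(n_train = 40, n_val = 16, seed = 5)
  mc <- model_config(n_blocks = 1, hidden_dim = 8, dropout_p = 0.1, input_dim = 6)
  tc <- train_config(epochs = 12, batch_size = 16, seed = 3,
                     plateau_patience = 2)
  m1 <- train_gcn(sets$train, sets$val, mc, tc)
  m2 <- train_gcn(sets$train, sets$val, mc, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(unlist(m1$params), unlist(m2$params))
  h <- m1$history
  expect_identical(nrow(h), 12L)
  expect_equal(h$lr[1], 0.01)
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(h$lr >= 1e-5))
  expect_gte(m1$best_epoch, 1L)
})

test_that("the learning rate is floored at lr_min under a forced plateau", {
  sets <- toy_graph_sets(n_train = 12, n_val = 8, seed = 8)
  # constant features -> nothing to learn -> plateau from the start
  flat <- lapply(sets$train, function(g) { g$features[] <- 1; g })
  flatv <- lapply(sets$val, function(g) { g$features[] <- 1; g })
  mc <- model_config(n_blocks = 1, hidden_dim = 4, dropout_p = 0, input_dim = 6)
  tc <- train_config(epochs = 30, batch_size = 12, seed = 2,
                     plateau_patience = 1, lr_init = 0.01, lr_min = 1e-5)
  m <- train_gcn(flat, flatv, mc, tc)
  expect_true(all(m$history$lr >= 1e-5 - 1e-12))
  expect_lte(min(m$history$lr), 1e-5 + 1e-12)
  expect_true(all(diff(m$history$lr) <= 0))
})

test_that("single-class training labels are rejected", {
  gs <- toy_graphs(6, seed = 10)
  gs <- lapply(gs, function(g) { g$label <- 1L; g })
  expect_error(train_gcn(gs[1:4], gs[5:6]), "single-class")
})

test_that("the GCN learns a planted node-feature signal", {
  sets <- toy_graph_sets(n_train = 100, n_val = 60, seed = 21)
  mc <- model_config(n_blocks = 2, hidden_dim = 8, dropout_p = 0.1, input_dim = 6)
  tc <- train_config(epochs = 30, batch_size = 32, seed = 4, plateau_patience = 5)
  m <- train_gcn(sets$train, sets$val, mc, tc)
  scores <- predict_risk(m, sets$val)
  labels <- vapply(sets$val, function(g) g$label, integer(1))
  auc <- roc_auc(scores, labels, conf = FALSE)$auc
  expect_gt(auc, 0.75)
})

test_that("identical features across patients give chance-level AUC", {
  gs <- toy_graphs(60, dim = 6, seed = 31, signal = FALSE)
  shared <- gs[[1]]$features
  gs <- lapply(gs, function(g) { g$features <- shared; g })
  tr <- gs[1:40]; va <- gs[41:60]
  if (length(unique(vapply(tr, function(g) g$label, integer(1)))) < 2)
    tr[[1]]$label <- 1L - tr[[1]]$label
  mc <- model_config(n_blocks = 1, hidden_dim = 6, dropout_p = 0, input_dim = 6)
  m <- train_gcn(tr, va, mc, train_config(epochs = 8, batch_size = 20, seed = 6))
  scores <- predict_risk(m, va)
  # identical inputs give identical scores: AUC is exactly 0.5 by midrank
  auc <- roc_auc(scores, vapply(va, function(g) g$label, integer(1)),
                 conf = FALSE)$auc
  expect_gte(auc, 0.4); expect_lte(auc, 0.6)
})

test_that("sweep_blocks trains all four depths and reports them", {
  sets <- toy_graph_sets(n_train = 24, n_val = 12, seed = 15)
  res <- sweep_blocks(sets$train, sets$val,
                      train_config(epochs = 2, batch_size = 24, seed = 2),
                      hidden_dim = 4, dropout_p = 0)
  expect_identical(nrow(res$results), 4L)
  expect_identical(res$results$n_blocks, 1:4)
  best <- res$results$n_blocks[which(res$results$val_auc ==
                                       max(res$results$val_auc))[1]]
  expect_identical(res$best_config$n_blocks, best)
})

test_that("model persistence round trips predictions", {
  sets <- toy_graph_sets(n_train = 20, n_val = 10, seed = 18)
  mc <- model_config(n_blocks = 1, hidden_dim = 4, dropout_p = 0, input_dim = 6)
  m <- train_gcn(sets$train, sets$val, mc,
                 train_config(epochs = 2, batch_size = 20, seed = 2))
  stem <- withr::local_tempfile()
  save_model(m, stem)
  back <- load_model(stem)
  expect_equal(predict_risk(back, sets$val), predict_risk(m, sets$val),
               tolerance = 1e-12)
})
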