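# GraphSAGE-style survival predictor, implemented from scratch: stacked
# SageConv blocks (LSTM neighbor aggregator -> concat with transformed self
# feature -> linear -> ReLU -> dropout -> layer norm), mean readout over the
# ten nodes, and a fully connected head with a sigmoid.  Higher score =
# higher predicted 5-year mortality risk.
#
# The LSTM aggregator is order-sensitive; neighbor sequences are always in
# canonical role order, which makes every forward pass deterministic.
# Gradients are hand-derived and checked against finite differences in the
# test suite.  Training uses Adam with L2 weight decay and a
# reduce-on-plateau learning-rate schedule.

#' Model configuration
#'
#' @param n_blocks number of SageConv blocks, 1..4.
#' @param hidden_dim block width (the reference setup does not report one;
#'   128 default, reduce for CPU test runs).
#' @param dropout_p dropout probability in \[0, 1).
#' @param input_dim node feature length (96).
#' @param aggregator fixed to `"lstm"`.
#' @return a `model_config`.
#' @export
model_config <- function(n_blocks = 2L, hidden_dim = 128L, dropout_p = 0.3,
                         input_dim = 96L, aggregator = "lstm") {
  if (!n_blocks %in% 1:4) stop("n_blocks must be in 1..4")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  if (aggregator != "lstm") stop("only the lstm aggregator is supported")
  structure(list(n_blocks = as.integer(n_blocks),
                 hidden_dim = as.integer(hidden_dim),
                 dropout_p = dropout_p, input_dim = as.integer(input_dim),
                 aggregator = aggregator),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: 100 epochs, learning rate
#' initialized at 0.01, reduced on validation-loss plateau and floored at
#' 1e-5, weight decay 5e-5.
#'
#' @param epochs total epochs (<= 100 in the reference setup).
#' @param lr_init,lr_min initial and minimal learning rate.
#' @param weight_decay L2 penalty added to every gradient.
#' @param batch_size graphs per minibatch.
#' @param seed seed for init, shuffling and dropout.
#' @param plateau_patience epochs without val-loss improvement before the
#'   rate is multiplied by `plateau_factor`.
#' @param plateau_factor learning-rate reduction factor.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 100L, lr_init = 0.01, lr_min = 1e-5,
                         weight_decay = 5e-5, batch_size = 32L, seed = 1L,
                         plateau_patience = 10L, plateau_factor = 0.1) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr_min > lr_init) stop("lr_min must be <= lr_init")
  structure(list(epochs = as.integer(epochs), lr_init = lr_init,
                 lr_min = lr_min, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor),
            class = "train_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameters ------------------------------------------------------------

init_gcn_params <- function(mc, seed) {
  with_seed(seed, {
    h <- mc$hidden_dim
    blocks <- vector("list", mc$n_blocks)
    d_in <- mc$input_dim
    for (b in seq_len(mc$n_blocks)) {
      Wx <- matrix(rnorm(4 * h * d_in, 0, sqrt(1 / d_in)), 4 * h, d_in)
      Wh <- matrix(rnorm(4 * h * h, 0, sqrt(1 / h)), 4 * h, h)
      bg <- rep(0, 4 * h); bg[(h + 1):(2 * h)] <- 1   # forget-gate bias 1
      blocks[[b]] <- list(
        Wx = Wx, Wh = Wh, b = bg,
        Wself = matrix(rnorm(h * d_in, 0, sqrt(2 / d_in)), h, d_in),
        bself = rep(0, h),
        Wcomb = matrix(rnorm(h * 2 * h, 0, sqrt(2 / (2 * h))), h, 2 * h),
        bcomb = rep(0, h),
        gamma = rep(1, h), beta = rep(0, h))
      d_in <- h
    }
    list(blocks = blocks,
         head = list(w = rnorm(h, 0, 1 / sqrt(h)), b = 0))
  })
}

param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- param_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

param_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- param_map(f, a[[nm]])
    out
  } else f(a)
}

# ---- batching --------------------------------------------------------------

# Stack a list of lung_graphs into one disjoint-union batch.
prepare_batch <- function(graphs) {
  G <- length(graphs)
  roles <- node_roles()
  H0 <- do.call(rbind, lapply(graphs, function(g) g$features))
  graph_id <- rep(seq_len(G), each = length(roles))
  nbrs <- lapply(graphs, graph_neighbors)
  deg <- unlist(lapply(nbrs, function(nb) vapply(nb, length, integer(1))),
                use.names = FALSE)
  dmax <- max(deg)
  nbr_idx <- matrix(0L, nrow = length(deg), ncol = dmax)
  for (gi in seq_len(G)) {
    off <- (gi - 1L) * length(roles)
    nb <- nbrs[[gi]]
    for (v in seq_along(roles)) {
      js <- match(nb[[v]], roles) + off
      if (length(js) > 0) nbr_idx[off + v, seq_along(js)] <- js
    }
  }
  labels <- vapply(graphs, function(g) as.numeric(g$label), numeric(1))
  ids <- vapply(graphs, function(g) as.character(g$patient_id), character(1))
  list(H = H0, nbr_idx = nbr_idx, deg = deg, graph_id = graph_id,
       labels = labels, ids = ids, n_graphs = G)
}

# ---- SageConv block --------------------------------------------------------

#' One SageConv block forward pass
#'
#' Per node: the neighbor features (canonical role order) are consumed as a
#' sequence by an LSTM; the final LSTM state is concatenated with the
#' node's own linearly transformed feature, then linear map, ReLU, dropout
#' (training only) and layer normalization.
#'
#' @param params block parameter list (see `init_gcn_params`).
#' @param H `n_nodes x d_in` feature block.
#' @param nbr_idx `n_nodes x max_degree` neighbor index matrix (0 = pad),
#'   neighbors in canonical role order.
#' @param deg per-node neighbor counts.
#' @param dropout_p dropout probability (applied only when `train = TRUE`).
#' @param train logical; dropout active and cache returned when TRUE.
#' @return the `n_nodes x hidden` output block; with `train = TRUE`, a list
#'   `(out, cache)` for the backward pass.
#' @export
sage_block <- function(params, H, nbr_idx, deg, dropout_p = 0, train = FALSE) {
  n <- nrow(H)
  h <- length(params$gamma)
  dmax <- ncol(nbr_idx)
  hs <- matrix(0, n, h); cs <- matrix(0, n, h)
  steps <- vector("list", dmax)
  for (t in seq_len(dmax)) {
    act <- which(deg >= t)
    if (length(act) == 0) break
    xt <- H[nbr_idx[act, t], , drop = FALSE]
    hprev <- hs[act, , drop = FALSE]; cprev <- cs[act, , drop = FALSE]
    gates <- xt %*% t(params$Wx) + hprev %*% t(params$Wh) +
      matrix(params$b, length(act), 4 * h, byrow = TRUE)
    i <- sigmoid(gates[, 1:h, drop = FALSE])
    f <- sigmoid(gates[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(gates[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(gates[, (3 * h + 1):(4 * h), drop = FALSE])
    cnew <- f * cprev + i * g
    hs[act, ] <- o * tanh(cnew)
    cs[act, ] <- cnew
    steps[[t]] <- list(act = act, i = i, f = f, g = g, o = o,
                       cprev = cprev, c = cnew, hprev = hprev)
  }
  a <- hs
  s <- H %*% t(params$Wself) + matrix(params$bself, n, h, byrow = TRUE)
  z <- cbind(s, a) %*% t(params$Wcomb) + matrix(params$bcomb, n, h, byrow = TRUE)
  r <- pmax(z, 0)
  if (train && dropout_p > 0) {
    mask <- matrix((runif(n * h) >= dropout_p) / (1 - dropout_p), n, h)
    rd <- r * mask
  } else {
    mask <- NULL
    rd <- r
  }
  eps <- 1e-5
  mu <- rowMeans(rd)
  xc <- rd - mu
  sig <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sig
  out <- sweep(xhat, 2, params$gamma, "*") +
    matrix(params$beta, n, h, byrow = TRUE)
  if (!train) return(out)
  list(out = out,
       cache = list(H = H, s = s, a = a, z = z, mask = mask,
                    xhat = xhat, sig = sig, steps = steps,
                    nbr_idx = nbr_idx, deg = deg))
}

sage_block_backward <- function(params, cache, dOut) {
  n <- nrow(dOut); h <- ncol(dOut)
  xhat <- cache$xhat; sig <- cache$sig
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, params$gamma, "*")
  drd <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sig
  dr <- if (is.null(cache$mask)) drd else drd * cache$mask
  dz <- dr * (cache$z > 0)
  sa <- cbind(cache$s, cache$a)
  dWcomb <- t(dz) %*% sa
  dbcomb <- colSums(dz)
  dsa <- dz %*% params$Wcomb
  ds <- dsa[, 1:h, drop = FALSE]
  da <- dsa[, (h + 1):(2 * h), drop = FALSE]

  dH <- ds %*% params$Wself
  dWself <- t(ds) %*% cache$H
  dbself <- colSums(ds)

  dWx <- matrix(0, nrow(params$Wx), ncol(params$Wx))
  dWh <- matrix(0, nrow(params$Wh), ncol(params$Wh))
  db <- rep(0, length(params$b))
  dh_next <- da
  dc_next <- matrix(0, n, h)
  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    if (is.null(st)) next
    act <- st$act
    dh <- dh_next[act, , drop = FALSE]
    tc_ <- tanh(st$c)
    dc <- dc_next[act, , drop = FALSE] + dh * st$o * (1 - tc_^2)
    do_ <- dh * tc_
    di <- dc * st$g
    df <- dc * st$cprev
    dg <- dc * st$i
    dgates <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    dg * (1 - st$g^2),
                    do_ * st$o * (1 - st$o))
    xt <- cache$H[cache$nbr_idx[act, t], , drop = FALSE]
    dWx <- dWx + t(dgates) %*% xt
    dWh <- dWh + t(dgates) %*% st$hprev
    db <- db + colSums(dgates)
    dxt <- dgates %*% params$Wx
    tgt <- cache$nbr_idx[act, t]
    agg <- rowsum(dxt, tgt)
    rows <- as.integer(rownames(agg))
    dH[rows, ] <- dH[rows, , drop = FALSE] + agg
    dh_next[act, ] <- dgates %*% params$Wh
    dc_next[act, ] <- dc * st$f
  }
  list(dH = dH,
       grads = list(Wx = dWx, Wh = dWh, b = db,
                    Wself = dWself, bself = dbself,
                    Wcomb = dWcomb, bcomb = dbcomb,
                    gamma = dgamma, beta = dbeta))
}

# ---- full network ----------------------------------------------------------

gcn_batch_forward <- function(params, batch, mc, train = FALSE) {
  H <- batch$H
  caches <- vector("list", length(params$blocks))
  for (b in seq_along(params$blocks)) {
    res <- sage_block(params$blocks[[b]], H, batch$nbr_idx, batch$deg,
                      dropout_p = mc$dropout_p, train = train)
    if (train) { H <- res$out; caches[[b]] <- res$cache } else H <- res
  }
  hg <- rowsum(H, batch$graph_id) / 10
  logit <- as.numeric(hg %*% params$head$w + params$head$b)
  list(H = H, hg = hg, logit = logit, score = sigmoid(logit), caches = caches)
}

gcn_batch_backward <- function(params, batch, fwd, mc) {
  y <- batch$labels
  G <- batch$n_graphs
  dlogit <- (sigmoid(fwd$logit) - y) / G
  dw <- as.numeric(t(fwd$hg) %*% dlogit)
  db <- sum(dlogit)
  dhg <- outer(dlogit, params$head$w)
  dH <- dhg[batch$graph_id, , drop = FALSE] / 10
  grads_blocks <- vector("list", length(params$blocks))
  for (b in rev(seq_along(params$blocks))) {
    bk <- sage_block_backward(params$blocks[[b]], fwd$caches[[b]], dH)
    grads_blocks[[b]] <- bk$grads
    dH <- bk$dH
  }
  list(blocks = grads_blocks, head = list(w = dw, b = db))
}

bce_loss <- function(logit, y) {
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

#' Predict 5-year mortality risk scores
#'
#' Deterministic inference (dropout disabled).
#'
#' @param model a `trained_gcn` (or a bare list with `params` and `model_config`).
#' @param graphs list of `lung_graph`s.
#' @return named numeric vector of risk scores in \[0, 1\].
#' @export
predict_risk <- function(model, graphs) {
  if (inherits(graphs, "lung_graph")) graphs <- list(graphs)
  batch <- prepare_batch(graphs)
  fwd <- gcn_batch_forward(model$params, batch, model$model_config, train = FALSE)
  stats::setNames(fwd$score, batch$ids)
}

#' Forward pass for a single graph
#' @param model a `trained_gcn`.
#' @param g a `lung_graph`.
#' @return risk score in \[0, 1\].
#' @export
gcn_forward <- function(model, g) unname(predict_risk(model, list(g)))

#' Train the survival GCN
#'
#' Binary cross-entropy on the 5-year label, Adam with L2 weight decay,
#' learning rate reduced on validation-loss plateau (floored at `lr_min`),
#' weights of the best-validation-loss epoch returned.  Fully reproducible
#' given `tc$seed`.
#'
#' @param train_graphs,val_graphs nonempty lists of labeled `lung_graph`s.
#' @param mc a [model_config].
#' @param tc a [train_config].
#' @return a `trained_gcn`: `params`, `model_config`, `train_config`,
#'   `history` (per-epoch train/val loss, val AUC, learning rate),
#'   `best_epoch`.
#' @export
train_gcn <- function(train_graphs, val_graphs, mc = model_config(),
                      tc = train_config()) {
  stopifnot(length(train_graphs) > 0, length(val_graphs) > 0)
  ytr <- vapply(train_graphs, function(g) as.integer(g$label), integer(1))
  yv <- vapply(val_graphs, function(g) as.integer(g$label), integer(1))
  if (anyNA(ytr) || anyNA(yv)) stop("all training/validation graphs must be labeled")
  if (length(unique(ytr)) < 2) stop("training labels are single-class")

  params <- init_gcn_params(mc, tc$seed)
  mstate <- param_map(function(p) p * 0, params)
  vstate <- param_map(function(p) p * 0, params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  lr <- tc$lr_init
  val_batch <- prepare_batch(val_graphs)
  history <- data.frame()
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  bad <- 0L

  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(length(train_graphs))
      losses <- c()
      for (start in seq(1, length(ord), by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1, length(ord))]
        batch <- prepare_batch(train_graphs[idx])
        fwd <- gcn_batch_forward(params, batch, mc, train = TRUE)
        losses <- c(losses, bce_loss(fwd$logit, batch$labels))
        grads <- gcn_batch_backward(params, batch, fwd, mc)
        grads <- param_map2(function(g, p) g + tc$weight_decay * p, grads, params)
        step <- step + 1
        mstate <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g, mstate, grads)
        vstate <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, vstate, grads)
        mh <- param_map(function(m) m / (1 - beta1^step), mstate)
        vh <- param_map(function(v) v / (1 - beta2^step), vstate)
        upd <- param_map2(function(m, v) m / (sqrt(v) + eps), mh, vh)
        params <- param_map2(function(p, u) p - lr * u, params, upd)
      }
      vfwd <- gcn_batch_forward(params, val_batch, mc, train = FALSE)
      val_loss <- bce_loss(vfwd$logit, val_batch$labels)
      val_auc <- if (length(unique(val_batch$labels)) < 2) NA_real_ else
        roc_auc(vfwd$score, val_batch$labels, conf = FALSE)$auc
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = val_loss,
        val_auc = val_auc, lr = lr))
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss; best_params <- params; best_epoch <- epoch
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad > tc$plateau_patience && lr > tc$lr_min) {
          lr <- max(lr * tc$plateau_factor, tc$lr_min)
          bad <- 0L
        }
      }
    }
  })
  structure(list(params = best_params, model_config = mc, train_config = tc,
                 history = history, best_epoch = best_epoch),
            class = "trained_gcn")
}

#' @export
print.trained_gcn <- function(x, ...) {
  cat(sprintf("<trained_gcn> %d block(s), hidden %d; best epoch %d (val loss %.4f, val AUC %.3f)\n",
              x$model_config$n_blocks, x$model_config$hidden_dim, x$best_epoch,
              min(x$history$val_loss), x$history$val_auc[x$best_epoch]))
  invisible(x)
}

#' Sweep the number of SageConv blocks (1..4)
#'
#' Trains one model per depth and returns the configuration (and model)
#' with the best validation AUC; ties break toward fewer blocks.
#'
#' @param train_graphs,val_graphs labeled graph lists.
#' @param tc a [train_config].
#' @param hidden_dim,dropout_p forwarded to each [model_config].
#' @return list: `best_config`, `best_model`, `results` (one row per depth).
#' @export
sweep_blocks <- function(train_graphs, val_graphs, tc = train_config(),
                         hidden_dim = 128L, dropout_p = 0.3) {
  results <- data.frame()
  models <- list()
  for (nb in 1:4) {
    mc <- model_config(n_blocks = nb, hidden_dim = hidden_dim,
                       dropout_p = dropout_p,
                       input_dim = ncol(train_graphs[[1]]$features))
    m <- train_gcn(train_graphs, val_graphs, mc, tc)
    scores <- predict_risk(m, val_graphs)
    auc <- roc_auc(scores, vapply(val_graphs, function(g) g$label, integer(1)),
                   conf = FALSE)$auc
    results <- rbind(results, data.frame(n_blocks = nb, val_auc = auc))
    models[[nb]] <- m
  }
  best <- which(results$val_auc == max(results$val_auc))[1]  # tie -> fewest blocks
  list(best_config = models[[best]]$model_config,
       best_model = models[[best]],
       results = results)
}

#' Save / load a trained model (JSON config + TSV weights)
#' @param model a `trained_gcn`.
#' @param stem path stem; writes `<stem>.json`, `<stem>_weights.tsv`,
#'   `<stem>_history.csv`.
#' @return `stem`, invisibly.
#' @export
save_model <- function(model, stem) {
  flat <- unlist(model$params)
  jsonlite::write_json(list(model_config = unclass(model$model_config),
                            train_config = unclass(model$train_config),
                            best_epoch = model$best_epoch,
                            n_weights = length(flat)),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  writeLines(sprintf("%.17g", flat), paste0(stem, "_weights.tsv"))
  write.csv(model$history, paste0(stem, "_history.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname save_model
#' @param stem path stem used by [save_model].
#' @return a `trained_gcn`.
#' @export
load_model <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  mc <- do.call(model_config, as.list(meta$model_config))
  tc <- do.call(train_config, as.list(meta$train_config))
  skeleton <- init_gcn_params(mc, tc$seed)
  flat <- as.numeric(readLines(paste0(stem, "_weights.tsv")))
  params <- utils::relist(flat, skeleton)
  params <- param_map2(function(p, s) { attributes(p) <- attributes(s); p },
                       params, skeleton)
  structure(list(params = params, model_config = mc, train_config = tc,
                 history = read.csv(paste0(stem, "_history.csv")),
                 best_epoch = meta$best_epoch),
            class = "trained_gcn")
}
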