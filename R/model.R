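# Hierarchical graph attention model.
#
# Two branches share one architecture: per attention head, node features
# are linearly projected, neighbours are scored by the dot product of the
# projected features through a LeakyReLU, scores are softmax-normalised
# over each node's neighbour set, and the neighbour features are
# aggregated through an ELU; heads are averaged.  The heterogeneous
# branch runs this over the metapath subgraphs of one node type and fuses
# them with semantic (metapath-level) attention; the homogeneous branch
# runs it over the KNN similarity graph.  The per-node embeddings of the
# two branches are concatenated; a fully connected layer reconstructs
# each node's representation and a lncRNA-disease pair is scored by the
# sigmoid of the reconstructions' inner product.
#
# Gradients are derived analytically (reverse mode, full batch) and the
# parameters are updated with Adam using decoupled weight decay
# (parameters shrink by lr * weight_decay per step, outside the moment
# estimates).

#' Model configuration
#'
#' @param proj_dim width of the projected feature space per head
#'   (default 64).  The final per-node embedding is `proj_dim` per branch,
#'   so 128 with both branches active.
#' @param n_heads number of attention heads (default 4); each head owns
#'   its projection matrix.
#' @param semantic_dim width of the semantic attention space (default 128).
#' @param knn_k neighbours per node in the homogeneous KNN graphs
#'   (default 20).
#' @param alpha,divisor similarity fusion parameters, see
#'   [fuse_similarities()].
#' @param leaky_slope negative slope of the LeakyReLU in the attention
#'   scores (0.2).
#' @param lr,weight_decay,epochs Adam learning rate (0.001), L2 weight
#'   decay (0.005) and epoch budget (500).
#' @param threshold classification threshold for the thresholded metrics
#'   (0.5).
#' @param ablation_nho drop the homogeneous (KNN) branch entirely.
#' @param ablation_na replace the learned semantic attention weights by
#'   fixed uniform weights (`1/GN` per metapath type).
#' @param pair_head pair scoring layer.  `"bilinear"` (default) passes
#'   each node embedding through a fully connected layer that
#'   reconstructs its features and scores a pair by the inner product of
#'   the two reconstructions (plus bias), so the score can express
#'   lncRNA-disease interactions.  `"additive"` is the purely additive
#'   alternative `sigmoid(w (Z_l + Z_d) + b)`; its logit decomposes as
#'   f(lncRNA) + g(disease) and cannot represent interaction structure,
#'   so it is provided for comparison only.
#' @param branch_combine how the heterogeneous and homogeneous branch
#'   embeddings of a node are fused: `"concat"` (default, embedding
#'   width `2 * proj_dim`) or `"sum"`.
#' @param recompute_gip_per_fold recompute GIP similarity from the
#'   training-fold association matrix (avoids test-edge leakage).
#' @param rebuild_graphs_per_fold rebuild metapath subgraphs from the
#'   training-fold association matrix.
#' @param seed integer seed controlling initialisation and sampling.
#' @return list of class `model_config`.
#' @export
model_config <- function(proj_dim = 64L, n_heads = 4L, semantic_dim = 128L,
                         knn_k = 20L, alpha = 0.5, divisor = 2,
                         leaky_slope = 0.2, lr = 0.001, weight_decay = 0.005,
                         epochs = 500L, threshold = 0.5,
                         ablation_nho = FALSE, ablation_na = FALSE,
                         pair_head = c("bilinear", "additive"),
                         branch_combine = c("concat", "sum"),
                         recompute_gip_per_fold = TRUE,
                         rebuild_graphs_per_fold = TRUE, seed = 1L) {
  pair_head <- match.arg(pair_head)
  branch_combine <- match.arg(branch_combine)
  stopifnot(proj_dim >= 1, n_heads >= 1, semantic_dim >= 1, knn_k >= 1,
            alpha >= 0, alpha <= 1, divisor > 0, lr > 0, weight_decay >= 0,
            epochs >= 1, threshold > 0, threshold < 1,
            is.logical(ablation_nho), is.logical(ablation_na))
  structure(list(proj_dim = as.integer(proj_dim),
                 n_heads = as.integer(n_heads),
                 semantic_dim = as.integer(semantic_dim),
                 knn_k = as.integer(knn_k), alpha = alpha, divisor = divisor,
                 leaky_slope = leaky_slope, lr = lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 threshold = threshold, ablation_nho = ablation_nho,
                 ablation_na = ablation_na, pair_head = pair_head,
                 branch_combine = branch_combine,
                 recompute_gip_per_fold = recompute_gip_per_fold,
                 rebuild_graphs_per_fold = rebuild_graphs_per_fold,
                 seed = as.integer(seed)),
            class = "model_config")
}

# Activations ---------------------------------------------------------------

leaky_relu <- function(x, slope) pmax(x, 0) + slope * pmin(x, 0)

elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Node-level attention (one head) -------------------------------------------

# Forward pass of dot-product graph attention on adjacency A (binary,
# self-loops included) and projected features H.  Returns the embedding
# and the intermediates needed for the backward pass.
att_forward <- function(A, H, slope) {
  .att_forward_cpp(A, H, slope)
}

# Reverse-mode gradient of att_forward w.r.t. H, given dL/dZ.
att_backward <- function(A, H, slope, fw, dZ) {
  .att_backward_cpp(A, H, slope, fw$S, fw$a, fw$P, fw$Z, dZ)
}

mh_forward <- function(A, H_list, slope) {
  heads <- lapply(H_list, function(H) att_forward(A, H, slope))
  Z <- Reduce(`+`, lapply(heads, `[[`, "Z")) / length(heads)
  list(Z = Z, heads = heads)
}

mh_backward <- function(A, H_list, slope, fw, dZ) {
  K <- length(H_list)
  lapply(seq_len(K), function(k)
    att_backward(A, H_list[[k]], slope, fw$heads[[k]], dZ / K))
}

#' Multihead node-level graph attention
#'
#' Convenience entry point: runs the dot-product attention aggregation on
#' one graph with `n_heads` identical heads over the given projected
#' features (averaging identical heads reproduces the single-head
#' output).  Inside the full model each head owns its projection; this
#' function exposes the aggregation operator itself.
#'
#' @param adj binary adjacency matrix with self-loops (every row must
#'   have at least one neighbour).
#' @param H projected node feature matrix (one row per node).
#' @param n_heads number of (identical) heads.
#' @param slope LeakyReLU negative slope (0.2).
#' @param weights return the attention coefficient matrix as attribute
#'   `"attention"`.
#' @return embedding matrix, one row per node.
#' @export
node_attention <- function(adj, H, n_heads = 1L, slope = 0.2,
                           weights = FALSE) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj), nrow(adj) == nrow(H))
  if (any(rowSums(adj) == 0)) {
    stop("invariant violation: node without neighbours (no self-loop); ",
         "attention softmax is undefined")
  }
  fw <- mh_forward(adj, rep(list(H), n_heads), slope)
  if (weights) attr(fw$Z, "attention") <- fw$heads[[1L]]$a
  fw$Z
}

# Semantic (metapath-level) attention ----------------------------------------

sem_forward <- function(Z_list, sp, uniform) {
  GN <- length(Z_list)
  if (GN == 0L) stop("semantic attention needs at least one embedding")
  if (uniform) {
    omega <- rep(1 / GN, GN)
    return(list(Z = Reduce(`+`, Z_list) / GN, omega = omega, M = NULL,
                scores = NULL))
  }
  N <- nrow(Z_list[[1L]])
  M <- lapply(Z_list, function(Z) tanh(sweep(Z %*% t(sp$Wg), 2L, sp$b, `+`)))
  scores <- vapply(M, function(Mg) mean(Mg %*% sp$q), numeric(1))
  omega <- softmax(scores)
  Z <- Reduce(`+`, Map(`*`, as.list(omega), Z_list))
  list(Z = Z, omega = omega, M = M, scores = scores)
}

sem_backward <- function(Z_list, sp, uniform, fw, dZ) {
  GN <- length(Z_list)
  if (uniform) {
    return(list(dZ_list = rep(list(dZ / GN), GN),
                dWg = sp$Wg * 0, db = sp$b * 0, dq = sp$q * 0))
  }
  N <- nrow(dZ_list_proto <- Z_list[[1L]])
  domega <- vapply(seq_len(GN), function(g) sum(dZ * Z_list[[g]]), numeric(1))
  ds <- fw$omega * (domega - sum(fw$omega * domega))
  dWg <- sp$Wg * 0; db <- sp$b * 0; dq <- sp$q * 0
  dZ_list <- vector("list", GN)
  for (g in seq_len(GN)) {
    dZ_list[[g]] <- fw$omega[g] * dZ
    Mg <- fw$M[[g]]
    dq <- dq + (ds[g] / N) * colSums(Mg)
    dpre <- (ds[g] / N) * matrix(sp$q, N, length(sp$q), byrow = TRUE) *
      (1 - Mg^2)
    dWg <- dWg + crossprod(dpre, Z_list[[g]])
    db <- db + colSums(dpre)
    dZ_list[[g]] <- dZ_list[[g]] + dpre %*% sp$Wg
  }
  list(dZ_list = dZ_list, dWg = dWg, db = db, dq = dq)
}

#' Semantic attention over metapath-specific embeddings
#'
#' Scores each metapath type by the node-averaged projection
#' `q' tanh(Wg z + b)` of its embedding, softmax-normalises the scores
#' into weights, and returns the weighted sum of the embeddings.
#'
#' @param Z_list list of embedding matrices sharing shape (one per
#'   metapath type).
#' @param params list with elements `Wg` (semantic_dim x emb_dim), `b`
#'   (semantic_dim) and `q` (semantic_dim); may be `NULL` when `uniform`.
#' @param uniform fix the weights to `1/GN` (the no-attention ablation).
#' @return list with `Z` (fused embedding) and `weights`.
#' @export
semantic_attention <- function(Z_list, params = NULL, uniform = FALSE) {
  if (!uniform && is.null(params)) {
    stop("`params` required unless `uniform = TRUE`")
  }
  dims <- vapply(Z_list, dim, integer(2))
  if (length(Z_list) > 1 && any(dims != dims[, 1L])) {
    stop("embeddings must share dimensions")
  }
  fw <- sem_forward(Z_list, params, uniform)
  list(Z = fw$Z, weights = fw$omega)
}

# Parameter initialisation ---------------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

glorot_vec <- function(n) {
  lim <- sqrt(6 / (n + 1))
  stats::runif(n, -lim, lim)
}

#' Initialise model parameters
#'
#' Glorot-style uniform initialisation, seeded for reproducibility.
#'
#' @param cfg a [model_config()].
#' @param n_lnc,n_dis node counts (feature widths).
#' @return nested parameter list.
#' @export
hgat_init <- function(cfg, n_lnc, n_dis) {
  p <- cfg$proj_dim; s <- cfg$semantic_dim; K <- cfg$n_heads
  emb <- if (cfg$ablation_nho || cfg$branch_combine == "sum") p else 2L * p
  withr::with_seed(cfg$seed, {
    params <- list(
      het = list(
        W_l = replicate(K, glorot(n_lnc, p), simplify = FALSE),
        W_d = replicate(K, glorot(n_dis, p), simplify = FALSE)),
      sem_l = list(Wg = glorot(s, p), b = numeric(s), q = glorot_vec(s)),
      sem_d = list(Wg = glorot(s, p), b = numeric(s), q = glorot_vec(s)))
    if (!cfg$ablation_nho) {
      params$homo <- list(
        W_l = replicate(K, glorot(n_lnc, p), simplify = FALSE),
        W_d = replicate(K, glorot(n_dis, p), simplify = FALSE))
    }
    params$head <- if (cfg$pair_head == "bilinear") {
      list(U = glorot(emb, p), V = glorot(emb, p), b = 0)
    } else {
      list(w = glorot_vec(emb), b = 0)
    }
    params
  })
}

# Full forward / backward ----------------------------------------------------

#' Forward pass of the hierarchical attention model
#'
#' @param params parameter list from [hgat_init()].
#' @param feats [assemble_node_features()] output (`lnc`, `dis` feature
#'   matrices).
#' @param graphs list with `lnc` and `dis` (named lists of metapath
#'   adjacency matrices or [metapath_subgraph()] objects) and, unless the
#'   homogeneous branch is ablated, `knn_l`, `knn_d` adjacency matrices.
#' @param cfg a [model_config()].
#' @param pairs optional data frame with columns `lnc`, `dis` (integer
#'   indices); when given, pair probabilities are computed.
#' @return list with embeddings `Z_l`, `Z_d`, semantic weights
#'   `omega_l`, `omega_d`, `probs` (if pairs given) and the caches used
#'   by [hgat_backward()].
#' @export
hgat_forward <- function(params, feats, graphs, cfg, pairs = NULL) {
  slope <- cfg$leaky_slope
  adj_l <- lapply(graphs$lnc, as_adjacency)
  adj_d <- lapply(graphs$dis, as_adjacency)
  H_l <- lapply(params$het$W_l, function(W) feats$lnc %*% W)
  H_d <- lapply(params$het$W_d, function(W) feats$dis %*% W)
  mh_l <- lapply(adj_l, function(A) mh_forward(A, H_l, slope))
  mh_d <- lapply(adj_d, function(A) mh_forward(A, H_d, slope))
  sem_l <- sem_forward(lapply(mh_l, `[[`, "Z"), params$sem_l, cfg$ablation_na)
  sem_d <- sem_forward(lapply(mh_d, `[[`, "Z"), params$sem_d, cfg$ablation_na)
  out <- list(H_l = H_l, H_d = H_d, mh_l = mh_l, mh_d = mh_d,
              sem_l = sem_l, sem_d = sem_d,
              omega_l = sem_l$omega, omega_d = sem_d$omega)
  if (!cfg$ablation_nho) {
    Hh_l <- lapply(params$homo$W_l, function(W) feats$lnc %*% W)
    Hh_d <- lapply(params$homo$W_d, function(W) feats$dis %*% W)
    out$homo_l <- mh_forward(as_adjacency(graphs$knn_l), Hh_l, slope)
    out$homo_d <- mh_forward(as_adjacency(graphs$knn_d), Hh_d, slope)
    out$Hh_l <- Hh_l; out$Hh_d <- Hh_d
    if (cfg$branch_combine == "concat") {
      out$Z_l <- cbind(sem_l$Z, out$homo_l$Z)
      out$Z_d <- cbind(sem_d$Z, out$homo_d$Z)
    } else {
      out$Z_l <- sem_l$Z + out$homo_l$Z
      out$Z_d <- sem_d$Z + out$homo_d$Z
    }
  } else {
    out$Z_l <- sem_l$Z
    out$Z_d <- sem_d$Z
  }
  if (!is.null(pairs)) {
    out$logits <- pair_logits(out$Z_l, out$Z_d, pairs, params$head,
                              cfg$pair_head)
    out$probs <- sigmoid(out$logits)
  }
  out
}

pair_logits <- function(Z_l, Z_d, pairs, head, pair_head) {
  if (any(pairs$lnc < 1 | pairs$lnc > nrow(Z_l)) ||
      any(pairs$dis < 1 | pairs$dis > nrow(Z_d))) {
    stop("pair index out of range")
  }
  zl <- Z_l[pairs$lnc, , drop = FALSE]
  zd <- Z_d[pairs$dis, , drop = FALSE]
  if (pair_head == "bilinear") {
    rowSums((zl %*% head$U) * (zd %*% head$V)) + head$b
  } else {
    drop((zl + zd) %*% head$w) + head$b
  }
}

#' Pair association probabilities from node embeddings
#'
#' Fully connected scoring layer.  With `pair_head = "bilinear"` each
#' embedding is reconstructed through a linear layer and the pair logit
#' is the inner product of the reconstructions plus bias; with
#' `"additive"` the logit is `w (Z_l + Z_d) + b`.  The probability is
#' the sigmoid of the logit, so outputs lie strictly inside (0, 1) and
#' increase monotonically with the logit.
#'
#' @param Z_l,Z_d embedding matrices for lncRNAs and diseases.
#' @param pairs data frame with integer index columns `lnc`, `dis`.
#' @param head parameter list (`U`, `V`, `b` for bilinear; `w`, `b` for
#'   additive).
#' @param pair_head `"bilinear"` or `"additive"`.
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @export
predict_scores <- function(Z_l, Z_d, pairs, head,
                           pair_head = c("bilinear", "additive")) {
  pair_head <- match.arg(pair_head)
  sigmoid(pair_logits(Z_l, Z_d, pairs, head, pair_head))
}

#' Mean binary cross-entropy
#'
#' @param probs predicted probabilities.
#' @param labels binary labels of the same length.
#' @param eps probabilities are clamped to `[eps, 1 - eps]` (with a
#'   warning) so the logarithms stay finite.
#' @return scalar loss.
#' @export
bce_loss <- function(probs, labels, eps = 1e-12) {
  stopifnot(length(probs) == length(labels))
  if (any(probs <= 0 | probs >= 1)) {
    warning("probabilities at 0 or 1 clamped by eps for the log loss")
  }
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Backward pass: analytic gradients of the mean BCE loss
#'
#' @param params,feats,graphs,cfg as in [hgat_forward()].
#' @param fw forward cache from [hgat_forward()] (must have been called
#'   with the same `pairs`).
#' @param pairs,labels training pairs and their 0/1 labels.
#' @return gradient list with the same structure as `params`.
#' @export
hgat_backward <- function(params, fw, feats, graphs, cfg, pairs, labels) {
  slope <- cfg$leaky_slope
  p <- cfg$proj_dim
  n <- length(labels)
  dlogit <- (fw$probs - labels) / n
  emb <- ncol(fw$Z_l)
  grads <- list()

  # head + scatter into embeddings
  dZ_l <- matrix(0, nrow(fw$Z_l), emb)
  dZ_d <- matrix(0, nrow(fw$Z_d), emb)
  zl <- fw$Z_l[pairs$lnc, , drop = FALSE]
  zd <- fw$Z_d[pairs$dis, , drop = FALSE]
  if (cfg$pair_head == "bilinear") {
    al <- zl %*% params$head$U
    ad <- zd %*% params$head$V
    dA <- dlogit * ad                 # d logit / d (zl U)
    dB <- dlogit * al
    grads$head <- list(U = crossprod(zl, dA), V = crossprod(zd, dB),
                       b = sum(dlogit))
    sl <- rowsum(dA %*% t(params$head$U), pairs$lnc)
    dZ_l[as.integer(rownames(sl)), ] <- sl
    sd <- rowsum(dB %*% t(params$head$V), pairs$dis)
    dZ_d[as.integer(rownames(sd)), ] <- sd
  } else {
    grads$head <- list(w = drop(crossprod(zl + zd, dlogit)),
                       b = sum(dlogit))
    sl <- rowsum(dlogit, pairs$lnc)
    dZ_l[as.integer(rownames(sl)), ] <- sl %*% t(params$head$w)
    sd <- rowsum(dlogit, pairs$dis)
    dZ_d[as.integer(rownames(sd)), ] <- sd %*% t(params$head$w)
  }

  if (!cfg$ablation_nho && cfg$branch_combine == "concat") {
    dZ_het_l <- dZ_l[, seq_len(p), drop = FALSE]
    dZ_homo_l <- dZ_l[, p + seq_len(p), drop = FALSE]
    dZ_het_d <- dZ_d[, seq_len(p), drop = FALSE]
    dZ_homo_d <- dZ_d[, p + seq_len(p), drop = FALSE]
  } else {
    dZ_het_l <- dZ_homo_l <- dZ_l
    dZ_het_d <- dZ_homo_d <- dZ_d
  }

  adj_l <- lapply(graphs$lnc, as_adjacency)
  adj_d <- lapply(graphs$dis, as_adjacency)

  # semantic level
  sb_l <- sem_backward(lapply(fw$mh_l, `[[`, "Z"), params$sem_l,
                       cfg$ablation_na, fw$sem_l, dZ_het_l)
  sb_d <- sem_backward(lapply(fw$mh_d, `[[`, "Z"), params$sem_d,
                       cfg$ablation_na, fw$sem_d, dZ_het_d)
  grads$sem_l <- list(Wg = sb_l$dWg, b = sb_l$db, q = sb_l$dq)
  grads$sem_d <- list(Wg = sb_d$dWg, b = sb_d$db, q = sb_d$dq)

  # node level, heterogeneous branch: accumulate dH over subgraphs
  K <- cfg$n_heads
  dH_l <- rep(list(0), K)
  for (g in seq_along(adj_l)) {
    dHg <- mh_backward(adj_l[[g]], fw$H_l, slope, fw$mh_l[[g]],
                       sb_l$dZ_list[[g]])
    for (k in seq_len(K)) dH_l[[k]] <- dH_l[[k]] + dHg[[k]]
  }
  dH_d <- rep(list(0), K)
  for (g in seq_along(adj_d)) {
    dHg <- mh_backward(adj_d[[g]], fw$H_d, slope, fw$mh_d[[g]],
                       sb_d$dZ_list[[g]])
    for (k in seq_len(K)) dH_d[[k]] <- dH_d[[k]] + dHg[[k]]
  }
  grads$het <- list(
    W_l = lapply(dH_l, function(dH) crossprod(feats$lnc, dH)),
    W_d = lapply(dH_d, function(dH) crossprod(feats$dis, dH)))

  if (!cfg$ablation_nho) {
    dHh_l <- mh_backward(as_adjacency(graphs$knn_l), fw$Hh_l, slope,
                         fw$homo_l, dZ_homo_l)
    dHh_d <- mh_backward(as_adjacency(graphs$knn_d), fw$Hh_d, slope,
                         fw$homo_d, dZ_homo_d)
    grads$homo <- list(
      W_l = lapply(dHh_l, function(dH) crossprod(feats$lnc, dH)),
      W_d = lapply(dHh_d, function(dH) crossprod(feats$dis, dH)))
  }
  grads[names(params)]
}

as_adjacency <- function(x) {
  if (inherits(x, "metapath_subgraph")) x$adjacency else x
}

# Adam ------------------------------------------------------------------------

# Apply f leafwise over parallel nested lists of numeric arrays.
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- lapply(seq_along(trees[[1L]]), function(i)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(trees[[1L]])
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(params) {
  list(t = 0L,
       m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params))
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p * (1 - lr * weight_decay) - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

#' Train the model on one set of labelled pairs
#'
#' Full-batch gradient training with Adam (learning rate, weight decay
#' and epoch budget from the configuration).  Deterministic for a fixed
#' configuration seed.
#'
#' @param feats,graphs as in [hgat_forward()].
#' @param pairs data frame with columns `lnc`, `dis`, `label`.
#' @param cfg a [model_config()].
#' @param init optional pre-initialised parameters.
#' @return list with `params`, `loss_trace` (one mean BCE value per
#'   epoch) and `config`.
#' @export
hgat_fit <- function(feats, graphs, pairs, cfg, init = NULL) {
  stopifnot(nrow(pairs) > 0)
  params <- init %||% hgat_init(cfg, nrow(feats$lnc), nrow(feats$dis))
  state <- adam_init(params)
  labels <- pairs$label
  loss_trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    fw <- hgat_forward(params, feats, graphs, cfg, pairs)
    loss <- bce_loss(fw$probs, labels)
    if (!is.finite(loss)) {
      stop(sprintf("non-finite loss at epoch %d (lr = %g)", epoch, cfg$lr))
    }
    loss_trace[epoch] <- loss
    grads <- hgat_backward(params, fw, feats, graphs, cfg, pairs, labels)
    upd <- adam_step(params, grads, state, cfg$lr, cfg$weight_decay)
    params <- upd$params
    state <- upd$state
  }
  list(params = params, loss_trace = loss_trace, config = cfg)
}
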