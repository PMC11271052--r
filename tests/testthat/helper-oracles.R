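# Independent oracles and small fixture builders shared across tests.
# Every oracle is a deliberately naive reimplementation (explicit loops,
# explicit enumeration) kept separate from the package's code paths.

# Full O(mn) dynamic-programming weighted edit distance.
edit_dist_oracle <- function(a, b, sub_cost = 2, indel_cost = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x)
  n <- length(y)
  D <- matrix(0, m + 1, n + 1)
  D[, 1] <- (0:m) * indel_cost
  D[1, ] <- (0:n) * indel_cost
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1, j + 1] <- min(
        D[i, j] + if (x[i] == y[j]) 0 else sub_cost,
        D[i, j + 1] + indel_cost,
        D[i + 1, j] + indel_cost)
    }
  }
  D[m + 1, n + 1]
}

# Semantic similarity by explicit enumeration of every upward path:
# the contribution of an ancestor reached through a path of length k is
# 0.5^k, maximised over paths.
dss_path_oracle <- function(edges, d1, d2) {
  parents_of <- function(v) edges$parent[edges$child == v]
  contribs <- function(D) {
    res <- new.env()
    rec <- function(node, depth) {
      val <- 0.5^depth
      cur <- get0(node, envir = res, inherits = FALSE, ifnotfound = -Inf)
      if (val > cur) assign(node, val, envir = res)
      for (p in parents_of(node)) rec(p, depth + 1)
    }
    rec(D, 0)
    unlist(as.list(res))
  }
  c1 <- contribs(d1)
  c2 <- contribs(d2)
  shared <- intersect(names(c1), names(c2))
  if (!length(shared)) return(0)
  sum(c1[shared] + c2[shared]) / (sum(c1) + sum(c2))
}

# Random DAG edge list over n nodes: parents always precede children in
# a fixed topological order, so acyclicity holds by construction.
random_dag_edges <- function(n, p_edge = 0.3) {
  ids <- paste0("d", seq_len(n))
  edges <- data.frame(child = character(), parent = character())
  for (i in seq_len(n)[-1]) {
    parents <- which(stats::runif(i - 1) < p_edge)
    if (!length(parents)) parents <- sample(i - 1, 1)
    edges <- rbind(edges, data.frame(child = ids[i], parent = ids[parents]))
  }
  list(edges = edges, nodes = ids)
}

# GIP kernel by direct elementwise recomputation.
gip_oracle <- function(P) {
  n <- nrow(P)
  xi <- 1 / mean(rowSums(P^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- exp(-xi * sum((P[i, ] - P[j, ])^2))
    }
  }
  S
}

# Mann-Whitney AUC: fraction of positive/negative score pairs ranked
# correctly, ties counted half.
auc_mw_oracle <- function(probs, labels) {
  sp <- probs[labels == 1]
  sn <- probs[labels == 0]
  cmp <- outer(sp, sn, `>`) + 0.5 * outer(sp, sn, `==`)
  mean(cmp)
}

# Random symmetric similarity matrix with unit diagonal.
random_similarity <- function(n, ids = paste0("n", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

# Small planted-block dataset for fast end-to-end tests.
toy_spec <- function(seed = 7, ...) {
  synthetic_spec(n_lnc = 30, n_dis = 20, n_mir = 15, n_blocks = 3,
                 p_in = 0.5, p_out = 0.03,
                 seq_len_range = c(40L, 60L), seed = seed, ...)
}

toy_config <- function(...) {
  args <- list(proj_dim = 8, n_heads = 2, semantic_dim = 6, knn_k = 5,
               epochs = 30)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_config, args)
}

toy_model_inputs <- function(seed = 21, n_lnc = 10, n_dis = 8, n_mir = 6) {
  set.seed(seed)
  E_ld <- matrix(rbinom(n_lnc * n_dis, 1, .3), n_lnc, n_dis)
  E_ld[1, 1] <- 1
  E_lm <- matrix(rbinom(n_lnc * n_mir, 1, .3), n_lnc, n_mir)
  E_md <- matrix(rbinom(n_mir * n_dis, 1, .35), n_mir, n_dis)
  g <- build_hetero_graph(E_ld, E_lm, E_md)
  lsm <- fuse_similarities(random_similarity(n_lnc),
                           gip_kernel_similarity(E_ld, "rows"))
  dsm <- fuse_similarities(random_similarity(n_dis),
                           gip_kernel_similarity(E_ld, "columns"))
  list(feats = assemble_node_features(lsm, dsm),
       graphs = list(lnc = list(LDL = metapath_subgraph(g, "LDL"),
                                LML = metapath_subgraph(g, "LML")),
                     dis = list(DLD = metapath_subgraph(g, "DLD"),
                                DMD = metapath_subgraph(g, "DMD")),
                     knn_l = knn_graph(lsm, 4),
                     knn_d = knn_graph(dsm, 4)),
       E_ld = E_ld)
}

# Straight-line, loop-based computation of one attention aggregation:
# phi_uv = LeakyReLU(H_u . H_v), softmax over u's neighbours, ELU of the
# weighted neighbour sum.
attention_loop_oracle <- function(A, H, slope = 0.2) {
  n <- nrow(A)
  Z <- matrix(0, n, ncol(H))
  for (u in seq_len(n)) {
    nb <- which(A[u, ] == 1)
    phi <- vapply(nb, function(v) {
      s <- sum(H[u, ] * H[v, ])
      if (s > 0) s else slope * s
    }, numeric(1))
    a <- exp(phi - max(phi))
    a <- a / sum(a)
    agg <- numeric(ncol(H))
    for (k in seq_along(nb)) agg <- agg + a[k] * H[nb[k], ]
    Z[u, ] <- ifelse(agg > 0, agg, exp(agg) - 1)
  }
  Z
}


# Straight-line oracle of the whole forward pass (default architecture:
# per-head projections, loop attention on every subgraph, semantic
# fusion, KNN branch, branch concatenation, bilinear pair scoring).
forward_loop_oracle <- function(params, feats, graphs, cfg, pairs) {
  branch <- function(F, W_heads, adjs) {
    lapply(adjs, function(A) {
      Zh <- lapply(W_heads, function(W) attention_loop_oracle(A, F %*% W))
      Reduce(`+`, Zh) / length(Zh)
    })
  }
  sem <- function(Z_list, sp) {
    scores <- vapply(Z_list, function(Z) {
      mean(apply(Z, 1, function(z) sum(sp$q * tanh(sp$Wg %*% z + sp$b))))
    }, numeric(1))
    w <- exp(scores - max(scores)); w <- w / sum(w)
    Zf <- 0
    for (g in seq_along(Z_list)) Zf <- Zf + w[g] * Z_list[[g]]
    list(Z = Zf, w = w)
  }
  adj <- function(s) if (inherits(s, "metapath_subgraph")) s$adjacency else s
  sl <- sem(branch(feats$lnc, params$het$W_l, lapply(graphs$lnc, adj)),
            params$sem_l)
  sd <- sem(branch(feats$dis, params$het$W_d, lapply(graphs$dis, adj)),
            params$sem_d)
  Z_l <- cbind(sl$Z, branch(feats$lnc, params$homo$W_l,
                            list(adj(graphs$knn_l)))[[1]])
  Z_d <- cbind(sd$Z, branch(feats$dis, params$homo$W_d,
                            list(adj(graphs$knn_d)))[[1]])
  probs <- vapply(seq_len(nrow(pairs)), function(k) {
    zl <- Z_l[pairs$lnc[k], ]
    zd <- Z_d[pairs$dis[k], ]
    1 / (1 + exp(-(sum((zl %*% params$head$U) * (zd %*% params$head$V)) +
                     params$head$b)))
  }, numeric(1))
  list(Z_l = Z_l, Z_d = Z_d, omega_l = sl$w, omega_d = sd$w, probs = probs)
}
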