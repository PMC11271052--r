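# Attention operators and the full forward pass against a loop-based
# oracle; optimisation sanity.

test_that("node attention weights form a distribution over each neighbour set", {
  inp <- toy_model_inputs()
  A <- inp$graphs$lnc$LDL$adjacency
  H <- matrix(rnorm(10 * 5), 10, 5)
  Z <- node_attention(A, H, n_heads = 1, weights = TRUE)
  a <- attr(Z, "attention")
  expect_equal(unname(rowSums(a)), rep(1, 10), tolerance = 1e-6)
  expect_true(all(a >= 0))
  expect_true(all(a[A == 0] == 0))
  # single-neighbour node aggregates exactly its neighbour
  A1 <- diag(4); A1[2, 3] <- 0  # node 1 only has its self-loop
  H1 <- matrix(rnorm(8), 4, 2)
  Z1 <- node_attention(A1, H1)
  expect_equal(Z1[1, ], ifelse(H1[1, ] > 0, H1[1, ], exp(H1[1, ]) - 1))
  expect_error(node_attention(matrix(0, 3, 3), matrix(0, 3, 2)),
               "self-loop")
})

test_that("averaging identical heads equals a single head; oracle agreement", {
  inp <- toy_model_inputs()
  A <- inp$graphs$dis$DMD$adjacency
  H <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(node_attention(A, H, n_heads = 4), node_attention(A, H, 1))
  expect_equal(node_attention(A, H, 1), attention_loop_oracle(A, H),
               tolerance = 1e-12)
})

test_that("semantic attention weights are a distribution, uniform under ablation", {
  set.seed(22)
  Zs <- replicate(3, matrix(rnorm(12), 4, 3), simplify = FALSE)
  params <- list(Wg = matrix(rnorm(15), 5, 3), b = rnorm(5), q = rnorm(5))
  out <- semantic_attention(Zs, params)
  expect_equal(sum(out$weights), 1, tolerance = 1e-6)
  expect_true(all(out$weights > 0))
  outu <- semantic_attention(Zs, uniform = TRUE)
  expect_equal(outu$weights, rep(1 / 3, 3))
  # one embedding: weight 1, passthrough
  one <- semantic_attention(Zs[1], params)
  expect_equal(one$weights, 1)
  expect_equal(one$Z, Zs[[1]])
  # identical embeddings get equal weight and pass through
  two <- semantic_attention(list(Zs[[1]], Zs[[1]]), params)
  expect_equal(two$weights, c(.5, .5), tolerance = 1e-9)
  expect_equal(two$Z, Zs[[1]], tolerance = 1e-9)
  expect_error(semantic_attention(list(), params), "at least one")
})

test_that("pair scoring is bounded, monotone, and 0.5 at zero parameters", {
  set.seed(23)
  Z_l <- matrix(rnorm(20), 5, 4)
  Z_d <- matrix(rnorm(12), 3, 4)
  pairs <- data.frame(lnc = c(1, 2, 5), dis = c(1, 3, 2))
  head0 <- list(w = rep(0, 4), b = 0)
  expect_equal(predict_scores(Z_l, Z_d, pairs, head0, "additive"),
               rep(0.5, 3))
  head1 <- list(w = rnorm(4), b = 0.3)
  p1 <- predict_scores(Z_l, Z_d, pairs, head1, "additive")
  expect_true(all(p1 > 0 & p1 < 1))
  head2 <- head1; head2$b <- head1$b + 1
  expect_true(all(predict_scores(Z_l, Z_d, pairs, head2, "additive") > p1))
  headb <- list(U = matrix(rnorm(8), 4, 2), V = matrix(rnorm(8), 4, 2), b = 0)
  pb <- predict_scores(Z_l, Z_d, pairs, headb, "bilinear")
  expect_true(all(pb > 0 & pb < 1))
  expect_error(predict_scores(Z_l, Z_d, data.frame(lnc = 9, dis = 1), headb),
               "out of range")
})

test_that("binary cross-entropy matches its closed forms and a direct oracle", {
  expect_equal(bce_loss(rep(0.5, 10), rbinom(10, 1, .5)), log(2))
  expect_lt(suppressWarnings(bce_loss(c(1, 0, 1), c(1, 0, 1))), 1e-10)
  expect_warning(bce_loss(c(1, 0.5), c(1, 0)), "clamped")
  set.seed(24)
  p <- runif(50, 0.01, 0.99)
  y <- rbinom(50, 1, .5)
  direct <- -sum(y * log(p) + (1 - y) * log(1 - p)) / 50
  expect_equal(bce_loss(p, y), direct, tolerance = 1e-12)
})

test_that("full forward pass matches a loop-based oracle on a toy graph", {
  inp <- toy_model_inputs()
  cfg <- model_config(proj_dim = 5, n_heads = 2, semantic_dim = 4, knn_k = 4,
                      epochs = 1, seed = 31)
  params <- hgat_init(cfg, 10, 8)
  pairs <- data.frame(lnc = c(1, 4, 7, 10), dis = c(2, 5, 8, 1))
  fw <- hgat_forward(params, inp$feats, inp$graphs, cfg, pairs)

  # oracle: explicit per-head projection, loop attention, semantic fusion,
  # branch concatenation and bilinear scoring
  sem_oracle <- function(Z_list, sp) {
    scores <- vapply(Z_list, function(Z) {
      vals <- apply(Z, 1, function(z) sum(sp$q * tanh(sp$Wg %*% z + sp$b)))
      mean(vals)
    }, numeric(1))
    w <- exp(scores - max(scores)); w <- w / sum(w)
    Zf <- 0
    for (g in seq_along(Z_list)) Zf <- Zf + w[g] * Z_list[[g]]
    list(Z = Zf, w = w)
  }
  branch_oracle <- function(F, W_heads, adjs) {
    lapply(adjs, function(A) {
      Zh <- lapply(W_heads, function(W) attention_loop_oracle(A, F %*% W))
      Reduce(`+`, Zh) / length(Zh)
    })
  }
  Zg_l <- branch_oracle(inp$feats$lnc, params$het$W_l,
                        lapply(inp$graphs$lnc, function(s) s$adjacency))
  Zg_d <- branch_oracle(inp$feats$dis, params$het$W_d,
                        lapply(inp$graphs$dis, function(s) s$adjacency))
  sl <- sem_oracle(Zg_l, params$sem_l)
  sd <- sem_oracle(Zg_d, params$sem_d)
  Zh_l <- branch_oracle(inp$feats$lnc, params$homo$W_l,
                        list(inp$graphs$knn_l))[[1]]
  Zh_d <- branch_oracle(inp$feats$dis, params$homo$W_d,
                        list(inp$graphs$knn_d))[[1]]
  Z_l <- cbind(sl$Z, Zh_l)
  Z_d <- cbind(sd$Z, Zh_d)
  probs <- vapply(seq_len(nrow(pairs)), function(k) {
    zl <- Z_l[pairs$lnc[k], ]
    zd <- Z_d[pairs$dis[k], ]
    1 / (1 + exp(-(sum((zl %*% params$head$U) * (zd %*% params$head$V)) +
                     params$head$b)))
  }, numeric(1))

  expect_equal(fw$omega_l, sl$w, tolerance = 1e-5)
  expect_equal(fw$omega_d, sd$w, tolerance = 1e-5)
  expect_equal(unname(fw$Z_l), unname(Z_l), tolerance = 1e-5)
  expect_equal(unname(fw$Z_d), unname(Z_d), tolerance = 1e-5)
  expect_equal(unname(fw$probs), unname(probs), tolerance = 1e-5)
})

test_that("embeddings are equivariant under node permutations", {
  inp <- toy_model_inputs(seed = 25)
  cfg <- model_config(proj_dim = 4, n_heads = 2, semantic_dim = 3, knn_k = 3,
                      epochs = 1, seed = 32)
  params <- hgat_init(cfg, 10, 8)
  fw <- hgat_forward(params, inp$feats, inp$graphs, cfg)
  perm <- sample(10)
  # permute the lncRNA nodes everywhere they appear (rows of features and
  # feature columns stay put: features are fixed per-node vectors)
  permute <- function(A) A[perm, perm]
  graphs2 <- inp$graphs
  graphs2$lnc <- lapply(inp$graphs$lnc, function(s) {
    s$adjacency <- permute(s$adjacency); s
  })
  graphs2$knn_l <- permute(inp$graphs$knn_l)
  feats2 <- inp$feats
  feats2$lnc <- inp$feats$lnc[perm, , drop = FALSE]
  fw2 <- hgat_forward(params, feats2, graphs2, cfg)
  expect_equal(fw2$Z_l, fw$Z_l[perm, ], tolerance = 1e-10)
  expect_equal(fw2$Z_d, fw$Z_d, tolerance = 1e-10)
})

test_that("gradient flow: training loss decreases on planted data", {
  data <- generate_data(toy_spec())
  data <- ldagat:::prepare_data(data)
  cfg <- toy_config(seed = 33, epochs = 25)
  inputs <- ldagat:::build_model_inputs(data, data$E_ld, data$E_ld, cfg)
  pairs <- sample_negatives(data$E_ld, seed = 2)
  fit <- hgat_fit(inputs$feats, inputs$graphs, pairs, cfg)
  expect_lt(fit$loss_trace[20], fit$loss_trace[1])
  expect_true(all(is.finite(fit$loss_trace)))
})

test_that("ablation configurations change the architecture as advertised", {
  inp <- toy_model_inputs(seed = 26)
  base <- model_config(proj_dim = 4, n_heads = 2, semantic_dim = 3,
                       knn_k = 3, epochs = 1, seed = 34)
  p_full <- hgat_init(base, 10, 8)
  fw <- hgat_forward(p_full, inp$feats, inp$graphs, base)
  expect_equal(ncol(fw$Z_l), 8)   # concat of two 4-dim branches

  nho <- model_config(proj_dim = 4, n_heads = 2, semantic_dim = 3, knn_k = 3,
                      epochs = 1, seed = 34, ablation_nho = TRUE)
  p_nho <- hgat_init(nho, 10, 8)
  expect_null(p_nho$homo)
  fw_nho <- hgat_forward(p_nho, inp$feats, inp$graphs, nho)
  expect_equal(ncol(fw_nho$Z_l), 4)

  na <- model_config(proj_dim = 4, n_heads = 2, semantic_dim = 3, knn_k = 3,
                     epochs = 1, seed = 34, ablation_na = TRUE)
  fw_na <- hgat_forward(hgat_init(na, 10, 8), inp$feats, inp$graphs, na)
  expect_equal(fw_na$omega_l, c(.5, .5))
  expect_equal(fw_na$omega_d, c(.5, .5))
})
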