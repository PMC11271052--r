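# Heterogeneous graph assembly, negative sampling, metapath subgraphs
# and KNN graphs.

test_that("hetero graph validates shapes and assembles the block matrix", {
  E_ld <- matrix(c(1, 0, 0, 1), 2, 2)
  E_lm <- matrix(0, 2, 3)
  E_md <- matrix(0, 3, 2)
  g <- build_hetero_graph(E_ld, E_lm, E_md)
  G <- block_matrix(g)
  expect_equal(dim(G), c(7, 7))
  expect_equal(G, t(G))
  expect_equal(sum(G[1:2, 3:4]), 2)     # each lnc-dis edge once per direction
  expect_equal(sum(G), 4)
  expect_true(all(diag(G) == 0))

  expect_error(build_hetero_graph(E_ld, matrix(0, 3, 3), E_md), "E_lm")
  expect_error(build_hetero_graph(E_ld, E_lm, matrix(0, 3, 4)), "E_md")
  # all-zero matrices are a valid (edgeless) graph
  g0 <- build_hetero_graph(matrix(0, 2, 2), E_lm, matrix(0, 3, 2))
  expect_equal(sum(block_matrix(g0)), 0)
  # benchmark-scale shapes give the expected block-matrix size
  gd <- build_hetero_graph(matrix(0, 240, 412), matrix(0, 240, 495),
                           matrix(0, 495, 412))
  expect_equal(dim(block_matrix(gd)), c(1147, 1147))
})

test_that("negative sampling is balanced, disjoint from positives and seeded", {
  set.seed(10)
  E <- matrix(rbinom(20 * 15, 1, 0.2), 20, 15)
  pairs <- sample_negatives(E, seed = 5)
  expect_equal(sum(pairs$label == 1), sum(E))
  expect_equal(sum(pairs$label == 0), sum(E))
  expect_false(anyDuplicated(pairs[c("lnc", "dis")]) > 0)
  neg <- pairs[pairs$label == 0, ]
  expect_true(all(E[cbind(neg$lnc, neg$dis)] == 0))
  expect_identical(pairs, sample_negatives(E, seed = 5))
  pairs2 <- sample_negatives(E, seed = 6)
  expect_identical(pairs[pairs$label == 1, ], pairs2[pairs2$label == 1, ])
  expect_false(identical(pairs, pairs2))
  expect_error(sample_negatives(matrix(1, 3, 3), seed = 1), "infeasible")
  # excluded pairs are never drawn
  excl <- data.frame(lnc = rep(1:20, each = 15), dis = rep(1:15, 20))
  expect_error(sample_negatives(E, seed = 1, exclude = excl), "infeasible")
})

test_that("metapath subgraphs equal the binarized cross-product oracle", {
  E_ld <- rbind(c(1, 1), c(0, 1))
  g <- build_hetero_graph(E_ld, matrix(0, 2, 2), matrix(0, 2, 2))
  sg <- metapath_subgraph(g, "LDL")
  expect_equal(sg$adjacency[1, 2], 1)   # l1 and l2 share disease d2
  expect_equal(diag(sg$adjacency), c(l1 = 1, l2 = 1))
  expect_equal(sg$node_type, "lnc")

  set.seed(11)
  for (rep in 1:25) {
    E_ld <- matrix(rbinom(100, 1, 0.3), 10, 10)
    E_lm <- matrix(rbinom(100, 1, 0.3), 10, 10)
    E_md <- matrix(rbinom(100, 1, 0.3), 10, 10)
    g <- build_hetero_graph(E_ld, E_lm, E_md)
    for (pt in c("LDL", "LML", "DLD", "DMD")) {
      B <- switch(pt, LDL = E_ld, LML = E_lm, DLD = t(E_ld), DMD = t(E_md))
      want <- (B %*% t(B) > 0) * 1
      diag(want) <- 1
      expect_equal(unname(metapath_subgraph(g, pt)$adjacency), unname(want))
    }
  }
  expect_error(metapath_subgraph(g, "MLM"), "path_type")
  # zero associations leave only self-loops
  g0 <- build_hetero_graph(matrix(0, 4, 3), matrix(0, 4, 2), matrix(0, 2, 3))
  expect_equal(unname(metapath_subgraph(g0, "LDL")$adjacency), diag(4))
})

test_that("metapath adjacency is monotone and intermediate-permutation invariant", {
  set.seed(12)
  E <- matrix(rbinom(80, 1, 0.2), 8, 10)
  g <- build_hetero_graph(E, matrix(0, 8, 2), matrix(0, 2, 10))
  A <- metapath_subgraph(g, "LDL")$adjacency
  # permuting the intermediate (disease) set leaves the adjacency unchanged
  gp <- build_hetero_graph(E[, sample(10)], matrix(0, 8, 2), matrix(0, 2, 10))
  expect_equal(unname(metapath_subgraph(gp, "LDL")$adjacency), unname(A))
  # adding an association never removes a metapath edge
  E2 <- E
  zero <- which(E2 == 0)[1]
  E2[zero] <- 1
  g2 <- build_hetero_graph(E2, matrix(0, 8, 2), matrix(0, 2, 10))
  expect_true(all(metapath_subgraph(g2, "LDL")$adjacency >= A))
})

test_that("KNN graph selects k columns per row including self, with the tie rule", {
  set.seed(13)
  for (rep in 1:10) {
    sim <- random_similarity(8)
    A <- knn_graph(sim, 3, symmetrize = FALSE)
    expect_equal(unname(rowSums(A)), rep(3, 8))
    expect_equal(unname(diag(A)), rep(1, 8))
    # sort-based oracle: self first, then similarity descending, ties by index
    for (i in 1:8) {
      others <- setdiff(1:8, i)
      ord <- others[order(-sim[i, others], others)]
      expect_equal(which(A[i, ] == 1), sort(c(i, ord[1:2])),
                   ignore_attr = TRUE)
    }
    As <- knn_graph(sim, 3)
    expect_equal(As, ((A + t(A)) > 0) * 1)
  }
  sim <- random_similarity(5)
  expect_equal(unname(knn_graph(sim, 5)), matrix(1, 5, 5))
  expect_equal(unname(knn_graph(sim, 1, symmetrize = FALSE)), diag(5))
  expect_error(knn_graph(sim, 6), "k")
  # constant similarity: deterministic under the index tie rule
  cs <- matrix(0.3, 4, 4); diag(cs) <- 1
  expect_identical(knn_graph(cs, 2, symmetrize = FALSE),
                   knn_graph(cs, 2, symmetrize = FALSE))
  expect_equal(unname(knn_graph(cs, 2, symmetrize = FALSE)[4, ]),
               c(1, 0, 0, 1))   # ties broken by ascending index
})

test_that("node features are the exact similarity rows", {
  lsm <- random_similarity(6)
  dsm <- random_similarity(4)
  f <- assemble_node_features(lsm, dsm)
  expect_identical(f$lnc, lsm)
  expect_identical(f$dis, dsm)
  expect_equal(f$lnc[3, ], lsm[3, ])
  f2 <- assemble_node_features(diag(5), diag(3))
  expect_equal(f2$lnc[2, ], c(0, 1, 0, 0, 0))
})
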