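# Cross-validation protocol, metrics, and candidate ranking.

test_that("folds partition positives, stay disjoint and balanced", {
  set.seed(50)
  # benchmark-sized association matrix with exactly 2697 positives
  E <- matrix(0, 240, 412)
  E[sample(length(E), 2697)] <- 1
  folds <- make_folds(E, 5, seed = 3)
  test_sizes <- vapply(folds, function(f) sum(f$test$label == 1), numeric(1))
  expect_equal(sort(unname(test_sizes)), c(539, 539, 539, 540, 540))
  expect_equal(sum(test_sizes), 2697)
  keys <- lapply(folds, function(f) {
    p <- f$test[f$test$label == 1, ]
    paste(p$lnc, p$dis)
  })
  expect_equal(sort(unlist(keys)),
               sort(paste(which(E == 1, arr.ind = TRUE)[, 1],
                          which(E == 1, arr.ind = TRUE)[, 2])))
  expect_equal(length(unique(unlist(keys))), 2697)   # pairwise disjoint
  for (f in folds) {
    expect_equal(sum(f$train$label == 1), sum(f$train$label == 0))
    expect_equal(sum(f$test$label == 1), sum(f$test$label == 0))
    expect_equal(nrow(merge(f$train, f$test, by = c("lnc", "dis"))), 0)
  }
  # small case: 4 positives over 2 folds
  E2 <- matrix(0, 3, 3); E2[c(1, 5, 6, 9)] <- 1
  f2 <- make_folds(E2, 2, seed = 1)
  expect_equal(vapply(f2, function(f) sum(f$test$label == 1), numeric(1)),
               c(2, 2))
  expect_error(make_folds(E2, 9, seed = 1), "n_folds")
})

test_that("thresholded metrics reproduce the worked confusion example", {
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  probs <- c(.9, .8, .7, .6, .4, .3, .2, .1, .15, .25)
  # at 0.5: TP=3, FP=1, TN=4, FN=2
  row <- evaluate_predictions(probs, labels)
  expect_equal(row$accuracy, 0.7)
  expect_equal(row$recall, 0.6)
  expect_equal(row$precision, 0.75)
  expect_equal(row$f1, 2 / 3)
  expect_equal(row$f1,
               2 * row$precision * row$recall / (row$precision + row$recall))
})

test_that("AUC and AUPR behave at the extremes and under label swap", {
  labels <- rep(c(1, 0), 10)
  perfect <- evaluate_predictions(as.numeric(labels), labels)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)
  set.seed(51)
  probs <- runif(20)
  a1 <- suppressWarnings(evaluate_predictions(probs, labels)$auc)
  a2 <- suppressWarnings(evaluate_predictions(1 - probs, 1 - labels)$auc)
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_warning(ldagat:::auc_score(runif(5), rep(1, 5)), "single class")
  r <- suppressWarnings(evaluate_predictions(runif(5), rep(1, 5)))
  expect_true(is.na(r$auc))
  expect_true(is.na(r$aupr))
  # random scores on balanced labels concentrate near 0.5
  big_labels <- rep(c(0, 1), 1000)
  set.seed(52)
  expect_equal(evaluate_predictions(runif(2000), big_labels)$auc, 0.5,
               tolerance = 0.05)
})

test_that("AUC equals the Mann-Whitney oracle, including tied scores", {
  set.seed(53)
  for (rep in 1:8) {
    n <- sample(50:500, 1)
    labels <- rbinom(n, 1, .4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(ldagat:::auc_score(probs, labels),
                 auc_mw_oracle(probs, labels), tolerance = 1e-9)
  }
})

test_that("AUPR step interpolation matches a direct curve walk", {
  set.seed(54)
  labels <- rbinom(60, 1, .5)
  probs <- runif(60)
  ord <- order(probs, decreasing = TRUE)
  l <- labels[ord]
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  rec <- tp / sum(l)
  direct <- sum(diff(c(0, rec)) * prec)   # distinct scores: every point kept
  expect_equal(pr_auc(probs, labels), direct, tolerance = 1e-12)
  co <- pr_coordinates(probs, labels)
  expect_true(all(diff(co$recall) >= 0))
  ro <- roc_coordinates(probs, labels)
  expect_equal(ro$fpr[1], 0)
  expect_equal(ro$tpr[nrow(ro)], 1)
})

test_that("cross-validation is reproducible and reports the full schema", {
  data <- generate_data(toy_spec())
  cfg <- toy_config(seed = 55, epochs = 10)
  r1 <- cross_validate(data, cfg, n_folds = 3)
  r2 <- cross_validate(data, cfg, n_folds = 3)
  expect_equal(r1$per_fold, r2$per_fold, tolerance = 1e-6)
  expect_equal(r1$mean, r2$mean, tolerance = 1e-6)
  expect_named(r1$per_fold,
               c("fold", "auc", "aupr", "accuracy", "precision", "recall",
                 "f1", "threshold"))
  expect_equal(nrow(r1$per_fold), 3)
  expect_true(all(vapply(r1$loss_traces, length, numeric(1)) == 10))
  expect_true(all(r1$per_fold$auc >= 0 & r1$per_fold$auc <= 1))
  # different seed: same positives in play, different numbers out
  r3 <- cross_validate(data, toy_config(seed = 56, epochs = 10), n_folds = 3)
  expect_false(isTRUE(all.equal(r1$mean, r3$mean)))
})

test_that("candidate ranking follows the case-study protocol", {
  data <- generate_data(toy_spec(seed = 57))
  cfg <- toy_config(seed = 57, epochs = 60)
  dis <- colnames(data$E_ld)[5]
  ranked <- rank_candidates(data, dis, cfg, top_n = 10)
  expect_equal(nrow(ranked), 10)
  expect_equal(ranked$rank, 1:10)
  expect_true(all(diff(ranked$score) <= 0))
  expect_error(rank_candidates(data, "no-such-disease", cfg), "unknown disease")
  # planted-structure recovery: lncRNAs sharing the query's block score
  # higher on average than the rest
  all_ranked <- rank_candidates(data, dis, cfg, top_n = nrow(data$E_ld))
  block_d <- data$blocks$dis[5]
  idx <- match(all_ranked$lncRNA, rownames(data$E_ld))
  same <- data$blocks$lnc[idx] == block_d
  expect_gt(mean(all_ranked$score[same]), mean(all_ranked$score[!same]))
  # at least one same-block lncRNA in the top quartile
  expect_true(any(same[seq_len(ceiling(nrow(all_ranked) / 4))]))
})
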