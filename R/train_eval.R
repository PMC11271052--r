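# Five-fold cross-validation protocol, metric computation, and the
# case-study candidate ranking procedure.

#' Stratify known associations into cross-validation folds
#'
#' Positives are shuffled under the seed and partitioned into `n_folds`
#' near-equal test sets; an equal number of negatives is drawn once from
#' the unknown pairs and partitioned in parallel, so every fold's train
#' and test sets are balanced and mutually disjoint.
#'
#' @param E_ld binary lncRNA x disease association matrix.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return list of folds; each fold is a list with `fold_id`, `train`
#'   and `test` (data frames with columns `lnc`, `dis`, `label`).
#' @export
make_folds <- function(E_ld, n_folds = 5L, seed = 1L) {
  check_binary(E_ld, "E_ld")
  pos <- which(E_ld == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_folds < 2 || n_folds > n_pos) {
    stop(sprintf("`n_folds` must lie in [2, %d]", n_pos))
  }
  pairs <- sample_negatives(E_ld, seed = seed)
  neg <- pairs[pairs$label == 0, ]
  perm <- withr::with_seed(seed, sample(n_pos))
  fold_of_pos <- integer(n_pos)
  fold_of_pos[perm] <- rep(seq_len(n_folds), length.out = n_pos)
  fold_of_neg <- rep(seq_len(n_folds), length.out = n_pos)
  lapply(seq_len(n_folds), function(f) {
    test_pos <- data.frame(lnc = pos[fold_of_pos == f, 1L],
                           dis = pos[fold_of_pos == f, 2L], label = 1)
    train_pos <- data.frame(lnc = pos[fold_of_pos != f, 1L],
                            dis = pos[fold_of_pos != f, 2L], label = 1)
    list(fold_id = f,
         train = rbind(train_pos, neg[fold_of_neg != f, ]),
         test = rbind(test_pos, neg[fold_of_neg == f, ]))
  })
}

# Metrics ---------------------------------------------------------------------

auc_score <- function(probs, labels) {
  if (length(unique(labels)) < 2) {
    warning("AUC undefined: labels contain a single class")
    return(NA_real_)
  }
  r <- pROC::roc(labels, probs, levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Area under the precision-recall curve
#'
#' Step-wise (right-continuous) interpolation: ranking by decreasing
#' score, the curve is evaluated at each distinct threshold and the area
#' is `sum (recall_i - recall_{i-1}) * precision_i`.
#'
#' @param probs scores.
#' @param labels binary labels.
#' @return scalar AUPR, or `NA` when only one class is present.
#' @export
pr_auc <- function(probs, labels) {
  if (length(unique(labels)) < 2) {
    warning("AUPR undefined: labels contain a single class")
    return(NA_real_)
  }
  ord <- order(probs, decreasing = TRUE)
  l <- labels[ord]
  s <- probs[ord]
  n <- length(l)
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  keep <- c(s[-1] != s[-n], TRUE)   # last index at each distinct threshold
  prec <- (tp / (tp + fp))[keep]
  rec <- (tp / sum(l))[keep]
  sum(diff(c(0, rec)) * prec)
}

#' ROC curve coordinates
#'
#' @param probs scores; @param labels binary labels.
#' @return data frame with `threshold`, `fpr`, `tpr` at each distinct
#'   threshold (descending), starting from (0, 0).
#' @export
roc_coordinates <- function(probs, labels) {
  ord <- order(probs, decreasing = TRUE)
  l <- labels[ord]
  s <- probs[ord]
  n <- length(l)
  keep <- c(s[-1] != s[-n], TRUE)
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / max(sum(labels == 0), 1)),
             tpr = c(0, tp / max(sum(labels == 1), 1)))
}

#' Precision-recall curve coordinates
#'
#' @param probs scores; @param labels binary labels.
#' @return data frame with `threshold`, `recall`, `precision` at each
#'   distinct threshold (descending).
#' @export
pr_coordinates <- function(probs, labels) {
  ord <- order(probs, decreasing = TRUE)
  l <- labels[ord]
  s <- probs[ord]
  n <- length(l)
  keep <- c(s[-1] != s[-n], TRUE)
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  data.frame(threshold = s[keep],
             recall = tp / max(sum(labels == 1), 1),
             precision = tp / (tp + fp))
}

#' Evaluation metrics for one set of predictions
#'
#' AUC (trapezoidal ROC area), step-interpolated AUPR, and thresholded
#' accuracy, precision, recall and F1 (harmonic mean of precision and
#' recall).
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param threshold classification threshold (default 0.5).
#' @return one-row data frame with columns `auc`, `aupr`, `accuracy`,
#'   `precision`, `recall`, `f1`, `threshold`.  Metrics whose denominator
#'   is empty (e.g. precision with no positive prediction) are `NA`.
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.5) {
  stopifnot(length(probs) == length(labels))
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  data.frame(auc = auc_score(probs, labels),
             aupr = pr_auc(probs, labels),
             accuracy = (tp + tn) / length(labels),
             precision = precision, recall = recall, f1 = f1,
             threshold = threshold)
}

# Fold input assembly ---------------------------------------------------------

# Build the similarity-derived features and all graphs from a (possibly
# training-masked) association matrix.
build_model_inputs <- function(data, E_ld_graphs, E_ld_gip, cfg) {
  lgs <- gip_kernel_similarity(E_ld_gip, "rows")
  dgs <- gip_kernel_similarity(E_ld_gip, "columns")
  lsm <- fuse_similarities(data$lss, lgs, cfg$alpha, cfg$divisor)
  dsm <- fuse_similarities(data$dss, dgs, cfg$alpha, cfg$divisor)
  g <- build_hetero_graph(E_ld_graphs, data$E_lm, data$E_md)
  feats <- assemble_node_features(lsm, dsm)
  graphs <- list(
    lnc = list(LDL = metapath_subgraph(g, "LDL"),
               LML = metapath_subgraph(g, "LML")),
    dis = list(DLD = metapath_subgraph(g, "DLD"),
               DMD = metapath_subgraph(g, "DMD")))
  if (!cfg$ablation_nho) {
    graphs$knn_l <- knn_graph(lsm, min(cfg$knn_k, nrow(lsm)))
    graphs$knn_d <- knn_graph(dsm, min(cfg$knn_k, nrow(dsm)))
  }
  list(feats = feats, graphs = graphs, lsm = lsm, dsm = dsm)
}

# Ensure the dataset carries precomputed fold-independent similarities.
prepare_data <- function(data) {
  if (is.null(data$lss)) {
    if (is.null(data$seqs)) stop("dataset needs either `lss` or `seqs`")
    data$lss <- lncrna_sequence_similarity(data$seqs)
  }
  if (is.null(data$dss)) {
    if (is.null(data$dag)) stop("dataset needs either `dss` or `dag`")
    dis_ids <- colnames(data$E_ld) %||% data$dag$nodes
    data$dss <- disease_semantic_similarity(data$dag, dis_ids)
  }
  data
}

#' Five-fold cross-validated training and evaluation
#'
#' Runs the full protocol: fold construction with balanced negative
#' sampling, per-fold masking of test positives from the association
#' matrix (used both for the GIP similarity and for metapath/KNN graph
#' construction, so held-out edges never leak into the inputs), training
#' with Adam, and metric computation on the held-out pairs.
#'
#' @param data list with `E_ld`, `E_lm`, `E_md` and either raw inputs
#'   (`seqs`, `dag`) or precomputed similarities (`lss`, `dss`).
#' @param cfg a [model_config()].
#' @param n_folds number of folds (default 5).
#' @param seed seed for fold construction (default: the config seed).
#' @return object of class `eval_report`: list with `per_fold` (metrics
#'   data frame, one row per fold), `mean` (unweighted column means),
#'   `loss_traces` and `config`.
#' @export
cross_validate <- function(data, cfg = model_config(), n_folds = 5L,
                           seed = cfg$seed) {
  data <- prepare_data(data)
  folds <- make_folds(data$E_ld, n_folds, seed)
  rows <- vector("list", length(folds))
  traces <- vector("list", length(folds))
  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    E_tr <- data$E_ld
    test_pos <- fold$test[fold$test$label == 1, ]
    E_tr[cbind(test_pos$lnc, test_pos$dis)] <- 0
    E_graphs <- if (cfg$rebuild_graphs_per_fold) E_tr else data$E_ld
    E_gip <- if (cfg$recompute_gip_per_fold) E_tr else data$E_ld
    inputs <- build_model_inputs(data, E_graphs, E_gip, cfg)
    cfg_fold <- cfg
    cfg_fold$seed <- cfg$seed + f
    fit <- hgat_fit(inputs$feats, inputs$graphs, fold$train, cfg_fold)
    fw <- hgat_forward(fit$params, inputs$feats, inputs$graphs, cfg_fold,
                       fold$test)
    row <- evaluate_predictions(fw$probs, fold$test$label, cfg$threshold)
    rows[[f]] <- cbind(fold = f, row)
    traces[[f]] <- fit$loss_trace
    preds[[f]] <- cbind(fold = f, fold$test, prob = fw$probs)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, -1L]),
                 loss_traces = traces,
                 predictions = do.call(rbind, preds),
                 config = cfg, n_folds = n_folds,
                 seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$n_folds, x$seed))
  print(round(x$per_fold[, 1:7], digits), row.names = FALSE)
  cat("mean:\n")
  print(round(x$mean[1:6], digits))
  invisible(x)
}

#' Rank candidate lncRNAs for a query disease
#'
#' Case-study protocol: the query disease's known associations are
#' removed from the association matrix, the model is trained on the
#' remaining associations plus an equal number of sampled negatives
#' (pairs involving the query disease are excluded from the negative
#' candidates), and all lncRNAs are then scored against the query and
#' ranked by descending probability.
#'
#' @param data dataset list as in [cross_validate()].
#' @param disease disease identifier (must match a column of `E_ld`).
#' @param cfg a [model_config()].
#' @param top_n number of candidates returned (default 15).
#' @param exclude_known drop lncRNAs whose association with the query
#'   disease is already recorded in `E_ld` (default `FALSE`: known
#'   associations stay in the ranking, which is how recovery is checked).
#' @return data frame with columns `rank`, `lncRNA`, `score`, scores
#'   descending.
#' @export
rank_candidates <- function(data, disease, cfg = model_config(),
                            top_n = 15L, exclude_known = FALSE) {
  data <- prepare_data(data)
  dis_ids <- colnames(data$E_ld) %||% paste0("d", seq_len(ncol(data$E_ld)))
  j <- match(disease, dis_ids)
  if (is.na(j)) stop("unknown disease id: ", disease)
  E_tr <- data$E_ld
  E_tr[, j] <- 0
  query_col <- data.frame(lnc = seq_len(nrow(E_tr)), dis = j)
  pairs <- sample_negatives(E_tr, seed = cfg$seed, exclude = query_col)
  inputs <- build_model_inputs(data, E_tr, E_tr, cfg)
  fit <- hgat_fit(inputs$feats, inputs$graphs, pairs, cfg)
  all_pairs <- data.frame(lnc = seq_len(nrow(E_tr)), dis = j)
  fw <- hgat_forward(fit$params, inputs$feats, inputs$graphs, cfg, all_pairs)
  lnc_ids <- rownames(data$E_ld) %||% paste0("l", seq_len(nrow(data$E_ld)))
  res <- data.frame(lncRNA = lnc_ids, score = fw$probs)
  if (exclude_known) res <- res[data$E_ld[, j] == 0, ]
  res <- res[order(-res$score, seq_len(nrow(res))), ]
  res <- utils::head(res, top_n)
  res <- data.frame(rank = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
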