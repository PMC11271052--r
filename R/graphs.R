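# Graph construction: the ternary lncRNA-miRNA-disease heterogeneous graph,
# balanced negative sampling, the four metapath-specific homogeneous
# subgraphs, and the KNN similarity graphs.

#' Assemble the ternary lncRNA-miRNA-disease heterogeneous graph
#'
#' @param E_ld binary lncRNA x disease association matrix.
#' @param E_lm binary lncRNA x miRNA association matrix.
#' @param E_md binary miRNA x disease association matrix.
#' @return object of class `hetero_graph` holding the three matrices and
#'   the three ordered id vectors (taken from dimnames when present,
#'   otherwise generated as `l1..`, `d1..`, `m1..`).
#' @details Shapes must be mutually consistent: `nrow(E_ld) == nrow(E_lm)`
#'   (lncRNAs), `ncol(E_ld) == ncol(E_md)` (diseases) and
#'   `ncol(E_lm) == nrow(E_md)` (miRNAs).  The full adjacency over all
#'   node types is available via [block_matrix()].
#' @export
build_hetero_graph <- function(E_ld, E_lm, E_md) {
  check_binary(E_ld, "E_ld")
  check_binary(E_lm, "E_lm")
  check_binary(E_md, "E_md")
  if (nrow(E_ld) != nrow(E_lm)) {
    stop(sprintf("dimension error: E_ld has %d lncRNA rows but E_lm has %d",
                 nrow(E_ld), nrow(E_lm)))
  }
  if (ncol(E_ld) != ncol(E_md)) {
    stop(sprintf("dimension error: E_ld has %d disease columns but E_md has %d",
                 ncol(E_ld), ncol(E_md)))
  }
  if (ncol(E_lm) != nrow(E_md)) {
    stop(sprintf("dimension error: E_lm has %d miRNA columns but E_md has %d miRNA rows",
                 ncol(E_lm), nrow(E_md)))
  }
  lnc_ids <- rownames(E_ld) %||% paste0("l", seq_len(nrow(E_ld)))
  dis_ids <- colnames(E_ld) %||% paste0("d", seq_len(ncol(E_ld)))
  mir_ids <- colnames(E_lm) %||% paste0("m", seq_len(ncol(E_lm)))
  dimnames(E_ld) <- list(lnc_ids, dis_ids)
  dimnames(E_lm) <- list(lnc_ids, mir_ids)
  dimnames(E_md) <- list(mir_ids, dis_ids)
  structure(list(E_ld = E_ld, E_lm = E_lm, E_md = E_md,
                 lnc_ids = lnc_ids, dis_ids = dis_ids, mir_ids = mir_ids),
            class = "hetero_graph")
}

#' Block adjacency matrix of a heterogeneous graph
#'
#' Returns the symmetric block matrix over all node types
#' (lncRNA, disease, miRNA in that order) with zero diagonal blocks:
#' off-diagonal blocks are `E_ld`, `E_lm`, `E_md` and their transposes.
#'
#' @param g a [build_hetero_graph()] object.
#' @return square symmetric binary matrix of size
#'   `N_lnc + N_dis + N_mir`.
#' @export
block_matrix <- function(g) {
  stopifnot(inherits(g, "hetero_graph"))
  nl <- length(g$lnc_ids); nd <- length(g$dis_ids); nm <- length(g$mir_ids)
  G <- matrix(0, nl + nd + nm, nl + nd + nm)
  ids <- c(g$lnc_ids, g$dis_ids, g$mir_ids)
  dimnames(G) <- list(ids, ids)
  il <- seq_len(nl); id <- nl + seq_len(nd); im <- nl + nd + seq_len(nm)
  G[il, id] <- g$E_ld;    G[id, il] <- t(g$E_ld)
  G[il, im] <- g$E_lm;    G[im, il] <- t(g$E_lm)
  G[im, id] <- g$E_md;    G[id, im] <- t(g$E_md)
  G
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf(paste0("hetero_graph: %d lncRNAs, %d diseases, %d miRNAs; ",
                     "edges L-D %d, L-M %d, M-D %d\n"),
              length(x$lnc_ids), length(x$dis_ids), length(x$mir_ids),
              sum(x$E_ld), sum(x$E_lm), sum(x$E_md)))
  invisible(x)
}

#' Balanced positive/negative lncRNA-disease pairs
#'
#' Labels every known association 1 and draws an equal number of unknown
#' (zero) pairs uniformly without replacement, labelled 0.  Sampled
#' negatives are training labels only; they are never added as graph
#' edges.
#'
#' @param E_ld binary lncRNA x disease matrix.
#' @param seed integer seed; the draw is reproducible and leaves the
#'   caller's RNG state untouched.
#' @param n_neg number of negatives (default: number of positives).
#' @param exclude optional two-column matrix/data frame of (lnc, dis)
#'   index pairs that must not be sampled as negatives (e.g. a held-out
#'   fold's positive pairs that were masked out of `E_ld`).
#' @return data frame with columns `lnc`, `dis` (integer indices into the
#'   rows/columns of `E_ld`) and `label` (1/0), positives first.
#' @export
sample_negatives <- function(E_ld, seed, n_neg = NULL, exclude = NULL) {
  check_binary(E_ld, "E_ld")
  pos <- which(E_ld == 1, arr.ind = TRUE)
  if (is.null(n_neg)) n_neg <- nrow(pos)
  zeros <- which(E_ld == 0)
  if (!is.null(exclude) && NROW(exclude) > 0) {
    ex <- as.data.frame(exclude)
    excl_lin <- (as.integer(ex[[2L]]) - 1L) * nrow(E_ld) + as.integer(ex[[1L]])
    zeros <- setdiff(zeros, excl_lin)
  }
  if (length(zeros) < n_neg) {
    stop(sprintf(paste0("infeasible sampling: %d negatives requested but ",
                        "only %d unknown pairs available"),
                 n_neg, length(zeros)))
  }
  neg_lin <- withr::with_seed(seed, sample(zeros, n_neg))
  neg <- cbind((neg_lin - 1L) %% nrow(E_ld) + 1L,
               (neg_lin - 1L) %/% nrow(E_ld) + 1L)
  out <- data.frame(
    lnc = c(pos[, 1L], neg[, 1L]),
    dis = c(pos[, 2L], neg[, 2L]),
    label = rep(c(1, 0), c(nrow(pos), nrow(neg))))
  rownames(out) <- NULL
  out
}

#' Metapath-induced homogeneous subgraph
#'
#' Two same-type nodes are adjacent iff at least one instance of the
#' metapath connects them through a middle node: `LDL` joins lncRNAs
#' sharing a disease, `LML` lncRNAs sharing a miRNA, `DLD` diseases
#' sharing a lncRNA, `DMD` diseases sharing a miRNA.  Multiplicity is
#' ignored (binary edges) and a self-loop is added to every node so that
#' attention over neighbours is always well defined.
#'
#' @param g a [build_hetero_graph()] object.
#' @param path_type one of `"LDL"`, `"LML"`, `"DLD"`, `"DMD"`.
#' @return object of class `metapath_subgraph` with fields `path_type`,
#'   `node_type` (`"lnc"` or `"dis"`) and `adjacency` (binary symmetric
#'   matrix with unit diagonal).
#' @export
metapath_subgraph <- function(g, path_type) {
  stopifnot(inherits(g, "hetero_graph"))
  if (length(path_type) != 1L || !path_type %in% c("LDL", "LML", "DLD", "DMD")) {
    stop("unknown path_type: must be one of LDL, LML, DLD, DMD")
  }
  B <- switch(path_type,
              LDL = g$E_ld,
              LML = g$E_lm,
              DLD = t(g$E_ld),
              DMD = t(g$E_md))
  A <- (tcrossprod(B) > 0) * 1
  diag(A) <- 1
  structure(list(path_type = path_type,
                 node_type = if (path_type %in% c("LDL", "LML")) "lnc" else "dis",
                 adjacency = A),
            class = "metapath_subgraph")
}

#' K-nearest-neighbour graph from a similarity matrix
#'
#' Each node selects the `k` most similar nodes; the neighbour set always
#' contains the node itself (self is treated as the most similar), and the
#' remaining `k - 1` slots are filled by descending similarity with ties
#' broken by ascending node index.  The directed selection is then
#' symmetrised by union so the result is an undirected graph.
#'
#' @param sim square similarity matrix.
#' @param k number of neighbours per node, `1 <= k <= nrow(sim)`.
#' @param symmetrize symmetrise by union (default `TRUE`); with `FALSE`
#'   the raw row-wise selection is returned (every row sums to `k`).
#' @return binary adjacency matrix.
#' @export
knn_graph <- function(sim, k, symmetrize = TRUE) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  n <- nrow(sim)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) {
    stop(sprintf("`k` must lie in [1, %d]", n))
  }
  k <- as.integer(k)
  A <- matrix(0, n, n, dimnames = dimnames(sim))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    # order by similarity descending, ties by ascending index
    ord <- others[order(-sim[i, others], others)]
    A[i, c(i, utils::head(ord, k - 1L))] <- 1
  }
  if (symmetrize) A <- ((A + t(A)) > 0) * 1
  A
}

#' Node feature matrices from the fused similarities
#'
#' Node features are the raw rows of the fused similarity matrices: the
#' feature vector of lncRNA i is row i of the fused lncRNA similarity,
#' and likewise for diseases (so feature width equals the number of nodes
#' of that type).
#'
#' @param lsm fused lncRNA similarity matrix.
#' @param dsm fused disease similarity matrix.
#' @return list of class `node_features` with elements `lnc` and `dis`.
#' @export
assemble_node_features <- function(lsm, dsm) {
  stopifnot(is.matrix(lsm), nrow(lsm) == ncol(lsm),
            is.matrix(dsm), nrow(dsm) == ncol(dsm))
  structure(list(lnc = lsm, dis = dsm), class = "node_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
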