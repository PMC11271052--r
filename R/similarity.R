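# Similarity matrices feeding the node features of both graph branches:
# sequence similarity for lncRNAs, DAG semantic similarity for diseases,
# GIP kernel similarity for either side, and their linear fusion.

#' Pairwise lncRNA sequence similarity from weighted edit distance
#'
#' Computes, for every pair of sequences, a similarity of the form
#' `1 - dist / (len_i + len_j)` where `dist` is the minimum-cost weighted
#' Levenshtein distance with substitution cost `sub_cost` and
#' insertion/deletion cost `indel_cost`.  With the default costs
#' (substitution 2, indel 1) every entry lies in `[0, 1]` and identical
#' sequences score 1.
#'
#' @param seqs named character vector of nucleotide sequences; names are
#'   the lncRNA identifiers and must be unique and non-empty.  Case is
#'   ignored.  Characters outside `A,C,G,T,U` are kept and matched
#'   literally (a warning is emitted once).
#' @param sub_cost positive substitution cost (default 2).
#' @param indel_cost positive insertion/deletion cost (default 1).
#' @return symmetric numeric matrix with the sequence ids as dimnames;
#'   the diagonal is 1 (self-similarity).
#' @details A pair of two *distinct* empty sequences has a zero
#'   denominator and is rejected with an error naming the pair.  An empty
#'   sequence against a non-empty one is well defined (all insertions).
#' @export
lncrna_sequence_similarity <- function(seqs, sub_cost = 2, indel_cost = 1) {
  seqs <- as_sequences(seqs)
  if (length(seqs) == 0L) stop("`seqs` must contain at least one sequence")
  if (!is.numeric(sub_cost) || sub_cost <= 0 || !is.numeric(indel_cost) ||
      indel_cost <= 0) {
    stop("edit costs must be positive")
  }
  up <- toupper(seqs)
  if (any(grepl("[^ACGTU]", up[nzchar(up)]))) {
    warning("sequences contain characters outside {A,C,G,T,U}; ",
            "they are treated as ordinary symbols by the edit distance")
  }
  lens <- nchar(up)
  denom <- outer(lens, lens, "+")
  empty_pair <- denom == 0
  diag(empty_pair) <- FALSE
  if (any(empty_pair)) {
    ij <- which(empty_pair, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "similarity undefined for pair ('%s', '%s'): both sequences empty",
      names(seqs)[ij[1L]], names(seqs)[ij[2L]]))
  }
  d <- utils::adist(up, costs = list(insertions = indel_cost,
                                     deletions = indel_cost,
                                     substitutions = sub_cost))
  diag(denom) <- pmax(diag(denom), 1)  # self-pairs: dist is 0 anyway
  sim <- 1 - d / denom
  diag(sim) <- 1
  sim <- (sim + t(sim)) / 2
  dimnames(sim) <- list(names(seqs), names(seqs))
  sim
}

# Coerce a list or character vector of sequences to a named character
# vector with validated, unique, non-empty ids.
as_sequences <- function(seqs) {
  if (is.list(seqs)) seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("`seqs` must contain at least one sequence")
  if (!is.character(seqs)) stop("`seqs` must be a character vector")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("every sequence must have a non-empty id (names of `seqs`)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs
}

#' Disease semantic similarity over an ontology DAG
#'
#' Implements the Wang-style semantic similarity: each disease `D` spreads
#' a contribution of 1 to itself and `0.5^depth` (taking the maximum over
#' paths) to every ancestor; the semantic value `DV(D)` is the sum of the
#' contributions over the ancestor set `T(D)`.  The similarity of two
#' diseases is the sum of both contributions over the shared ancestors,
#' divided by `DV(d_i) + DV(d_j)`.
#'
#' @param dag a [disease_dag()] object.
#' @param diseases character vector of disease ids (default: all DAG
#'   nodes, in their declared order).  Unknown ids raise an error.
#' @return symmetric similarity matrix with unit diagonal; diseases in
#'   disjoint DAG components have similarity 0.
#' @export
disease_semantic_similarity <- function(dag, diseases = NULL) {
  stopifnot(inherits(dag, "disease_dag"))
  if (is.null(diseases)) diseases <- dag$nodes
  missing_ids <- setdiff(diseases, dag$nodes)
  if (length(missing_ids)) {
    stop("diseases absent from the DAG: ",
         paste(missing_ids, collapse = ", "))
  }
  contribs <- lapply(diseases, function(d) semantic_contributions(dag, d))
  names(contribs) <- diseases
  dv <- vapply(contribs, sum, numeric(1))
  n <- length(diseases)
  s <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      ci <- contribs[[i]]
      for (j in seq.int(i + 1L, n)) {
        cj <- contribs[[j]]
        shared <- intersect(names(ci), names(cj))
        if (length(shared)) {
          s[i, j] <- s[j, i] <-
            sum(ci[shared] + cj[shared]) / (dv[i] + dv[j])
        }
      }
    }
  }
  dimnames(s) <- list(diseases, diseases)
  s
}

# Contribution of every ancestor of D to D's semantics: 1 for D itself,
# otherwise 0.5 * max over the node's children that lie on a path to D.
# The decay factor 0.5 is a fixed constant of the measure.
semantic_contributions <- function(dag, d) {
  anc <- dag_ancestors(dag, d)
  contrib <- stats::setNames(rep(NA_real_, length(anc)), anc)
  contrib[[d]] <- 1
  visit <- function(node) {
    if (!is.na(contrib[[node]])) return(contrib[[node]])
    kids <- intersect(dag$children[[node]], anc)
    val <- 0.5 * max(vapply(kids, visit, numeric(1)))
    contrib[[node]] <<- val
    val
  }
  for (node in anc) visit(node)
  contrib
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity of two nodes from their binary association profiles:
#' `exp(-xi * ||profile_i - profile_j||^2)` with bandwidth
#' `xi = 1 / mean(||profile||^2)` over the chosen orientation.
#'
#' @param assoc binary association matrix (e.g. lncRNA x disease).
#' @param orientation `"rows"` to compare row profiles (lncRNAs),
#'   `"columns"` for column profiles (diseases).
#' @return symmetric similarity matrix with unit diagonal and strictly
#'   positive entries.
#' @export
gip_kernel_similarity <- function(assoc, orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  check_binary(assoc, "assoc")
  p <- if (orientation == "rows") assoc else t(assoc)
  if (all(p == 0)) {
    stop("degenerate input: association matrix is all zero, ",
         "GIP bandwidth is undefined")
  }
  sq <- rowSums(p^2)
  xi <- 1 / mean(sq)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(p), 0)
  s <- exp(-xi * d2)
  diag(s) <- 1
  s <- (s + t(s)) / 2
  ids <- rownames(p)
  if (!is.null(ids)) dimnames(s) <- list(ids, ids)
  s
}

#' Linear fusion of two similarity matrices
#'
#' Entry-wise `(alpha * a + (1 - alpha) * b) / divisor`.  The default
#' divisor of 2 halves the convex combination, so fused entries reach at
#' most 0.5; the uniform scale is immaterial downstream because node
#' features pass through a learned projection.
#'
#' @param a,b similarity matrices with identical node ids and order
#'   (dimnames, when present, must agree).
#' @param alpha weight of `a`, in `[0, 1]` (default 0.5).
#' @param divisor positive scalar (default 2).
#' @return fused similarity matrix.
#' @export
fuse_similarities <- function(a, b, alpha = 0.5, divisor = 2) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]")
  }
  if (!is.numeric(divisor) || divisor <= 0) stop("`divisor` must be positive")
  if (!identical(dim(a), dim(b))) {
    stop("similarity matrices have different dimensions: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("similarity matrices are over different (or differently ordered) ",
         "node sets")
  }
  (alpha * a + (1 - alpha) * b) / divisor
}

# Shared validation helpers --------------------------------------------------

check_binary <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("`%s` must be a numeric matrix", name))
  }
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1 entries)", name))
  }
  invisible(m)
}

check_similarity <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) stop("similarity matrix is not symmetric")
  if (min(m) < -tol || max(m) > 1 + tol) {
    stop("similarity entries outside [0, 1]")
  }
  invisible(m)
}
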