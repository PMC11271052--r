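# Synthetic data generator: clustered lncRNA sequences, a rooted random
# disease ontology DAG, and three sparse bipartite association matrices
# with planted block structure.  The same block assignment drives all
# three matrices (and the sequence/DAG clusters), so metapaths carry a
# recoverable signal, which is exactly the mechanism the attention model
# exploits.  Held-out links inside planted blocks are then statistically
# recoverable from the remaining data.

#' Specification of a synthetic dataset
#'
#' Defaults emulate the scale of the benchmark association collection
#' used throughout: 240 lncRNAs x 412 diseases x 495 miRNAs, with
#' per-matrix association probabilities tuned so the expected edge counts
#' are about 2697 (lncRNA-disease), 1002 (lncRNA-miRNA) and 13562
#' (miRNA-disease).
#'
#' @param n_lnc,n_dis,n_mir node counts.
#' @param n_blocks number of planted communities; nodes of every type
#'   are assigned to blocks round-robin.
#' @param p_in,p_out within-/between-block association probabilities;
#'   either scalars or named vectors with entries `ld`, `lm`, `md`.
#'   Must satisfy `0 <= p_out < p_in <= 1` per matrix.
#' @param seq_len_range integer range of the ancestral sequence lengths.
#' @param mutation_rate per-base divergence of a sequence from its block
#'   ancestor, in `[0, 1]`.
#' @param dag_branching children per internal node of the within-block
#'   disease trees.
#' @param extra_parent_prob probability that a disease receives a second
#'   parent (making the ontology a DAG rather than a tree).
#' @param shuffle_blocks destroy the planted structure: associations are
#'   drawn i.i.d. at the matched marginal density, independent of the
#'   blocks, so held-out links carry no recoverable signal (null model
#'   for ablation checks).
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lnc = 240L, n_dis = 412L, n_mir = 495L,
                           n_blocks = 6L,
                           p_in = c(ld = 0.1387, lm = 0.0406, md = 0.2990),
                           p_out = c(ld = 0.005, lm = 0.002, md = 0.02),
                           seq_len_range = c(150L, 250L),
                           mutation_rate = 0.05, dag_branching = 3L,
                           extra_parent_prob = 0.1, shuffle_blocks = FALSE,
                           seed = 1L) {
  expand <- function(p) {
    if (length(p) == 1L) p <- c(ld = unname(p), lm = unname(p), md = unname(p))
    stopifnot(all(c("ld", "lm", "md") %in% names(p)))
    p[c("ld", "lm", "md")]
  }
  p_in <- expand(p_in); p_out <- expand(p_out)
  stopifnot(n_lnc >= 1, n_dis >= 1, n_mir >= 1, n_blocks >= 1,
            all(p_out >= 0), all(p_out < p_in), all(p_in <= 1),
            mutation_rate >= 0, mutation_rate <= 1,
            length(seq_len_range) == 2L,
            seq_len_range[1] >= 1, seq_len_range[2] >= seq_len_range[1],
            dag_branching >= 1, extra_parent_prob >= 0, extra_parent_prob <= 1)
  structure(list(n_lnc = as.integer(n_lnc), n_dis = as.integer(n_dis),
                 n_mir = as.integer(n_mir), n_blocks = as.integer(n_blocks),
                 p_in = p_in, p_out = p_out,
                 seq_len_range = as.integer(seq_len_range),
                 mutation_rate = mutation_rate,
                 dag_branching = as.integer(dag_branching),
                 extra_parent_prob = extra_parent_prob,
                 shuffle_blocks = isTRUE(shuffle_blocks),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

block_assignment <- function(n, n_blocks) rep_len(seq_len(n_blocks), n)

#' Generate clustered lncRNA sequences
#'
#' Each block has a random ancestral RNA sequence; members are copies
#' with independent per-base mutations at `mutation_rate`, so
#' within-block sequence similarity exceeds between-block similarity in
#' expectation.
#'
#' @param spec a [synthetic_spec()].
#' @return named character vector over the alphabet `A,C,G,U`, ids
#'   `l1..`; the block assignment is attached as attribute `"block"`.
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  alphabet <- c("A", "C", "G", "U")
  blocks <- block_assignment(spec$n_lnc, spec$n_blocks)
  seqs <- withr::with_seed(spec$seed + 1L, {
    ancestors <- lapply(seq_len(spec$n_blocks), function(b) {
      len <- sample(seq.int(spec$seq_len_range[1], spec$seq_len_range[2]), 1L)
      sample(alphabet, len, replace = TRUE)
    })
    vapply(seq_len(spec$n_lnc), function(i) {
      s <- ancestors[[blocks[i]]]
      mut <- which(stats::runif(length(s)) < spec$mutation_rate)
      for (j in mut) s[j] <- sample(setdiff(alphabet, s[j]), 1L)
      paste(s, collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("l", seq_len(spec$n_lnc))
  attr(seqs, "block") <- blocks
  seqs
}

#' Generate a rooted random disease ontology DAG
#'
#' Diseases are grouped by block under a shared root: the first disease
#' is the global root, each block's first member hangs off the root, and
#' every further member attaches to an earlier member of its own block
#' in a `dag_branching`-ary tree, so block-mates share close ancestors.
#' With probability `extra_parent_prob` a disease receives a second
#' (earlier, same-block) parent; acyclicity holds by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return a [disease_dag()] over ids `d1..`; block assignment in
#'   attribute `"block"`.
#' @export
generate_dag <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_dis
  ids <- paste0("d", seq_len(n))
  blocks <- block_assignment(n, spec$n_blocks)
  members <- split(seq_len(n), blocks)
  edges <- list()
  withr::with_seed(spec$seed + 2L, {
    for (b in seq_along(members)) {
      mem <- members[[b]]
      for (m in seq_along(mem)) {
        node <- mem[m]
        if (node == 1L) next                      # global root
        parent <- if (m == 1L) 1L else mem[ceiling((m - 1) / spec$dag_branching)]
        edges[[length(edges) + 1L]] <- c(ids[node], ids[parent])
        if (m > 2L && stats::runif(1) < spec$extra_parent_prob) {
          extra <- sample(mem[seq_len(m - 1L)], 1L)
          if (extra != parent) {
            edges[[length(edges) + 1L]] <- c(ids[node], ids[extra])
          }
        }
      }
    }
  })
  edge_df <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character())
  }
  dag <- disease_dag(edge_df, nodes = ids)
  attr(dag, "block") <- blocks
  dag
}

#' Generate the three planted-block association matrices
#'
#' Entries are independent Bernoulli draws at `p_in` inside matched
#' blocks and `p_out` elsewhere (or i.i.d. at the marginal density when
#' `shuffle_blocks` is set).  A repair step then gives every node at
#' least one association in each matrix it participates in, by adding a
#' within-block edge (any edge under `shuffle_blocks`).
#'
#' @param spec a [synthetic_spec()].
#' @return list with binary matrices `E_ld`, `E_lm`, `E_md` (dimnames
#'   `l*`, `d*`, `m*`), block assignments in attribute `"block"`, and the
#'   repair count in attribute `"n_repaired"`.
#' @export
generate_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bl <- block_assignment(spec$n_lnc, spec$n_blocks)
  bd <- block_assignment(spec$n_dis, spec$n_blocks)
  bm <- block_assignment(spec$n_mir, spec$n_blocks)
  n_repaired <- 0L
  draw <- function(brow, bcol, p_in, p_out) {
    same <- outer(brow, bcol, `==`)
    P <- ifelse(same, p_in, p_out)
    if (spec$shuffle_blocks) P[] <- mean(P)
    (matrix(stats::runif(length(P)), nrow(P)) < P) * 1
  }
  fix_rows <- function(E, br, bc) {
    for (i in which(rowSums(E) == 0)) {
      cand <- if (spec$shuffle_blocks) seq_len(ncol(E)) else which(bc == br[i])
      if (!length(cand)) cand <- seq_len(ncol(E))
      E[i, if (length(cand) == 1L) cand else sample(cand, 1L)] <- 1
      n_repaired <<- n_repaired + 1L
    }
    E
  }
  repair <- function(E, brow, bcol) {
    E <- fix_rows(E, brow, bcol)
    t(fix_rows(t(E), bcol, brow))
  }
  out <- withr::with_seed(spec$seed + 3L, {
    E_ld <- repair(draw(bl, bd, spec$p_in["ld"], spec$p_out["ld"]), bl, bd)
    E_lm <- repair(draw(bl, bm, spec$p_in["lm"], spec$p_out["lm"]), bl, bm)
    E_md <- repair(draw(bm, bd, spec$p_in["md"], spec$p_out["md"]), bm, bd)
    list(E_ld = E_ld, E_lm = E_lm, E_md = E_md)
  })
  dimnames(out$E_ld) <- list(paste0("l", seq_len(spec$n_lnc)),
                             paste0("d", seq_len(spec$n_dis)))
  dimnames(out$E_lm) <- list(paste0("l", seq_len(spec$n_lnc)),
                             paste0("m", seq_len(spec$n_mir)))
  dimnames(out$E_md) <- list(paste0("m", seq_len(spec$n_mir)),
                             paste0("d", seq_len(spec$n_dis)))
  attr(out, "block") <- list(lnc = bl, dis = bd, mir = bm)
  attr(out, "n_repaired") <- n_repaired
  out
}

#' Generate a complete in-memory synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `seqs`, `dag`, `E_ld`, `E_lm`, `E_md`, `blocks` and
#'   the `spec`; directly usable by [cross_validate()].
#' @export
generate_data <- function(spec = synthetic_spec()) {
  assoc <- generate_associations(spec)
  list(seqs = generate_sequences(spec),
       dag = generate_dag(spec),
       E_ld = assoc$E_ld, E_lm = assoc$E_lm, E_md = assoc$E_md,
       blocks = attr(assoc, "block"), spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Produces exactly the plain-text formats the package readers consume:
#' a FASTA file, a child/parent DAG TSV, three edge-list TSVs, three
#' node-universe files and a YAML manifest recording the spec (round
#' trips through [read_dataset()] reproduce the matrices bit-exactly).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return the generated dataset, invisibly.
#' @export
generate_dataset <- function(spec, dir) {
  data <- generate_data(spec)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  write_fasta(data$seqs, file.path(dir, "sequences.fasta"))
  utils::write.table(
    data.frame(child = data$dag$edges$child, parent = data$dag$edges$parent),
    file.path(dir, "disease_dag.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(data$E_ld, file.path(dir, "lnc_dis.tsv"),
                  c("lncRNA", "disease"))
  write_edge_list(data$E_lm, file.path(dir, "lnc_mir.tsv"),
                  c("lncRNA", "miRNA"))
  write_edge_list(data$E_md, file.path(dir, "mir_dis.tsv"),
                  c("miRNA", "disease"))
  writeLines(rownames(data$E_ld), file.path(dir, "nodes_lnc.txt"))
  writeLines(colnames(data$E_ld), file.path(dir, "nodes_dis.txt"))
  writeLines(colnames(data$E_lm), file.path(dir, "nodes_mir.txt"))
  manifest <- list(
    spec = lapply(unclass(spec), function(x) if (is.numeric(x)) unname(x) else x),
    p_names = c("ld", "lm", "md"),
    densities = list(ld = mean(data$E_ld), lm = mean(data$E_lm),
                     md = mean(data$E_md)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(data)
}
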