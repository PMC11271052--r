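# Readers and writers for the on-disk formats: FASTA sequences, DAG and
# association edge lists (TSV with headers), node-universe files and
# similarity matrices.

#' Read sequences from a FASTA file
#'
#' Multi-line records are concatenated; the id of each record is the
#' first whitespace-delimited token of its header line.
#'
#' @param path FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bss <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("cannot parse FASTA file ", path, ": ",
                         conditionMessage(e))
                  })
  if (length(bss) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(bss)
  names(seqs) <- sub("\\s.*$", "", names(bss))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequences(seqs)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a node-universe file (one id per line)
#'
#' @param path text file.
#' @return character vector of ids.
#' @export
read_node_ids <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) stop("duplicate node ids in ", path)
  ids
}

#' Read a two-column association edge list into a binary matrix
#'
#' The TSV must have a header and exactly two columns (left id, right
#' id).  Unknown ids raise an error listing them; duplicate edges are
#' collapsed to a single entry with a warning.
#'
#' @param path TSV file.
#' @param left_universe,right_universe ordered id vectors indexing the
#'   rows and columns of the result.
#' @return binary matrix of dimension
#'   `length(left_universe) x length(right_universe)`.
#' @export
read_edge_list <- function(path, left_universe, right_universe) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) != 2L) {
    stop(sprintf("edge list %s: expected 2 columns, found %d", path, ncol(df)))
  }
  E <- matrix(0, length(left_universe), length(right_universe),
              dimnames = list(left_universe, right_universe))
  if (nrow(df) > 0) {
    i <- match(df[[1L]], left_universe)
    j <- match(df[[2L]], right_universe)
    unknown <- unique(c(df[[1L]][is.na(i)], df[[2L]][is.na(j)]))
    if (length(unknown)) {
      stop("edge list ", path, " contains unknown identifiers: ",
           paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(cbind(i, j))) {
      warning("duplicate edges in ", path, " collapsed to single entries")
    }
    E[cbind(i, j)] <- 1
  }
  E
}

#' Write a binary association matrix as an edge list
#'
#' @param E binary matrix with dimnames.
#' @param path output TSV.
#' @param col_names header names for the two columns.
#' @export
write_edge_list <- function(E, path, col_names = c("left", "right")) {
  check_binary(E, "E")
  idx <- which(E == 1, arr.ind = TRUE)
  df <- data.frame(rownames(E)[idx[, 1L]], colnames(E)[idx[, 2L]])
  df <- df[order(idx[, 1L], idx[, 2L]), ]
  names(df) <- col_names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease DAG from a child/parent TSV
#'
#' @param path TSV with header and two columns: child id, parent id.
#' @param nodes optional node universe (ids without edges are allowed).
#' @return a [disease_dag()].
#' @export
read_dag_file <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) != 2L) {
    stop(sprintf("DAG file %s: expected 2 columns, found %d", path, ncol(df)))
  }
  disease_dag(df, nodes = nodes)
}

#' Write / read a similarity matrix as TSV
#'
#' The matrix is stored with a header row and a leading id column.
#'
#' @param m similarity matrix with dimnames.
#' @param path file path.
#' @export
write_similarity_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read a dataset directory written by [generate_dataset()]
#'
#' @param dir directory containing `sequences.fasta`, `disease_dag.tsv`,
#'   the three association TSVs and the three node-universe files.
#' @return dataset list usable by [cross_validate()].
#' @export
read_dataset <- function(dir) {
  lnc <- read_node_ids(file.path(dir, "nodes_lnc.txt"))
  dis <- read_node_ids(file.path(dir, "nodes_dis.txt"))
  mir <- read_node_ids(file.path(dir, "nodes_mir.txt"))
  list(
    seqs = read_fasta(file.path(dir, "sequences.fasta")),
    dag = read_dag_file(file.path(dir, "disease_dag.tsv"), nodes = dis),
    E_ld = read_edge_list(file.path(dir, "lnc_dis.tsv"), lnc, dis),
    E_lm = read_edge_list(file.path(dir, "lnc_mir.tsv"), lnc, mir),
    E_md = read_edge_list(file.path(dir, "mir_dis.tsv"), mir, dis))
}
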