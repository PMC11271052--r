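# Disease ontology DAG: MeSH-style child -> parent edge list with
# acyclicity checks and ancestor queries (used by the semantic similarity).

#' Construct a disease ontology DAG
#'
#' @param edges two-column data frame or matrix of directed
#'   `child -> parent` pairs (character ids).  May have zero rows.
#' @param nodes optional character vector declaring the full node
#'   universe (so isolated diseases are representable); defaults to the
#'   ids appearing in `edges`.  Every edge endpoint must be declared.
#' @return an object of class `disease_dag` with elements `nodes`,
#'   `edges` (data frame `child`, `parent`), `parents` and `children`
#'   (named lists), and `roots` (nodes without parents).
#' @export
disease_dag <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2 && nrow(edges) > 0) {
    stop("`edges` must have two columns: child, parent")
  }
  if (nrow(edges) > 0) {
    edges <- data.frame(child = as.character(edges[[1L]]),
                        parent = as.character(edges[[2L]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = character(), parent = character())
  }
  if (is.null(nodes)) {
    nodes <- unique(c(edges$child, edges$parent))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node ids in `nodes`")
    unknown <- setdiff(unique(c(edges$child, edges$parent)), nodes)
    if (length(unknown)) {
      stop("edge endpoints not declared as nodes: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (length(nodes) == 0L) stop("DAG must contain at least one node")
  if (nrow(edges) > 0 && any(edges$child == edges$parent)) {
    stop("invalid DAG: self-loop edge")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) stop("invalid DAG: cycle detected")
  parents <- lapply(nodes, function(v) edges$parent[edges$child == v])
  children <- lapply(nodes, function(v) edges$child[edges$parent == v])
  names(parents) <- names(children) <- nodes
  structure(list(nodes = nodes, edges = edges, parents = parents,
                 children = children, graph = g,
                 roots = nodes[lengths(parents) == 0L]),
            class = "disease_dag")
}

#' Ancestor set of a disease (including the disease itself)
#'
#' @param dag a [disease_dag()].
#' @param d disease id.
#' @return character vector of ancestors, `d` first.
#' @export
dag_ancestors <- function(dag, d) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!d %in% dag$nodes) stop("disease not in DAG: ", d)
  anc <- igraph::subcomponent(dag$graph, d, mode = "out")$name
  c(d, setdiff(anc, d))
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d nodes, %d edges, %d root(s)\n",
              length(x$nodes), nrow(x$edges), length(x$roots)))
  invisible(x)
}
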