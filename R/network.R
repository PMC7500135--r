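#' Protein-protein interaction network container
#'
#' A `ppi_network` is a simple undirected graph: a character vector of node
#' identifiers plus a two-column edge table with each pair stored once
#' (`from < to` lexicographically). Confidence scores are dropped once edges
#' pass the filter; all downstream propagation statistics are purely
#' topological.
#'
#' @param nodes character vector of node identifiers.
#' @param edges two-column character matrix or data.frame of endpoints.
#' @return An object of class `ppi_network` with elements `nodes` (sorted
#'   character vector) and `edges` (data.frame with columns `from`, `to`).
#' @keywords internal
new_network <- function(nodes = character(), edges = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(from = character(), to = character(),
                     stringsAsFactors = FALSE)
  } else {
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste0(lo, "\r", hi)
    dup <- duplicated(key)
    lo <- lo[!dup]; hi <- hi[!dup]
    o <- order(lo, hi)
    ed <- data.frame(from = lo[o], to = hi[o], stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(as.character(nodes), ed$from, ed$to)))
  structure(list(nodes = nodes, edges = ed), class = "ppi_network")
}

#' Build a simple undirected network from interaction rows
#'
#' Collapses duplicate pairs regardless of orientation and drops self-loops
#' (the number removed is reported via [message()]).
#'
#' @param interactions data.frame with node-id columns `protein_a` and
#'   `protein_b` (extra columns such as `score` are ignored), or any
#'   two-column table of endpoints. May be empty.
#' @return A [new_network()] object.
#' @examples
#' net <- build_network(data.frame(protein_a = c("A", "B", "A"),
#'                                 protein_b = c("B", "A", "A")))
#' n_edges(net)  # 1
#' @export
build_network <- function(interactions) {
  if (is.null(interactions) || NROW(interactions) == 0L)
    return(new_network())
  if (all(c("protein_a", "protein_b") %in% names(interactions))) {
    a <- as.character(interactions$protein_a)
    b <- as.character(interactions$protein_b)
  } else {
    a <- as.character(interactions[[1L]])
    b <- as.character(interactions[[2L]])
  }
  n_self <- sum(a == b)
  if (n_self > 0L)
    message("build_network: dropped ", n_self, " self-loop(s)")
  new_network(edges = data.frame(a, b))
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Node and edge counts
#' @param network a `ppi_network`.
#' @return Integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Degree of every node
#' @param network a `ppi_network`.
#' @return Named integer vector over all nodes (isolated nodes have 0).
#' @export
network_degrees <- function(network) {
  deg <- integer(length(network$nodes))
  names(deg) <- network$nodes
  if (nrow(network$edges) > 0L) {
    tab <- table(c(network$edges$from, network$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Adjacency list of a network
#' @param network a `ppi_network`.
#' @return Named list mapping each node to the character vector of its
#'   neighbors (possibly empty).
#' @export
network_adjacency <- function(network) {
  adj <- rep(list(character()), length(network$nodes))
  names(adj) <- network$nodes
  if (nrow(network$edges) > 0L) {
    ends <- c(network$edges$from, network$edges$to)
    other <- c(network$edges$to, network$edges$from)
    sp <- split(other, ends)
    adj[names(sp)] <- sp
  }
  adj
}

#' Seed-centered analysis network
#'
#' Induced subgraph on the union of the seed nodes and all of their direct
#' neighbors (the union of 1-neighborhoods). Edges between any two retained
#' nodes are kept, including neighbor-neighbor edges. Seeds absent from the
#' network are retained as isolated nodes with a warning, so degenerate
#' propagation profiles can still be reported for them.
#'
#' @param network a `ppi_network`.
#' @param seeds non-empty character vector of seed node ids.
#' @return A `ppi_network` subgraph of `network` (plus any missing seeds as
#'   isolated nodes).
#' @export
seed_network <- function(network, seeds) {
  seeds <- as.character(seeds)
  if (length(seeds) == 0L) stop("seeds must be non-empty")
  missing <- setdiff(seeds, network$nodes)
  if (length(missing) > 0L)
    warning("seed_network: ", length(missing),
            " seed(s) absent from the network kept as isolated nodes: ",
            paste(missing, collapse = ", "))
  ed <- network$edges
  hit <- ed$from %in% seeds | ed$to %in% seeds
  keep_nodes <- unique(c(seeds, ed$from[hit], ed$to[hit]))
  ind <- ed$from %in% keep_nodes & ed$to %in% keep_nodes
  new_network(nodes = keep_nodes, edges = ed[ind, , drop = FALSE])
}

#' Convert to an igraph object
#' @param network a `ppi_network`.
#' @return An [igraph::graph] with vertex names, isolated nodes included.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Write a network as a reproducible edge-list TSV
#'
#' Two id columns; ids sorted within each row and rows sorted
#' lexicographically, so identical networks serialize byte-identically.
#'
#' @param network a `ppi_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("protein_a", "protein_b"))
  invisible(path)
}

#' Read an edge-list TSV written by [write_edgelist()]
#' @param path input file path.
#' @return A `ppi_network`.
#' @export
read_edgelist <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  build_network(df)
}
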