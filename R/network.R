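#' Fixed interaction networks
#'
#' An `interaction_network` is a simple undirected graph over `n_nodes`
#' agents, stored as a canonical edge matrix, optionally carrying per-edge
#' spring rest lengths (in lattice-spacing units). It is the fixed topology
#' through which agents interact in both the VN and AE models.
#'
#' @param n_nodes Positive integer, number of agents/nodes.
#' @param edges Two-column integer matrix of node index pairs (1-based).
#'   Self-loops are forbidden; duplicate edges are collapsed.
#' @param rest_lengths Optional numeric vector of positive rest lengths,
#'   one per row of `edges` (in the order supplied).
#'
#' @return An object of class `interaction_network` with elements
#'   `n_nodes`, `edges` (canonical: each row `i < j`, rows sorted), and
#'   `rest_lengths` (`NULL` if unset).
#' @export
interaction_network <- function(n_nodes, edges, rest_lengths = NULL) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoints out of range 1..n_nodes")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed in an interaction network")
  }
  # canonical form: i < j, rows sorted lexicographically, duplicates dropped
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) edges[swap, ] <- edges[swap, c(2L, 1L)]
  key <- (edges[, 1L] - 1) * as.double(n_nodes) + (edges[, 2L] - 1)
  ord <- order(key)
  edges <- edges[ord, , drop = FALSE]
  key <- key[ord]
  dup <- duplicated(key)
  if (!is.null(rest_lengths)) {
    stopifnot(length(rest_lengths) == nrow(edges), all(rest_lengths > 0))
    rest_lengths <- rest_lengths[ord]
    rest_lengths <- rest_lengths[!dup]
  }
  edges <- edges[!dup, , drop = FALSE]
  dimnames(edges) <- NULL
  structure(
    list(n_nodes = n_nodes, edges = edges, rest_lengths = rest_lengths),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %d nodes, %d edges%s>\n",
              x$n_nodes, nrow(x$edges),
              if (is.null(x$rest_lengths)) "" else ", rest lengths set"))
  invisible(x)
}

#' Number of edges of an interaction network
#' @param network An `interaction_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  nrow(network$edges)
}

#' Convert an interaction network to an igraph object
#' @param network An `interaction_network`.
#' @return An undirected `igraph` graph with the same nodes and edges.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  igraph::graph_from_edgelist(network$edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, network$n_nodes - max(network$edges, 0L)))
}

#' Degree histogram of a network
#'
#' Counts how many nodes have each degree, the quantity compared across the
#' NN, ER and SF topologies.
#'
#' @param network An `interaction_network`.
#' @return A `degree_sequence`: named integer vector of node counts `n_k`,
#'   names are the degrees `k`, ascending, zero-count degrees omitted
#'   (except degree 0, reported when present).
#' @export
degree_histogram <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  deg <- tabulate(network$edges, nbins = network$n_nodes)
  tab <- table(deg)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  degree_sequence(counts)
}

#' Degree sequence (degree histogram) object
#'
#' @param counts Named integer vector: `counts[["k"]]` is the number of
#'   nodes with degree `k`. All counts must be nonnegative integers.
#' @return A `degree_sequence` object (named integer vector, degrees
#'   ascending).
#' @export
degree_sequence <- function(counts) {
  k <- as.integer(names(counts))
  if (anyNA(k)) stop("counts must be named by integer degrees")
  n <- as.integer(counts)
  if (any(n < 0L)) stop("counts must be nonnegative")
  ord <- order(k)
  structure(stats::setNames(n[ord], k[ord]), class = "degree_sequence")
}

#' @export
print.degree_sequence <- function(x, ...) {
  cat(sprintf("<degree_sequence: %d nodes, %d stubs, degrees %s..%s>\n",
              sum(x), sum(as.integer(names(x)) * x),
              names(x)[1L], names(x)[length(x)]))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Expand a degree histogram to one degree per node
#' @param seq A `degree_sequence`.
#' @return Integer vector of node degrees, descending.
#' @export
degrees_from_sequence <- function(seq) {
  k <- as.integer(names(seq))
  sort(rep.int(k, as.integer(seq)), decreasing = TRUE)
}

#' Is the network connected?
#'
#' Generated topologies are only accepted when a single component spans all
#' nodes; this is the acceptance check used by every generator.
#'
#' @param network An `interaction_network`.
#' @return `TRUE` iff the graph has exactly one connected component
#'   covering all `n_nodes` (a single node counts as connected).
#' @export
is_connected <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  if (network$n_nodes == 1L) return(TRUE)
  if (nrow(network$edges) < network$n_nodes - 1L) return(FALSE)
  if (any(tabulate(network$edges, nbins = network$n_nodes) == 0L))
    return(FALSE) # isolated node: cheap rejection before the full search
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, t(network$edges))
  igraph::is_connected(g)
}

#' Do two networks have identical edge sets?
#' @param a,b `interaction_network` objects.
#' @return `TRUE` iff node counts and canonical edge matrices agree.
#' @export
same_edge_set <- function(a, b) {
  a$n_nodes == b$n_nodes && nrow(a$edges) == nrow(b$edges) &&
    all(a$edges == b$edges)
}

#' Read / write plain-text edge lists
#'
#' File format: one edge per line, two whitespace-separated 0-based node
#' indexes, with an optional third column giving the rest length. A header
#' comment line starting with `#` records the node count so isolated
#' trailing nodes survive the round trip.
#'
#' @param network An `interaction_network`.
#' @param path File path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns an `interaction_network`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes %d", network$n_nodes), con)
  e <- network$edges - 1L
  lines <- if (is.null(network$rest_lengths)) {
    sprintf("%d %d", e[, 1L], e[, 2L])
  } else {
    sprintf("%d %d %.17g", e[, 1L], e[, 2L], network$rest_lengths)
  }
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_nodes Optional node count override when reading a headerless
#'   file (defaults to `max index + 1`).
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  m <- regmatches(lines[hdr], regexpr("[0-9]+", lines[hdr]))
  if (is.null(n_nodes) && length(m)) n_nodes <- as.integer(m[[1L]])
  lines <- lines[!hdr & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ncol <- lengths(parts)
  if (length(ncol) && !all(ncol %in% c(2L, 3L)))
    stop("edge-list lines must have 2 or 3 columns")
  i <- as.integer(vapply(parts, `[[`, "", 1L)) + 1L
  j <- as.integer(vapply(parts, `[[`, "", 2L)) + 1L
  rl <- if (length(ncol) && all(ncol == 3L))
    as.numeric(vapply(parts, `[[`, "", 3L)) else NULL
  if (is.null(n_nodes)) n_nodes <- max(i, j, 1L)
  interaction_network(n_nodes, cbind(i, j), rest_lengths = rl)
}

#' Export a network to GraphML (for external visualization)
#' @param network An `interaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  if (!is.null(network$rest_lengths))
    igraph::E(g)$rest_length <- network$rest_lengths
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
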