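# Bipartite network construction and centrality. Networks are undirected
# and unweighted; centrality is computed with igraph (Brandes betweenness)
# and normalized by (N-1)(N-2)/2 over the full graph, the Cytoscape-style
# convention, including for disconnected graphs.

#' Build a bipartite network
#'
#' Constructs a validated two-partition graph (compound-target,
#' target-pathway, or organ-gene). Every edge must cross the partitions;
#' self-loops and within-partition edges are rejected. Duplicate edges are
#' stored once. Declared nodes without edges are retained as isolated
#' nodes (degree 0, betweenness 0).
#'
#' @param edges Data frame whose first two columns are the edge endpoints
#'   (either orientation), or a 2-column character matrix.
#' @param left_ids,right_ids Disjoint character vectors declaring the two
#'   partitions.
#' @return A `bipartite_network`: list with `left`, `right` and `edges`
#'   (data frame `from` in left, `to` in right, deduplicated, sorted).
#' @export
build_bipartite <- function(edges, left_ids, right_ids) {
  left_ids <- unique(as.character(left_ids))
  right_ids <- unique(as.character(right_ids))
  overlap <- intersect(left_ids, right_ids)
  if (length(overlap)) {
    stop("partitions are not disjoint: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (any(a == b)) {
    stop("self-loop edge: ", a[a == b][1], call. = FALSE)
  }
  undeclared <- setdiff(c(a, b), c(left_ids, right_ids))
  if (length(undeclared)) {
    stop("edge endpoint(s) not declared in either partition: ",
         paste(sort(unique(undeclared)), collapse = ", "), call. = FALSE)
  }
  a_left <- a %in% left_ids
  b_left <- b %in% left_ids
  within <- which(a_left == b_left)
  if (length(within)) {
    stop(sprintf("edge (%s, %s) does not cross the partitions",
                 a[within[1]], b[within[1]]), call. = FALSE)
  }
  from <- ifelse(a_left, a, b)
  to <- ifelse(a_left, b, a)
  ed <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(left = left_ids, right = right_ids, edges = ed),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite network: %d + %d nodes, %d edges\n",
              length(x$left), length(x$right), nrow(x$edges)))
  invisible(x)
}

#' Convert a bipartite network to an igraph object
#'
#' Vertices carry a `partition` attribute (`"left"`/`"right"`); isolated
#' declared nodes are included.
#'
#' @param network A `bipartite_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  vertices <- data.frame(
    name = c(network$left, network$right),
    partition = c(rep("left", length(network$left)),
                  rep("right", length(network$right))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = vertices)
}

#' Degree and normalized betweenness centrality of a bipartite network
#'
#' Degree is the number of incident edges (so degrees sum to twice the
#' edge count). Betweenness is Brandes shortest-path betweenness on the
#' undirected, unweighted graph, endpoints excluded; when `normalized`,
#' raw values are divided by `(N-1)(N-2)/2` with `N` the full node count
#' (graphs with fewer than 3 nodes report 0 rather than dividing by zero).
#'
#' @param network A `bipartite_network`.
#' @param normalized Divide betweenness by `(N-1)(N-2)/2` (default `TRUE`).
#' @return Data frame with columns `node_id`, `partition`, `degree`,
#'   `betweenness`.
#' @export
centrality_table <- function(network, normalized = TRUE) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(data.frame(node_id = character(0), partition = character(0),
                      degree = integer(0), betweenness = numeric(0),
                      stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(g, mode = "all")
  btw <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  if (normalized) {
    btw <- if (n < 3L) rep(0, n) else btw / ((n - 1) * (n - 2) / 2)
  }
  data.frame(node_id = igraph::V(g)$name,
             partition = igraph::V(g)$partition,
             degree = as.integer(deg),
             betweenness = unname(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname centrality_table
#' @export
degree_centrality <- function(network) {
  centrality_table(network, normalized = TRUE)[, c("node_id", "partition", "degree")]
}

#' @rdname centrality_table
#' @param normalized See [centrality_table()].
#' @export
betweenness_centrality <- function(network, normalized = TRUE) {
  centrality_table(network, normalized = normalized)[
    , c("node_id", "partition", "betweenness")]
}

#' Rank nodes by a centrality metric
#'
#' Descending order; ties broken lexicographically by node id so output is
#' deterministic. Optionally restricted to one partition.
#'
#' @param table Centrality table from [centrality_table()] (or one of its
#'   single-metric wrappers).
#' @param metric `"degree"` or `"betweenness"`.
#' @param partition Optional `"left"` or `"right"` filter.
#' @return Character vector of node ids in rank order.
#' @export
rank_nodes <- function(table, metric = c("degree", "betweenness"),
                       partition = NULL) {
  if (!is.character(metric) || !all(metric %in% c("degree", "betweenness"))) {
    stop("unknown ranking metric: ", paste(metric, collapse = ", "),
         call. = FALSE)
  }
  metric <- match.arg(metric)
  if (!metric %in% names(table)) {
    stop("centrality table has no '", metric, "' column", call. = FALSE)
  }
  if (!is.null(partition)) {
    table <- table[table$partition == partition, , drop = FALSE]
  }
  table$node_id[order(-table[[metric]], table$node_id)]
}
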