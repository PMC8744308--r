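#' Street network container
#'
#' A pedestrian street network: nodes with planar coordinates in meters and
#' undirected edges with strictly positive lengths. All travel-time
#' computations in the package run over this structure.
#'
#' @param nodes data frame with columns `node_id` (unique integers), `x`, `y`
#'   (planar coordinates, meters).
#' @param edges data frame with columns `from`, `to` (node ids) and
#'   `length_m` (> 0). Edges are undirected; self-loops and duplicate
#'   undirected edges are rejected.
#' @return An object of class `street_network` with elements `nodes` and
#'   `edges` (tibbles).
#' @export
street_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)))
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "length_m") %in% names(edges)))
  } else {
    edges <- tibble::tibble(from = integer(), to = integer(), length_m = numeric())
  }
  net <- structure(list(nodes = nodes, edges = edges), class = "street_network")
  validate_street_network(net)
  net
}

#' Validate a street network's structural invariants
#'
#' Checks unique node ids, edge endpoints present, no self-loops, no
#' duplicate undirected edges, and strictly positive lengths.
#'
#' @param net a `street_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_street_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids")
  if (nrow(edges) > 0) {
    if (!all(edges$from %in% nodes$node_id) || !all(edges$to %in% nodes$node_id)) {
      stop("edge endpoint not found among nodes")
    }
    if (any(edges$from == edges$to)) stop("self-loop edge")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("duplicate undirected edge")
    if (any(!is.finite(edges$length_m)) || any(edges$length_m <= 0)) {
      stop("edge lengths must be strictly positive")
    }
  }
  invisible(net)
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf(
    "<street_network> %d nodes, %d undirected edges\n",
    nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

# igraph view of the network; vertex names are node ids as character,
# edge weights are lengths in meters.
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = as.character(net$edges$from),
      to = as.character(net$edges$to)
    ),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$node_id))
  )
  igraph::E(g)$weight <- net$edges$length_m
  g
}

network_is_connected <- function(net) {
  if (nrow(net$nodes) <= 1) return(TRUE)
  igraph::is_connected(as_igraph(net))
}

#' Snap a point to the nearest network node
#'
#' Returns the node minimizing Euclidean distance to `(x_m, y_m)`; ties are
#' broken by the smallest node id. Needed when block centroids or site
#' coordinates are supplied off-network.
#'
#' @param x_m,y_m planar coordinates in meters.
#' @param net a `street_network` with at least one node.
#' @return the `node_id` of the nearest node.
#' @export
snap_to_node <- function(x_m, y_m, net) {
  if (nrow(net$nodes) == 0) stop("cannot snap to an empty network")
  d2 <- (net$nodes$x - x_m)^2 + (net$nodes$y - y_m)^2
  cand <- net$nodes$node_id[d2 == min(d2)]
  min(cand)
}
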