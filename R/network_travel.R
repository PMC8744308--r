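#' @keywords internal
METERS_PER_MILE <- 1609.344

#' Walking speed in meters per minute
#'
#' Fixed conversion: 1 mile = 1609.344 m, so 3 mph = 80.4672 m/min.
#'
#' @param walk_speed_mph walking speed in miles per hour (> 0); default 3.
#' @return speed in meters per minute.
#' @export
walk_speed_m_per_min <- function(walk_speed_mph = 3) {
  if (!is.finite(walk_speed_mph) || walk_speed_mph <= 0) {
    stop("walk_speed_mph must be strictly positive")
  }
  walk_speed_mph * METERS_PER_MILE / 60
}

#' Walking time between two network nodes
#'
#' Shortest-path length in meters over the street network divided by the
#' walking speed. Returns `Inf` when no path exists.
#'
#' @param net a `street_network`.
#' @param origin_node,dest_node node ids present in the network.
#' @param walk_speed_mph walking speed in miles per hour; default 3.
#' @return travel time in minutes (`Inf` if unreachable).
#' @export
travel_time <- function(net, origin_node, dest_node, walk_speed_mph = 3) {
  ids <- net$nodes$node_id
  if (!(origin_node %in% ids) || !(dest_node %in% ids)) {
    stop("origin or destination node not in network")
  }
  tt <- travel_time_matrix(net, origin_node, dest_node, walk_speed_mph)
  unname(tt$minutes[1, 1])
}

#' Walking-time matrix between origins and destinations
#'
#' Computes minutes of walking time from every origin node to every
#' destination node with one single-source Dijkstra sweep per distinct
#' origin node (never per pair). Unreachable pairs carry `Inf`.
#'
#' @param net a `street_network`.
#' @param origin_nodes,dest_nodes vectors of node ids (repeats allowed:
#'   several blocks may share a node).
#' @param walk_speed_mph walking speed in miles per hour; default 3.
#' @param origin_ids,dest_ids optional identifiers for the rows/columns
#'   (e.g. block ids / site ids); default the node ids themselves.
#' @return a `travel_time_matrix`: list with `minutes` (numeric matrix,
#'   rows = origins, cols = destinations), `origin_ids`, `dest_ids`,
#'   `origin_nodes`, `dest_nodes`.
#' @export
travel_time_matrix <- function(net, origin_nodes, dest_nodes,
                               walk_speed_mph = 3,
                               origin_ids = origin_nodes,
                               dest_ids = dest_nodes) {
  ids <- net$nodes$node_id
  if (!all(origin_nodes %in% ids) || !all(dest_nodes %in% ids)) {
    stop("all origin and destination nodes must be in the network")
  }
  if (length(origin_ids) != length(origin_nodes) ||
      length(dest_ids) != length(dest_nodes)) {
    stop("ids must match nodes in length")
  }
  speed <- walk_speed_m_per_min(walk_speed_mph)

  uo <- unique(origin_nodes)
  ud <- unique(dest_nodes)
  if (length(origin_nodes) == 0 || length(dest_nodes) == 0) {
    minutes <- matrix(
      numeric(0),
      nrow = length(origin_nodes), ncol = length(dest_nodes),
      dimnames = list(as.character(origin_ids), as.character(dest_ids))
    )
  } else {
    g <- as_igraph(net)
    dist_m <- igraph::distances(
      g,
      v = as.character(uo), to = as.character(ud),
      algorithm = "dijkstra"
    )
    minutes <- dist_m[
      match(origin_nodes, uo), match(dest_nodes, ud),
      drop = FALSE
    ] / speed
    dimnames(minutes) <- list(as.character(origin_ids), as.character(dest_ids))
  }
  new_travel_time_matrix(minutes, origin_ids, dest_ids,
                         origin_nodes, dest_nodes)
}

#' Construct a travel-time matrix from raw minutes
#'
#' Escape hatch for externally supplied travel times (or worked examples):
#' wraps a plain minutes matrix in the container the access metrics consume.
#'
#' @param minutes numeric matrix of minutes, `Inf` for unreachable pairs.
#' @param origin_ids,dest_ids row/column identifiers; default from dimnames
#'   or indices.
#' @return a `travel_time_matrix`.
#' @export
travel_matrix <- function(minutes,
                          origin_ids = rownames(minutes) %||% seq_len(nrow(minutes)),
                          dest_ids = colnames(minutes) %||% seq_len(ncol(minutes))) {
  minutes <- as.matrix(minutes)
  if (any(minutes < 0, na.rm = TRUE)) stop("travel times must be >= 0")
  dimnames(minutes) <- list(as.character(origin_ids), as.character(dest_ids))
  new_travel_time_matrix(minutes, origin_ids, dest_ids, NULL, NULL)
}

new_travel_time_matrix <- function(minutes, origin_ids, dest_ids,
                                   origin_nodes, dest_nodes) {
  structure(
    list(
      minutes = minutes,
      origin_ids = origin_ids,
      dest_ids = dest_ids,
      origin_nodes = origin_nodes,
      dest_nodes = dest_nodes
    ),
    class = "travel_time_matrix"
  )
}

#' @export
print.travel_time_matrix <- function(x, ...) {
  cat(sprintf(
    "<travel_time_matrix> %d origins x %d destinations; %d unreachable pairs\n",
    nrow(x$minutes), ncol(x$minutes), sum(!is.finite(x$minutes))
  ))
  invisible(x)
}

#' Reachability flags of a travel-time matrix
#'
#' @param tt a `travel_time_matrix`.
#' @return logical matrix, TRUE where a path exists.
#' @export
reachable <- function(tt) {
  is.finite(tt$minutes)
}

#' Catchment membership under a travel-time threshold
#'
#' The catchment indicator is the strict inequality `t_ij < T` (boundary
#' pairs excluded); set `inclusive = TRUE` for a `<=` sensitivity variant.
#' Unreachable pairs are never members.
#'
#' @param tt a `travel_time_matrix`.
#' @param T_minutes catchment threshold in minutes (> 0); default 30.
#' @param inclusive use `<=` instead of the default strict `<`.
#' @return list with `by_origin` (for each origin, destination ids within
#'   the threshold) and `by_dest` (for each destination, origin ids).
#' @export
catchment_members <- function(tt, T_minutes = 30, inclusive = FALSE) {
  ind <- catchment_indicator(tt, T_minutes, inclusive)
  list(
    by_origin = apply(ind, 1, function(r) tt$dest_ids[r], simplify = FALSE),
    by_dest = apply(ind, 2, function(cc) tt$origin_ids[cc], simplify = FALSE)
  )
}

# logical matrix of the Eq.-style indicator I(t_ij < T)
catchment_indicator <- function(tt, T_minutes, inclusive = FALSE) {
  if (!is.finite(T_minutes) || T_minutes <= 0) {
    stop("catchment threshold must be strictly positive")
  }
  if (inclusive) tt$minutes <= T_minutes else tt$minutes < T_minutes
}
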