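# Independent brute-force shortest-path oracle: plain O(V^2) Dijkstra on a
# dense weight matrix, written without reference to the package's travel
# code. Distances are in meters; divide by speed to get minutes.

oracle_weight_matrix <- function(net) {
  n <- nrow(net$nodes)
  W <- matrix(Inf, n, n)
  i <- match(net$edges$from, net$nodes$node_id)
  j <- match(net$edges$to, net$nodes$node_id)
  W[cbind(i, j)] <- net$edges$length_m
  W[cbind(j, i)] <- net$edges$length_m
  W
}

oracle_dijkstra <- function(W, src) {
  n <- nrow(W)
  dist <- rep(Inf, n)
  dist[src] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- ifelse(done, Inf, dist)
    u <- which.min(cand)
    if (!is.finite(cand[u])) break
    done[u] <- TRUE
    nd <- dist[u] + W[u, ]
    upd <- !done & nd < dist
    dist[upd] <- nd[upd]
    if (all(done)) break
  }
  dist
}

# all-pairs minutes matrix by repeated single-source Dijkstra
oracle_travel_minutes <- function(net, origin_nodes, dest_nodes, walk_speed_mph = 3) {
  W <- oracle_weight_matrix(net)
  speed <- walk_speed_mph * 1609.344 / 60
  oi <- match(origin_nodes, net$nodes$node_id)
  di <- match(dest_nodes, net$nodes$node_id)
  t(vapply(
    oi,
    function(s) oracle_dijkstra(W, s)[di] / speed,
    numeric(length(di))
  ))
}

# random connected network: random spanning tree plus extra random edges
random_connected_network <- function(n_nodes, extra_edges = n_nodes %/% 2) {
  nodes <- tibble::tibble(
    node_id = seq_len(n_nodes),
    x = stats::runif(n_nodes, 0, 5000),
    y = stats::runif(n_nodes, 0, 5000)
  )
  from <- to <- integer(0)
  if (n_nodes > 1) {
    to <- 2:n_nodes
    from <- vapply(to, function(v) sample.int(v - 1L, 1L), integer(1))
  }
  seen <- paste(from, to)
  for (k in seq_len(extra_edges)) {
    pair <- sort(sample.int(n_nodes, 2))
    key <- paste(pair[1], pair[2])
    if (!key %in% seen) {
      seen <- c(seen, key)
      from <- c(from, pair[1])
      to <- c(to, pair[2])
    }
  }
  edges <- tibble::tibble(
    from = from, to = to,
    length_m = stats::runif(length(from), 50, 400)
  )
  street_network(nodes, edges)
}

# independent connectivity check by breadth-first traversal over edge lists
oracle_is_connected <- function(net) {
  n <- nrow(net$nodes)
  if (n <= 1) return(TRUE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  i <- match(net$edges$from, net$nodes$node_id)
  j <- match(net$edges$to, net$nodes$node_id)
  for (e in seq_along(i)) {
    adj[[i[e]]] <- c(adj[[i[e]]], j[e])
    adj[[j[e]]] <- c(adj[[j[e]]], i[e])
  }
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    u <- queue[1]
    queue <- queue[-1]
    nxt <- adj[[u]][!seen[adj[[u]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}
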