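# Independent oracles and small builders shared across tests.

# Build a bare excitation_network from an explicit edge list + coords,
# bypassing the LAT machinery, for pure graph-algorithm tests.
mock_network <- function(edges, coords, ids = NULL) {
  n <- nrow(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  coords <- cbind(coords, matrix(0, n, 3 - ncol(coords)))
  nodes <- data.frame(node = seq_len(n), electrode = seq_len(n), id = ids,
                      lat = seq_len(n), x = coords[, 1], y = coords[, 2],
                      z = coords[, 3])
  e <- data.frame(src = edges[, 1], dst = edges[, 2])
  e$dlat <- 1; e$dist <- sqrt((nodes$x[e$dst] - nodes$x[e$src])^2 +
                                (nodes$y[e$dst] - nodes$y[e$src])^2)
  e$speed <- 1; e$window <- 1L
  structure(list(nodes = nodes, edges = e, t = 0, delta_t = NA_real_,
                 bounds = cv_bounds(0.01, 100), ids = ids,
                 positions = coords, collapse = TRUE),
            class = "excitation_network")
}

# Exhaustive enumeration of all simple directed cycles (DFS, each cycle
# found once from its smallest vertex). Returns a list of integer node
# sequences. Independent of the package's BFS search.
enumerate_simple_cycles <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i) sort(edges[edges[, 1] == i, 2]))
  cycles <- list()
  path <- integer(0)
  onpath <- rep(FALSE, n)
  dfs <- function(v, root) {
    path[[length(path) + 1]] <<- v
    onpath[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == root) {
        cycles[[length(cycles) + 1]] <<- path
      } else if (!onpath[w] && w > root) {
        dfs(w, root)
      }
    }
    onpath[v] <<- FALSE
    path <<- path[-length(path)]
  }
  for (root in seq_len(n)) dfs(root, root)
  cycles
}

# shortest cycle length through each node, from the exhaustive list
oracle_smallest_through <- function(n, cycles) {
  best <- rep(NA_integer_, n)
  for (cy in cycles) {
    for (v in cy) best[v] <- min(best[v], length(cy), na.rm = TRUE)
  }
  best
}

random_sparse_digraph <- function(n, m) {
  e <- unique(cbind(sample(n, 3 * m, replace = TRUE),
                    sample(n, 3 * m, replace = TRUE)))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e[seq_len(min(m, nrow(e))), , drop = FALSE]
}

# winding number of a closed polyline (node coordinates) about a point
winding_number <- function(xy, about) {
  a <- atan2(xy[, 2] - about[2], xy[, 1] - about[1])
  d <- diff(c(a, a[1]))
  d <- ((d + pi) %% (2 * pi)) - pi
  round(sum(d) / (2 * pi))
}

# Floyd-Warshall all-pairs shortest paths (edge weights w), independent
# of igraph
floyd_warshall <- function(n, edges, w) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(edges)))
    D[edges[k, 1], edges[k, 2]] <- min(D[edges[k, 1], edges[k, 2]], w[k])
  for (k in seq_len(n)) for (i in seq_len(n)) {
    D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  }
  D
}
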