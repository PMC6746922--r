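#' Cycle detection and reentry-core localization
#'
#' Rotational activity appears in the excitation network as directed
#' cycles: closed directed walks without node repetition. The smallest
#' cycle through each node is found by breadth-first search (the network
#' is small and sparse, so this is effectively instantaneous), the cycles
#' are grouped into bundles by the proximity of their geometric centers,
#' and each bundle's center is reported as a reentry core.
#'
#' @name reentry_detection
NULL

cycle_from_nodes <- function(network, node_seq) {
  n <- network$nodes
  el <- n$electrode[node_seq]
  coords <- cbind(n$x[node_seq], n$y[node_seq], n$z[node_seq])
  per <- sum(sqrt(rowSums((coords - coords[c(2:nrow(coords), 1), ,
                                           drop = FALSE])^2)))
  structure(list(nodes = node_seq, electrodes = el, ids = n$id[node_seq],
                 center = colMeans(coords), length_edges = length(node_seq),
                 perimeter = per),
            class = "dg_cycle")
}

#' @export
print.dg_cycle <- function(x, ...) {
  cat(sprintf("cycle: %d edges, center (%.1f, %.1f, %.1f) mm\n",
              x$length_edges, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Smallest directed cycle through a node
#'
#' BFS from the node gives shortest directed paths; closing a path back
#' through any in-neighbor yields a candidate cycle, and the minimum over
#' in-neighbors is the smallest cycle through the node. Ties on edge
#' count are broken by smaller geometric perimeter, then by the
#' lexicographically smallest node sequence, so results are reproducible.
#'
#' @param network an `excitation_network`.
#' @param node electrode id (character) or node index (integer).
#' @return a `dg_cycle`, or `NULL` when the node lies on no cycle.
#' @export
smallest_cycle_through <- function(network, node) {
  if (is.character(node)) {
    node <- which(network$nodes$id == node)[1]
    if (is.na(node)) stop("node not found in network")
  }
  stopifnot(node >= 1, node <= nrow(network$nodes))
  res <- smallest_cycles_cpp(nrow(network$nodes), edge_matrix(network),
                             node_coords(network), as.integer(node))
  if (is.null(res[[1]])) return(NULL)
  cycle_from_nodes(network, res[[1]])
}

edge_matrix <- function(network) {
  el <- as.matrix(network$edges[, c("src", "dst")])
  storage.mode(el) <- "integer"
  if (!nrow(el)) el <- matrix(integer(0), ncol = 2)
  el
}

node_coords <- function(network) {
  cbind(network$nodes$x, network$nodes$y, network$nodes$z)
}

#' All smallest cycles of a network
#'
#' One smallest cycle per node that lies on any cycle, deduplicated by
#' node set.
#'
#' @param network an `excitation_network`.
#' @return list of `dg_cycle` objects (possibly empty).
#' @export
find_all_smallest_cycles <- function(network) {
  n <- nrow(network$nodes)
  if (!n || !nrow(network$edges)) return(list())
  res <- smallest_cycles_cpp(n, edge_matrix(network), node_coords(network),
                             seq_len(n))
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(list())
  key <- vapply(res, function(s) paste(sort(s), collapse = "-"), "")
  res <- res[!duplicated(key)]
  lapply(res, function(s) cycle_from_nodes(network, s))
}

#' Group cycles into reentry cores
#'
#' Cycles whose geometric centers lie closer than `proximity_threshold`
#' belong to the same core (single-linkage clustering, so the result does
#' not depend on cycle order). An optional second pass merges bundles
#' that share nodes. Each core carries the mean and the coordinate-wise
#' median of its cycle centers, its cycle count, and its member
#' electrodes.
#'
#' @param cycles list of `dg_cycle`.
#' @param proximity_threshold bundling threshold, mm (default 10 = 1 cm).
#' @param merge_shared_nodes run the shared-node merge pass (default on).
#' @return list of `reentry_core` objects, ordered by decreasing cycle
#'   count.
#' @export
bundle_cycles <- function(cycles, proximity_threshold = 10,
                          merge_shared_nodes = TRUE) {
  stopifnot(proximity_threshold > 0)
  if (!length(cycles)) return(list())
  centers <- do.call(rbind, lapply(cycles, `[[`, "center"))
  if (length(cycles) == 1) {
    grp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(centers), method = "single")
    grp <- stats::cutree(hc, h = proximity_threshold)
  }
  if (merge_shared_nodes) {
    # union-find over bundles sharing >= 1 node
    parent <- seq_len(max(grp))
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ng <- max(grp)
    nodesets <- lapply(seq_len(ng), function(g)
      unique(unlist(lapply(cycles[grp == g], `[[`, "nodes"))))
    for (i in seq_len(ng)) for (j in seq_len(ng)) {
      if (i < j && length(intersect(nodesets[[i]], nodesets[[j]]))) {
        ri <- findp(i); rj <- findp(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    grp <- vapply(grp, findp, 1L)
  }
  grp <- match(grp, sort(unique(grp)))
  cores <- lapply(sort(unique(grp)), function(g) {
    cyc <- cycles[grp == g]
    ctr <- do.call(rbind, lapply(cyc, `[[`, "center"))
    lens <- vapply(cyc, `[[`, 1L, "length_edges")
    per <- vapply(cyc, `[[`, 1.0, "perimeter")
    rep_i <- order(lens, per)[1]
    structure(list(center = colMeans(ctr),
                   center_median = apply(ctr, 2, stats::median),
                   n_cycles = length(cyc),
                   member_electrodes = sort(unique(unlist(
                     lapply(cyc, `[[`, "ids")))),
                   cycles = cyc, representative = cyc[[rep_i]]),
              class = "reentry_core")
  })
  cores[order(-vapply(cores, `[[`, 1L, "n_cycles"))]
}

#' @export
print.reentry_core <- function(x, ...) {
  cat(sprintf("reentry core at (%.1f, %.1f, %.1f) mm: %d cycle(s), %d electrodes\n",
              x$center[1], x$center[2], x$center[3], x$n_cycles,
              length(x$member_electrodes)))
  invisible(x)
}

#' Dominant reentry core
#'
#' The core supported by the largest number of cycles (more cycles =
#' stronger evidence of true rotation). Ties are broken by smaller mean
#' cycle length, then by lexicographically smaller center coordinates.
#'
#' @param cores list of `reentry_core`.
#' @return a single `reentry_core`.
#' @export
dominant_core <- function(cores) {
  if (!length(cores)) stop("no cores: dominant core undefined")
  n <- vapply(cores, `[[`, 1L, "n_cycles")
  mlen <- vapply(cores, function(c)
    mean(vapply(c$cycles, `[[`, 1L, "length_edges")), 1.0)
  ctr <- do.call(rbind, lapply(cores, `[[`, "center"))
  o <- order(-n, mlen, ctr[, 1], ctr[, 2], ctr[, 3])
  cores[[o[1]]]
}

#' Does the network contain any directed cycle?
#' @param network an `excitation_network`.
#' @export
has_cycles <- function(network) {
  if (!nrow(network$edges)) return(FALSE)
  !igraph::is_dag(as_igraph(network))
}
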