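#' Network-derived features
#'
#' Beyond locating sources, the excitation network supports attribution
#' and flow summaries: the region of cycles (electrodes taking part in a
#' core's cycles), the region of influence (which source excited each
#' electrode, by shortest network distance from the core's cycle nodes),
#' and wave averaging (local averaging of outgoing arrows into a smooth
#' propagation field).
#'
#' @name network_features
NULL

#' Region of cycles
#'
#' For each core, the electrodes that are part of any of its bundled
#' cycles.
#'
#' @param cores list of `reentry_core` from [bundle_cycles()].
#' @return named list of electrode-id vectors, one per core.
#' @export
region_of_cycles <- function(cores) {
  stats::setNames(lapply(cores, `[[`, "member_electrodes"),
                  paste0("core", seq_along(cores)))
}

#' Region of influence
#'
#' Every electrode is assigned to the core from whose cycle-node set it
#' is reachable at the smallest network distance; electrodes reachable
#' from no core are labeled unassigned (`NA`). The distance metric is the
#' accumulated LAT difference along directed edges by default ("network
#' arrival time"), with hop count and path length in mm as alternatives.
#' Ties go to the core with more cycles, then to the lower core index.
#'
#' @param network an `excitation_network`.
#' @param cores list of `reentry_core` detected on the same network.
#' @param metric `"dlat"` (arrival time, ms; default), `"hops"`, or
#'   `"mm"`.
#' @return a `region_assignment`: data frame (id, core, distance) plus
#'   per-core id sets in `attr(, "regions")`.
#' @export
region_of_influence <- function(network, cores,
                                metric = c("dlat", "hops", "mm")) {
  metric <- match.arg(metric)
  stopifnot(length(cores) >= 1)
  g <- as_igraph(network)
  w <- switch(metric, dlat = network$edges$dlat, mm = network$edges$dist,
              hops = NULL)
  D <- vapply(cores, function(core) {
    nodes <- which(network$nodes$id %in% core$member_electrodes)
    if (!length(nodes)) return(rep(Inf, nrow(network$nodes)))
    d <- igraph::distances(g, v = nodes, mode = "out", weights = w)
    apply(d, 2, min)
  }, numeric(nrow(network$nodes)))
  D <- matrix(D, nrow = nrow(network$nodes))
  ncyc <- vapply(cores, `[[`, 1L, "n_cycles")
  assign_core <- apply(D, 1, function(dr) {
    if (all(!is.finite(dr))) return(NA_integer_)
    cand <- which(dr == min(dr))
    if (length(cand) > 1) cand <- cand[order(-ncyc[cand], cand)][1]
    cand[1]
  })
  out <- data.frame(id = network$nodes$id, core = assign_core,
                    distance = D[cbind(seq_len(nrow(D)),
                                       ifelse(is.na(assign_core), 1,
                                              assign_core))])
  out$distance[is.na(out$core)] <- NA_real_
  attr(out, "regions") <- lapply(seq_along(cores), function(k)
    out$id[!is.na(out$core) & out$core == k])
  attr(out, "metric") <- metric
  class(out) <- c("region_assignment", "data.frame")
  out
}

# nearest point on a triangle (3D), vertices rows of tri
closest_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * (d1 / (d1 - d3)))
  cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * (d2 / (d2 - d6)))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6))))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

project_to_mesh <- function(pts, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  t(apply(pts, 1, function(p) {
    best <- NULL; bestd <- Inf
    for (k in seq_len(nrow(f))) {
      q <- closest_point_triangle(p, v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
      d <- sum((p - q)^2)
      if (d < bestd) { bestd <- d; best <- q }
    }
    best
  }))
}

#' Wave averaging
#'
#' Every directed arrow is split into 4 equal segments; with a surface
#' mesh the segment endpoints are projected onto the mesh (nearest-point
#' projection), in the planar case projection is the identity and the
#' subdivision is a no-op. For each node, all segments starting within
#' `radius` of the node are averaged into a single local propagation
#' vector.
#'
#' @param network an `excitation_network`.
#' @param radius averaging radius, mm (default 10 = 1 cm).
#' @param mesh optional surface: `list(vertices = n x 3, faces = m x 3)`.
#' @return a `flow_field` data frame: id, position, unit direction
#'   (vx, vy, vz) and magnitude (mm; the norm of the mean arrow). Nodes
#'   with no nearby outgoing arrows carry a zero vector.
#' @export
wave_average <- function(network, radius = 10, mesh = NULL) {
  stopifnot(radius > 0)
  nd <- network$nodes
  e <- network$edges
  P <- cbind(nd$x, nd$y, nd$z)
  if (nrow(e)) {
    A <- P[e$src, , drop = FALSE]
    B <- P[e$dst, , drop = FALSE]
    if (!is.null(mesh)) {
      # subdivide each arrow into 4 parts and project the 5 points
      segs_start <- NULL; segs_vec <- NULL
      fr <- seq(0, 1, by = 0.25)
      pts <- lapply(fr, function(s) A + (B - A) * s)
      proj <- lapply(pts, function(q) project_to_mesh(q, mesh))
      for (k in 1:4) {
        segs_start <- rbind(segs_start, proj[[k]])
        segs_vec <- rbind(segs_vec, proj[[k + 1]] - proj[[k]])
      }
    } else {
      segs_start <- A
      segs_vec <- B - A
    }
  } else {
    segs_start <- matrix(0, 0, 3); segs_vec <- matrix(0, 0, 3)
  }
  res <- t(vapply(seq_len(nrow(nd)), function(i) {
    if (!nrow(segs_start)) return(c(0, 0, 0, 0))
    d2 <- rowSums(sweep(segs_start, 2, P[i, ])^2)
    near <- d2 <= radius^2
    if (!any(near)) return(c(0, 0, 0, 0))
    m <- colMeans(segs_vec[near, , drop = FALSE])
    nm <- vec_norm(m)
    if (nm == 0) c(0, 0, 0, 0) else c(m / nm, nm)
  }, numeric(4)))
  out <- data.frame(id = nd$id, x = nd$x, y = nd$y, z = nd$z,
                    vx = res[, 1], vy = res[, 2], vz = res[, 3],
                    magnitude = res[, 4])
  class(out) <- c("flow_field", "data.frame")
  out
}
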