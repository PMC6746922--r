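#' Electrode sets and neighbor relations
#'
#' A directed excitation edge may only be drawn between electrodes that
#' are geometric neighbors, i.e. between which the wavefront can travel
#' directly. For regular grids the neighborhood is a sphere around each
#' electrode (up to 8 neighbors in a 2D grid, up to 26 in a regular 3D
#' grid); for irregular electrode clouds (clinical-style maps) the edges
#' of a Delaunay triangulation are used.
#'
#' @param ids electrode identifiers (unique).
#' @param positions numeric n x 3 (or n x 2) matrix, mm.
#' @param layout_kind layout descriptor.
#' @return object of class `electrode_set`.
#' @export
electrode_set <- function(ids, positions,
                          layout_kind = c("irregular", "regular_grid_2d",
                                          "regular_grid_3d")) {
  layout_kind <- match.arg(layout_kind)
  positions <- as.matrix(positions)
  if (ncol(positions) == 2) positions <- cbind(positions, 0)
  stopifnot(length(ids) >= 2, !anyDuplicated(ids), all(is.finite(positions)),
            nrow(positions) == length(ids))
  structure(list(ids = as.character(ids), positions = positions,
                 layout_kind = layout_kind),
            class = "electrode_set")
}

as_electrode_set <- function(x, layout_kind = "irregular") {
  if (inherits(x, "electrode_set")) return(x)
  if (inherits(x, "activation_field"))
    return(electrode_set(x$ids, x$positions, layout_kind))
  stop("cannot interpret input as an electrode set")
}

new_neighbor_relation <- function(a, b, distance, method, n) {
  # canonical: a < b (by index), sorted, unique
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b)
  keep <- !duplicated(key) & a != b
  o <- order(a[keep], b[keep])
  structure(list(pairs = data.frame(a = a[keep][o], b = b[keep][o],
                                    distance = distance[keep][o]),
                 method = method, n_electrodes = n),
            class = "neighbor_relation")
}

#' @export
print.neighbor_relation <- function(x, ...) {
  cat(sprintf("neighbor_relation (%s): %d pairs over %d electrodes\n",
              x$method, nrow(x$pairs), x$n_electrodes))
  iso <- setdiff(seq_len(x$n_electrodes), c(x$pairs$a, x$pairs$b))
  if (length(iso))
    cat(sprintf("  %d isolated electrode(s): %s\n", length(iso),
                paste(head(iso, 10), collapse = ", ")))
  invisible(x)
}

#' Spherical-distance neighbors for regular grids
#'
#' Electrodes a and b are neighbors iff `0 < ||pos_a - pos_b|| <= radius`.
#' With the default radius of 1.5 x the grid spacing, an interior point of
#' a 2D grid has exactly 8 neighbors; 1.8 x spacing covers the
#' 26-neighborhood of a regular 3D grid.
#'
#' @param set an `electrode_set` or `activation_field`.
#' @param radius neighborhood radius, mm. Default: 1.5 x the minimal
#'   inter-electrode distance.
#' @return a `neighbor_relation`.
#' @export
neighbors_regular <- function(set, radius = NULL) {
  set <- as_electrode_set(set)
  p <- set$positions
  d <- as.matrix(stats::dist(p))
  if (is.null(radius)) radius <- 1.5 * min(d[d > 0])
  if (radius <= 0) stop("radius must be > 0")
  if (radius < min(d[d > 0]))
    stop(sprintf("radius %.3g mm is below the minimal inter-electrode distance %.3g mm: empty neighbor relation",
                 radius, min(d[d > 0])))
  idx <- which(d > 0 & d <= radius, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  new_neighbor_relation(idx[, 1], idx[, 2], d[idx], "sphere", nrow(p))
}

# best-fit plane coordinates for (near-)planar 3D clouds
plane_coords <- function(p) {
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) stop("electrode positions are collinear")
  list(uv = sweep(p, 2, ctr) %*% sv$v[, 1:2],
       planar_residual = if (length(sv$d) >= 3) sv$d[3] else 0)
}

#' Delaunay-triangulation neighbors for irregular electrode clouds
#'
#' Neighbor pairs are the edges of the Delaunay triangulation of the
#' electrode positions. Point clouds embedded (near-)planarly in 3D — the
#' usual shape of clinical mapping exports over an atrial wall patch —
#' are triangulated in their best-fit plane. Cocircular degeneracies
#' follow the triangulator's tie-break; the returned edge set is
#' canonicalized (sorted id pairs) so output is reproducible.
#'
#' @param set an `electrode_set` or `activation_field`.
#' @param max_edge_length optional pruning: drop Delaunay edges longer
#'   than this (mm), guarding against spurious long edges across
#'   concavities such as valve orifices. Default `NULL` (off).
#' @return a `neighbor_relation`.
#' @export
neighbors_delaunay <- function(set, max_edge_length = NULL) {
  set <- as_electrode_set(set)
  p <- set$positions
  if (nrow(p) < 3) stop("need at least 3 electrodes for triangulation")
  pc <- plane_coords(p)
  uv <- pc$uv
  if (nrow(p) == 3) {
    a <- c(1, 1, 2); b <- c(2, 3, 3)
  } else {
    tri <- deldir::deldir(uv[, 1], uv[, 2], suppressMsge = TRUE)
    a <- tri$delsgs$ind1; b <- tri$delsgs$ind2
  }
  dd <- sqrt(rowSums((p[a, , drop = FALSE] - p[b, , drop = FALSE])^2))
  if (!is.null(max_edge_length)) {
    keep <- dd <= max_edge_length
    a <- a[keep]; b <- b[keep]; dd <- dd[keep]
  }
  new_neighbor_relation(a, b, dd, "delaunay", nrow(p))
}

#' Write a neighbor relation as an edge-list CSV
#' @param relation a `neighbor_relation`.
#' @param set the `electrode_set` it refers to (for ids).
#' @param path output file.
#' @export
write_neighbor_csv <- function(relation, set, path) {
  set <- as_electrode_set(set)
  df <- data.frame(id_a = set$ids[relation$pairs$a],
                   id_b = set$ids[relation$pairs$b],
                   distance_mm = relation$pairs$distance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
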