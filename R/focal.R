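#' Focal-source detection
#'
#' A focal source appears in the excitation network as a region whose
#' nodes have only outgoing arrows (in-degree 0, out-degree > 0). Raw
#' LATs are first bundled into intervals to suppress inter-electrode
#' annotation variability, the network is rebuilt from the bundled
#' values, and connected regions of source nodes are reported with their
#' centroid as the source origin. Per the diagnosis flowchart, focal
#' search is only meaningful when no cycles are present.
#'
#' @name focal_detection
NULL

#' Bundle LATs into fixed intervals
#'
#' Each LAT is replaced by the center of its containing interval
#' `[k*interval, (k+1)*interval)`. `interval = 0` is the identity. The
#' operation is idempotent.
#'
#' @param lat_map named list of LAT vectors, or a single numeric vector.
#' @param interval bin width, ms (>= 0).
#' @export
bundle_lats <- function(lat_map, interval) {
  stopifnot(interval >= 0)
  if (interval == 0) return(lat_map)
  f <- function(v) sort((floor(v / interval) + 0.5) * interval)
  if (is.numeric(lat_map)) return(f(lat_map))
  lapply(lat_map, f)
}

#' Find focal sources in an activation window
#'
#' Builds the dual-window network from interval-bundled LATs and returns
#' the connected components (over the neighbor relation) of nodes with
#' in-degree 0 and positive out-degree. If the unbundled network contains
#' any directed cycle the mechanism is rotational, and an empty list is
#' returned (cycle detection takes precedence over focal search).
#'
#' Moving wavefront edges can masquerade as in-degree-0 nodes depending
#' on the construction time; with `check_stability = TRUE` a source
#' region is only kept when it recurs at a second construction time.
#'
#' @inheritParams build_merged_graph
#' @param interval LAT bundling interval, ms (default 5).
#' @param check_stability require the region to be detected at two
#'   construction times (needs >= 2 beats).
#' @return list of `focal_source` objects: electrodes, centroid origin,
#'   earliest-activating electrode, earliest LAT.
#' @export
find_focal_sources <- function(set, relation, lat_map = NULL, t = 0,
                               bounds = cv_preset("ventricular"),
                               interval = 5, delta_t = 40,
                               check_stability = FALSE) {
  if (is.null(lat_map) && inherits(set, "activation_field"))
    lat_map <- set$lats
  eset <- as_electrode_set(set)
  net <- build_merged_graph(eset, relation, lat_map, t, delta_t, bounds)
  if (has_cycles(net)) return(list())
  srcs <- source_regions(eset, relation, lat_map, t, bounds, interval,
                         delta_t)
  if (check_stability && length(srcs)) {
    period <- stats::median(unlist(lapply(lat_map, diff)), na.rm = TRUE)
    if (is.finite(period) && period > 0) {
      s2 <- source_regions(eset, relation, lat_map, t + period / 3,
                           bounds, interval, delta_t)
      keep <- vapply(srcs, function(s)
        any(vapply(s2, function(q)
          length(intersect(s$electrodes, q$electrodes)) > 0, TRUE)), TRUE)
      srcs <- srcs[keep]
    }
  }
  srcs
}

source_regions <- function(eset, relation, lat_map, t, bounds, interval,
                           delta_t) {
  bl <- bundle_lats(lat_map, interval)
  net <- build_merged_graph(eset, relation, bl, t, delta_t, bounds)
  if (has_cycles(net) || !nrow(net$edges)) return(list())
  indeg <- tabulate(net$edges$dst, nbins = nrow(net$nodes))
  outdeg <- tabulate(net$edges$src, nbins = nrow(net$nodes))
  src_nodes <- which(indeg == 0 & outdeg > 0)
  if (!length(src_nodes)) return(list())
  src_el <- net$nodes$electrode[src_nodes]
  # components over the neighbor relation restricted to source electrodes
  keep <- relation$pairs$a %in% src_el & relation$pairs$b %in% src_el
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(relation$pairs$a[keep], src_el),
               to = match(relation$pairs$b[keep], src_el)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(src_el)))
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(k) {
    el <- src_el[comp == k]
    pos <- eset$positions[el, , drop = FALSE]
    Lb <- first_lats_after(bl, t)[el]
    first <- el[which.min(Lb)]
    structure(list(electrodes = eset$ids[el],
                   origin = colMeans(pos),
                   earliest_electrode = eset$ids[first],
                   earliest_lat = min(Lb)),
              class = "focal_source")
  })
}

#' @export
print.focal_source <- function(x, ...) {
  cat(sprintf("focal source at (%.1f, %.1f, %.1f) mm: %d electrode(s), earliest LAT %.1f ms\n",
              x$origin[1], x$origin[2], x$origin[3], length(x$electrodes),
              x$earliest_lat))
  invisible(x)
}
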