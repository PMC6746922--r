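#' Conduction-velocity bounds
#'
#' A directed edge from electrode u to v (activating later) is allowed
#' only when the apparent propagation speed, Euclidean distance divided by
#' the LAT difference, lies strictly between `cv_min` and `cv_max`. The
#' ventricular preset uses 0.2-2.0 mm/ms; the atrial preset lowers
#' `cv_min` to 0.08 mm/ms, the slowest conduction measured in human
#' atria.
#'
#' @param cv_min,cv_max conduction-velocity bounds, mm/ms (0 < min < max).
#' @export
cv_bounds <- function(cv_min = 0.2, cv_max = 2.0) {
  stopifnot(cv_min > 0, cv_max > cv_min)
  structure(list(cv_min = cv_min, cv_max = cv_max), class = "cv_bounds")
}

#' @rdname cv_bounds
#' @param preset `"ventricular"` (0.2-2.0 mm/ms) or `"atrial"`
#'   (0.08-2.0 mm/ms).
#' @export
cv_preset <- function(preset = c("ventricular", "atrial")) {
  preset <- match.arg(preset)
  if (preset == "ventricular") cv_bounds(0.2, 2.0) else cv_bounds(0.08, 2.0)
}

#' First activation after a query time
#'
#' For each electrode, the smallest LAT strictly larger than `t`.
#' Electrodes whose recording holds no such LAT get `NA` and are listed in
#' the `"missing"` attribute.
#'
#' @param lat_map named list of sorted LAT vectors (ms) per electrode.
#' @param t window start time, ms.
#' @return named numeric vector, one entry per electrode.
#' @export
first_lats_after <- function(lat_map, t) {
  out <- vapply(lat_map, function(v) {
    k <- which(v > t)
    if (length(k)) v[k[1]] else NA_real_
  }, 1.0)
  attr(out, "missing") <- names(out)[is.na(out)]
  out
}

# directed edges induced by a per-electrode LAT assignment
edges_for_lats <- function(L, relation, positions, bounds) {
  a <- relation$pairs$a; b <- relation$pairs$b; d <- relation$pairs$distance
  ok <- !is.na(L[a]) & !is.na(L[b])
  a <- a[ok]; b <- b[ok]; d <- d[ok]
  dl <- L[b] - L[a]
  # orient each pair from earlier to later activation
  src <- ifelse(dl > 0, a, b)
  dst <- ifelse(dl > 0, b, a)
  dlat <- abs(dl)
  speed <- d / dlat
  keep <- dlat > 0 & speed > bounds$cv_min & speed < bounds$cv_max
  data.frame(src = src[keep], dst = dst[keep], dlat = dlat[keep],
             dist = d[keep], speed = speed[keep])
}

new_excitation_network <- function(nodes, edges, t, delta_t, bounds,
                                   set, collapse) {
  structure(list(nodes = nodes, edges = edges, t = t, delta_t = delta_t,
                 bounds = bounds, ids = set$ids, positions = set$positions,
                 collapse = collapse),
            class = "excitation_network")
}

#' @export
print.excitation_network <- function(x, ...) {
  cat(sprintf("excitation_network: %d nodes, %d edges (t = %.1f ms, dt = %s, CV %g-%g mm/ms)\n",
              nrow(x$nodes), nrow(x$edges), x$t,
              if (is.na(x$delta_t)) "-" else sprintf("%.0f ms", x$delta_t),
              x$bounds$cv_min, x$bounds$cv_max))
  invisible(x)
}

#' Build the single-window excitation graph
#'
#' Takes, for every electrode, the first LAT after `t` and draws a
#' directed edge u -> v for every neighbor pair whose LAT difference is
#' positive and whose apparent speed `dist/dLAT` lies strictly within the
#' conduction-velocity bounds. Because every edge increases LAT, this
#' graph is always acyclic.
#'
#' @param set `electrode_set` (or `activation_field`).
#' @param relation `neighbor_relation` over the same electrodes.
#' @param lat_map named list of LAT vectors (defaults to the field's).
#' @param t window start time, ms.
#' @param bounds a [cv_bounds()] object.
#' @return an `excitation_network`.
#' @export
build_single_graph <- function(set, relation, lat_map = NULL, t = 0,
                               bounds = cv_preset("ventricular")) {
  if (is.null(lat_map) && inherits(set, "activation_field"))
    lat_map <- set$lats
  set <- as_electrode_set(set)
  L <- first_lats_after(lat_map, t)
  present <- which(!is.na(L))
  E <- edges_for_lats(L, relation, set$positions, bounds)
  nodes <- data.frame(node = seq_along(present), electrode = present,
                      id = set$ids[present], lat = L[present],
                      x = set$positions[present, 1],
                      y = set$positions[present, 2],
                      z = set$positions[present, 3])
  remap <- match(seq_along(L), present)
  E$src <- remap[E$src]; E$dst <- remap[E$dst]
  E$window <- if (nrow(E)) 1L else integer(0)
  new_excitation_network(nodes, E, t, NA_real_, bounds, set, TRUE)
}

#' Build the merged dual-window excitation network
#'
#' The single-window graph is acyclic by construction, so reentry can
#' never appear in it. A second graph is therefore built at `t + delta_t`
#' and merged into the first: an edge of the second graph is added only
#' when the LAT of its origin node is unchanged between the windows, i.e.
#' the origin has not yet re-fired. The added edges are exactly those that
#' close the loop of a reentrant circuit.
#'
#' @inheritParams build_single_graph
#' @param delta_t second-window offset, ms (default 40; must satisfy
#'   `0 < delta_t < cycle_length/2` — a warning is issued when a known
#'   cycle length contradicts this).
#' @param cycle_length optional known period, ms (for the warning only).
#' @param collapse if `TRUE` (default) a re-fired target electrode is
#'   identified with its first-window node, keeping one node per
#'   electrode; if `FALSE` such targets become distinct (electrode, LAT)
#'   nodes.
#' @return an `excitation_network`.
#' @export
build_merged_graph <- function(set, relation, lat_map = NULL, t = 0,
                               delta_t = 40,
                               bounds = cv_preset("ventricular"),
                               cycle_length = NULL, collapse = TRUE) {
  if (is.null(lat_map) && inherits(set, "activation_field")) {
    if (is.null(cycle_length)) cycle_length <- set$cycle_length
    lat_map <- set$lats
  }
  set <- as_electrode_set(set)
  stopifnot(delta_t >= 0)
  if (!is.null(cycle_length) && !is.na(cycle_length) &&
      delta_t >= cycle_length / 2)
    warning(sprintf("delta_t = %g ms >= cycle_length/2 = %g ms: windows may overlap a full beat",
                    delta_t, cycle_length / 2))
  L1 <- first_lats_after(lat_map, t)
  L2 <- first_lats_after(lat_map, t + delta_t)
  E1 <- edges_for_lats(L1, relation, set$positions, bounds)
  E2 <- edges_for_lats(L2, relation, set$positions, bounds)
  # second-window edges admissible only from origins whose LAT is unchanged
  same <- !is.na(L1) & !is.na(L2) & L1 == L2
  E2 <- E2[same[E2$src], , drop = FALSE]

  if (collapse) {
    present <- sort(unique(c(which(!is.na(L1)), E2$src, E2$dst)))
    lat_node <- ifelse(is.na(L1), L2, L1)[present]
    key1 <- paste(E1$src, E1$dst)
    key2 <- paste(E2$src, E2$dst)
    E2 <- E2[!(key2 %in% key1), , drop = FALSE]
    E1$window <- if (nrow(E1)) 1L else integer(0)
    E2$window <- if (nrow(E2)) 2L else integer(0)
    E <- rbind(E1, E2)
    remap <- match(seq_along(L1), present)
    E$src <- remap[E$src]; E$dst <- remap[E$dst]
    nodes <- data.frame(node = seq_along(present), electrode = present,
                        id = set$ids[present], lat = lat_node,
                        x = set$positions[present, 1],
                        y = set$positions[present, 2],
                        z = set$positions[present, 3])
    net <- new_excitation_network(nodes, E, t, delta_t, bounds, set, TRUE)
  } else {
    # node identity = (electrode, LAT)
    n1 <- data.frame(electrode = which(!is.na(L1)),
                     lat = L1[!is.na(L1)])
    tgt2 <- unique(E2$dst)
    extra <- tgt2[is.na(L1[tgt2]) | L2[tgt2] != L1[tgt2]]
    n2 <- data.frame(electrode = extra, lat = L2[extra])
    nodes_el <- rbind(n1, n2)
    nodes_el <- nodes_el[!duplicated(nodes_el), , drop = FALSE]
    key <- paste(nodes_el$electrode, signif(nodes_el$lat, 12))
    node_of <- function(el, lat) match(paste(el, signif(lat, 12)), key)
    E1n <- data.frame(src = node_of(E1$src, L1[E1$src]),
                      dst = node_of(E1$dst, L1[E1$dst]),
                      dlat = E1$dlat, dist = E1$dist, speed = E1$speed,
                      window = if (nrow(E1)) 1L else integer(0))
    E2n <- data.frame(src = node_of(E2$src, L2[E2$src]),
                      dst = node_of(E2$dst, L2[E2$dst]),
                      dlat = E2$dlat, dist = E2$dist, speed = E2$speed,
                      window = if (nrow(E2)) 2L else integer(0))
    E <- rbind(E1n, E2n)
    E <- E[!duplicated(E[, c("src", "dst")]), , drop = FALSE]
    nodes <- data.frame(node = seq_len(nrow(nodes_el)),
                        electrode = nodes_el$electrode,
                        id = set$ids[nodes_el$electrode],
                        lat = nodes_el$lat,
                        x = set$positions[nodes_el$electrode, 1],
                        y = set$positions[nodes_el$electrode, 2],
                        z = set$positions[nodes_el$electrode, 3])
    net <- new_excitation_network(nodes, E, t, delta_t, bounds, set, FALSE)
  }
  net
}

as_igraph <- function(network) {
  n <- nrow(network$nodes)
  if (!nrow(network$edges)) return(igraph::make_empty_graph(n))
  el <- as.matrix(network$edges[, c("src", "dst")])
  storage.mode(el) <- "integer"
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Serialize an excitation network to CSV (+ JSON metadata)
#' @param network an `excitation_network`.
#' @param path CSV path; a `.json` sidecar with t, delta_t and CV bounds
#'   is written next to it.
#' @export
write_network_csv <- function(network, path) {
  e <- network$edges
  n <- network$nodes
  df <- data.frame(src_id = n$id[e$src], src_lat = n$lat[e$src],
                   dst_id = n$id[e$dst], dst_lat = n$lat[e$dst],
                   distance_mm = e$dist, speed_mm_per_ms = e$speed,
                   window = e$window)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(t = network$t, delta_t = network$delta_t,
               cv_min = network$bounds$cv_min,
               cv_max = network$bounds$cv_max)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
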