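#' Directed graph mapping of an activation field
#'
#' The full diagnosis pipeline: determine electrode neighbors, build the
#' dual-window directed excitation network under the conduction-velocity
#' rule, search for directed cycles (reentry), bundle them into cores —
#' and only if no cycle exists, look for focal sources as regions with
#' only outgoing arrows. Reentrant diagnoses also carry the region of
#' cycles and the region of influence of every core.
#'
#' @param field an `activation_field`, or the list returned by
#'   [read_lat_table()].
#' @param relation optional `neighbor_relation`; by default a spherical
#'   1.5-spacing neighborhood on regular grids and Delaunay
#'   triangulation on irregular clouds.
#' @param t window start time, ms; default just before the earliest LAT.
#' @param bounds [cv_bounds()] or a preset name (`"ventricular"`,
#'   `"atrial"`).
#' @param delta_t dual-window offset, ms (default 40).
#' @param core_threshold cycle-bundling proximity threshold, mm
#'   (default 10).
#' @param bundle_interval LAT bundling interval for focal search, ms.
#' @param metric region-of-influence distance metric (see
#'   [region_of_influence()]).
#' @param compute_features also compute regions and the averaged flow
#'   field (default `TRUE`).
#' @param check_stability require focal regions stable across two
#'   construction times; default: on when >= 2 beats are available.
#' @return an object of class `dgmap` with elements `mechanism`
#'   (`"reentry"`, `"focal"` or `"none"`), `cores`, `focal_sources`,
#'   `network`, `regions`, `flow` and `config`.
#' @export
dgmap <- function(field, relation = NULL, t = NULL,
                  bounds = "ventricular", delta_t = 40,
                  core_threshold = 10, bundle_interval = 5,
                  metric = "dlat", compute_features = TRUE,
                  check_stability = NULL) {
  if (is.list(field) && !inherits(field, "activation_field") &&
      !is.null(field$set)) {
    field <- activation_field(field$set$ids, field$set$positions,
                              field$lat_map, field$cycle_length,
                              field$truth)
  }
  stopifnot(inherits(field, "activation_field"))
  if (!any(lengths(field$lats) > 0)) stop("empty field: no LATs")
  if (is.character(bounds)) bounds <- cv_preset(bounds)
  eset <- as_electrode_set(field)
  if (is.null(relation)) {
    relation <- if (is_regular_grid(eset$positions))
      neighbors_regular(eset) else neighbors_delaunay(eset)
  }
  if (is.null(t)) t <- min(unlist(field$lats)) - 1e-6
  net <- build_merged_graph(eset, relation, field$lats, t, delta_t,
                            bounds, cycle_length = field$cycle_length)
  cycles <- find_all_smallest_cycles(net)
  cores <- list(); sources <- list(); regions <- NULL; flow <- NULL
  if (length(cycles)) {
    cores <- bundle_cycles(cycles, core_threshold)
    mechanism <- "reentry"
    if (compute_features) regions <- region_of_influence(net, cores, metric)
  } else {
    if (is.null(check_stability))
      check_stability <- any(lengths(field$lats) >= 2)
    sources <- find_focal_sources(eset, relation, field$lats, t, bounds,
                                  bundle_interval, delta_t,
                                  check_stability)
    mechanism <- if (length(sources)) "focal" else "none"
  }
  if (compute_features) flow <- wave_average(net)
  structure(list(mechanism = mechanism, cores = cores,
                 focal_sources = sources, network = net,
                 regions = regions, flow = flow, field = field,
                 config = list(cv_min = bounds$cv_min,
                               cv_max = bounds$cv_max, t = t,
                               delta_t = delta_t,
                               core_threshold = core_threshold,
                               bundle_interval = bundle_interval,
                               metric = metric,
                               neighbor_method = relation$method,
                               package_version =
                                 as.character(utils::packageVersion("dgmap")))),
            class = "dgmap")
}

#' @rdname dgmap
#' @param ... passed on to [dgmap()].
#' @export
diagnose <- function(field, ...) dgmap(field, ...)

is_regular_grid <- function(pos, tol = 1e-6) {
  if (diff(range(pos[, 3])) > tol) return(FALSE)
  xs <- sort(unique(round(pos[, 1], 6)))
  ys <- sort(unique(round(pos[, 2], 6)))
  if (length(xs) < 2 || length(ys) < 2) return(FALSE)
  if (nrow(pos) != length(xs) * length(ys)) return(FALSE)
  all(abs(diff(diff(xs))) < tol) && all(abs(diff(diff(ys))) < tol)
}

#' @export
print.dgmap <- function(x, ...) {
  cat("Directed graph mapping diagnosis\n")
  cat(sprintf("  mechanism: %s\n", x$mechanism))
  cat(sprintf("  network: %d nodes, %d edges\n", nrow(x$network$nodes),
              nrow(x$network$edges)))
  if (length(x$cores)) {
    for (i in seq_along(x$cores)) {
      co <- x$cores[[i]]
      cat(sprintf("  core %d: center (%.1f, %.1f) mm, %d cycle(s)\n", i,
                  co$center[1], co$center[2], co$n_cycles))
    }
  }
  if (length(x$focal_sources)) {
    for (i in seq_along(x$focal_sources)) {
      s <- x$focal_sources[[i]]
      cat(sprintf("  focal source %d: origin (%.1f, %.1f) mm, %d electrode(s)\n",
                  i, s$origin[1], s$origin[2], length(s$electrodes)))
    }
  }
  invisible(x)
}

#' @export
summary.dgmap <- function(object, ...) {
  print(object)
  e <- object$network$edges
  if (nrow(e))
    cat(sprintf("  edge speeds: %.2f-%.2f mm/ms (median %.2f)\n",
                min(e$speed), max(e$speed), stats::median(e$speed)))
  if (!is.null(object$regions)) {
    tab <- table(factor(object$regions$core,
                        levels = seq_along(object$cores)))
    cat(sprintf("  region of influence sizes: %s\n",
                paste(tab, collapse = ", ")))
  }
  invisible(object)
}

#' Plot a directed-graph mapping diagnosis
#'
#' Electrodes colored by activation time, network arrows in grey, the
#' representative cycle of each reentry core in red with the core center
#' marked, and focal-source regions in orange.
#'
#' @param x a `dgmap` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dgmap <- function(x, ...) {
  nd <- x$network$nodes
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[cut(nd$lat, 64, labels = FALSE)]
  graphics::plot(nd$x, nd$y, pch = 16, col = col, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("DG mapping: %s", x$mechanism), ...)
  e <- x$network$edges
  if (nrow(e))
    graphics::arrows(nd$x[e$src], nd$y[e$src], nd$x[e$dst], nd$y[e$dst],
                     length = 0.05, col = grDevices::adjustcolor("grey40", 0.4))
  for (co in x$cores) {
    cyc <- co$representative
    xx <- nd$x[cyc$nodes]; yy <- nd$y[cyc$nodes]
    graphics::lines(c(xx, xx[1]), c(yy, yy[1]), col = "red", lwd = 2)
    graphics::points(co$center[1], co$center[2], pch = 4, cex = 2,
                     lwd = 3, col = "red")
  }
  for (s in x$focal_sources) {
    m <- match(s$electrodes, nd$id)
    graphics::points(nd$x[m], nd$y[m], pch = 2, cex = 1.5, col = "orange",
                     lwd = 2)
    graphics::points(s$origin[1], s$origin[2], pch = 17, col = "orange",
                     cex = 1.5)
  }
  invisible(x)
}
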