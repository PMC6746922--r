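#' Synthetic activation fields
#'
#' An activation field holds, for a set of electrodes, 3D positions (mm)
#' and a sorted list of local activation times (LATs, ms) per electrode,
#' plus the ground truth used by the generators (mechanism kind and true
#' core/source coordinates). The generators emulate the canonical
#' excitation patterns of stable tachycardias — a functional-reentry
#' rotor, anatomical reentry around an inexcitable obstacle, focal
#' sources, and a centrifugal target wave — so every downstream stage can
#' be exercised and validated without simulating an ionic model.
#'
#' @param ids character or integer electrode identifiers.
#' @param positions numeric matrix (n x 3) of electrode coordinates in mm.
#' @param lats list of numeric vectors: strictly increasing LATs (ms) per
#'   electrode. An empty vector marks a no-signal (scar) electrode.
#' @param cycle_length arrhythmia period in ms (NA when aperiodic).
#' @param truth list describing the ground truth: `kind` (one of
#'   `"rotor"`, `"anatomical_reentry"`, `"focal"`, `"target_wave"`,
#'   `"multi_rotor"`) and `core` (matrix of true core/source coordinates,
#'   one row each).
#' @return An object of class `activation_field`.
#' @export
activation_field <- function(ids, positions, lats, cycle_length = NA_real_,
                             truth = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) == 2) positions <- cbind(positions, 0)
  stopifnot(nrow(positions) == length(ids), length(lats) == length(ids),
            !anyDuplicated(ids), all(is.finite(positions)))
  lats <- lapply(lats, function(v) sort(as.numeric(v)))
  for (v in lats) {
    if (length(v) > 1 && any(diff(v) <= 0))
      stop("LATs per electrode must be strictly increasing")
  }
  structure(list(ids = as.character(ids), positions = positions,
                 lats = stats::setNames(lats, as.character(ids)),
                 cycle_length = cycle_length, truth = truth),
            class = "activation_field")
}

#' @export
print.activation_field <- function(x, ...) {
  nl <- lengths(x$lats)
  cat(sprintf("activation_field: %d electrodes, %d LATs (%s)\n",
              length(x$ids), sum(nl),
              if (is.null(x$truth)) "no truth" else x$truth$kind))
  if (!is.na(x$cycle_length))
    cat(sprintf("  cycle length %.1f ms, LAT range [%.1f, %.1f] ms\n",
                x$cycle_length, min(unlist(x$lats)), max(unlist(x$lats))))
  invisible(x)
}

#' Regular-grid electrode positions
#'
#' Row-major planar grid: electrode (r, c) sits at
#' `((c-1)*spacing, (r-1)*spacing, 0)` mm.
#' @param grid_shape `c(rows, cols)`.
#' @param spacing inter-electrode distance, mm.
#' @export
grid_positions <- function(grid_shape, spacing) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  # row-major: electrode (r, c) at index (r-1)*cols + c
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  cbind(x = (g$col - 1) * spacing, y = (g$row - 1) * spacing, z = 0)
}

#' Generate a stable rotor activation field
#'
#' Archimedean-spiral rotor on a regular grid: the electrode at angle
#' `theta` and radius `r` about the core activates at
#' `cycle_length * (k + theta/2pi + r/lambda)` in beat `k`, where the
#' spiral wavelength is `lambda = wave_speed * cycle_length`. Isochrones
#' are spiral arms rotating once per cycle about the core; away from the
#' core the wavefront travels at `wave_speed` (the plane-wave conduction
#' velocity of ventricular tissue, ~0.7 mm/ms) and the apparent velocity
#' falls below physiological bounds only close to the core — the
#' structure of a spatially stable functional-reentry rotor, without
#' meander. `wave_speed = 0` drops the radial term and yields a rigidly
#' rotating pure phase rotor (straight-spoke isochrones).
#'
#' @param grid_shape integer vector `c(rows, cols)`.
#' @param spacing inter-electrode distance, mm (default 8: a 16 x 16
#'   grid then covers a ~120 mm ventricular tissue slab).
#' @param cycle_length rotation period, ms.
#' @param core_xy rotor core `c(x, y)` in mm; default grid center.
#' @param chirality `"ccw"` (phase increases counter-clockwise) or `"cw"`.
#' @param n_cycles number of rotations recorded (>= 2).
#' @param wave_speed far-field propagation speed, mm/ms.
#' @return `activation_field` with `truth$kind == "rotor"`.
#' @export
make_rotor_field <- function(grid_shape = c(16, 16), spacing = 8,
                             cycle_length = 260, core_xy = NULL,
                             chirality = c("ccw", "cw"), n_cycles = 4,
                             wave_speed = 0.7) {
  chirality <- match.arg(chirality)
  stopifnot(n_cycles >= 2, spacing > 0, cycle_length > 0, wave_speed >= 0)
  pos <- grid_positions(grid_shape, spacing)
  if (is.null(core_xy))
    core_xy <- c(max(pos[, 1]) / 2, max(pos[, 2]) / 2)
  if (core_xy[1] < 0 || core_xy[1] > max(pos[, 1]) ||
      core_xy[2] < 0 || core_xy[2] > max(pos[, 2]))
    stop("rotor core lies outside the electrode grid footprint")
  th <- atan2(pos[, 2] - core_xy[2], pos[, 1] - core_xy[1])
  if (chirality == "cw") th <- -th
  th <- th %% (2 * pi)
  rr <- sqrt((pos[, 1] - core_xy[1])^2 + (pos[, 2] - core_xy[2])^2)
  radial <- if (wave_speed > 0) rr / (wave_speed * cycle_length) else 0
  lat0 <- cycle_length * (th / (2 * pi) + radial)
  lats <- lapply(lat0, function(l) l + cycle_length * (seq_len(n_cycles) - 1))
  activation_field(seq_len(nrow(pos)), pos, lats, cycle_length,
                   truth = list(kind = "rotor",
                                core = matrix(c(core_xy, 0), nrow = 1),
                                chirality = chirality))
}

#' Generate a multi-rotor activation field
#'
#' Four (or `n x n`) phase rotors of alternating chirality tiled over a
#' regular grid; each electrode follows the rotor whose core is nearest.
#' Phase is discontinuous across tile borders, which mimics the
#' wavebreak lines separating neighbouring counter-rotating spiral
#' domains and keeps each rotor's cycles confined to its own domain.
#'
#' @inheritParams make_rotor_field
#' @param n_rotors_side rotors per side (2 gives the four-rotor layout).
#' @export
make_multi_rotor_field <- function(grid_shape = c(25, 25), spacing = 5,
                                   cycle_length = 260, n_cycles = 4,
                                   n_rotors_side = 2) {
  pos <- grid_positions(grid_shape, spacing)
  span_x <- max(pos[, 1]); span_y <- max(pos[, 2])
  cx <- (seq_len(n_rotors_side) - 0.5) * span_x / n_rotors_side
  cy <- (seq_len(n_rotors_side) - 0.5) * span_y / n_rotors_side
  cores <- as.matrix(expand.grid(x = cx, y = cy))
  chir <- outer(seq_along(cx), seq_along(cy), function(i, j) (i + j) %% 2)
  chir <- as.vector(chir)
  d2 <- sapply(seq_len(nrow(cores)), function(k)
    (pos[, 1] - cores[k, 1])^2 + (pos[, 2] - cores[k, 2])^2)
  near <- max.col(-d2)
  th <- atan2(pos[, 2] - cores[near, 2], pos[, 1] - cores[near, 1])
  th <- ifelse(chir[near] == 1, -th, th) %% (2 * pi)
  lat0 <- cycle_length * th / (2 * pi)
  lats <- lapply(lat0, function(l) l + cycle_length * (seq_len(n_cycles) - 1))
  activation_field(seq_len(nrow(pos)), pos, lats, cycle_length,
                   truth = list(kind = "multi_rotor",
                                core = cbind(cores, z = 0)))
}

#' Generate a focal-source activation field
#'
#' Centrifugal activation from one or more point sources firing
#' periodically: each electrode's LAT within a beat is its distance to the
#' nearest source divided by the conduction velocity, plus the beat
#' offset.
#'
#' @param positions electrode positions (n x 2 or n x 3, mm) or an
#'   `activation_field`/matrix; a `grid_shape`+`spacing` pair may be given
#'   instead via [grid_positions()].
#' @param source_xyz matrix of source coordinates (one row per source, mm).
#' @param conduction_velocity wavefront speed, mm/ms (> 0).
#' @param period firing period, ms.
#' @param n_beats number of beats recorded.
#' @export
make_focal_field <- function(positions, source_xyz, conduction_velocity = 0.5,
                             period = 500, n_beats = 3) {
  pos <- as.matrix(positions)
  if (ncol(pos) == 2) pos <- cbind(pos, 0)
  src <- source_xyz
  if (is.null(dim(src))) src <- matrix(src, nrow = 1)
  src <- as.matrix(src)
  if (ncol(src) == 2) src <- cbind(src, 0)
  if (conduction_velocity <= 0) stop("conduction velocity must be > 0")
  if (nrow(src) < 1 || nrow(src) > nrow(pos))
    stop("number of sources must be between 1 and the electrode count")
  dmin <- apply(src, 1, function(s)
    sqrt((pos[, 1] - s[1])^2 + (pos[, 2] - s[2])^2 + (pos[, 3] - s[3])^2))
  dmin <- if (is.matrix(dmin)) apply(dmin, 1, min) else dmin
  lat0 <- dmin / conduction_velocity
  lats <- lapply(lat0, function(l) l + period * (seq_len(n_beats) - 1))
  activation_field(seq_len(nrow(pos)), pos, lats, period,
                   truth = list(kind = "focal", core = src,
                                conduction_velocity = conduction_velocity))
}

#' Generate a centrifugal target-wave field
#'
#' Single point source, no reentry: the specificity fixture. Identical to
#' [make_focal_field()] with one source, but tagged `target_wave`.
#' @inheritParams make_focal_field
#' @param center_xyz source coordinates (length 2 or 3, mm).
#' @export
make_target_wave_field <- function(positions, center_xyz,
                                   conduction_velocity = 0.5, period = 500,
                                   n_beats = 3) {
  f <- make_focal_field(positions, matrix(center_xyz, nrow = 1),
                        conduction_velocity, period, n_beats)
  f$truth$kind <- "target_wave"
  f
}

# ray-casting point-in-polygon (polygon k x 2, open or closed)
point_in_polygon <- function(pts, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  k <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- k
  for (i in seq_len(k)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > pts[, 2]) != (yj > pts[, 2])
    xint <- (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (pts[, 1] < xint))
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Generate an anatomical-reentry activation field
#'
#' Excitation circulating around an inexcitable obstacle: LATs follow the
#' angular phase about the obstacle centroid, and electrodes inside the
#' obstacle polygon carry no LATs (scar). The smallest detected cycle in
#' the excitation network then winds once around the obstacle.
#'
#' @param positions electrode positions (mm).
#' @param obstacle_polygon k x 2 matrix of polygon vertices (mm),
#'   strictly inside the electrode footprint.
#' @param path_cycle_length revolution period, ms.
#' @param n_cycles number of revolutions recorded.
#' @param chirality rotation sense.
#' @export
make_anatomical_reentry_field <- function(positions, obstacle_polygon,
                                          path_cycle_length = 260,
                                          n_cycles = 4,
                                          chirality = c("ccw", "cw")) {
  chirality <- match.arg(chirality)
  pos <- as.matrix(positions)
  if (ncol(pos) == 2) pos <- cbind(pos, 0)
  poly <- as.matrix(obstacle_polygon)
  if (nrow(poly) < 3 || polygon_area(poly) <= 0)
    stop("degenerate obstacle polygon")
  ctr <- colMeans(poly[!duplicated(poly), , drop = FALSE])
  th <- atan2(pos[, 2] - ctr[2], pos[, 1] - ctr[1])
  if (chirality == "cw") th <- -th
  th <- th %% (2 * pi)
  lat0 <- path_cycle_length * th / (2 * pi)
  inside <- point_in_polygon(pos[, 1:2, drop = FALSE], poly)
  lats <- lapply(seq_len(nrow(pos)), function(i) {
    if (inside[i]) numeric(0)
    else lat0[i] + path_cycle_length * (seq_len(n_cycles) - 1)
  })
  activation_field(seq_len(nrow(pos)), pos, lats, path_cycle_length,
                   truth = list(kind = "anatomical_reentry",
                                core = matrix(c(ctr, 0), nrow = 1),
                                obstacle = poly))
}

#' Add LAT measurement noise
#'
#' Perturbs every LAT independently. Gaussian noise is additive
#' N(0, sigma^2); lognormal noise (a skewed alternative) is shifted to
#' zero mean and rescaled so its standard deviation equals `sigma`, making
#' the two distributions comparable. Positions, electrode identities and
#' the truth block are untouched, and the result is deterministic for a
#' given `seed`.
#'
#' @param field an `activation_field`.
#' @param sigma noise standard deviation, ms (>= 0; 0 returns the field
#'   unchanged).
#' @param distribution `"gaussian"` or `"lognormal"`.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @export
add_lat_noise <- function(field, sigma,
                          distribution = c("gaussian", "lognormal"),
                          seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(field, "activation_field"), sigma >= 0)
  if (sigma == 0) return(field)
  nl <- lengths(field$lats)
  n <- sum(nl)
  noise <- with_seed(seed, {
    if (distribution == "gaussian") {
      stats::rnorm(n, 0, sigma)
    } else {
      # standard lognormal (meanlog 0, sdlog 1), centred and scaled
      x <- stats::rlnorm(n, 0, 1)
      mu <- exp(0.5); s <- sqrt((exp(1) - 1) * exp(1))
      (x - mu) / s * sigma
    }
  })
  idx <- cumsum(nl)
  out <- field
  start <- c(1, head(idx, -1) + 1)
  for (i in seq_along(out$lats)) {
    if (nl[i] == 0) next
    v <- out$lats[[i]] + noise[start[i]:idx[i]]
    out$lats[[i]] <- sort(v)
  }
  out
}

#' Split a recording into analysis frames
#'
#' Frame `i` contains, per electrode, the first LAT at or after
#' `(i-1) * frame_separation` plus the following LAT (the next beat),
#' which the dual-time-window graph construction needs. A separation
#' larger than the cycle length guarantees pairwise disjoint frame
#' windows.
#'
#' @param field an `activation_field`.
#' @param n_frames number of frames.
#' @param frame_separation spacing of frame start times, ms.
#' @return list of `activation_field` objects (two LATs per electrode).
#' @export
extract_frames <- function(field, n_frames, frame_separation) {
  stopifnot(n_frames >= 1, frame_separation > 0)
  need <- (n_frames - 1) * frame_separation
  have <- suppressWarnings(min(vapply(field$lats, function(v)
    if (length(v)) max(v) else Inf, 1.0)))
  lapply(seq_len(n_frames), function(i) {
    t0 <- (i - 1) * frame_separation
    lats <- lapply(field$lats, function(v) {
      k <- which(v >= t0)
      if (!length(v)) return(numeric(0))
      if (!length(k))
        stop(sprintf(paste0("recording too short: frame %d needs a LAT >= ",
                            "%.0f ms but the electrode ends at %.0f ms"),
                     i, t0, max(v)))
      v[k[1]:min(k[1] + 1, length(v))]
    })
    out <- field
    out$lats <- lats
    attr(out, "frame_start") <- t0
    out
  })
}
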