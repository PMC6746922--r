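#' Phase-mapping baseline
#'
#' The classical alternative to network-based rotor detection: LATs are
#' converted to a sawtooth phase in `[-pi, pi)` and phase singularities
#' (points where all phases meet) are found from the topological charge
#' of the wrapped phase gradient, computed by kernel convolution and
#' thresholded at a fraction of the maximal response.
#'
#' @name phase_mapping
NULL

wrap_angle <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Sawtooth phase frame from LATs
#'
#' The phase of an electrode at query time `t` is
#' `2*pi*(t - LAT)/cycle_length` wrapped into `[-pi, pi)`, using the
#' activation nearest in time to `t`. Phase is exactly 0 at the moment of
#' activation and advances linearly with slope `2*pi/cycle_length`.
#'
#' @param field an `activation_field` on a regular 2D grid.
#' @param t query time, ms.
#' @param cycle_length sawtooth period, ms; default: the field's period,
#'   or the median inter-activation interval when absent.
#' @return a `phase_frame`: phase matrix (rows = y, cols = x) plus grid
#'   coordinates in mm. Electrodes without LATs are `NA` and listed in
#'   `attr(, "excluded")`.
#' @export
lat_to_phase <- function(field, t, cycle_length = NULL) {
  stopifnot(inherits(field, "activation_field"))
  if (is.null(cycle_length)) cycle_length <- field$cycle_length
  if (is.null(cycle_length) || is.na(cycle_length))
    cycle_length <- stats::median(unlist(lapply(field$lats, diff)))
  stopifnot(cycle_length > 0)
  xs <- sort(unique(field$positions[, 1]))
  ys <- sort(unique(field$positions[, 2]))
  phi <- matrix(NA_real_, nrow = length(ys), ncol = length(xs))
  ri <- match(field$positions[, 2], ys)
  ci <- match(field$positions[, 1], xs)
  excluded <- character(0)
  for (k in seq_along(field$lats)) {
    v <- field$lats[[k]]
    if (!length(v)) { excluded <- c(excluded, field$ids[k]); next }
    nearest <- v[which.min(abs(v - t))]
    phi[ri[k], ci[k]] <- wrap_angle(2 * pi * (t - nearest) / cycle_length)
  }
  structure(list(phase = phi, xs = xs, ys = ys,
                 spacing = c(stats::median(diff(xs)),
                             stats::median(diff(ys))),
                 cycle_length = cycle_length, t = t),
            class = "phase_frame", excluded = excluded)
}

conv2_valid <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(m) - kr + 1; nc <- ncol(m) - kc + 1
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    out <- out + k[i, j] * m[i:(i + nr - 1), j:(j + nc - 1), drop = FALSE]
  }
  out
}

#' Topological charge of a phase frame
#'
#' Wrapped phase differences (shortest angular distance) are summed
#' around each 2x2 plaquette; the result is +/-1 at a phase singularity
#' and 0 elsewhere (discrete winding number). Plaquettes touching missing
#' electrodes are `NA`.
#'
#' @param frame a `phase_frame`.
#' @return matrix of plaquette charges ((rows-1) x (cols-1)).
#' @export
phase_charge <- function(frame) {
  phi <- frame$phase
  r <- nrow(phi); c <- ncol(phi)
  dx <- wrap_angle(phi[, -1, drop = FALSE] - phi[, -c, drop = FALSE])
  dy <- wrap_angle(phi[-1, , drop = FALSE] - phi[-r, , drop = FALSE])
  (dx[-r, , drop = FALSE] + dy[, -1, drop = FALSE] -
     dx[-1, , drop = FALSE] - dy[, -c, drop = FALSE]) / (2 * pi)
}

#' Detect phase singularities
#'
#' The phase field is differentiated in x and y on the circle (wrapped
#' shortest-angle differences — naive differences would produce spurious
#' 2*pi jumps), the derivative images are filtered with the Sobel
#' kernels (or the plain central-difference "Nabla" kernels), and the
#' two filtered derivatives are combined into a single response
#' magnitude. At a phase singularity all phase values meet, so the
#' spatial phase variation — and hence the response — is maximal there.
#' The response is not quantized: an aberrant LAT produces a near-pi
#' wrapped phase jump and thus a competing response anywhere in the
#' frame, which is the known noise fragility of phase mapping.
#' Convolution is valid-only (no padding), so frame edges cannot yield
#' false positives. Cells whose response reaches `threshold_fraction`
#' of the maximal
#' response are detections; cells within ~3 grid steps of each other —
#' the footprint of a single singularity's response ring — are
#' aggregated into one detected singularity at their response-weighted
#' centroid, signed by the topological charge the cluster encloses
#' (with `cluster = FALSE` every suprathreshold cell is reported
#' separately, the raw binary-threshold map).
#'
#' @param frame a `phase_frame` (grid at least 3 x 3; at least 5 x 5 for
#'   the Sobel kernel).
#' @param kernel `"sobel"` or `"nabla"`.
#' @param threshold_fraction detection threshold as a fraction of the
#'   maximal response (default 0.95).
#' @param cluster aggregate suprathreshold cells into one detection per
#'   singularity (default `TRUE`; the response of the gradient detector
#'   peaks on a ring of cells around a singularity, and the aggregated
#'   response-weighted centroid recovers its position).
#' @param min_response absolute response floor, rad per grid step: when
#'   no response reaches it the frame is declared singularity-free. A
#'   resolvable singularity drives phase steps toward the wrap scale
#'   (~pi) near its core, while smooth travelling waves stay well below
#'   it; the default pi/6 separates the two regimes.
#' @return a `singularity_detection` data frame (x, y in mm, response)
#'   with the threshold used in attributes; zero rows when the phase
#'   field carries no singular response.
#' @export
detect_singularities <- function(frame, kernel = c("sobel", "nabla"),
                                 threshold_fraction = 0.95,
                                 cluster = TRUE, min_response = pi / 6) {
  kernel <- match.arg(kernel)
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  phi <- frame$phase
  if (nrow(phi) < 3 || ncol(phi) < 3) stop("grid must be at least 3 x 3")
  r <- nrow(phi); c <- ncol(phi)
  if (r < 5 || c < 5) stop("grid must be at least 5 x 5")
  # centred wrapped phase derivatives on interior nodes
  gx <- wrap_angle(phi[, 3:c, drop = FALSE] -
                     phi[, 1:(c - 2), drop = FALSE]) / 2  # r x (c-2)
  gy <- wrap_angle(phi[3:r, , drop = FALSE] -
                     phi[1:(r - 2), , drop = FALSE]) / 2  # (r-2) x c
  gx_i <- gx[2:(r - 1), , drop = FALSE]                   # (r-2) x (c-2)
  gy_i <- gy[, 2:(c - 1), drop = FALSE]
  na_mask <- is.na(gx_i) | is.na(gy_i)
  gx_i[is.na(gx_i)] <- 0; gy_i[is.na(gy_i)] <- 0
  if (kernel == "sobel") {
    # Sobel = central difference smoothed with [1,2,1]/4 across-track;
    # applied to the wrapped derivatives this is the Sobel-filtered
    # phase gradient
    Sx <- matrix(c(1, 2, 1) / 4, nrow = 1)  # smooth along x
    Sy <- matrix(c(1, 2, 1) / 4, ncol = 1)  # smooth along y
    Gx <- conv2_valid(gx_i, Sy)             # (r-4) x (c-2)
    Gy <- conv2_valid(gy_i, Sx)             # (r-2) x (c-4)
    Gx <- Gx[, 2:(ncol(Gx) - 1), drop = FALSE]  # -> (r-4) x (c-4)
    Gy <- Gy[2:(nrow(Gy) - 1), , drop = FALSE]
    bad <- conv2_valid(matrix(as.numeric(na_mask), nrow(na_mask)),
                       matrix(1, 3, 3)) > 0
  } else {
    Gx <- gx_i[2:(r - 3), 2:(c - 3), drop = FALSE]
    Gy <- gy_i[2:(r - 3), 2:(c - 3), drop = FALSE]
    bad <- na_mask[2:(r - 3), 2:(c - 3), drop = FALSE]
  }
  resp <- sqrt(Gx^2 + Gy^2)
  resp[bad] <- NA
  rx <- frame$xs[3:(c - 2)]
  ry <- frame$ys[3:(r - 2)]
  q <- phase_charge(frame)
  q[is.na(q)] <- 0
  mx <- suppressWarnings(max(abs(resp), na.rm = TRUE))
  empty <- structure(data.frame(x = numeric(0), y = numeric(0),
                                response = numeric(0)),
                     class = c("singularity_detection", "data.frame"),
                     kernel = kernel, threshold = NA_real_)
  # a resolvable singularity forces phase steps near the wrap scale close
  # to its core; a frame whose strongest response stays below this floor
  # (e.g. a smooth planar wave) contains no singularity
  if (!is.finite(mx) || mx < min_response) return(empty)
  thr <- threshold_fraction * mx
  hit <- which(!is.na(resp) & abs(resp) >= thr, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  if (!cluster) {
    out <- data.frame(x = rx[hit[, 2]], y = ry[hit[, 1]],
                      response = resp[hit])
    o <- order(-abs(out$response), out$x, out$y)
    return(structure(out[o, , drop = FALSE],
                     class = c("singularity_detection", "data.frame"),
                     kernel = kernel, threshold = thr))
  }
  # the discrete signature of one singularity is a ring of cells of
  # diameter ~3 spacings around its core: aggregate suprathreshold cells
  # at that scale (single linkage), position each singularity at the
  # response-weighted centroid, and sign it by the topological charge it
  # encloses
  if (nrow(hit) == 1) {
    grp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(hit), method = "single")
    grp <- stats::cutree(hc, h = 3.5)
  }
  dets <- lapply(sort(unique(grp)), function(k) {
    idx <- hit[grp == k, , drop = FALSE]
    w <- abs(resp[idx])
    # plaquette window spanned by the cluster's nodes (nodes 3..r-2 of
    # the full grid touch plaquette rows i+1..i+2 in plaquette indexing)
    pr <- max(1, min(idx[, 1])) : min(nrow(q), max(idx[, 1]) + 3)
    pc <- max(1, min(idx[, 2])) : min(ncol(q), max(idx[, 2]) + 3)
    chg <- sum(q[pr, pc])
    sgn <- if (chg < -0.5) -1 else 1
    c(x = sum(rx[idx[, 2]] * w) / sum(w),
      y = sum(ry[idx[, 1]] * w) / sum(w),
      response = sgn * max(w))
  })
  out <- as.data.frame(do.call(rbind, dets))
  structure(out, class = c("singularity_detection", "data.frame"),
            kernel = kernel, threshold = thr)
}

# Shared outcome taxonomy for both mapping methods. A false core is a
# detection outside the correctness radius; detections inside the radius
# all count as the (one) correct core.
classify_outcome <- function(centers, true_core, radius) {
  if (is.null(centers) || !NROW(centers)) return("error3")
  centers <- as.matrix(centers)
  tc <- as.numeric(true_core)
  if (ncol(centers) == 2) centers <- cbind(centers, 0)
  if (length(tc) == 2) tc <- c(tc, 0)
  d <- sqrt((centers[, 1] - tc[1])^2 + (centers[, 2] - tc[2])^2 +
              (centers[, 3] - tc[3])^2)
  within <- d <= radius
  if (all(within)) return("correct")
  if (any(within)) return("error1")
  "error2"
}

#' Classify a phase-mapping outcome
#'
#' `correct` iff exactly one singularity was detected and it lies within
#' `radius` of the true core; `error1` = a false core detected in
#' addition to the correct one; `error2` = only false cores; `error3` =
#' no detection at all.
#'
#' @param detections a `singularity_detection` (or matrix of positions).
#' @param true_core true core coordinates (mm).
#' @param radius correctness radius, mm (default 10 = 1 cm).
#' @export
classify_pm_outcome <- function(detections, true_core, radius = 10) {
  stopifnot(radius > 0)
  centers <- if (is.data.frame(detections))
    as.matrix(detections[, c("x", "y"), drop = FALSE]) else detections
  classify_outcome(centers, true_core, radius)
}
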