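#' Unipolar electrograms from transmembrane potentials
#'
#' Closes the loop from membrane potential to LATs: a unipolar
#' electrogram at electrode position x is the volume integral of
#' `grad V . (r - x) / |r - x|^3` over the tissue, discretised as a
#' midpoint quadrature over grid cells with central-difference spatial
#' gradients. The local activation time is then annotated at the
#' steepest negative slope (-dV/dt) of the electrogram, which coincides
#' with the action-potential upstroke passing under the electrode.
#'
#' @name egm
NULL

# stereotyped action-potential template: fast sigmoidal upstroke,
# plateau, sigmoidal repolarisation (times in ms, output in mV-like a.u.).
# The upstroke is centred at tau = 0 (steepest dV/dt at the activation
# time), so annotated LATs are directly comparable to the truth.
ap_template <- function(tau, upstroke = 2, apd = 150, amplitude = 100,
                        rest = -85) {
  up <- 1 / (1 + exp(-tau / (upstroke / 8)))
  rep <- 1 / (1 + exp((tau - apd) / (apd / 15)))
  rest + amplitude * up * rep
}

#' Synthetic transmembrane-potential field
#'
#' Advects an action-potential template according to a per-cell
#' activation-time map: `V(cell, t) = sum_k AP(t - LAT_k(cell))`, one
#' term per beat. This produces potential fields whose true LATs are
#' known exactly, so electrogram computation and LAT annotation can be
#' validated end to end.
#'
#' @param lat_grid numeric matrix (rows x cols): first-beat activation
#'   time of each tissue cell, ms; or a list of per-cell LAT vectors of
#'   this shape for multi-beat fields.
#' @param spacing cell size, mm.
#' @param dt time step, ms.
#' @param duration recording length, ms.
#' @param period beat period for multi-beat fields (ms); `NULL` = single
#'   beat.
#' @param n_beats number of beats when `period` is given.
#' @param upstroke,apd,amplitude,rest action-potential template
#'   parameters (ms, ms, mV, mV).
#' @return a `potential_field`: V array (rows x cols x time), grid
#'   spacing, dt and times.
#' @export
make_potential_field <- function(lat_grid, spacing = 1, dt = 0.5,
                                 duration = 400, period = NULL,
                                 n_beats = 1, upstroke = 2, apd = 150,
                                 amplitude = 100, rest = -85) {
  stopifnot(is.matrix(lat_grid), spacing > 0, dt > 0, duration > 3 * dt)
  times <- seq(0, duration, by = dt)
  r <- nrow(lat_grid); c <- ncol(lat_grid)
  V <- array(rest, dim = c(r, c, length(times)))
  offs <- if (is.null(period)) 0 else period * (seq_len(n_beats) - 1)
  lat_flat <- as.vector(lat_grid)
  for (ti in seq_along(times)) {
    v <- rep(0, r * c)
    for (o in offs) {
      tau <- times[ti] - (lat_flat + o)
      v <- v + (ap_template(tau, upstroke, apd, amplitude, rest) - rest)
    }
    V[, , ti] <- rest + v
  }
  structure(list(V = V, spacing = spacing, dt = dt, times = times,
                 lat_grid = lat_grid, offsets = offs),
            class = "potential_field")
}

#' Compute a unipolar electrogram
#'
#' Midpoint-rule quadrature of the dipole-kernel integral: the
#' contribution of each interior grid cell is
#' `grad V . (r - x) / |r - x|^3 * dA`, with `grad V` by central
#' differences. A minimum-distance guard of half a cell keeps the
#' electrode away from the kernel singularity; typical use places the
#' electrode slightly above the tissue plane.
#'
#' @param pf a `potential_field`.
#' @param x electrode position, mm (length 3; tissue lies in z = 0).
#' @param guard minimum allowed electrode-to-cell distance, mm (default
#'   half a cell).
#' @return an `electrogram`: times (ms), signal (a.u.), position.
#' @export
unipolar_egm <- function(pf, x, guard = NULL) {
  stopifnot(inherits(pf, "potential_field"), length(x) == 3)
  h <- pf$spacing
  if (is.null(guard)) guard <- h / 2
  r <- dim(pf$V)[1]; c <- dim(pf$V)[2]; nt <- dim(pf$V)[3]
  # interior cells (central differences defined)
  ri <- 2:(r - 1); ci <- 2:(c - 1)
  cx <- (ci - 1) * h; cy <- (ri - 1) * h
  cellx <- rep(cx, each = length(ri))
  celly <- rep(cy, times = length(ci))
  dx <- cellx - x[1]; dy <- celly - x[2]; dz <- 0 - x[3]
  dist3 <- (dx^2 + dy^2 + dz^2)^(3 / 2)
  dmin <- min(sqrt(dx^2 + dy^2 + dz^2))
  if (dmin < guard)
    stop(sprintf("electrode is %.3g mm from a grid cell (< guard %.3g mm)",
                 dmin, guard))
  wx <- dx / dist3; wy <- dy / dist3
  sig <- numeric(nt)
  for (ti in seq_len(nt)) {
    Vt <- pf$V[, , ti]
    gx <- (Vt[ri, ci + 1] - Vt[ri, ci - 1]) / (2 * h)
    gy <- (Vt[ri + 1, ci] - Vt[ri - 1, ci]) / (2 * h)
    sig[ti] <- sum(as.vector(gx) * wx + as.vector(gy) * wy) * h^2
  }
  structure(list(t = pf$times, signal = sig, position = x),
            class = "electrogram")
}

#' @export
print.electrogram <- function(x, ...) {
  cat(sprintf("electrogram at (%.1f, %.1f, %.1f) mm: %d samples, %.1f ms\n",
              x$position[1], x$position[2], x$position[3], length(x$t),
              max(x$t)))
  invisible(x)
}

#' Annotate LATs on an electrogram
#'
#' Per beat, the LAT is the time of the steepest negative discrete slope
#' of the signal. Beats are separated by a refractory blanking period of
#' half the estimated cycle length (estimated from the spacing of
#' candidate deflections, or given explicitly). Signals with no negative
#' deflection (flat or inverted) yield no LAT.
#'
#' @param egm an `electrogram`.
#' @param blanking blanking period, ms; `NULL` = 0.5 x estimated CL.
#' @param threshold_frac a deflection counts as a candidate beat when its
#'   downslope reaches this fraction of the global steepest downslope.
#' @return numeric vector of LATs (ms), possibly empty.
#' @export
annotate_lat <- function(egm, blanking = NULL, threshold_frac = 0.5) {
  stopifnot(inherits(egm, "electrogram"), length(egm$t) >= 3)
  dt <- egm$t[2] - egm$t[1]
  d <- diff(egm$signal) / dt
  tmid <- (egm$t[-1] + egm$t[-length(egm$t)]) / 2
  gmin <- min(d)
  if (gmin >= 0 || !is.finite(gmin) || abs(gmin) < 1e-12) return(numeric(0))
  cand <- which(d <= threshold_frac * gmin)
  if (is.null(blanking)) {
    # estimated CL: spacing between candidate deflection groups
    gaps <- diff(tmid[cand])
    big <- gaps[gaps > 10 * dt]
    blanking <- if (length(big)) 0.5 * stats::median(big) else
      (max(egm$t) - min(egm$t))
    blanking <- max(blanking, 20 * dt)
  }
  lats <- numeric(0)
  avail <- rep(TRUE, length(d))
  repeat {
    pool <- which(avail & d <= threshold_frac * gmin)
    if (!length(pool)) break
    i <- pool[which.min(d[pool])]
    lats <- c(lats, tmid[i])
    avail[tmid >= tmid[i] - blanking & tmid <= tmid[i] + blanking] <- FALSE
  }
  sort(lats)
}
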