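#' LAT-noise robustness benchmark
#'
#' Monte-Carlo comparison of directed-graph (DG) mapping and phase
#' mapping under LAT annotation noise: a periodic activation field is cut
#' into frames, each frame is perturbed many times with Gaussian (or
#' centred lognormal) LAT noise, both methods are run on every replicate,
#' and each run is classified as correct (exactly one core within the
#' correctness radius of the true core) or as one of three error types:
#' a false core in addition to the correct one (type 1), only false
#' cores (type 2), or no core at all (type 3). Because replicates within
#' a frame are correlated, confidence intervals use a cluster-robust
#' sandwich standard error with frames as clusters.
#'
#' @name benchmark
NULL

#' Benchmark design
#'
#' @param sigmas noise standard deviations, ms.
#' @param n_frames number of activation frames (study design: 25).
#' @param n_replicates noisy replicates per frame (desk default 40; the
#'   full design uses 1000).
#' @param frame_separation frame spacing, ms (study design: 520).
#' @param correctness_radius classification radius, mm (10 = 1 cm).
#' @param distribution noise distribution.
#' @param master_seed integer; replicate r of frame f draws its own
#'   sub-seed from this, so the whole design is reproducible.
#' @export
benchmark_design <- function(sigmas = c(0, 5, 10, 15, 20, 25, 30),
                             n_frames = 25, n_replicates = 40,
                             frame_separation = 520,
                             correctness_radius = 10,
                             distribution = c("gaussian", "lognormal"),
                             master_seed = 1) {
  distribution <- match.arg(distribution)
  stopifnot(n_frames >= 1, n_replicates >= 1, correctness_radius > 0,
            all(sigmas >= 0))
  structure(list(sigmas = sigmas, n_frames = n_frames,
                 n_replicates = n_replicates,
                 frame_separation = frame_separation,
                 correctness_radius = correctness_radius,
                 distribution = distribution, master_seed = master_seed),
            class = "benchmark_design")
}

#' Classify a DG-mapping outcome
#'
#' With the dominant-core rule (default) only the core with the most
#' cycles is considered and its median cycle center is compared to the
#' truth; without it, all bundle centers enter the classification (extra
#' cores then produce type-1 errors).
#'
#' @param cores list of `reentry_core`.
#' @param true_core true core coordinates, mm.
#' @param radius correctness radius, mm.
#' @param dominant apply the dominant-core rule.
#' @return one of `"correct"`, `"error1"`, `"error2"`, `"error3"`.
#' @export
classify_dg_outcome <- function(cores, true_core, radius = 10,
                                dominant = TRUE) {
  stopifnot(radius > 0)
  if (!length(cores)) return("error3")
  centers <- if (dominant) {
    matrix(dominant_core(cores)$center_median, nrow = 1)
  } else {
    do.call(rbind, lapply(cores, `[[`, "center_median"))
  }
  classify_outcome(centers, true_core, radius)
}

# one DG run on a noisy frame: returns list(outcome, n_det, dmin)
dg_run <- function(eset, relation, lats, true_core, radius, bounds,
                   delta_t, core_threshold, cycle_length) {
  t_run <- min(vapply(lats, function(v) if (length(v)) v[1] else Inf,
                      1.0)) - 1e-6
  net <- build_merged_graph(eset, relation, lats, t_run, delta_t, bounds)
  cycles <- find_all_smallest_cycles(net)
  if (!length(cycles))
    return(list(outcome = "error3", n_det = 0L, dmin = NA_real_))
  cores <- bundle_cycles(cycles, core_threshold)
  dom <- dominant_core(cores)
  tc <- as.numeric(true_core)
  if (length(tc) == 2) tc <- c(tc, 0)
  dmin <- vec_norm(dom$center_median - tc)
  list(outcome = classify_outcome(matrix(dom$center_median, nrow = 1),
                                  tc, radius),
       n_det = 1L, dmin = dmin)
}

pm_run <- function(field, true_core, radius, kernel, threshold_fraction) {
  t_run <- min(vapply(field$lats, function(v) if (length(v)) v[1] else Inf,
                      1.0)) - 1e-6
  fr <- lat_to_phase(field, t_run)
  det <- detect_singularities(fr, kernel, threshold_fraction)
  tc <- as.numeric(true_core)
  if (length(tc) == 2) tc <- c(tc, 0)
  if (!nrow(det))
    return(list(outcome = "error3", n_det = 0L, dmin = NA_real_))
  d <- sqrt((det$x - tc[1])^2 + (det$y - tc[2])^2)
  list(outcome = classify_outcome(as.matrix(det[, c("x", "y")]), tc,
                                  radius),
       n_det = nrow(det), dmin = min(d))
}

#' Run the LAT-noise robustness study
#'
#' @param field a periodic `activation_field` with known truth (e.g. a
#'   rotor from [make_rotor_field()]), long enough for the frame design.
#' @param design a [benchmark_design()].
#' @param methods subset of `c("dg", "pm")`.
#' @param bounds conduction-velocity bounds for DG mapping.
#' @param delta_t dual-window offset, ms.
#' @param core_threshold cycle-bundling threshold, mm.
#' @param kernel,threshold_fraction phase-mapping detector settings.
#' @return a `benchmark_result` data frame with one row per
#'   method x sigma: accuracy and error-type proportions plus the 95%
#'   cluster-robust CI half-width. Per-run records (for
#'   [accuracy_vs_radius()]) are kept in `attr(, "runs")`.
#' @export
run_noise_study <- function(field, design = benchmark_design(),
                            methods = c("dg", "pm"),
                            bounds = cv_preset("ventricular"),
                            delta_t = 40, core_threshold = 10,
                            kernel = "sobel", threshold_fraction = 0.95) {
  methods <- match.arg(methods, c("dg", "pm"), several.ok = TRUE)
  stopifnot(inherits(field, "activation_field"), !is.null(field$truth))
  frames <- extract_frames(field, design$n_frames, design$frame_separation)
  eset <- as_electrode_set(field)
  relation <- neighbors_regular(eset)
  true_core <- field$truth$core[1, ]
  radius <- design$correctness_radius
  recs <- vector("list",
                 length(design$sigmas) * design$n_frames *
                   design$n_replicates * length(methods))
  k <- 0L
  for (si in seq_along(design$sigmas)) {
    sigma <- design$sigmas[si]
    for (f in seq_len(design$n_frames)) {
      for (r in seq_len(design$n_replicates)) {
        seed <- derive_seed(design$master_seed, f, r, si)
        noisy <- add_lat_noise(frames[[f]], sigma, design$distribution,
                               seed)
        for (m in methods) {
          run <- if (m == "dg")
            dg_run(eset, relation, noisy$lats, true_core, radius, bounds,
                   delta_t, core_threshold, field$cycle_length)
          else
            pm_run(noisy, true_core, radius, kernel, threshold_fraction)
          k <- k + 1L
          recs[[k]] <- data.frame(method = m, sigma = sigma, frame = f,
                                  rep = r, outcome = run$outcome,
                                  n_det = run$n_det, dmin = run$dmin)
        }
      }
    }
  }
  runs <- do.call(rbind, recs)
  agg <- do.call(rbind, lapply(split(runs, list(runs$method, runs$sigma),
                                     drop = TRUE), function(d) {
    ci <- proportion_ci(d$outcome == "correct", d$frame)
    data.frame(method = d$method[1], sigma = d$sigma[1], n = nrow(d),
               accuracy = mean(d$outcome == "correct"),
               err1 = mean(d$outcome == "error1"),
               err2 = mean(d$outcome == "error2"),
               err3 = mean(d$outcome == "error3"),
               ci_halfwidth = ci$half_width)
  }))
  agg <- agg[order(agg$method, agg$sigma), ]
  rownames(agg) <- NULL
  structure(agg, class = c("benchmark_result", "data.frame"),
            runs = runs, design = design)
}

#' Cluster-robust proportion confidence interval
#'
#' Overall proportion with a sandwich standard error that respects the
#' correlation of replicates within a frame: with clusters f holding
#' n_f outcomes summing to S_f,
#' `SE^2 = G/(G-1) * sum_f (S_f - n_f*p)^2 / N^2`. The returned
#' half-width is `1.96 * SE`.
#'
#' @param outcomes logical (or 0/1) vector of per-run successes.
#' @param clusters cluster label per outcome (the frame index).
#' @return list with `p`, `se`, `half_width`.
#' @export
proportion_ci <- function(outcomes, clusters) {
  y <- as.numeric(outcomes)
  stopifnot(length(y) == length(clusters))
  G <- length(unique(clusters))
  if (G < 2) stop("cluster-robust SE needs at least 2 clusters")
  N <- length(y)
  p <- mean(y)
  S <- tapply(y, clusters, sum)
  n_f <- tapply(y, clusters, length)
  se2 <- G / (G - 1) * sum((S - n_f * p)^2) / N^2
  list(p = p, se = sqrt(se2), half_width = 1.96 * sqrt(se2))
}

#' Specificity study on a target-wave field
#'
#' Runs DG mapping on noisy replicates of a centrifugal point-source
#' field (no reentry present) and reports the proportion of runs in
#' which at least one rotational core was (falsely) detected. The
#' single-window excitation graph is acyclic by construction and the
#' dual-window merge only adds edges from nodes that have not re-fired,
#' so on purely centrifugal activation no directed cycle should ever
#' arise.
#'
#' @param design a [benchmark_design()].
#' @param field target-wave field; default: 16 x 16 grid at 5 mm with a
#'   central source, 500 ms period.
#' @inheritParams run_noise_study
#' @return false-positive proportion (0 = perfect specificity), with a
#'   per-sigma breakdown in `attr(, "per_sigma")`.
#' @export
run_specificity_study <- function(design = benchmark_design(
                                    n_replicates = 10),
                                  field = NULL,
                                  bounds = cv_preset("ventricular"),
                                  delta_t = 40) {
  if (is.null(field)) {
    pos <- grid_positions(c(16, 16), 5)
    n_beats <- ceiling(((design$n_frames - 1) * design$frame_separation +
                          2 * 500) / 500) + 1
    field <- make_target_wave_field(pos, c(max(pos[, 1]) / 2,
                                           max(pos[, 2]) / 2, 0),
                                    conduction_velocity = 0.5,
                                    period = 500, n_beats = n_beats)
  }
  frames <- extract_frames(field, design$n_frames, design$frame_separation)
  eset <- as_electrode_set(field)
  relation <- neighbors_regular(eset)
  fp <- matrix(0, nrow = length(design$sigmas),
               ncol = design$n_frames * design$n_replicates)
  for (si in seq_along(design$sigmas)) {
    k <- 0
    for (f in seq_len(design$n_frames)) {
      for (r in seq_len(design$n_replicates)) {
        seed <- derive_seed(design$master_seed, f, r, si)
        noisy <- add_lat_noise(frames[[f]], design$sigmas[si],
                               design$distribution, seed)
        t_run <- min(vapply(noisy$lats, function(v)
          if (length(v)) v[1] else Inf, 1.0)) - 1e-6
        net <- build_merged_graph(eset, relation, noisy$lats, t_run,
                                  delta_t, bounds)
        k <- k + 1
        fp[si, k] <- as.numeric(has_cycles(net))
      }
    }
  }
  out <- mean(fp)
  attr(out, "per_sigma") <- data.frame(sigma = design$sigmas,
                                       fp_rate = rowMeans(fp))
  out
}

#' Accuracy as a function of the correctness radius
#'
#' Re-classifies the stored per-run records of a [run_noise_study()]
#' result at each radius: a run is correct at radius r iff it produced
#' exactly one detection and that detection lies within r of the true
#' core. Accuracy is non-decreasing in r by construction.
#'
#' @param result a `benchmark_result`.
#' @param radii radii to evaluate, mm.
#' @return data frame: method, sigma, radius, accuracy.
#' @export
accuracy_vs_radius <- function(result, radii) {
  runs <- attr(result, "runs")
  stopifnot(!is.null(runs), all(radii >= 0))
  out <- do.call(rbind, lapply(split(runs, list(runs$method, runs$sigma),
                                     drop = TRUE), function(d) {
    data.frame(method = d$method[1], sigma = d$sigma[1], radius = radii,
               accuracy = vapply(radii, function(r)
                 mean(d$n_det == 1 & !is.na(d$dmin) & d$dmin <= r), 1.0))
  }))
  rownames(out) <- NULL
  out
}
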