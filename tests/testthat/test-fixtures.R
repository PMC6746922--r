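test_that("rotor field is exactly periodic and phase-symmetric", {
  f <- make_rotor_field(c(8, 8), spacing = 10, cycle_length = 200,
                        n_cycles = 4)
  for (v in f$lats) expect_equal(diff(v), rep(200, 3))
  # electrodes symmetric about the core differ by CL/2 within one cycle
  core <- f$truth$core[1, 1:2]  # (35, 35): between grid nodes
  i <- which(f$positions[, 1] == 30 & f$positions[, 2] == 30)
  j <- which(f$positions[, 1] == 40 & f$positions[, 2] == 40)
  d <- (f$lats[[i]][1] - f$lats[[j]][1]) %% 200
  expect_equal(min(d, 200 - d), 100)
})

test_that("rotor LAT phase winds once about the core and not elsewhere", {
  f <- make_rotor_field(c(16, 16), spacing = 8, cycle_length = 260,
                        n_cycles = 2)
  fr <- lat_to_phase(f, t = -1e-6)
  q <- phase_charge(fr)
  expect_equal(abs(sum(q)), 1)           # one singularity in total
  # charge concentrated at the core plaquette, zero far away
  hot <- which(abs(q) > 0.5, arr.ind = TRUE)
  expect_equal(nrow(hot), 1)
  core <- f$truth$core[1, 1:2]
  expect_lt(abs((hot[1, 2] - 0.5) * 8 - core[1]), 8 + 1e-9)
  expect_lt(abs((hot[1, 1] - 0.5) * 8 - core[2]), 8 + 1e-9)
})

test_that("rotor core outside the footprint is rejected", {
  expect_error(make_rotor_field(c(8, 8), 10, 200, core_xy = c(-5, 10)),
               "outside")
})

test_that("focal fields place the earliest activation at the source", {
  pos <- grid_positions(c(8, 8), 10)
  src <- pos[19, , drop = FALSE]  # an electrode position
  f <- make_focal_field(pos, src, conduction_velocity = 0.5, period = 500,
                        n_beats = 3)
  first <- vapply(f$lats, `[`, 1.0, 1)
  expect_equal(as.integer(which.min(first)), 19L)
  expect_equal(unname(first[19]), 0)
  for (v in f$lats) expect_equal(diff(v), rep(500, 2))
  expect_error(make_focal_field(pos, src, conduction_velocity = 0),
               "velocity")
  expect_error(make_focal_field(pos[1:2, ], pos[1:3, ]), "sources")
})

test_that("target wave from a corner has a monotone LAT gradient", {
  pos <- grid_positions(c(8, 8), 10)
  f <- make_target_wave_field(pos, c(0, 0, 0), 0.5, 500, 2)
  first <- vapply(f$lats, `[`, 1.0, 1)
  d <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  expect_true(all(diff(first[order(d)]) >= -1e-12))
  expect_equal(f$truth$kind, "target_wave")
})

test_that("anatomical reentry excludes obstacle electrodes and rejects degenerate polygons", {
  pos <- grid_positions(c(8, 8), 10)
  th <- seq(0, 2 * pi, length.out = 13)
  poly <- cbind(35 + 12 * cos(th), 35 + 12 * sin(th))
  f <- make_anatomical_reentry_field(pos, poly, 260, 3)
  inside <- sqrt((pos[, 1] - 35)^2 + (pos[, 2] - 35)^2) < 12
  expect_equal(unname(lengths(f$lats) == 0), unname(inside))
  expect_error(make_anatomical_reentry_field(pos, poly[1:2, ], 260),
               "degenerate")
  expect_error(
    make_anatomical_reentry_field(pos, rbind(c(0, 0), c(1, 1), c(2, 2)),
                                  260), "degenerate")
})

test_that("LAT noise is centred, scaled, reproducible and truth-preserving", {
  f <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 40)
  expect_identical(add_lat_noise(f, 0), f)
  a <- add_lat_noise(f, 15, seed = 7)
  b <- add_lat_noise(f, 15, seed = 7)
  expect_identical(a, b)
  expect_identical(a$positions, f$positions)
  expect_identical(a$truth, f$truth)
  dif <- unlist(a$lats) - unlist(lapply(f$lats, sort))
  expect_equal(length(dif), 256 * 40)
  expect_lt(abs(sd(dif) - 15) / 15, 0.02)
  expect_lt(abs(mean(dif)), 0.5)
})

test_that("lognormal noise matches the requested moments and keeps its skew", {
  f <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 40)
  a <- add_lat_noise(f, 15, "lognormal", seed = 11)
  dif <- unlist(a$lats) - unlist(f$lats)
  expect_lt(abs(mean(dif)), 0.5)
  expect_lt(abs(sd(dif) - 15) / 15, 0.10)
  skew <- mean((dif - mean(dif))^3) / sd(dif)^3
  expect_gt(skew, 1)
})

test_that("frames hold disjoint LAT windows plus the following beat", {
  f <- make_rotor_field(c(8, 8), 10, 200, n_cycles = 30)
  fr <- extract_frames(f, 5, 520)
  expect_length(fr, 5)
  for (i in 1:5) {
    firsts <- vapply(fr[[i]]$lats, `[`, 1.0, 1)
    expect_true(all(firsts >= (i - 1) * 520))
    expect_true(all(lengths(fr[[i]]$lats) == 2))
  }
  # pairwise disjoint when separation > 2 CL
  sets <- lapply(fr, function(x) unlist(x$lats))
  for (i in 1:4) expect_length(intersect(sets[[i]], sets[[i + 1]]), 0)
  # one frame equals the head of the recording
  one <- extract_frames(f, 1, 520)[[1]]
  expect_equal(vapply(one$lats, `[`, 1.0, 1),
               vapply(f$lats, `[`, 1.0, 1))
  expect_error(extract_frames(f, 40, 520), "too short")
})
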