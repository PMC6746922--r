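test_that("the region of cycles of a single rotor equals its bundle's electrodes", {
  f <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 3)
  d <- dgmap(f)
  roc <- region_of_cycles(d$cores)
  expect_length(roc, 1)
  expect_setequal(roc$core1, d$cores[[1]]$member_electrodes)
})

test_that("a single rotor's region of influence covers all reachable electrodes", {
  f <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 3)
  d <- dgmap(f)
  ra <- region_of_influence(d$network, d$cores)
  g <- dgmap:::as_igraph(d$network)
  seeds <- which(d$network$nodes$id %in% d$cores[[1]]$member_electrodes)
  reach <- is.finite(apply(igraph::distances(g, v = seeds, mode = "out"),
                           2, min))
  expect_true(all(ra$core[reach] == 1))
  expect_true(all(is.na(ra$core[!reach])))
  # electrodes inside the cycle set sit at distance 0
  inside <- ra$id %in% d$cores[[1]]$member_electrodes
  expect_true(all(ra$distance[inside] == 0))
})

test_that("four rotors partition the grid into four regions of influence", {
  f <- make_multi_rotor_field(c(25, 25), 5, 260, n_cycles = 3)
  d <- dgmap(f)
  expect_length(d$cores, 4)
  ra <- region_of_influence(d$network, d$cores)
  sizes <- table(ra$core)
  expect_length(sizes, 4)
  expect_true(all(sizes > 20))
  # exhaustive & exclusive over assigned nodes
  expect_true(all(is.na(ra$core) | (ra$core >= 1 & ra$core <= 4)))
})

test_that("region-of-influence distances agree with an independent all-pairs computation", {
  f <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  d <- dgmap(f)
  net <- d$network
  D <- floyd_warshall(nrow(net$nodes),
                      as.matrix(net$edges[, c("src", "dst")]),
                      net$edges$dlat)
  seeds <- which(net$nodes$id %in% d$cores[[1]]$member_electrodes)
  expected <- apply(D[seeds, , drop = FALSE], 2, min)
  ra <- region_of_influence(net, d$cores, metric = "dlat")
  got <- ra$distance
  got[is.na(got)] <- Inf
  expect_equal(unname(got), unname(expected), tolerance = 1e-9)
  # triangle inequality on the independent matrix
  n <- nrow(net$nodes)
  for (k in seq_len(10)) {
    ijk <- sample(n, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("wave averaging of a planar wave is parallel to propagation", {
  pos <- grid_positions(c(8, 8), 10)
  # plane wave travelling along +x at 0.5 mm/ms
  lats <- lapply(pos[, 1] / 0.5, function(l) l + c(0, 500))
  f <- activation_field(seq_len(64), pos, lats, 500)
  rel <- neighbors_regular(f)
  net <- build_merged_graph(f, rel, t = -1e-6, delta_t = 40)
  flow <- wave_average(net, radius = 10)
  # two rows of margin: boundary rows lack symmetric diagonal arrows and
  # also feed the averaging window of the first interior row
  interior <- flow$x >= 10 & flow$x <= 60 & flow$y >= 20 & flow$y <= 50
  act <- interior & flow$magnitude > 0
  expect_gt(sum(act), 15)
  ang <- abs(atan2(flow$vy[act], flow$vx[act])) * 180 / pi
  expect_true(all(ang <= 5))
})

test_that("wave averaging around a rotor circulates consistently", {
  f <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 3)
  d <- dgmap(f)
  flow <- wave_average(d$network, radius = 10)
  core <- f$truth$core[1, 1:2]
  rx <- flow$x - core[1]; ry <- flow$y - core[2]
  rr <- sqrt(rx^2 + ry^2)
  ann <- which(rr > 20 & rr < 50 & flow$magnitude > 0)
  tang <- (-ry[ann] * flow$vx[ann] + rx[ann] * flow$vy[ann]) / rr[ann]
  # counter-clockwise rotor: tangential component has one dominant sign
  expect_gt(mean(sign(tang) == sign(median(tang))), 0.9)
})

test_that("an isolated arrow averages to itself", {
  net <- mock_network(cbind(1, 2), rbind(c(0, 0), c(5, 0), c(100, 100)))
  flow <- wave_average(net, radius = 3)
  expect_equal(c(flow$vx[1], flow$vy[1]), c(1, 0))
  expect_equal(flow$magnitude[1], 5)
  expect_equal(flow$magnitude[3], 0)  # far node: zero vector
})

test_that("wave averaging commutes with rigid rotation", {
  f <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  rel <- neighbors_regular(f)
  net <- build_merged_graph(f, rel, t = -1e-6, delta_t = 40)
  flow <- wave_average(net, radius = 12)
  th <- pi / 5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g <- activation_field(f$ids, f$positions %*% t(R), f$lats,
                        f$cycle_length)
  relg <- neighbors_regular(g)
  netg <- build_merged_graph(g, relg, t = -1e-6, delta_t = 40)
  flowg <- wave_average(netg, radius = 12)
  v <- as.matrix(flow[, c("vx", "vy", "vz")]) %*% t(R)
  expect_equal(unname(as.matrix(flowg[, c("vx", "vy", "vz")])),
               unname(v), tolerance = 1e-9)
})

test_that("mesh projection preserves directions on a coplanar mesh", {
  net <- mock_network(cbind(1, 2), rbind(c(2, 2), c(6, 2), c(50, 50)))
  mesh <- list(vertices = rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                                c(0, 10, 0), c(60, 60, 0), c(40, 60, 0),
                                c(60, 40, 0)),
               faces = rbind(c(1, 2, 3), c(1, 3, 4), c(5, 6, 7)))
  proj <- wave_average(net, radius = 3, mesh = mesh)
  # the projected quarter-segments of the 1 -> 2 arrow stay in-plane and
  # keep its +x direction; the far node sees no nearby arrows
  expect_equal(c(proj$vx[1], proj$vy[1], proj$vz[1]), c(1, 0, 0),
               tolerance = 1e-9)
  expect_equal(proj$magnitude[3], 0)
  # subdivided segments are each a quarter of the 4 mm arrow
  expect_equal(proj$magnitude[1], 1, tolerance = 1e-9)
})
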