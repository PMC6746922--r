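two_electrode_net <- function(lats, d = 4, bounds = cv_bounds(0.08, 2)) {
  set <- electrode_set(c("a", "b"), rbind(c(0, 0, 0), c(d, 0, 0)))
  rel <- neighbors_regular(set, radius = d + 1)
  build_single_graph(set, rel, list(a = lats[[1]], b = lats[[2]]),
                     t = -1, bounds = bounds)
}

test_that("first_lats_after is strictly greater than t", {
  lm <- list(a = c(100, 300), b = c(50))
  expect_equal(unname(first_lats_after(lm, 150)["a"]), 300)
  expect_equal(unname(first_lats_after(lm, 100)["a"]), 300)
  L <- first_lats_after(lm, 400)
  expect_true(all(is.na(L)))
  expect_setequal(attr(L, "missing"), c("a", "b"))
})

test_that("edges obey the conduction-velocity rule strictly", {
  # d = 4 mm, dLAT = 10 ms -> 0.4 mm/ms inside (0.08, 2): edge exists
  net <- two_electrode_net(list(0, 10))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$speed, 0.4)
  expect_equal(net$nodes$id[net$edges$src], "a")
  # dLAT = 1 ms -> 4 mm/ms > cv_max: no edge
  expect_equal(nrow(two_electrode_net(list(0, 1))$edges), 0)
  # dLAT = 0: no edge either direction
  expect_equal(nrow(two_electrode_net(list(5, 5))$edges), 0)
  # boundary speeds are excluded (strict inequalities)
  expect_equal(nrow(two_electrode_net(list(0, 2))$edges), 0)  # 2.0 mm/ms
  expect_equal(nrow(two_electrode_net(list(0, 50))$edges), 0) # 0.08 mm/ms
})

test_that("the single-window graph is a DAG on every fixture", {
  rotor <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  focal <- make_focal_field(grid_positions(c(8, 8), 10),
                            rbind(c(10, 10, 0), c(60, 60, 0)), 0.5, 500, 2)
  for (f in list(rotor, focal)) {
    rel <- neighbors_regular(f)
    net <- build_single_graph(f, rel, t = min(unlist(f$lats)) - 1e-6)
    expect_false(has_cycles(net))
    expect_true(all(net$nodes$lat[net$edges$dst] >
                      net$nodes$lat[net$edges$src]))
  }
})

test_that("the dual-window merge closes rotor cycles but leaves target waves acyclic", {
  rotor <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 3)
  rel <- neighbors_regular(rotor)
  t0 <- min(unlist(rotor$lats)) - 1e-6
  single <- build_single_graph(rotor, rel, t = t0)
  merged <- build_merged_graph(rotor, rel, t = t0, delta_t = 40)
  expect_false(has_cycles(single))
  expect_true(has_cycles(merged))

  tw <- make_target_wave_field(grid_positions(c(16, 16), 8), c(60, 60, 0),
                               0.5, 500, 3)
  relt <- neighbors_regular(tw)
  for (dt in c(10, 40, 100, 200)) {
    m <- build_merged_graph(tw, relt, t = -1e-6, delta_t = dt)
    expect_false(has_cycles(m))
  }
})

test_that("delta_t = 0 reproduces the single-window graph", {
  f <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  rel <- neighbors_regular(f)
  t0 <- min(unlist(f$lats)) - 1e-6
  a <- build_single_graph(f, rel, t = t0)
  b <- build_merged_graph(f, rel, t = t0, delta_t = 0)
  expect_equal(a$edges[, c("src", "dst")], b$edges[, c("src", "dst")])
})

test_that("a common rescaling of LATs and CV bounds leaves the edge set unchanged", {
  f <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  rel <- neighbors_regular(f)
  t0 <- min(unlist(f$lats)) - 1e-6
  a <- build_merged_graph(f, rel, t = t0, delta_t = 40,
                          bounds = cv_preset("ventricular"))
  lats2 <- lapply(f$lats, `*`, 2)
  b <- build_merged_graph(as_set <- electrode_set(f$ids, f$positions), rel,
                          lats2, t = 2 * t0, delta_t = 80,
                          bounds = cv_bounds(0.1, 1.0))
  expect_equal(a$edges[, c("src", "dst")], b$edges[, c("src", "dst")])
})

test_that("without node collapse every merged edge satisfies the CV rule on its stored LATs", {
  f <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 3)
  rel <- neighbors_regular(f)
  net <- build_merged_graph(f, rel, t = min(unlist(f$lats)) - 1e-6,
                            delta_t = 40, collapse = FALSE)
  dlat <- net$nodes$lat[net$edges$dst] - net$nodes$lat[net$edges$src]
  speed <- net$edges$dist / dlat
  expect_true(all(dlat > 0))
  expect_true(all(speed > net$bounds$cv_min & speed < net$bounds$cv_max))
  # re-fired electrodes appear as distinct (electrode, LAT) nodes
  expect_gt(nrow(net$nodes), length(unique(net$nodes$electrode)) - 1)
})

test_that("a delta_t of half the cycle length or more triggers a warning", {
  f <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  rel <- neighbors_regular(f)
  expect_warning(build_merged_graph(f, rel, t = -1e-6, delta_t = 130),
                 "cycle_length/2")
})

test_that("networks round-trip through the edge-list CSV", {
  f <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  rel <- neighbors_regular(f)
  net <- build_merged_graph(f, rel, t = -1e-6, delta_t = 40)
  path <- tempfile(fileext = ".csv")
  write_network_csv(net, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(net$edges))
  expect_equal(sort(unique(as.character(c(df$src_id, df$dst_id)))),
               sort(unique(net$nodes$id[c(net$edges$src, net$edges$dst)])))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$delta_t, 40)
  unlink(c(path, paste0(path, ".json")))
})
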