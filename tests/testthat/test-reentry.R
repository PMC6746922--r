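test_that("every node of a directed ring returns the full ring as its smallest cycle", {
  ring <- mock_network(cbind(1:4, c(2, 3, 4, 1)),
                       rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  for (v in 1:4) {
    cy <- smallest_cycle_through(ring, v)
    expect_equal(cy$length_edges, 4)
    expect_setequal(cy$nodes, 1:4)
    expect_equal(cy$nodes[1], v)
  }
  expect_length(find_all_smallest_cycles(ring), 1)  # dedup by node set
})

test_that("acyclic networks yield no cycles", {
  dag <- mock_network(cbind(c(1, 1, 2, 3), c(2, 3, 4, 4)),
                      cbind(runif(4), runif(4)))
  for (v in 1:4) expect_null(smallest_cycle_through(dag, v))
  expect_length(find_all_smallest_cycles(dag), 0)
})

test_that("BFS smallest cycles match exhaustive enumeration on random sparse digraphs", {
  set.seed(123)
  for (k in 1:30) {
    n <- sample(8:30, 1)
    edges <- random_sparse_digraph(n, round(1.4 * n))
    if (!nrow(edges)) next
    net <- mock_network(edges, cbind(runif(n, 0, 50), runif(n, 0, 50)))
    oracle <- oracle_smallest_through(n, enumerate_simple_cycles(n, edges))
    for (v in seq_len(n)) {
      cy <- smallest_cycle_through(net, v)
      if (is.na(oracle[v])) expect_null(cy)
      else expect_equal(cy$length_edges, oracle[v])
    }
  }
})

test_that("two disjoint rings give exactly two deduplicated cycles", {
  edges <- rbind(cbind(1:3, c(2, 3, 1)), cbind(4:6, c(5, 6, 4)))
  net <- mock_network(edges, cbind(c(0, 1, 0.5, 10, 11, 10.5),
                                   c(0, 0, 1, 0, 0, 1)))
  cyc <- find_all_smallest_cycles(net)
  expect_length(cyc, 2)
})

test_that("cycle bundling groups by center proximity and merges shared nodes", {
  ringat <- function(cx, cy, off) {
    list(edges = cbind(off + 1:4, off + c(2, 3, 4, 1)),
         pos = cbind(cx + c(-1, 1, 1, -1), cy + c(-1, -1, 1, 1)))
  }
  a <- ringat(0, 0, 0); b <- ringat(2, 0, 4); c <- ringat(40, 0, 8)
  net <- mock_network(rbind(a$edges, b$edges, c$edges),
                      rbind(a$pos, b$pos, c$pos))
  cyc <- find_all_smallest_cycles(net)
  expect_length(cyc, 3)
  cores <- bundle_cycles(cyc, proximity_threshold = 10)
  expect_length(cores, 2)  # a+b within 10 mm, c far away
  expect_setequal(vapply(cores, `[[`, 1L, "n_cycles"), c(2L, 1L))
  # tighter threshold separates a and b
  expect_length(bundle_cycles(cyc, proximity_threshold = 1.5,
                              merge_shared_nodes = FALSE), 3)
})

test_that("shared-node merging joins bundles with distant centers", {
  # two 4-cycles sharing an edge, centers ~20 mm apart
  e <- rbind(cbind(c(1, 2, 3, 4), c(2, 3, 4, 1)),
             cbind(c(2, 5, 6, 3), c(5, 6, 3, 2)))
  pos <- rbind(c(0, 0), c(0, 20), c(20, 20), c(20, 0),
               c(0, 60), c(40, 60))
  net <- mock_network(e, pos)
  cyc <- find_all_smallest_cycles(net)
  with_merge <- bundle_cycles(cyc, proximity_threshold = 10)
  without <- bundle_cycles(cyc, proximity_threshold = 10,
                           merge_shared_nodes = FALSE)
  expect_lt(length(with_merge), length(without) + 1)
  expect_length(with_merge, 1)
})

test_that("dominant core selection follows cycle count with deterministic ties", {
  f <- make_rotor_field(c(16, 16), 8, 260, n_cycles = 3)
  d <- dgmap(f, compute_features = FALSE)
  cores <- d$cores
  expect_identical(dominant_core(cores), cores[[
    which.max(vapply(cores, `[[`, 1L, "n_cycles"))]])
  expect_identical(dominant_core(cores[1]), cores[[1]])
  expect_error(dominant_core(list()), "no cores")
  # tie on n_cycles: repeated calls agree
  two <- list(cores[[1]], cores[[1]])
  expect_identical(dominant_core(two), dominant_core(two))
})

test_that("noiseless rotors are localized within one grid spacing at both scales", {
  for (cfg in list(list(g = c(8, 8), s = 16), list(g = c(16, 16), s = 8))) {
    f <- make_rotor_field(cfg$g, cfg$s, 260, n_cycles = 3)
    d <- dgmap(f, compute_features = FALSE)
    expect_equal(d$mechanism, "reentry")
    expect_length(d$cores, 1)
    err <- sqrt(sum((dominant_core(d$cores)$center_median -
                       c(f$truth$core[1, 1:2], 0))^2))
    expect_lt(err, cfg$s)
  }
})

test_that("the smallest anatomical-reentry cycle winds once around the obstacle", {
  pos <- grid_positions(c(8, 8), 10)
  th <- seq(0, 2 * pi, length.out = 13)
  poly <- cbind(35 + 12 * cos(th), 35 + 12 * sin(th))
  f <- make_anatomical_reentry_field(pos, poly, 260, 3)
  rel <- neighbors_regular(electrode_set(f$ids, f$positions), radius = 15)
  net <- build_merged_graph(f, rel, t = min(unlist(f$lats)) - 1e-6,
                            delta_t = 40)
  cyc <- find_all_smallest_cycles(net)
  expect_gt(length(cyc), 0)
  smallest <- cyc[[which.min(vapply(cyc, `[[`, 1L, "length_edges"))]]
  nd <- net$nodes[smallest$nodes, ]
  expect_equal(abs(winding_number(cbind(nd$x, nd$y), c(35, 35))), 1)
})

test_that("core centers are invariant under electrode relabeling", {
  f <- make_rotor_field(c(8, 8), 16, 260, n_cycles = 3)
  set.seed(9)
  perm <- sample(length(f$ids))
  g <- activation_field(paste0("e", seq_along(perm)),
                        f$positions[perm, ], f$lats[perm],
                        f$cycle_length, f$truth)
  c1 <- dominant_core(dgmap(f, compute_features = FALSE)$cores)
  c2 <- dominant_core(dgmap(g, compute_features = FALSE)$cores)
  expect_equal(c1$center, c2$center, tolerance = 1e-9)
  expect_equal(c1$n_cycles, c2$n_cycles)
})
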