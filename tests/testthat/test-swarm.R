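# Position decoding, regulation, velocity updates, and the full optimizer.

test_that("positions decode to nearest-centroid partitions with low-index ties", {
  g <- two_edge_graph()
  pos <- c(0.5, 0.5, 0, 0, 0, 0, 0.5, 0.5)
  p <- decode_position(pos, g, 2)
  expect_identical(p$labels, c(0L, 0L, 1L, 1L))
  # centroids equal to two adjacency rows pin those vertices exactly
  pos2 <- c(g$adjacency[1, ], g$adjacency[3, ])
  p2 <- decode_position(pos2, g, 2)
  expect_identical(p2$labels[1], 0L)
  expect_identical(p2$labels[3], 1L)
  # equidistant vertex goes to community 0
  p3 <- decode_position(rep(0.3, 8), g, 2)
  expect_identical(p3$labels, rep(0L, 4))
  expect_error(decode_position(rep(0.3, 7), g, 2), "length")
})

test_that("position fitness is the modularity of the decoded partition", {
  g <- two_edge_graph()
  fit <- position_fitness(c(0.5, 0.5, 0, 0, 0, 0, 0.5, 0.5), g, 2)
  expect_equal(fit$Q, 0.5)
  expect_equal(position_fitness(runif(4), g, 1)$Q, 0)
  # all-equal centroids collapse to one community
  fit3 <- position_fitness(rep(0.4, 12), g, 3)
  expect_identical(fit3$partition$effective_K, 1L)
  expect_equal(fit3$Q, 0)
})

test_that("centroid update averages member rows and keeps empty centroids", {
  g <- two_edge_graph()
  p <- partition(c(0, 0, 1, 1))
  C <- centroid_update(p, g)
  expect_equal(C[1, ], c(0.5, 0.5, 0, 0))
  expect_equal(C[2, ], c(0, 0, 0.5, 0.5))
  single <- centroid_update(partition(c(0, 1, 1, 1)), g)
  expect_equal(single[1, ], g$adjacency[1, ])
  prev <- matrix(0.9, 3, 4)
  with_empty <- centroid_update(partition(c(0, 0, 1, 1), K = 3), g, prev)
  expect_equal(with_empty[3, ], rep(0.9, 4))
})

test_that("regulation accepts the centroid candidate only on strict improvement", {
  g <- planted_benchmark(c(5, 5), seed = 11)$graph
  set.seed(1)
  for (i in 1:20) {
    pos <- runif(2 * g$n)
    reg <- regulate_particle(pos, g, 2)
    expect_gte(reg$Q, position_fitness(pos, g, 2)$Q)
  }
  # a centroid fixed point is left untouched
  p <- partition(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  fix <- as.vector(t(centroid_update(p, g)))
  reg <- regulate_particle(fix, g, 2)
  expect_false(reg$accepted)
  expect_identical(reg$position, fix)
})

test_that("inertia weight decreases linearly from wmax to wmin", {
  expect_equal(inertia_weight(0, 100), 1.0)
  expect_equal(inertia_weight(100, 100), 0.1)
  expect_equal(inertia_weight(50, 100), 0.55)
  expect_error(inertia_weight(1, 0), "positive")
})

test_that("the velocity rule matches a hand-evaluated pinned update", {
  up <- update_velocity_position(position = 0.2, velocity = 0, pbest = 0.4,
                                 gbest = 0.6, kc = 0.2, w = 0.5,
                                 r = c(0.5, 0.5, 0.5))
  expect_equal(up$velocity, 0.6)
  expect_equal(up$position, 0.8)
  # fixed point when every attractor equals the position
  still <- update_velocity_position(rep(0.3, 4), rep(0, 4), rep(0.3, 4),
                                    rep(0.3, 4), rep(0.3, 4), w = 0.7)
  expect_equal(still$velocity, rep(0, 4))
  expect_equal(still$position, rep(0.3, 4))
  # pure inertia when the acceleration coefficients vanish
  pure <- update_velocity_position(rep(0.5, 3), rep(0.2, 3), runif(3),
                                   runif(3), runif(3), w = 1,
                                   c1 = 0, c2 = 0, c3 = 0)
  expect_equal(pure$velocity, rep(0.2, 3))
  # clamps: velocity to [-1, 1], position to [0, 1]
  big <- update_velocity_position(1, 0.9, 1, 1, 1, w = 2, r = c(0, 0, 0))
  expect_lte(big$velocity, 1)
  expect_lte(big$position, 1)
})

test_that("a fixed-K run solves the two-edge toy and traces are monotone", {
  g <- two_edge_graph()
  cfg <- upso_config(npop = 20, tmax = 50, S = 2, Q0 = 11)
  for (seed in c(1, 7)) {
    res <- run_upso_fixed_k(g, 2, cfg, seed = seed)
    expect_equal(res$best_Q, 0.5, tolerance = 1e-12)
    expect_true(all(diff(res$trace) >= 0))
    expect_true(res$termination %in% c("max_iterations", "stall"))
  }
  # the ablation solves the same easy instance
  res_pso <- run_upso_fixed_k(g, 2, cfg, seed = 3, method = "pso")
  expect_equal(res_pso$best_Q, 0.5, tolerance = 1e-12)
})

test_that("runs are reproducible bit-for-bit under a fixed seed", {
  g <- planted_benchmark(c(6, 6), seed = 4)$graph
  cfg <- upso_config(npop = 20, tmax = 20, S = 2, Q0 = 11, kmin = 1, kmax = 3,
                     seed = 123)
  a <- run_upso(g, cfg)
  b <- run_upso(g, cfg)
  expect_identical(a, b)
  ap <- run_pso(g, cfg)
  bp <- run_pso(g, cfg)
  expect_identical(ap, bp)
})

test_that("the K sweep finds both triangles and reports the effective count", {
  g <- two_triangles_graph()
  oracle <- exhaustive_max_modularity(g$adjacency)  # over all 203 partitions
  cfg <- upso_config(npop = 30, tmax = 40, S = 2, Q0 = 17, kmin = 1, kmax = 6,
                     seed = 9)
  res <- run_upso(g, cfg)
  expect_equal(res$best_Q, oracle, tolerance = 1e-9)
  expect_identical(res$chosen_K, 2L)
  expect_length(res$per_K_history, 6L)
  expect_identical(names(res$per_K_history), as.character(1:6))
  # K = 1 sweep returns the trivial partition
  cfg1 <- upso_config(npop = 10, tmax = 10, S = 2, Q0 = 5, kmin = 1, kmax = 1,
                      seed = 2)
  res1 <- run_upso(g, cfg1)
  expect_equal(res1$best_Q, 0)
  expect_identical(res1$chosen_K, 1L)
})

test_that("every particle position stays inside the unit box", {
  g <- planted_benchmark(c(5, 5), seed = 21)$graph
  cfg <- upso_config(npop = 15, tmax = 15, S = 2, Q0 = 11, seed = 5)
  res <- run_upso_fixed_k(g, 3, cfg, seed = 5)
  expect_true(all(res$position >= 0 & res$position <= 1))
})

test_that("stall termination respects the configured fraction of tmax", {
  g <- two_edge_graph()
  cfg <- upso_config(npop = 10, tmax = 40, S = 2, Q0 = 5, stall_fraction = 0.3)
  res <- run_upso_fixed_k(g, 2, cfg, seed = 2)
  if (res$termination == "stall") {
    stall_limit <- ceiling(0.3 * 40)
    tail_q <- utils::tail(res$trace, stall_limit)
    expect_lte(max(tail_q) - min(tail_q), 1e-12)
    expect_lt(res$iterations, 40)
  } else {
    expect_identical(res$iterations, 40L)
  }
})

test_that("invalid sweep and K arguments are rejected", {
  g <- two_edge_graph()
  expect_error(run_upso_fixed_k(g, 0), "invalid K")
  expect_error(run_upso_fixed_k(g, 9), "invalid K")
  expect_error(upso_config(kmin = 3, kmax = 2), "kmax")
  expect_error(upso_config(npop = 200, S = 4, Q0 = 31), "configuration error")
  expect_error(run_upso(g, upso_config(npop = 10, S = 2, Q0 = 5, kmax = 9)),
               "vertex count")
})
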