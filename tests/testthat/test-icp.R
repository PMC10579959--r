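test_that("correspondence search pairs identical clouds at distance zero", {
  set.seed(3)
  pts <- matrix(rnorm(90, sd = 10), 30, 3)
  corr <- find_correspondences(pts, pts)
  expect_equal(corr$fixed_index, seq_len(30))
  expect_equal(corr$distance, rep(0, 30))
})

test_that("a 1 mm shift of a lattice produces all-1 mm correspondences", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 2), y = seq(0, 10, 2), z = c(0, 2)))
  shifted <- sweep(g, 2, c(1, 0, 0), `+`)
  corr <- find_correspondences(shifted, g)
  # oracle: exhaustive pairwise scan
  expect_equal(corr$distance, brute_nn_dist(shifted, g))
  expect_true(all(abs(corr$distance - 1) < 1e-12))
})

test_that("median-factor rejection removes gross outliers", {
  set.seed(4)
  inliers <- matrix(runif(30, 0, 10), 10, 3)
  moving <- rbind(inliers + 0.3, c(200, 200, 200))
  corr <- find_correspondences(moving, inliers, rejection_distance_factor = 3)
  expect_equal(length(corr$distance), 10L)
  expect_false(11L %in% corr$moving_index)
  # direct median computation confirms the cut
  all_d <- brute_nn_dist(moving, inliers)
  expect_true(all(corr$distance <= 3 * median(all_d)))
  expect_error(find_correspondences(moving[1:3, ], inliers),
               "do not overlap")
})

test_that("the point-to-plane solver handles the zero and pure-translation cases", {
  set.seed(5)
  p <- matrix(rnorm(60, sd = 10), 20, 3)
  nrm <- random_unit_rows(20)
  est <- solve_point_to_plane(p, p, nrm)
  expect_lt(max(abs(est$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(est$translation)), 1e-9)

  # plane shifted along its common normal: minimum-norm solve recovers the
  # shift exactly in spite of the unconstrained in-plane motion
  plane <- cbind(runif(25, -10, 10), runif(25, -10, 10), 0)
  fixed <- sweep(plane, 2, c(0, 0, 2), `+`)
  nz <- matrix(rep(c(0, 0, 1), each = 25), 25, 3)
  est <- solve_point_to_plane(plane, fixed, nz)
  expect_lt(max(abs(est$translation - c(0, 0, 2))), 1e-9)
  expect_lt(max(abs(est$rotation - diag(3))), 1e-9)
  expect_true(attr(est, "rank_deficient"))
  expect_error(solve_point_to_plane(plane, fixed, nz, strict_rank = TRUE),
               "rank-deficient")
})

test_that("the solver matches a brute-force 6-parameter minimizer (small angles)", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    p <- matrix(rnorm(3 * n, sd = 15), n, 3)
    tr <- random_rigid_transform(3, 2, seed = seed)
    q <- atrialign:::transform_points(p, tr) + matrix(rnorm(3 * n, sd = 0.2), n, 3)
    nrm <- random_unit_rows(n)
    est <- solve_point_to_plane(p, q, nrm)
    expect_lt(abs(attr(est, "cost") - brute_force_p2p(p, q, nrm)), 1e-6)
  }
})

test_that("solver validates inputs", {
  p <- matrix(rnorm(15), 5, 3)
  expect_error(solve_point_to_plane(p, p, random_unit_rows(5)), "at least 6")
  p <- matrix(rnorm(30), 10, 3)
  expect_error(solve_point_to_plane(p, p, matrix(2, 10, 3)), "unit length")
})

test_that("self-alignment converges immediately to the identity", {
  ph <- test_phantom(seed = 8, spacing = 3)
  res <- icp_point_to_plane(ph, ph, config = icp_config(init_strategy = "identity"))
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(res$transform$translation)), 1e-9)
  expect_equal(res$diagnostics$iterations_run, 1L)
  expect_true(res$diagnostics$converged)
  expect_lt(res$diagnostics$rmse[1], 1e-9)
})

test_that("a known displacement is recovered to sub-0.05 mm on a noiseless phantom", {
  ph <- test_phantom(seed = 9)
  tr <- random_rigid_transform(10, 5, seed = 21)
  moved <- apply_transform(ph, tr)
  res <- icp_point_to_plane(ph, moved, config = icp_config())
  expect_lt(max_vertex_error(ph$vertices, res$transform, tr), 0.05)
})

test_that("the iteration cap is honoured and the accepted RMSE never rises", {
  ph <- test_phantom(seed = 10)
  tr <- random_rigid_transform(15, 8, seed = 31)
  moved <- apply_transform(ph, tr)
  res <- icp_point_to_plane(ph, moved, config = icp_config(max_iterations = 3))
  expect_lte(res$diagnostics$iterations_run, 3L)
  expect_equal(length(res$diagnostics$rmse), res$diagnostics$iterations_run)
  res2 <- icp_point_to_plane(ph, moved, config = icp_config())
  expect_true(all(diff(res2$diagnostics$rmse) <= 1e-9))
  expect_true(all(res2$diagnostics$rmse >= 0))
})

test_that("registering in either direction yields mutually inverse transforms", {
  ph <- test_phantom(seed = 11)
  tr <- random_rigid_transform(12, 6, seed = 41)
  moved <- apply_transform(ph, tr)
  fwd <- icp_point_to_plane(ph, moved, config = icp_config())
  bwd <- icp_point_to_plane(moved, ph, config = icp_config())
  expect_lt(max_vertex_error(ph$vertices, fwd$transform,
                             invert_transform(bwd$transform)), 0.1)
})

test_that("capture range: recovery holds to 20 degrees / 10 mm with centroid init", {
  for (seed in 1:8) {
    ph <- test_phantom(seed = 40 + seed)
    tr <- random_rigid_transform(20, 10, seed = 50 + seed)
    moved <- apply_transform(ph, tr)
    res <- icp_point_to_plane(ph, moved, config = icp_config())
    expect_lt(max_vertex_error(ph$vertices, res$transform, tr), 0.1)
  }
})

test_that("principal-axes initialization handles frames centroid init cannot", {
  ph <- test_phantom(seed = 12)
  tr <- random_rigid_transform(70, 30, seed = 61)
  moved <- apply_transform(ph, tr)
  res <- icp_point_to_plane(ph, moved,
                            config = icp_config(init_strategy = "centroid_pca"))
  expect_lt(max_vertex_error(ph$vertices, res$transform, tr), 0.1)
})
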