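test_that("identity alignment gives zero distances and 100% below thresholds", {
  ph <- test_phantom(seed = 20, spacing = 3)
  s <- residual_distances(ph, ph)
  expect_true(all(s$per_vertex_distance == 0))
  expect_equal(s$median_mm, 0)
  expect_equal(unname(s$pct_below), c(100, 100))
})

test_that("forced order statistics: distances {1,2,3,4,6} mm", {
  eam <- labeled_surface(rbind(c(0, 0, 0)), source_modality = "EAM")
  img <- labeled_surface(cbind(c(1, 2, 3, 4, 6), 0, 0))
  s <- residual_distances(img, eam)
  expect_equal(sort(s$per_vertex_distance), c(1, 2, 3, 4, 6))
  expect_equal(s$median_mm, 3.0)
  expect_equal(unname(s$pct_below["2.5"]), 40)
  expect_equal(unname(s$pct_below["5"]), 80)
})

test_that("vertex-mode distances equal an exhaustive all-pairs scan", {
  ph <- test_phantom(seed = 21)
  tr <- random_rigid_transform(5, 3, seed = 111)
  eam <- simulate_acquisition(ph, acquisition_params(tr, noise_sd = 1, seed = 8))
  expect_lte(n_vertices(ph), 2000L)
  s <- residual_distances(ph, eam)
  retained <- ph$vertices[s$retained, , drop = FALSE]
  expect_lt(max(abs(s$per_vertex_distance - brute_nn_dist(retained, eam$vertices))),
            1e-9)
})

test_that("threshold percentages are monotone in the threshold", {
  ph <- test_phantom(seed = 22)
  tr <- random_rigid_transform(10, 5, seed = 121)
  eam <- simulate_acquisition(ph, acquisition_params(tr, noise_sd = 1.5, seed = 9))
  aligned <- apply_transform(ph, tr)  # roughly aligned, noise remains
  s <- residual_distances(aligned, eam, thresholds = c(0.5, 1, 2.5, 5, 10))
  expect_true(all(diff(s$pct_below) >= 0))
  expect_true(all(s$pct_below >= 0 & s$pct_below <= 100))
  expect_gte(s$pct_below["5"], s$pct_below["2.5"])
})

test_that("surface-mode distances never exceed vertex-mode distances", {
  sph <- latlong_sphere(radius = 15, n_lat = 14, n_lon = 28)
  set.seed(10)
  probe <- labeled_surface(17 * random_unit_rows(200))
  dv <- residual_distances(probe, sph, mode = "vertex")$per_vertex_distance
  ds <- residual_distances(probe, sph, mode = "surface")$per_vertex_distance
  expect_true(all(ds <= dv + 1e-12))
  # for points outside a convex mesh, distance to the sphere is ~ r_probe - r
  # up to the chordal sagitta of the coarse fixture triangles
  expect_lt(max(abs(ds - 2)), 0.3)
  pc <- labeled_surface(matrix(rnorm(30), 10, 3))
  expect_error(residual_distances(probe, pc, mode = "surface"), "requires EAM faces")
})

test_that("distances are invariant under a common rigid transform", {
  ph <- test_phantom(seed = 23)
  tr0 <- random_rigid_transform(8, 4, seed = 131)
  eam <- simulate_acquisition(ph, acquisition_params(tr0, noise_sd = 0.8, seed = 11))
  s0 <- residual_distances(ph, eam)
  tr <- random_rigid_transform(40, 30, seed = 141)
  s1 <- residual_distances(apply_transform(ph, tr), apply_transform(eam, tr))
  expect_lt(max(abs(s0$per_vertex_distance - s1$per_vertex_distance)), 1e-9)
})

test_that("symmetric mode pools both directions", {
  ph <- test_phantom(seed = 24, spacing = 3)
  tr <- random_rigid_transform(5, 2, seed = 151)
  eam <- simulate_acquisition(ph, acquisition_params(tr, noise_sd = 0.5,
                                                     coverage_fraction = 0.7,
                                                     seed = 12))
  aligned <- apply_transform(ph, tr)
  s_one <- residual_distances(aligned, eam)
  s_sym <- residual_distances(aligned, eam, symmetric = TRUE)
  # the forward per-vertex map is unchanged; only the summary pools
  expect_identical(s_sym$per_vertex_distance, s_one$per_vertex_distance)
  expect_false(isTRUE(all.equal(s_sym$median_mm, s_one$median_mm)))
})

test_that("distance maps export with sentinels and read back losslessly", {
  ph <- test_phantom(seed = 25, spacing = 3)
  tr <- random_rigid_transform(5, 3, seed = 161)
  eam <- simulate_acquisition(ph, acquisition_params(tr, noise_sd = 0.5, seed = 13))
  aligned <- apply_transform(ph, tr)
  s <- residual_distances(aligned, eam)
  f <- withr::local_tempfile(fileext = ".ply")
  distance_map_export(s, aligned, f)
  back <- read_surface(f)
  field <- attr(back, "scalars")$distance
  expect_equal(length(field), n_vertices(aligned))
  expect_equal(sum(field == -1), n_vertices(aligned) - length(s$retained))
  expect_lt(max(abs(field[s$retained] - s$per_vertex_distance)), 1e-6)

  wrong <- s
  wrong$retained <- wrong$retained[-1]
  expect_error(distance_map_export(wrong, aligned, f), "do not match")
})
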