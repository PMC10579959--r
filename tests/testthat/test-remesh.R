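test_that("isotropy_cv is near zero on a lattice and exact on a known multiset", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 1), y = seq(0, 10, 1)))
  lattice <- labeled_surface(cbind(g, 0))
  expect_lt(isotropy_cv(lattice), 1e-6)

  # construct a cloud whose nearest-neighbour multiset is half 1 mm, half
  # 4 mm: 20 isolated pairs 1 mm apart plus a line of 40 points 4 mm apart
  pairs <- do.call(rbind, lapply(1:20, function(i)
    rbind(c(i * 50, 0, 0), c(i * 50 + 1, 0, 0))))
  line <- cbind(seq(0, by = 4, length.out = 40), 5000, 0)
  s <- labeled_surface(rbind(pairs, line))
  d <- c(rep(1, 40), rep(4, 40))           # the constructed multiset
  expect_equal(isotropy_cv(s), sd(d) / mean(d))
  expect_equal(isotropy_cv(s), 0.6, tolerance = 0.01)

  expect_error(isotropy_cv(labeled_surface(rbind(c(0, 0, 0)))), "at least 2")
  coincident <- labeled_surface(rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_error(isotropy_cv(coincident), "degenerate")
})

test_that("a non-uniform sphere remeshes to isotropic spacing on the surface", {
  sph <- latlong_sphere(radius = 30, n_lat = 24, n_lon = 48)
  expect_gt(isotropy_cv(sph), 0.3)  # fixture really is anisotropic
  out <- isotropic_remesh(sph, remesh_config(target_spacing = 1.5), seed = 42)
  expect_lt(isotropy_cv(out), 0.25)
  r <- sqrt(rowSums(out$vertices^2))
  expect_lt(max(abs(r - 30)), 0.15)
  # vertex count ~ area / (c * spacing^2), c in [0.5, 2]
  cc <- 4 * pi * 30^2 / (n_vertices(out) * 1.5^2)
  expect_gt(cc, 0.5)
  expect_lt(cc, 2)
})

test_that("an already-isotropic surface is not degraded and the map is idempotent", {
  g <- as.matrix(expand.grid(x = seq(0, 30, 1.5), y = seq(0, 30, 1.5)))
  lattice <- labeled_surface(cbind(g, 0))
  cfg <- remesh_config(target_spacing = 1.5)
  out <- isotropic_remesh(lattice, cfg, seed = 1)
  expect_lte(isotropy_cv(out), isotropy_cv(lattice))

  sph <- latlong_sphere(radius = 30, n_lat = 24, n_lon = 48)
  once <- isotropic_remesh(sph, cfg, seed = 7)
  twice <- isotropic_remesh(once, cfg, seed = 8)
  expect_lt(abs(isotropy_cv(twice) - isotropy_cv(once)), 0.05)
})

test_that("labels survive remeshing with stable per-label fractions", {
  ph <- test_phantom(seed = 7, spacing = 1.5)
  out <- isotropic_remesh(ph, remesh_config(target_spacing = 3), seed = 3)
  expect_lt(n_vertices(out), n_vertices(ph))  # resampling actually happened
  expect_setequal(unique(out$labels), unique(ph$labels))
  f_in <- table(factor(ph$labels, levels = LA_LABELS)) / n_vertices(ph)
  f_out <- table(factor(out$labels, levels = LA_LABELS)) / n_vertices(out)
  expect_lt(max(abs(f_in - f_out)) * 100, 10)
  # independent nearest-neighbour label vote on a sample of output vertices
  idx <- seq(1, n_vertices(out), by = 11)
  vote <- vapply(idx, function(i) {
    j <- which.min(colSums((t(ph$vertices) - out$vertices[i, ])^2))
    ph$labels[j]
  }, character(1))
  expect_gt(mean(vote == out$labels[idx]), 0.9)
})

test_that("remeshing is deterministic given a seed", {
  sph <- latlong_sphere(radius = 20, n_lat = 16, n_lon = 32)
  a <- isotropic_remesh(sph, remesh_config(target_spacing = 2), seed = 5)
  b <- isotropic_remesh(sph, remesh_config(target_spacing = 2), seed = 5)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$labels, b$labels)
})
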