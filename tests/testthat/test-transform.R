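test_that("rigid transforms validate, compose and invert within tolerance", {
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
  refl <- diag(c(1, 1, -1))
  expect_error(rigid_transform(refl), "determinant")

  t1 <- rigid_transform(rotation_from_axis_angle(c(1, 2, 3), 0.4), c(1, -2, 3))
  t2 <- rigid_transform(rotation_from_axis_angle(c(-1, 0, 1), 1.1), c(0, 5, -1))
  comp <- compose_transforms(t2, t1)
  p <- matrix(rnorm(30), 10, 3)
  via_comp <- atrialign:::transform_points(p, comp)
  via_steps <- atrialign:::transform_points(atrialign:::transform_points(p, t1), t2)
  expect_lt(max(abs(via_comp - via_steps)), 1e-12)

  inv <- invert_transform(t1)
  round_trip <- compose_transforms(inv, t1)
  expect_lt(max(abs(round_trip$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(round_trip$translation)), 1e-12)
})

test_that("apply_transform is rigid and involutive for half-turns", {
  ph <- test_phantom(seed = 6, spacing = 3)
  tr <- random_rigid_transform(30, 20, seed = 3)
  moved <- apply_transform(ph, tr)
  idx <- seq(1, n_vertices(ph), by = 7)
  d0 <- dist(ph$vertices[idx, ])
  d1 <- dist(moved$vertices[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_identical(moved$labels, ph$labels)

  half <- rigid_transform(rotation_from_axis_angle(c(0, 0, 1), pi))
  twice <- apply_transform(apply_transform(ph, half), half)
  expect_lt(max(abs(twice$vertices - ph$vertices)), 1e-9)

  back <- apply_transform(moved, invert_transform(tr))
  expect_lt(max(abs(back$vertices - ph$vertices)), 1e-9)
})

test_that("homogeneous and file serializations round-trip", {
  tr <- random_rigid_transform(25, 15, seed = 9)
  m <- as_homogeneous(tr)
  expect_equal(dim(m), c(4L, 4L))
  tr2 <- transform_from_homogeneous(m)
  expect_lt(max(abs(tr2$rotation - tr$rotation)), 1e-12)

  f <- withr::local_tempfile(fileext = ".txt")
  write_transform(tr, f)
  tr3 <- read_transform(f)
  expect_lt(max(abs(tr3$rotation - tr$rotation)), 1e-12)
  expect_lt(max(abs(tr3$translation - tr$translation)), 1e-12)
})

test_that("axis-angle construction and decomposition are mutually inverse", {
  for (seed in 1:25) {
    set.seed(seed)
    ax <- rnorm(3)
    ang <- runif(1, 0.01, pi - 0.01)
    R <- rotation_from_axis_angle(ax, ang)
    aa <- rotation_to_axis_angle(R)
    expect_lt(abs(aa$angle - ang), 1e-9)
    expect_lt(min(sum((aa$axis - ax / sqrt(sum(ax^2)))^2),
                  sum((aa$axis + ax / sqrt(sum(ax^2)))^2)), 1e-16)
  }
})

test_that("random rigid transforms satisfy the invariants across many seeds", {
  for (seed in 1:1000) {
    tr <- random_rigid_transform(40, 25, seed = seed)
    expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-9)
    expect_lt(abs(det(tr$rotation) - 1), 1e-9)
    expect_lte(attr(tr, "angle_deg"), 40)
    expect_lte(attr(tr, "translation_mm"), 25)
  }
  # degenerate bounds give the exact identity
  id <- random_rigid_transform(0, 0, seed = 1)
  expect_identical(id$rotation, diag(3))
  expect_identical(id$translation, c(0, 0, 0))
})

test_that("the sampled rotation angle is recoverable to 1e-9", {
  for (seed in c(2, 17, 101)) {
    tr <- random_rigid_transform(35, 10, seed = seed)
    aa <- rotation_to_axis_angle(tr$rotation)
    expect_lt(abs(aa$angle * 180 / pi - attr(tr, "angle_deg")), 1e-9)
  }
})
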