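test_that("the phantom is deterministic and carries all anatomical labels", {
  a <- generate_phantom(test_phantom_params(seed = 26))
  b <- generate_phantom(test_phantom_params(seed = 26))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$labels, b$labels)

  census <- table(factor(a$labels, levels = LA_LABELS))
  expect_true(all(census > 0))
  expect_equal(names(which.max(census)), "BODY")
})

test_that("body vertex count matches the ellipsoid area at the sampling density", {
  p <- test_phantom_params(seed = 27, spacing = 2)
  ph <- generate_phantom(p)
  n_body <- sum(ph$labels %in% c("BODY", "MV_ANNULUS"))
  ax <- p$body_semi_axes
  area <- 4 * pi * (((ax[1] * ax[2])^1.6075 + (ax[1] * ax[3])^1.6075 +
                       (ax[2] * ax[3])^1.6075) / 3)^(1 / 1.6075)
  cc <- area / (n_body * p$target_spacing^2)
  expect_gt(cc, 0.5)
  expect_lt(cc, 2)
})

test_that("impossible geometries are rejected", {
  expect_error(phantom_params(pv_radius = 30), "impossible")
  expect_error(phantom_params(annulus_radius = 40), "cross-section")
  expect_error(phantom_params(pv_length = -1), "positive")
})

test_that("changing one tube's length leaves the body sampling untouched", {
  short <- generate_phantom(test_phantom_params(seed = 28, pv_length = 8))
  long <- generate_phantom(test_phantom_params(seed = 28, pv_length = 16))
  expect_identical(short$vertices[short$labels == "BODY", ],
                   long$vertices[long$labels == "BODY", ])
  expect_gt(sum(long$labels == "LSPV"), sum(short$labels == "LSPV"))
})

test_that("a noiseless full-coverage acquisition only transforms and unlabels", {
  ph <- test_phantom(seed = 29, spacing = 3)
  out <- simulate_acquisition(ph, acquisition_params(rigid_transform(),
                                                     noise_sd = 0, seed = 1))
  expect_identical(out$vertices, ph$vertices)
  expect_true(all(out$labels == "BODY"))
  expect_equal(out$source_modality, "EAM")
  kept <- simulate_acquisition(ph, acquisition_params(rigid_transform(),
                                                      noise_sd = 0, seed = 1),
                               keep_labels = TRUE)
  expect_identical(kept$labels, ph$labels)
})

test_that("patch dropout is contiguous and too-low coverage errors", {
  ph <- test_phantom(seed = 30)
  out <- simulate_acquisition(ph, acquisition_params(rigid_transform(),
                                                     noise_sd = 0,
                                                     coverage_fraction = 0.7,
                                                     seed = 2))
  expect_equal(n_vertices(out), ceiling(0.7 * n_vertices(ph)), tolerance = 0.02)
  # the dropped region is one contiguous patch: the dropped points are
  # exactly the vertices nearest to the patch centroid
  key <- function(m) apply(round(m, 9), 1, paste, collapse = "_")
  dropped <- ph$vertices[!(key(ph$vertices) %in% key(out$vertices)), , drop = FALSE]
  ctr <- colMeans(dropped)
  d_all <- sqrt(colSums((t(ph$vertices) - ctr)^2))
  nearest_set <- order(d_all)[seq_len(nrow(dropped))]
  overlap <- mean(key(ph$vertices[nearest_set, ]) %in% key(dropped))
  expect_gt(overlap, 0.9)
  expect_error(
    simulate_acquisition(ph, acquisition_params(rigid_transform(),
                                                coverage_fraction = 0.05,
                                                seed = 3)),
    "< 100")
})

test_that("acquisition median residual matches the Monte-Carlo noise oracle", {
  ph <- test_phantom(seed = 31)
  out <- simulate_acquisition(ph, acquisition_params(rigid_transform(),
                                                     noise_sd = 0.5, seed = 4))
  d <- nearest_dist <- brute_nn_dist(ph$vertices[seq(1, n_vertices(ph), 3), ],
                                     out$vertices)
  mc <- mc_noise_residual(ph, 0.5, n_draws = 1e5, seed = 5)
  expect_lt(abs(median(d) - mc$median_mm) / mc$median_mm, 0.15)
})

test_that("more noise never lowers the expected median residual", {
  ph <- test_phantom(seed = 32, spacing = 3)
  med_at <- function(ns) {
    mean(vapply(1:3, function(s) {
      out <- simulate_acquisition(ph, acquisition_params(rigid_transform(),
                                                         noise_sd = ns,
                                                         seed = 10 + s))
      median(brute_nn_dist(ph$vertices[seq(1, n_vertices(ph), 4), ],
                           out$vertices))
    }, numeric(1)))
  }
  meds <- vapply(c(0, 0.5, 1, 2), med_at, numeric(1))
  expect_true(all(diff(meds) >= 0))
})
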