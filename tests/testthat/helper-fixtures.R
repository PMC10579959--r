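# Shared fixtures, built in code. Test phantoms use a coarser spacing than
# the package default so the whole suite stays fast; the sampling geometry is
# otherwise identical.

test_phantom_params <- function(seed = 1L, spacing = 2.5, ...) {
  phantom_params(target_spacing = spacing, seed = seed, ...)
}

# memoise phantoms across test files (generation is deterministic)
.phantom_cache <- new.env(parent = emptyenv())
test_phantom <- function(seed = 1L, spacing = 2.5, ...) {
  key <- paste(seed, spacing, ..., sep = "_")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(
      test_phantom_params(seed = seed, spacing = spacing, ...))
  .phantom_cache[[key]]
}

# latitude/longitude triangulated sphere with deliberately anisotropic
# sampling: rings equally spaced in latitude angle, so cells shrink towards
# the poles (dense poles, sparse equator)
latlong_sphere <- function(radius = 30, n_lat = 24, n_lon = 48) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)
  inner <- lat[-c(1, length(lat))]
  verts <- rbind(c(0, 0, -radius))
  for (th in inner) {
    phi <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
    verts <- rbind(verts, cbind(radius * cos(th) * cos(phi),
                                radius * cos(th) * sin(phi),
                                radius * sin(th)))
  }
  verts <- rbind(verts, c(0, 0, radius))
  n <- nrow(verts)
  ring <- function(i) 1L + (i - 1L) * n_lon + seq_len(n_lon)
  faces <- NULL
  r1 <- ring(1)
  faces <- rbind(faces, cbind(1L, r1, c(r1[-1], r1[1])))
  for (i in seq_len(length(inner) - 1)) {
    a <- ring(i); b <- ring(i + 1)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces <- rbind(faces, cbind(a, a2, b2), cbind(a, b2, b))
  }
  rl <- ring(length(inner))
  faces <- rbind(faces, cbind(n, c(rl[-1], rl[1]), rl))
  labeled_surface(verts, faces = faces, name = "latlong_sphere")
}

# independent brute-force nearest-neighbour oracle (O(N*M), plain R)
brute_nn_dist <- function(query, ref) {
  apply(query, 1, function(p)
    sqrt(min(colSums((t(ref) - p)^2))))
}

max_vertex_error <- function(points, t_est, t_true) {
  a <- sweep(points %*% t(t_est$rotation), 2, t_est$translation, `+`)
  b <- sweep(points %*% t(t_true$rotation), 2, t_true$translation, `+`)
  max(sqrt(rowSums((a - b)^2)))
}

# exact point-to-plane cost at a rigid transform
p2p_cost_at <- function(transform, moving, fixed, normals) {
  mv <- sweep(moving %*% t(transform$rotation), 2, transform$translation, `+`)
  sum(rowSums((mv - fixed) * normals)^2)
}

# derivative-free-style oracle: generic numeric minimization of the same cost
# over the 6 pose parameters (rotation vector + translation)
brute_force_p2p <- function(moving, fixed, normals) {
  cost_fn <- function(x) {
    ang <- sqrt(sum(x[1:3]^2))
    R <- if (ang < 1e-30) diag(3) else rotation_from_axis_angle(x[1:3], ang)
    p2p_cost_at(list(rotation = R, translation = x[4:6]), moving, fixed, normals)
  }
  optim(rep(0, 6), cost_fn, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-16,
                       ndeps = rep(1e-7, 6)))$value
}

random_unit_rows <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}
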