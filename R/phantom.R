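#' Phantom geometry parameters
#'
#' Controls for the synthetic labeled left-atrium phantom: a closed
#' ellipsoidal body carrying four tubular pulmonary-vein stubs on its
#' posterior aspect, one appendage lobe, and a mitral-annulus rim band around
#' an inferior opening. Defaults are sized to an adult left atrium (body
#' semi-axes 30 x 25 x 22 mm, roughly a 45 ml chamber).
#'
#' @param body_semi_axes ellipsoid semi-axes (mm), order x (left-right),
#'   y (posterior), z (superior).
#' @param pv_radius,pv_length pulmonary-vein stub radius and length (mm).
#' @param laa_radius,laa_length appendage lobe base radius and length (mm);
#'   the lobe tapers towards its tip.
#' @param annulus_radius radius (mm) of the inferior mitral opening.
#' @param annulus_band width (mm) of the rim band labeled `MV_ANNULUS`.
#' @param target_spacing isotropic sampling spacing (mm).
#' @param seed RNG seed making the phantom fully deterministic.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(body_semi_axes = c(30, 25, 22), pv_radius = 5,
                           pv_length = 10, laa_radius = 4.5, laa_length = 15,
                           annulus_radius = 12, annulus_band = 3,
                           target_spacing = 1.5, seed = 1L) {
  p <- list(body_semi_axes = as.numeric(body_semi_axes),
            pv_radius = pv_radius, pv_length = pv_length,
            laa_radius = laa_radius, laa_length = laa_length,
            annulus_radius = annulus_radius, annulus_band = annulus_band,
            target_spacing = target_spacing, seed = as.integer(seed))
  lens <- unlist(p[c("body_semi_axes", "pv_radius", "pv_length", "laa_radius",
                     "laa_length", "annulus_radius", "annulus_band",
                     "target_spacing")])
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive and finite")
  if (length(p$body_semi_axes) != 3L) stop("`body_semi_axes` must have length 3")
  if (p$pv_radius >= min(p$body_semi_axes) / 2 ||
      p$laa_radius >= min(p$body_semi_axes) / 2)
    stop("tube radius too large for the body (geometrically impossible)")
  if (p$annulus_radius >= mean(p$body_semi_axes[1:2]))
    stop("`annulus_radius` must be smaller than the body cross-section")
  structure(p, class = "phantom_params")
}

# anchor directions (unit-sphere frame): 4 PVs posterior (+y), LAA
# anterolateral-superior
.phantom_anchors <- list(
  LSPV = c(-0.55, 0.70, 0.45),
  LIPV = c(-0.60, 0.75, -0.10),
  RSPV = c(0.55, 0.70, 0.45),
  RIPV = c(0.60, 0.75, -0.10),
  LAA  = c(-0.65, -0.35, 0.60))

# ellipsoid helpers: point on the surface along direction d, outward normal
ellipsoid_point <- function(d, ax) d / sqrt(sum((d / ax)^2))
ellipsoid_normal <- function(p, ax) unit(p / ax^2)

# Thomsen's approximation to the ellipsoid surface area
ellipsoid_area <- function(ax) {
  a <- ax[1]; b <- ax[2]; c <- ax[3]; p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Generate a synthetic labeled left-atrium phantom
#'
#' Builds the labeled point-cloud phantom described in [phantom_params()]:
#' uniform area-weighted candidates on each structure, thinned to an isotropic
#' Poisson-disk sampling at `target_spacing`, with ostia cut into the body
#' where the tubes attach and the inferior cap removed for the mitral
#' opening. Deterministic for a given `params$seed`.
#'
#' @param params a [phantom_params()].
#' @return A [labeled_surface()] point cloud (`source_modality = "SYNTHETIC"`)
#'   carrying all seven labels of [LA_LABELS].
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  ax <- params$body_semi_axes
  s <- params$target_spacing
  # geometry of the attachments
  tubes <- lapply(names(.phantom_anchors), function(nm) {
    u <- unit(.phantom_anchors[[nm]])
    p0 <- ellipsoid_point(u, ax)
    axis <- ellipsoid_normal(p0, ax)
    if (nm == "LAA")
      list(label = nm, p0 = p0, axis = axis, radius = params$laa_radius,
           length = params$laa_length, taper = 0.65)
    else
      list(label = nm, p0 = p0, axis = axis, radius = params$pv_radius,
           length = params$pv_length, taper = 0)
  })
  rmean <- mean(ax[1:2])
  z0 <- ax[3] * sqrt(max(0, 1 - (params$annulus_radius / rmean)^2))

  ## body candidates: uniform on the ellipsoid by rejection on the area factor
  a_body <- ellipsoid_area(ax)
  n_body <- ceiling(10 * a_body / s^2)
  body <- with_seed(derive_seed(params$seed, "body"), {
    pts <- matrix(NA_real_, 0, 3)
    wmax <- prod(ax) / min(ax)  # max of abc*sqrt(sum(u^2/ax^2)) over the sphere
    while (nrow(pts) < n_body) {
      m <- 2L * (n_body - nrow(pts))
      u <- matrix(rnorm(3 * m), m, 3)
      u <- u / sqrt(rowSums(u^2))
      w <- prod(ax) * sqrt(rowSums(sweep(u, 2, ax, `/`)^2))
      acc <- runif(m) < w / wmax
      pts <- rbind(pts, sweep(u[acc, , drop = FALSE], 2, ax, `*`))
    }
    pts[seq_len(n_body), , drop = FALSE]
  })
  # cut the mitral opening and the tube ostia out of the body
  keep <- body[, 3] > -z0
  for (tb in tubes) {
    rel <- sweep(body, 2, tb$p0)
    t_ax <- rel %*% tb$axis
    rad <- sqrt(pmax(rowSums(rel^2) - t_ax^2, 0))
    keep <- keep & !(rad < tb$radius + 0.25 * s & t_ax > -2 * s)
  }
  body <- body[keep, , drop = FALSE]
  body_lab <- ifelse(body[, 3] <= -z0 + params$annulus_band, "MV_ANNULUS", "BODY")

  ## tube candidates on the lateral surface, kept only outside the body
  tube_cand <- lapply(tubes, function(tb) {
    e1 <- unit(if (abs(tb$axis[1]) < 0.9) pracma_cross(tb$axis, c(1, 0, 0))
               else pracma_cross(tb$axis, c(0, 1, 0)))
    e2 <- pracma_cross(tb$axis, e1)
    area <- 2 * pi * tb$radius * tb$length
    n_cand <- ceiling(10 * area / s^2)
    pts <- with_seed(derive_seed(params$seed, paste0("tube_", tb$label)), {
      tt <- runif(n_cand, 0, tb$length)
      if (tb$taper > 0) {  # rejection towards the tapering radius profile
        acc <- runif(n_cand) < (1 - tb$taper * tt / tb$length)
        tt <- tt[acc]
      }
      phi <- runif(length(tt), 0, 2 * pi)
      r_t <- tb$radius * (1 - tb$taper * tt / tb$length)
      sweep(outer(tt, tb$axis) + r_t * (cos(phi) %o% e1 + sin(phi) %o% e2),
            2, tb$p0, `+`)
    })
    inside <- rowSums(sweep(pts, 2, ax, `/`)^2) < 1
    pts <- pts[!inside, , drop = FALSE]
    list(pts = pts, lab = rep(tb$label, nrow(pts)))
  })

  cand <- rbind(body, do.call(rbind, lapply(tube_cand, `[[`, "pts")))
  labs <- c(body_lab, unlist(lapply(tube_cand, `[[`, "lab")))
  # thin in structure order with a seeded shuffle inside each structure, so
  # changing one tube's length leaves the sampling of the others untouched
  ord <- with_seed(derive_seed(params$seed, "thin"), {
    blocks <- c(list(seq_len(nrow(body))),
                lapply(seq_along(tube_cand), function(i) {
                  off <- nrow(body) +
                    if (i > 1) sum(vapply(tube_cand[1:(i - 1)],
                                          function(x) nrow(x$pts), 0L)) else 0L
                  off + seq_len(nrow(tube_cand[[i]]$pts))
                }))
    unlist(lapply(blocks, function(b) b[sample.int(length(b))]))
  })
  keep <- .thin_points(cand, ord, s)
  labeled_surface(cand[keep, , drop = FALSE], labels = labs[keep],
                  name = sprintf("phantom_seed%d", params$seed),
                  source_modality = "SYNTHETIC")
}

# cross product (kept local; avoids pulling a package for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' EAM acquisition simulation parameters
#'
#' Models the discrepancies between an imaging anatomy and its EAM
#' counterpart: a rigid displacement into the mapping-system frame, isotropic
#' Gaussian point noise, optional spacing jitter, and contiguous-patch
#' dropout mimicking unmapped regions.
#'
#' @param true_transform the ground-truth [rigid_transform()] into the
#'   mapping frame.
#' @param noise_sd per-axis Gaussian displacement SD (mm, >= 0).
#' @param coverage_fraction fraction of points retained, in (0, 1]; dropout
#'   removes one contiguous patch, not i.i.d. vertices.
#' @param spacing_jitter extra uniform jitter as a fraction of the median
#'   point spacing (dimensionless, >= 0).
#' @param seed RNG seed.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(true_transform = rigid_transform(),
                               noise_sd = 0.5, coverage_fraction = 1,
                               spacing_jitter = 0, seed = 1L) {
  stopifnot(inherits(true_transform, "rigid_transform"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (coverage_fraction <= 0 || coverage_fraction > 1)
    stop("`coverage_fraction` must be in (0, 1]")
  if (spacing_jitter < 0) stop("`spacing_jitter` must be >= 0")
  structure(list(true_transform = true_transform, noise_sd = noise_sd,
                 coverage_fraction = coverage_fraction,
                 spacing_jitter = spacing_jitter, seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Simulate an EAM acquisition of a surface
#'
#' Applies the ground-truth transform, perturbs every point with isotropic
#' Gaussian noise (and optional spacing jitter), drops a contiguous patch to
#' the requested coverage, and strips the anatomical labels (EAM anatomies
#' are unlabeled) unless `keep_labels`.
#'
#' @param surface a [labeled_surface()].
#' @param params an [acquisition_params()].
#' @param keep_labels retain the anatomical labels on the output.
#' @return A [labeled_surface()] with `source_modality = "EAM"`.
#' @export
simulate_acquisition <- function(surface, params = acquisition_params(),
                                 keep_labels = FALSE) {
  stopifnot(inherits(surface, "labeled_surface"),
            inherits(params, "acquisition_params"))
  out <- apply_transform(surface, params$true_transform)
  n <- n_vertices(out)
  out$vertices <- with_seed(derive_seed(params$seed, "noise"), {
    v <- out$vertices
    if (params$noise_sd > 0)
      v <- v + matrix(rnorm(3 * n, sd = params$noise_sd), n, 3)
    if (params$spacing_jitter > 0) {
      j <- params$spacing_jitter * median(spacing_distribution(surface))
      v <- v + matrix(runif(3 * n, -j, j), n, 3)
    }
    v
  })
  retained <- seq_len(n)
  if (params$coverage_fraction < 1) {
    retained <- with_seed(derive_seed(params$seed, "coverage"), {
      center <- out$vertices[sample.int(n, 1L), ]
      d <- sqrt(rowSums(sweep(out$vertices, 2, center)^2))
      # drop the contiguous patch nearest a random center
      which(d >= quantile(d, 1 - params$coverage_fraction))
    })
    if (length(retained) < 100L)
      stop("coverage_fraction leaves only ", length(retained),
           " points (< 100); too sparse to register")
  }
  labeled_surface(out$vertices[retained, , drop = FALSE],
                  labels = if (keep_labels) out$labels[retained] else "BODY",
                  name = paste0(surface$name, "_eam"),
                  source_modality = "EAM")
}

#' Draw a random rigid transform
#'
#' Uniform random rotation axis, rotation angle drawn uniformly in
#' `[0, max_rotation_deg]`, translation along a uniform random direction with
#' norm uniform in `[0, max_translation_mm]`. The sampled angle (deg) and
#' translation norm (mm) are attached as attributes `"angle_deg"` and
#' `"translation_mm"`.
#'
#' @param max_rotation_deg maximum rotation angle (deg).
#' @param max_translation_mm maximum translation norm (mm).
#' @param seed RNG seed.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_rotation_deg, max_translation_mm,
                                   seed = 1L) {
  stopifnot(max_rotation_deg >= 0, max_translation_mm >= 0)
  with_seed(derive_seed(seed, "rigid"), {
    axis <- unit(rnorm(3))
    angle <- runif(1, 0, max_rotation_deg) * pi / 180
    dir <- unit(rnorm(3))
    tnorm <- runif(1, 0, max_translation_mm)
    out <- rigid_transform(rotation_from_axis_angle(axis, angle), tnorm * dir)
    attr(out, "angle_deg") <- angle * 180 / pi
    attr(out, "translation_mm") <- tnorm
    out
  })
}

#' Monte-Carlo prediction of the residual distance under the noise model
#'
#' Under a perfect alignment, the residual distance at an imaging point is the
#' distance to the nearest noisy copy of the surface points around it. This
#' simulates that model directly on the actual phantom geometry: each draw
#' picks a random vertex, displaces it and its `k` nearest neighbours by
#' isotropic Gaussian noise, and records the minimum distance. Used as the
#' independent oracle for the noise-consistency checks.
#'
#' @param surface the noiseless [labeled_surface()].
#' @param noise_sd Gaussian displacement SD per axis (mm).
#' @param n_draws Monte-Carlo draws.
#' @param k neighbours displaced around each drawn vertex (enough to contain
#'   the nearest noisy point with near certainty).
#' @param seed RNG seed.
#' @return A list with `median_mm` and `mean_mm` of the simulated residual
#'   distances.
#' @export
mc_noise_residual <- function(surface, noise_sd, n_draws = 1e5, k = 30L,
                              seed = 1L) {
  stopifnot(inherits(surface, "labeled_surface"), noise_sd >= 0)
  v <- surface$vertices
  n <- nrow(v)
  k <- min(as.integer(k), n - 1L)
  nb <- cbind(seq_len(n), .knn_brute(v, k, TRUE))
  draws <- with_seed(derive_seed(seed, "mc"), {
    out <- numeric(n_draws)
    chunk <- 10000L
    done <- 0L
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      idx <- sample.int(n, m, replace = TRUE)
      # offsets of the neighbour set relative to the drawn vertex
      nbr <- nb[idx, , drop = FALSE]
      base <- v[rep(idx, each = k + 1L), , drop = FALSE]
      pts <- v[as.vector(t(nbr)), , drop = FALSE] - base
      pts <- pts + matrix(rnorm(length(pts), sd = noise_sd), nrow(pts), 3)
      d2 <- matrix(rowSums(pts^2), nrow = m, byrow = TRUE)
      out[done + seq_len(m)] <- sqrt(apply(d2, 1, min))
      done <- done + m
    }
    out
  })
  list(median_mm = median(draws), mean_mm = mean(draws))
}
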