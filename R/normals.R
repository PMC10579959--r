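#' Estimate per-vertex unit normals
#'
#' The point-to-plane registration treats both anatomies as samples of locally
#' planar surfaces; the normals returned here define those planes on the fixed
#' (EAM) side. When the surface has faces, each vertex normal is the
#' area-weighted average of its incident face normals, oriented by the face
#' winding. For bare point clouds the normal is the smallest principal axis of
#' the `k_neighbors` nearest points, with orientation made globally consistent
#' by propagation over the k-nearest-neighbour graph and a final majority flip
#' to point away from the centroid (outward on a closed chamber).
#'
#' @param surface a [labeled_surface()].
#' @param k_neighbors number of nearest neighbours for the local plane fits
#'   (point-cloud mode). Default 12, a common robust choice.
#' @return An object of class `normal_field`: list with `normals` (n x 3 unit
#'   rows) and `k_neighbors`.
#' @export
estimate_normals <- function(surface, k_neighbors = 12L) {
  stopifnot(inherits(surface, "labeled_surface"))
  n <- n_vertices(surface)
  if (!is.null(surface$faces)) {
    normals <- face_vertex_normals(surface)
  } else {
    k_neighbors <- as.integer(k_neighbors)
    if (k_neighbors < 3L) stop("`k_neighbors` must be at least 3")
    if (n < k_neighbors)
      stop("surface has ", n, " points but k_neighbors = ", k_neighbors)
    normals <- pca_normals(surface$vertices, k_neighbors)
  }
  structure(list(normals = normals, k_neighbors = as.integer(k_neighbors)),
            class = "normal_field")
}

#' @export
print.normal_field <- function(x, ...) {
  cat("Normal field:", nrow(x$normals), "unit normals (k =", x$k_neighbors, ")\n")
  invisible(x)
}

# area-weighted average of incident face normals (winding defines orientation)
face_vertex_normals <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # length = 2 * area
  # accumulate with rowsum (fast, handles vertices missing from any face)
  acc <- matrix(0, nrow(v), 3L)
  for (c in 1:3) {
    s <- rowsum(fn, group = f[, c], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  len <- sqrt(rowSums(acc^2))
  if (any(len < 1e-12)) {
    # isolated vertices or cancelling folds: fall back to a PCA normal there
    bad <- which(len < 1e-12)
    if (nrow(v) >= 4L) {
      pn <- pca_normals(v, min(12L, nrow(v) - 1L))
      acc[bad, ] <- pn[bad, , drop = FALSE]
      len[bad] <- 1
    } else stop("cannot orient normals for degenerate mesh")
  }
  acc / len
}

# PCA plane-fit normals with BFS orientation propagation over the kNN graph
pca_normals <- function(pts, k) {
  n <- nrow(pts)
  nb <- .knn_brute(pts, k, TRUE)
  normals <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    nh <- pts[c(i, nb[i, ]), , drop = FALSE]
    ctr <- colMeans(nh)
    M <- sweep(nh, 2, ctr)
    cv <- crossprod(M)
    eg <- eigen(cv, symmetric = TRUE)
    if (eg$values[2] < 1e-12 * max(eg$values[1], 1e-300)) {
      # collinear neighbourhood: widen once, then give up
      k2 <- min(2L * k, n - 1L)
      nh <- pts[c(i, .knn_brute(pts, k2, TRUE)[i, ]), , drop = FALSE]
      M <- sweep(nh, 2, colMeans(nh))
      eg <- eigen(crossprod(M), symmetric = TRUE)
      if (eg$values[2] < 1e-12 * max(eg$values[1], 1e-300))
        stop("rank-deficient neighbourhood at point ", i,
             "; cannot fit a tangent plane")
    }
    normals[i, ] <- eg$vectors[, 3L]
  }
  orient_normals(pts, normals, nb)
}

# Sign propagation along a minimum spanning forest of the symmetrized kNN
# graph, weighted 1 - |n_i . n_j| so the sign avoids crossing sharp creases
# (tube ostia, the annulus rim) when a smooth path exists; then a global
# outward majority flip (outward on a closed chamber).
orient_normals <- function(pts, normals, nb) {
  normals <- .orient_normals_msf(pts, normals, nb)
  ctr <- colMeans(pts)
  outward <- rowSums(normals * sweep(pts, 2, ctr)) > 0
  if (mean(outward) < 0.5) normals <- -normals
  normals
}
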