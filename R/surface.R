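#' Anatomical label vocabulary
#'
#' The seven per-vertex anatomical categories a left-atrial surface can carry:
#' the atrial body, the four pulmonary veins (left/right superior/inferior),
#' the left atrial appendage and the mitral valve annulus. EAM anatomies are
#' typically unlabeled and carry `BODY` everywhere.
#'
#' @format A character vector of length 7.
#' @export
LA_LABELS <- c("BODY", "LSPV", "LIPV", "RSPV", "RIPV", "LAA", "MV_ANNULUS")

#' Construct a labeled surface anatomy
#'
#' The unit both the imaging and the mapping pipeline consume: a triangle mesh
#' or bare point cloud in millimetre coordinates with an anatomical label per
#' vertex.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces optional integer matrix, m x 3, 1-based triangle vertex
#'   indices. `NULL` for a pure point cloud.
#' @param labels character vector of per-vertex labels from [LA_LABELS], or a
#'   single label recycled to all vertices. Defaults to `"BODY"`.
#' @param name free-text identifier carried through the pipeline.
#' @param source_modality one of `"MRI"`, `"CT"`, `"EAM"`, `"SYNTHETIC"`.
#'
#' @return An object of class `labeled_surface`: a list with elements
#'   `vertices`, `faces`, `labels`, `name`, `source_modality`.
#' @examples
#' tri <- labeled_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                        faces = rbind(c(1L, 2L, 3L)))
#' n_vertices(tri)
#' @export
labeled_surface <- function(vertices, faces = NULL, labels = "BODY",
                            name = "surface",
                            source_modality = c("SYNTHETIC", "MRI", "CT", "EAM")) {
  source_modality <- match.arg(source_modality)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stop("`vertices` must be an n x 3 matrix of mm coordinates")
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  n <- nrow(vertices)
  if (n == 0L) stop("a surface must have at least one vertex")
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  if (length(labels) == 1L) labels <- rep(labels, n)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("`labels` must have one entry per vertex (", n, "), got ", length(labels))
  bad <- setdiff(unique(labels), LA_LABELS)
  if (length(bad) > 0L)
    stop("unknown label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(LA_LABELS, collapse = ", "))
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3L) stop("`faces` must be an m x 3 matrix of vertex indices")
    storage.mode(faces) <- "integer"
    dimnames(faces) <- NULL
    if (nrow(faces) > 0L) {
      if (min(faces) < 1L || max(faces) > n)
        stop("face indices out of range [1, ", n, "]")
      degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
        faces[, 2] == faces[, 3]
      if (any(degen))
        stop(sum(degen), " degenerate face(s) with repeated vertex indices")
    } else faces <- NULL
  }
  structure(
    list(vertices = vertices, faces = faces, labels = labels,
         name = as.character(name)[1], source_modality = source_modality),
    class = "labeled_surface")
}

#' @export
print.labeled_surface <- function(x, ...) {
  cat("Labeled surface anatomy \"", x$name, "\" (", x$source_modality, ")\n", sep = "")
  cat("  ", n_vertices(x), " vertices",
      if (is.null(x$faces)) " (point cloud)" else paste0(", ", nrow(x$faces), " faces"),
      "\n", sep = "")
  tab <- table(factor(x$labels, levels = LA_LABELS))
  tab <- tab[tab > 0]
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f], y [%.1f, %.1f], z [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Number of vertices of a surface
#' @param surface a [labeled_surface()].
#' @return integer vertex count.
#' @export
n_vertices <- function(surface) nrow(surface$vertices)

#' Drop vertices carrying given anatomical labels
#'
#' Removes the vertices whose label is in `labels` together with every face
#' touching them; remaining faces are reindexed. Used by the second alignment
#' stage and by the residual-distance metrics to exclude the pulmonary veins,
#' appendage and mitral annulus.
#'
#' @param surface a [labeled_surface()].
#' @param labels character vector of labels to remove.
#' @return A list with `surface` (the reduced [labeled_surface()]) and
#'   `retained` (integer indices of the kept vertices in the input).
#' @export
exclude_labels <- function(surface, labels) {
  stopifnot(inherits(surface, "labeled_surface"))
  keep <- !(surface$labels %in% labels)
  if (!any(keep))
    stop("excluding labels {", paste(labels, collapse = ", "),
         "} leaves no vertices")
  idx <- which(keep)
  new_index <- integer(n_vertices(surface))
  new_index[idx] <- seq_along(idx)
  faces <- surface$faces
  if (!is.null(faces)) {
    ok <- keep[faces[, 1]] & keep[faces[, 2]] & keep[faces[, 3]]
    faces <- faces[ok, , drop = FALSE]
    if (nrow(faces) > 0L) {
      faces <- matrix(new_index[faces], ncol = 3L)
    } else faces <- NULL
  }
  out <- labeled_surface(surface$vertices[idx, , drop = FALSE], faces = faces,
                         labels = surface$labels[idx], name = surface$name,
                         source_modality = surface$source_modality)
  list(surface = out, retained = idx)
}
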