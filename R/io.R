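# Surface I/O: PLY (ascii + binary little-endian), OBJ, STL and the plain
# `xyzl` point format (whitespace-delimited `x y z [label]` lines, mm,
# `#` comments). PLY and xyzl carry labels losslessly; OBJ and STL have no
# per-vertex attribute slot, so labels are dropped on write and every vertex
# reads back as BODY.

.surface_formats <- c("ply", "obj", "stl", "xyzl")

infer_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% .surface_formats) ext
  else stop("cannot infer surface format from extension of ", path,
            "; pass `format` explicitly (one of ",
            paste(.surface_formats, collapse = ", "), ")")
}

#' Read a surface anatomy from disk
#'
#' @param path file path.
#' @param format one of `"ply"`, `"obj"`, `"stl"`, `"xyzl"`; inferred from the
#'   file extension when omitted.
#' @param name surface name; defaults to the file name.
#' @param source_modality stored on the returned surface.
#' @return A [labeled_surface()]. Vertices missing a label default to `BODY`;
#'   pure point files have no faces. For PLY files carrying extra per-vertex
#'   scalar properties (e.g. a residual-distance map), those are attached as
#'   an attribute `"scalars"` (a named list of numeric vectors).
#' @seealso [write_surface()]
#' @export
read_surface <- function(path, format = NULL, name = basename(path),
                         source_modality = "SYNTHETIC") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% infer_format(path)
  format <- match.arg(format, .surface_formats)
  parsed <- switch(format,
    xyzl = read_xyzl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path))
  out <- labeled_surface(parsed$vertices, faces = parsed$faces,
                         labels = parsed$labels %||% "BODY",
                         name = name, source_modality = source_modality)
  if (!is.null(parsed$scalars) && length(parsed$scalars))
    attr(out, "scalars") <- parsed$scalars
  out
}

#' Write a surface anatomy to disk
#'
#' PLY and xyzl round-trip labels losslessly; STL and OBJ cannot store them
#' (every vertex reads back as `BODY`). xyzl stores no faces.
#'
#' @param surface a [labeled_surface()].
#' @param path output file path.
#' @param format one of `"ply"`, `"obj"`, `"stl"`, `"xyzl"`; inferred from the
#'   extension when omitted.
#' @param scalars optional named list of per-vertex numeric vectors written as
#'   extra PLY vertex properties (ignored for other formats).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, format = NULL, scalars = NULL) {
  if (!inherits(surface, "labeled_surface"))
    stop("`surface` must be a labeled_surface")
  if (n_vertices(surface) == 0L) stop("refusing to write an empty surface")
  format <- format %||% infer_format(path)
  format <- match.arg(format, .surface_formats)
  switch(format,
    xyzl = write_xyzl(surface, path),
    ply = write_ply(surface, path, scalars = scalars),
    obj = write_obj(surface, path),
    stl = write_stl(surface, path))
  invisible(path)
}

## ---- xyzl ------------------------------------------------------------------

read_xyzl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no data lines in ", path)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt < 3L | nt > 4L)
  if (length(bad))
    stop("malformed line ", keep[bad[1]], " in ", path,
         ": expected `x y z [label]`, got \"", lines[keep[bad[1]]], "\"")
  xyz <- matrix(NA_real_, length(toks), 3L)
  labels <- rep("BODY", length(toks))
  for (i in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[i]][1:3]))
    if (any(!is.finite(v)))
      stop("non-finite or non-numeric coordinate on line ", keep[i], " in ", path)
    xyz[i, ] <- v
    if (nt[i] == 4L) labels[i] <- toks[[i]][4L]
  }
  unknown <- setdiff(unique(labels), LA_LABELS)
  if (length(unknown))
    stop("unknown label token(s) ", paste(unknown, collapse = ", "), " in ", path,
         "; allowed tokens: ", paste(LA_LABELS, collapse = ", "))
  list(vertices = xyz, faces = NULL, labels = labels)
}

write_xyzl <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x y z label (mm)", con)
  writeLines(sprintf("%.9f %.9f %.9f %s",
                     surface$vertices[, 1], surface$vertices[, 2],
                     surface$vertices[, 3], surface$labels), con)
}

## ---- PLY -------------------------------------------------------------------

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type) {
  sz <- .ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop(path, " is not a PLY file")
  fmt <- NULL
  elements <- list()   # name -> list(count, props = list(name, type, is_list, ...))
  current <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unterminated PLY header in ", path)
    tk <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tk) == 0L || tk[1] == "comment") next
    if (tk[1] == "format") {
      fmt <- tk[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format ", fmt, " in ", path)
    } else if (tk[1] == "element") {
      current <- tk[2]
      elements[[current]] <- list(count = as.integer(tk[3]), props = list())
    } else if (tk[1] == "property") {
      if (is.null(current)) stop("PLY property before element in ", path)
      if (tk[2] == "list") {
        p <- list(name = tk[5], is_list = TRUE, count_type = tk[3], type = tk[4])
      } else {
        p <- list(name = tk[3], is_list = FALSE, type = tk[2])
      }
      elements[[current]]$props <- c(elements[[current]]$props, list(p))
    } else if (tk[1] == "end_header") break
  }
  vert_el <- elements[["vertex"]]
  if (is.null(vert_el)) stop("PLY file ", path, " has no vertex element")
  face_el <- elements[["face"]]

  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    ptr <- 0L
    take_line <- function() {
      ptr <<- ptr + 1L
      if (ptr > length(rest)) stop("unexpected end of PLY data in ", path)
      strsplit(trimws(rest[ptr]), "\\s+")[[1]]
    }
    nv <- vert_el$count
    pnames <- vapply(vert_el$props, `[[`, "", "name")
    vdata <- matrix(NA_real_, nv, length(pnames))
    for (i in seq_len(nv)) {
      tk <- suppressWarnings(as.numeric(take_line()))
      if (length(tk) != length(pnames) || any(!is.finite(tk)))
        stop("malformed PLY vertex row ", i, " in ", path)
      vdata[i, ] <- tk
    }
    faces <- NULL
    if (!is.null(face_el) && face_el$count > 0L) {
      flist <- vector("list", face_el$count)
      for (i in seq_len(face_el$count)) {
        tk <- suppressWarnings(as.integer(as.numeric(take_line())))
        if (length(tk) < 1L || tk[1] != length(tk) - 1L)
          stop("malformed PLY face row ", i, " in ", path)
        flist[[i]] <- tk[-1L]
      }
      faces <- triangulate_fans(flist)
    }
  } else {
    nv <- vert_el$count
    pnames <- vapply(vert_el$props, `[[`, "", "name")
    if (any(vapply(vert_el$props, `[[`, TRUE, "is_list")))
      stop("list-typed vertex properties are not supported (", path, ")")
    vdata <- matrix(NA_real_, nv, length(pnames))
    for (i in seq_len(nv))
      for (j in seq_along(vert_el$props))
        vdata[i, j] <- .ply_read_scalar(con, vert_el$props[[j]]$type)
    faces <- NULL
    if (!is.null(face_el) && face_el$count > 0L) {
      fp <- face_el$props[[1]]
      if (!fp$is_list) stop("PLY face element without index list in ", path)
      flist <- vector("list", face_el$count)
      for (i in seq_len(face_el$count)) {
        cnt <- .ply_read_scalar(con, fp$count_type)
        idx <- integer(cnt)
        for (m in seq_len(cnt)) idx[m] <- .ply_read_scalar(con, fp$type)
        flist[[i]] <- idx
      }
      faces <- triangulate_fans(flist)
    }
  }

  colnames(vdata) <- pnames
  need <- c("x", "y", "z")
  if (!all(need %in% pnames)) stop("PLY vertex element lacks x/y/z in ", path)
  xyz <- vdata[, need, drop = FALSE]
  labels <- NULL
  if ("label" %in% pnames) {
    code <- as.integer(vdata[, "label"])
    if (any(code < 0L | code >= length(LA_LABELS)))
      stop("PLY label codes out of range in ", path)
    labels <- LA_LABELS[code + 1L]
  }
  extra <- setdiff(pnames, c(need, "label", "nx", "ny", "nz", "red", "green", "blue", "alpha"))
  scalars <- if (length(extra)) {
    s <- lapply(extra, function(nm) as.numeric(vdata[, nm]))
    names(s) <- extra
    s
  } else NULL
  list(vertices = unname(xyz), faces = faces, labels = labels, scalars = scalars)
}

# fan-triangulate polygon index lists (0-based on disk -> 1-based here)
triangulate_fans <- function(flist) {
  tri <- lapply(flist, function(ix) {
    if (length(ix) < 3L) stop("face with fewer than 3 vertices")
    k <- length(ix)
    cbind(ix[1L], ix[2:(k - 1L)], ix[3:k])
  })
  do.call(rbind, tri) + 1L
}

write_ply <- function(surface, path, scalars = NULL) {
  nv <- n_vertices(surface)
  if (!is.null(scalars)) {
    stopifnot(is.list(scalars), !is.null(names(scalars)))
    for (s in scalars)
      if (length(s) != nv) stop("scalar field length must equal vertex count")
  }
  con <- file(path, "w")
  on.exit(close(con))
  nf <- if (is.null(surface$faces)) 0L else nrow(surface$faces)
  header <- c(
    "ply", "format ascii 1.0",
    "comment labeled LA surface, coordinates in mm",
    paste("element vertex", nv),
    "property double x", "property double y", "property double z",
    "property int label",
    if (!is.null(scalars)) paste("property double", names(scalars)),
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
  writeLines(header, con)
  code <- match(surface$labels, LA_LABELS) - 1L
  cols <- cbind(surface$vertices, code)
  if (!is.null(scalars)) cols <- cbind(cols, do.call(cbind, scalars))
  writeLines(apply(cols, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  if (nf > 0L)
    writeLines(apply(surface$faces - 1L, 1,
                     function(f) paste(c(3L, f), collapse = " ")), con)
}

## ---- OBJ -------------------------------------------------------------------

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("no vertices in OBJ file ", path)
  verts <- t(vapply(strsplit(vl, "\\s+"), function(tk) {
    v <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(!is.finite(v))) stop("non-finite vertex in OBJ file ", path)
    v
  }, numeric(3)))
  faces <- NULL
  if (length(fl)) {
    flist <- lapply(strsplit(fl, "\\s+"), function(tk) {
      ix <- as.integer(sub("/.*", "", tk[-1L]))
      if (any(is.na(ix) | ix < 0L))
        stop("unsupported OBJ face indexing in ", path)
      ix - 1L  # triangulate_fans adds the 1 back
    })
    faces <- triangulate_fans(flist)
  }
  list(vertices = verts, faces = faces, labels = NULL)
}

write_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# labeled LA surface export (labels not representable in OBJ)", con)
  writeLines(sprintf("v %.9f %.9f %.9f", surface$vertices[, 1],
                     surface$vertices[, 2], surface$vertices[, 3]), con)
  if (!is.null(surface$faces))
    writeLines(sprintf("f %d %d %d", surface$faces[, 1], surface$faces[, 2],
                       surface$faces[, 3]), con)
}

## ---- STL (ascii) -----------------------------------------------------------

read_stl <- function(path) {
  head_bytes <- readBin(path, "raw", 80L)
  is_ascii <- grepl("^\\s*solid", rawToChar(head_bytes[head_bytes != as.raw(0)]))
  if (!is_ascii) return(read_stl_binary(path))
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL file ", path)
  pts <- t(vapply(strsplit(vl, "\\s+"), function(tk) {
    v <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(!is.finite(v))) stop("non-finite vertex in STL file ", path)
    v
  }, numeric(3)))
  weld_stl(pts)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  pts <- matrix(NA_real_, ntri * 3L, 3L)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    pts[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  weld_stl(pts)
}

# STL repeats vertices per facet; weld exact duplicates to rebuild connectivity
weld_stl <- function(pts) {
  key <- apply(pts, 1, function(r) paste(sprintf("%.9g", r), collapse = "_"))
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]
  faces <- faces[!degen, , drop = FALSE]
  list(vertices = verts, faces = if (nrow(faces)) faces else NULL, labels = NULL)
}

write_stl <- function(surface, path) {
  if (is.null(surface$faces))
    stop("STL requires faces; this surface is a point cloud")
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  f <- surface$faces
  writeLines("solid atrialign", con)
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-300)
  blocks <- vapply(seq_len(nrow(f)), function(i) {
    paste(
      sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "  outer loop",
      sprintf("    vertex %.9g %.9g %.9g", v[f[i, 1], 1], v[f[i, 1], 2], v[f[i, 1], 3]),
      sprintf("    vertex %.9g %.9g %.9g", v[f[i, 2], 1], v[f[i, 2], 2], v[f[i, 2], 3]),
      sprintf("    vertex %.9g %.9g %.9g", v[f[i, 3], 1], v[f[i, 3], 2], v[f[i, 3], 3]),
      "  endloop", "endfacet", sep = "\n")
  }, character(1))
  writeLines(blocks, con)
  writeLines("endsolid atrialign", con)
}
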