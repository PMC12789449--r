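#' Triangle mesh
#'
#' Minimal triangle-surface container used throughout the package: an n x 3
#' vertex matrix (mm) plus an m x 3 face matrix of 1-based vertex indices.
#' Degenerate faces (repeated vertex indices) are dropped on construction.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates in mm.
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3 || !is.numeric(vertices)) {
    stop("`vertices` must be an n x 3 numeric matrix", call. = FALSE)
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("mesh vertices must be finite", call. = FALSE)
  }
  if (anyNA(faces) || any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices must reference existing vertices", call. = FALSE)
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen)) faces <- faces[!degen, , drop = FALSE]
  if (nrow(vertices) < 4 || nrow(faces) < 4) {
    stop("mesh is degenerate: need at least 4 vertices and 4 faces",
         call. = FALSE)
  }
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh>  %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Transform a mesh rigidly
#'
#' @param transform a [rigid_transform()].
#' @param mesh a [tri_mesh()].
#' @return The transformed `tri_mesh` (same connectivity).
#' @export
transform_mesh <- function(transform, mesh) {
  stopifnot(is_tri_mesh(mesh))
  tri_mesh(transform_points(transform, mesh$vertices), mesh$faces)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas, in mm^2.
#'
#' @param mesh a [tri_mesh()].
#' @return Numeric scalar, mm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(is_tri_mesh(mesh))
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  e1 <- v[mesh$faces[, 2], , drop = FALSE] - a
  e2 <- v[mesh$faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# weld vertices that coincide to within `digits` decimals and drop
# unreferenced ones; STL stores one vertex triple per corner, so reading
# always goes through here to recover shared vertices
weld_vertices <- function(vertices, faces, digits = 6) {
  key <- apply(round(vertices, digits), 1, paste, collapse = ",")
  idx <- match(key, key)             # first occurrence of each coordinate
  keep <- sort(unique(idx[as.vector(faces)]))
  remap <- integer(nrow(vertices))
  remap[keep] <- seq_along(keep)
  list(vertices = vertices[keep, , drop = FALSE],
       faces = matrix(remap[idx[as.vector(faces)]], ncol = 3))
}

#' Read an STL file
#'
#' Reads a triangle mesh from `path`, auto-detecting binary versus ASCII STL.
#' Duplicate corner vertices are welded (coordinates equal to 1e-6 mm) and
#' unreferenced vertices dropped. STL is unitless; coordinates are treated
#' as mm.
#'
#' @param path file path.
#' @return A [tri_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 84)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(header[81:84], "integer", 1, size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    ntri <- readBin(header[81:84], "integer", 1, size = 4, endian = "little")
    body <- readBin(con, "raw", 50 * ntri)
    m <- matrix(body, nrow = 50)
    coords <- matrix(0, ntri, 9)
    for (j in 1:9) {  # skip the 12-byte normal, read 3 vertices x 3 floats
      off <- 12 + (j - 1) * 4
      coords[, j] <- readBin(as.vector(m[(off + 1):(off + 4), ]),
                             "numeric", ntri, size = 4, endian = "little")
    }
    verts <- matrix(t(coords), ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      stop("not a valid STL file: ", path, call. = FALSE)
    }
    verts <- matrix(
      as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                 "\\s+"))),
      ncol = 3, byrow = TRUE)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  w <- weld_vertices(verts, faces)
  tri_mesh(w$vertices, w$faces)
}

#' Write an STL file
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"ascii"` (default; plain text, diff-able) or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("ascii", "binary")) {
  stopifnot(is_tri_mesh(mesh))
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-30] <- 1
  nrm <- nrm / len
  if (format == "ascii") {
    num <- function(x) formatC(x, format = "e", digits = 9)
    block <- vapply(seq_len(nrow(f)), function(i) {
      paste0(
        " facet normal ", paste(num(nrm[i, ]), collapse = " "), "\n",
        "  outer loop\n",
        "   vertex ", paste(num(v[f[i, 1], ]), collapse = " "), "\n",
        "   vertex ", paste(num(v[f[i, 2], ]), collapse = " "), "\n",
        "   vertex ", paste(num(v[f[i, 3], ]), collapse = " "), "\n",
        "  endloop\n",
        " endfacet")
    }, character(1))
    writeLines(c("solid mesh", block, "endsolid mesh"), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(nrm[i, ]), con, size = 4, endian = "little")
      writeBin(as.numeric(t(v[f[i, ], ])), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
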