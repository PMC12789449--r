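#' Implant dimensions
#'
#' Diameter and length (coronal centre to apical centre) of a cylindrical
#' implant, in mm.
#'
#' @param diameter implant diameter, mm; must be > 0.
#' @param length implant length, mm; must be > 0.
#' @return An object of class `implant_spec`.
#' @examples
#' implant_spec(4, 10)  # the 4.0 x 10.0 mm implant used throughout
#' @export
implant_spec <- function(diameter = 4, length = 10) {
  if (!is.numeric(diameter) || length(diameter) != 1 || !is.finite(diameter) ||
      diameter <= 0 || !is.numeric(length) || length(length) != 1 ||
      !is.finite(length) || length <= 0) {
    stop("implant diameter and length must be positive finite numbers",
         call. = FALSE)
  }
  structure(list(diameter = diameter, length = length), class = "implant_spec")
}

#' Implant pose
#'
#' The position and orientation of one implant: coronal (platform) centre,
#' apical centre, and the unit long axis oriented coronal to apical, all in
#' model coordinates (mm).
#'
#' @param coronal length-3 coronal centre, mm.
#' @param apical length-3 apical centre, mm.
#' @return An object of class `implant_pose` with elements `coronal`,
#'   `apical`, `axis` (unit, coronal to apical) and `length` (mm).
#' @export
implant_pose <- function(coronal, apical) {
  coronal <- as.numeric(coronal)
  apical <- as.numeric(apical)
  if (length(coronal) != 3 || length(apical) != 3 ||
      anyNA(coronal) || anyNA(apical)) {
    stop("pose centres must be numeric 3-vectors", call. = FALSE)
  }
  d <- apical - coronal
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("coronal and apical centres coincide", call. = FALSE)
  structure(list(coronal = coronal, apical = apical, axis = d / len,
                 length = len),
            class = "implant_pose")
}

is_implant_pose <- function(x) inherits(x, "implant_pose")

#' @export
print.implant_pose <- function(x, ...) {
  cat(sprintf("<implant_pose>  coronal (%.3f, %.3f, %.3f)  apical (%.3f, %.3f, %.3f)  length %.3f mm\n",
              x$coronal[1], x$coronal[2], x$coronal[3],
              x$apical[1], x$apical[2], x$apical[3], x$length))
  invisible(x)
}

#' Apply a rigid transform to an implant pose
#'
#' Centres are mapped by the full transform; the axis by the rotation alone.
#'
#' @param transform a [rigid_transform()].
#' @param pose an [implant_pose()].
#' @return The transformed `implant_pose`.
#' @export
transform_pose <- function(transform, pose) {
  stopifnot(is_implant_pose(pose))
  implant_pose(transform_points(transform, pose$coronal),
               transform_points(transform, pose$apical))
}

#' Canonical cylindrical implant template
#'
#' Builds a closed right-cylinder mesh standing in for a dummy implant, in
#' the template frame: coronal (platform) centre at the origin, long axis
#' along -z, apical centre at `(0, 0, -length)`. The returned pose is exact
#' by construction.
#'
#' @param spec an [implant_spec()].
#' @param segments number of segments around the circumference (>= 8).
#' @return A list with elements `mesh` ([tri_mesh()]) and `pose`
#'   ([implant_pose()]).
#' @examples
#' tpl <- implant_template(implant_spec(4, 10), segments = 64)
#' mesh_area(tpl$mesh)  # close to 2*pi*2*10 + 2*pi*2^2
#' @export
implant_template <- function(spec = implant_spec(), segments = 64) {
  stopifnot(inherits(spec, "implant_spec"))
  if (!is.numeric(segments) || segments < 8) {
    stop("`segments` must be >= 8", call. = FALSE)
  }
  segments <- as.integer(segments)
  r <- spec$diameter / 2
  theta <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- cbind(r * cos(theta), r * sin(theta))
  top <- cbind(ring, 0)
  bottom <- cbind(ring, -spec$length)
  # vertex layout: 1 = top centre, 2 = bottom centre, then top ring, bottom ring
  verts <- rbind(c(0, 0, 0), c(0, 0, -spec$length), top, bottom)
  ti <- 2L + seq_len(segments)
  bi <- 2L + segments + seq_len(segments)
  nxt <- c(seq_len(segments)[-1], 1L)
  faces <- rbind(
    cbind(1L, ti[nxt], ti),                 # top cap fan (+z out)
    cbind(2L, bi, bi[nxt]),                 # bottom cap fan (-z out)
    cbind(ti, ti[nxt], bi[nxt]),            # side quads
    cbind(ti, bi[nxt], bi))
  list(mesh = tri_mesh(verts, faces),
       pose = implant_pose(c(0, 0, 0), c(0, 0, -spec$length)))
}

#' Dominant long axis of an elongated mesh
#'
#' Principal-component direction of the vertex cloud (vertices equally
#' weighted). The result is sign-ambiguous; the returned vector is
#' canonicalised so its largest-magnitude component is positive. Refuses
#' near-isotropic meshes where the axis is not well defined.
#'
#' @param mesh a [tri_mesh()].
#' @param min_elongation minimum ratio of first to second principal extent
#'   below which the axis is declared ambiguous.
#' @return A unit 3-vector (unoriented).
#' @export
fit_long_axis <- function(mesh, min_elongation = 1.2) {
  stopifnot(is_tri_mesh(mesh))
  v <- scale(mesh$vertices, scale = FALSE)
  sv <- svd(v, nu = 0)
  if (sv$d[1] < min_elongation * sv$d[2]) {
    stop("ambiguous axis: mesh is too isotropic (elongation ",
         sprintf("%.3f", sv$d[1] / sv$d[2]), " < ", min_elongation, ")",
         call. = FALSE)
  }
  axis <- sv$v[, 1]
  if (axis[which.max(abs(axis))] < 0) axis <- -axis
  axis
}

#' Extract an implant pose from a mesh
#'
#' Recovers the coronal centre, apical centre and long axis of a
#' near-cylindrical implant mesh. The long axis is the principal-component
#' direction of the vertices; its sign is fixed by `orientation_hint`, an
#' approximate coronal-to-apical direction (the batch pipeline passes the
#' planned axis for post-placement meshes). Each end centre is the centroid
#' of the vertices whose axial coordinate lies within `slab` mm of that
#' extreme.
#'
#' @param mesh a [tri_mesh()] of one implant.
#' @param spec an [implant_spec()]; used to sanity-check the recovered
#'   length (within 2%).
#' @param orientation_hint length-3 approximate coronal-to-apical direction;
#'   must not be near-perpendicular to the fitted axis
#'   (`|dot| > 0.1` after normalisation).
#' @param slab end-slab width in mm (default 0.2).
#' @return An [implant_pose()].
#' @export
pose_from_mesh <- function(mesh, spec = implant_spec(), orientation_hint,
                           slab = 0.2) {
  stopifnot(is_tri_mesh(mesh), inherits(spec, "implant_spec"))
  hint <- unit3(orientation_hint)
  axis <- fit_long_axis(mesh)
  d <- sum(axis * hint)
  if (abs(d) <= 0.1) {
    stop("orientation ambiguous: hint is near-perpendicular to the fitted axis",
         call. = FALSE)
  }
  if (d < 0) axis <- -axis
  t_ <- drop(mesh$vertices %*% axis)   # axial coordinate, increasing apically
  end_centroid <- function(sel) {
    if (sum(sel) < 3) {
      stop("degenerate end: fewer than 3 vertices in the end slab",
           call. = FALSE)
    }
    colMeans(mesh$vertices[sel, , drop = FALSE])
  }
  coronal <- end_centroid(t_ <= min(t_) + slab)
  apical <- end_centroid(t_ >= max(t_) - slab)
  pose <- implant_pose(coronal, apical)
  if (abs(pose$length - spec$length) > 0.02 * spec$length) {
    warning(sprintf("recovered implant length %.3f mm differs from spec %.1f mm by more than 2%%",
                    pose$length, spec$length), call. = FALSE)
  }
  pose
}
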