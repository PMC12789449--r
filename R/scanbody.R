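#' Canonical scan-body template mesh
#'
#' A synthetic stand-in for a scan body: a cylinder with one planed
#' (flattened) face, so that rotation about the implant axis is observable
#' during registration — the reason real scan bodies are rotationally
#' asymmetric. Library frame: base centre at the origin (the implant
#' interface), body extending along +z, flat face normal along +x.
#'
#' @param diameter body diameter, mm.
#' @param height body height, mm.
#' @param flat_fraction the planed face sits at `x = flat_fraction * radius`.
#' @param segments segments around the circumference.
#' @param rings number of vertex rings along the height (>= 2).
#' @return A [tri_mesh()].
#' @export
scan_body_template <- function(diameter = 5, height = 8, flat_fraction = 0.45,
                               segments = 48, rings = 5) {
  stopifnot(diameter > 0, height > 0, segments >= 8, rings >= 2)
  r <- diameter / 2
  theta <- 2 * pi * (seq_len(segments) - 1) / segments
  x <- pmin(r * cos(theta), flat_fraction * r)   # plane cut at x = f*r
  y <- r * sin(theta)
  zs <- seq(0, height, length.out = rings)
  verts <- do.call(rbind, lapply(zs, function(z) cbind(x, y, z)))
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, height))
  cb <- nrow(verts) - 1L   # base centre
  ct <- nrow(verts)        # top centre
  nxt <- c(seq_len(segments)[-1], 1L)
  faces <- NULL
  for (k in seq_len(rings - 1)) {
    lo <- (k - 1L) * segments
    hi <- k * segments
    faces <- rbind(faces,
                   cbind(lo + seq_len(segments), lo + nxt, hi + nxt),
                   cbind(lo + seq_len(segments), hi + nxt, hi + seq_len(segments)))
  }
  base <- seq_len(segments)
  top <- (rings - 1L) * segments + seq_len(segments)
  faces <- rbind(faces,
                 cbind(cb, base[nxt], base),
                 cbind(ct, top, top[nxt]))
  tri_mesh(verts, faces)
}

#' Scan-body library entry
#'
#' Pairs a scan-body template mesh with the implant pose it implies: the
#' transform `implant_offset` maps the library frame onto the implant frame
#' (the canonical implant template frame of [implant_template()]), so once
#' the template is registered onto a scan, the hidden implant's pose
#' follows by composition.
#'
#' @param template_mesh [tri_mesh()] of the scan body in library
#'   coordinates (default [scan_body_template()]).
#' @param implant_offset [rigid_transform()] mapping library frame ->
#'   implant frame. The default seats the implant platform 1 mm below the
#'   scan-body base, coaxial with it.
#' @param spec [implant_spec()] of the implant the body mates with.
#' @return An object of class `scan_body_library` with the template, the
#'   offset, the spec, and `implant_pose`: the implant pose expressed in
#'   library coordinates.
#' @export
scan_body_library <- function(template_mesh = scan_body_template(),
                              implant_offset = rigid_transform(
                                diag(3), c(0, 0, -1)),
                              spec = implant_spec()) {
  stopifnot(is_tri_mesh(template_mesh), is_rigid_transform(implant_offset),
            inherits(spec, "implant_spec"))
  canonical <- implant_pose(c(0, 0, 0), c(0, 0, -spec$length))
  structure(list(template_mesh = template_mesh,
                 implant_offset = implant_offset,
                 spec = spec,
                 implant_pose = transform_pose(implant_offset, canonical)),
            class = "scan_body_library")
}

#' Write / read a scan-body library definition
#'
#' The on-disk form is one STL (the template mesh) plus a small text config
#' holding the library-to-implant offset as 12 numbers: the 3x3 rotation
#' row-major, then the translation, one `key = value` per line
#' (`offset = r11 r12 ... t3`, `diameter`, `length`).
#'
#' @param library a [scan_body_library()].
#' @param stl_path,config_path file paths.
#' @return `write_scan_body_library()`: `config_path`, invisibly;
#'   `read_scan_body_library()`: a [scan_body_library()].
#' @export
write_scan_body_library <- function(library, stl_path, config_path) {
  stopifnot(inherits(library, "scan_body_library"))
  write_stl(library$template_mesh, stl_path, format = "ascii")
  off <- c(t(library$implant_offset$rotation), library$implant_offset$translation)
  writeLines(c(
    sprintf("offset = %s", paste(formatC(off, format = "g", digits = 17),
                                 collapse = " ")),
    sprintf("diameter = %.17g", library$spec$diameter),
    sprintf("length = %.17g", library$spec$length)), config_path)
  invisible(config_path)
}

#' @rdname write_scan_body_library
#' @export
read_scan_body_library <- function(stl_path, config_path) {
  cfg <- read_flat_config(config_path)
  off <- as.numeric(strsplit(trimws(cfg[["offset"]]), "\\s+")[[1]])
  if (length(off) != 12) {
    stop("library config `offset` must hold 12 numbers (rotation row-major, then translation)",
         call. = FALSE)
  }
  scan_body_library(
    template_mesh = read_stl(stl_path),
    implant_offset = rigid_transform(matrix(off[1:9], 3, 3, byrow = TRUE),
                                     off[10:12]),
    spec = implant_spec(as.numeric(cfg[["diameter"]]),
                        as.numeric(cfg[["length"]])))
}

#' Infer an implant pose from a scan-body scan
#'
#' Registers the library template onto a scanned scan body (Kabsch on
#' landmark correspondences when given, then ICP refinement) and composes
#' the registration with the library offset to obtain the hidden
#' (sub-gingival) implant's pose. A registration RMSD above
#' `rmsd_threshold` flags the result as a poor fit but does not discard it.
#'
#' @param scan [tri_mesh()] of the scanned scan body, in model coordinates.
#' @param library a [scan_body_library()].
#' @param init initial [rigid_transform()] template -> scan; `NULL`
#'   (default) starts ICP from a centroid alignment.
#' @param landmarks optional list with `source` (library frame) and
#'   `target` (scan frame) n x 3 landmark matrices.
#' @param rmsd_threshold poor-fit flag threshold in mm (default 0.15).
#' @param min_coverage minimum fraction of template vertices with a scan
#'   vertex within 0.3 mm after registration; below this the scan is
#'   rejected as not covering the template.
#' @param ... passed to [icp_refine()].
#' @return A list with `pose` (the inferred [implant_pose()]), `fit_rmsd`
#'   (mm), `poor_fit` (logical), `transform` (library -> scan) and
#'   `coverage`.
#' @export
infer_implant_pose <- function(scan, library, init = NULL,
                               landmarks = NULL, rmsd_threshold = 0.15,
                               min_coverage = 0.5, ...) {
  stopifnot(is_tri_mesh(scan), inherits(library, "scan_body_library"))
  if (!is.null(landmarks)) {
    init <- kabsch_align(landmarks$source, landmarks$target)$transform
  }
  fit <- icp_refine(library$template_mesh, scan, init = init, ...)
  moved <- transform_points(fit$transform, library$template_mesh$vertices)
  nn <- nearest_vertices(moved, scan$vertices)
  coverage <- mean(nn$dist < 0.3)
  if (coverage < min_coverage) {
    stop(sprintf("scan covers only %.0f%% of the scan-body template (need >= %.0f%%)",
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  list(pose = transform_pose(fit$transform, library$implant_pose),
       fit_rmsd = fit$rmsd,
       poor_fit = fit$rmsd > rmsd_threshold,
       transform = fit$transform,
       coverage = coverage)
}
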