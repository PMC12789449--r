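#' Least-squares rigid alignment of corresponding points (Kabsch)
#'
#' Closed-form least-squares rigid transform (proper rotation + translation)
#' mapping `source` points onto `target` points. Reflections are excluded:
#' the returned rotation always has det = +1, so a reflected correspondence
#' set yields the best proper rotation with a non-zero residual.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear), mm.
#' @return A list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (root-mean-square residual after alignment, mm).
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' tf <- rigid_transform(rotation_about_axis(c(1, 1, 0), 30), c(1, 2, 3))
#' fit <- kabsch_align(p, transform_points(tf, p))
#' fit$rmsd  # ~ 0
#' @export
kabsch_align <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (!identical(dim(source), dim(target)) || ncol(source) != 3) {
    stop("`source` and `target` must be n x 3 matrices of equal size",
         call. = FALSE)
  }
  if (nrow(source) < 3) {
    stop("need at least 3 correspondences", call. = FALSE)
  }
  cs <- colMeans(source)
  ct <- colMeans(target)
  sc <- sweep(source, 2, cs)
  tc <- sweep(target, 2, ct)
  sv_src <- svd(sc, nu = 0, nv = 0)$d
  if (sv_src[2] < 1e-9 * max(sv_src[1], 1)) {
    stop("degenerate correspondences: points are collinear or coincident",
         call. = FALSE)
  }
  h <- crossprod(sc, tc)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - drop(r %*% cs)
  resid <- tc - sc %*% t(r)
  list(transform = rigid_transform(r, tr),
       rmsd = sqrt(mean(rowSums(resid^2))))
}

# nearest target vertex for each query point; brute force, chunked to bound
# memory; ties broken by lowest target index (which.min)
nearest_vertices <- function(query, target, chunk = 2048L) {
  n <- nrow(query)
  tn <- rowSums(target^2)
  idx <- integer(n)
  d2 <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    i <- start:min(start + chunk - 1L, n)
    q <- query[i, , drop = FALSE]
    # squared distances: |q|^2 - 2 q.t + |t|^2
    cross <- q %*% t(target)
    dm <- sweep(-2 * cross, 2, tn, "+") + rowSums(q^2)
    idx[i] <- max.col(-dm, ties.method = "first")
    d2[i] <- dm[cbind(seq_along(i), idx[i])]
  }
  list(index = idx, dist = sqrt(pmax(d2, 0)))
}

#' Iterative closest point refinement
#'
#' Point-to-point ICP between two meshes: starting from `init`, alternates
#' nearest-vertex correspondence search (ties broken by lowest vertex index)
#' with a full Kabsch re-solve, so the correspondence RMSD is non-increasing
#' across iterations. Deterministic given its inputs.
#'
#' @param source,target [tri_mesh()] objects; `source` is aligned onto
#'   `target`.
#' @param init initial [rigid_transform()]. The default `NULL` starts from
#'   a centroid alignment of the two vertex clouds, which avoids the
#'   lattice-shifted local minima a raw identity start falls into when the
#'   displacement exceeds the vertex spacing; pass `rigid_transform()` to
#'   force a pure identity start, or a landmark-based fit for large
#'   displacements.
#' @param max_iter maximum iterations (>= 1).
#' @param tol stop when the RMSD improves by less than `tol` mm.
#' @return A list with `transform` (source -> target), `rmsd` (final
#'   nearest-point RMSD, mm), `iterations`, and `rmsd_trace` (per-iteration
#'   RMSD).
#' @export
icp_refine <- function(source, target, init = NULL,
                       max_iter = 50, tol = 1e-9) {
  stopifnot(is_tri_mesh(source), is_tri_mesh(target))
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (nrow(source$vertices) == 0 || nrow(target$vertices) == 0) {
    stop("empty mesh", call. = FALSE)
  }
  if (is.null(init)) {
    init <- rigid_transform(diag(3), colMeans(target$vertices) -
                              colMeans(source$vertices))
  }
  stopifnot(is_rigid_transform(init))
  tf <- init
  trace <- numeric(0)
  last <- Inf
  for (it in seq_len(max_iter)) {
    moved <- transform_points(tf, source$vertices)
    nn <- nearest_vertices(moved, target$vertices)
    fit <- kabsch_align(source$vertices,
                        target$vertices[nn$index, , drop = FALSE])
    tf <- fit$transform
    moved <- transform_points(tf, source$vertices)
    rmsd <- sqrt(mean(rowSums(
      (moved - target$vertices[nn$index, , drop = FALSE])^2)))
    trace <- c(trace, rmsd)
    if (last - rmsd < tol) break
    last <- rmsd
  }
  list(transform = tf, rmsd = trace[length(trace)], iterations = length(trace),
       rmsd_trace = trace)
}

#' Align a scan into a reference frame
#'
#' Convenience wrapper mirroring a typical dental CAD alignment: if landmark
#' correspondences are given (e.g. fixation-screw head centres), a Kabsch
#' fit on the landmarks initialises a surface ICP refinement; otherwise ICP
#' runs from the identity.
#'
#' @param scan,reference [tri_mesh()] objects; `scan` is aligned onto
#'   `reference`.
#' @param landmarks optional list with `source` and `target` n x 3 matrices
#'   of corresponding landmark points (scan frame, reference frame).
#' @param ... passed to [icp_refine()].
#' @return As [icp_refine()].
#' @export
align_scan <- function(scan, reference, landmarks = NULL, ...) {
  init <- if (is.null(landmarks)) NULL else
    kabsch_align(landmarks$source, landmarks$target)$transform
  icp_refine(scan, reference, init = init, ...)
}

#' Read labelled 3D landmark points
#'
#' Reads a plain-text CSV of labelled points (`label,x,y,z`, mm) as used for
#' fiducial-based alignment.
#'
#' @param path CSV file path.
#' @return A data frame with columns `label`, `x`, `y`, `z`.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("landmark file must have columns label,x,y,z", call. = FALSE)
  }
  d[need]
}
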