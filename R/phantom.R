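#' Synthetic edentulous ridge phantom mesh
#'
#' A synthetic stand-in for a scanned edentulous mandibular ridge: a
#' horseshoe-shaped surface (half-elliptical cross-section swept along a
#' circular arc) with a smooth asymmetric bump modulation so the surface
#' has no rotational or mirror symmetry — a well-conditioned target for
#' surface registration. Purely synthetic; not derived from any scan.
#'
#' @param arch_radius centreline arc radius, mm.
#' @param ridge_width cross-section width, mm.
#' @param ridge_height cross-section height, mm.
#' @param n_arc,n_profile grid resolution along the arc / across the
#'   profile.
#' @return A [tri_mesh()] (an open surface).
#' @export
ridge_phantom <- function(arch_radius = 20, ridge_width = 10,
                          ridge_height = 8, n_arc = 60, n_profile = 12) {
  stopifnot(n_arc >= 4, n_profile >= 4)
  u <- seq(-2 * pi / 3, 2 * pi / 3, length.out = n_arc)     # along the arch
  v <- seq(-1, 1, length.out = n_profile)                   # across the ridge
  verts <- matrix(0, n_arc * n_profile, 3)
  k <- 0
  for (i in seq_len(n_arc)) {
    # asymmetric modulation breaks left/right mirror symmetry
    bump <- 1 + 0.08 * sin(3 * u[i] + 0.7) + 0.05 * cos(5 * u[i])
    for (j in seq_len(n_profile)) {
      r <- arch_radius + (ridge_width / 2) * v[j]
      z <- ridge_height * bump * sqrt(pmax(0, 1 - v[j]^2))
      k <- k + 1
      verts[k, ] <- c(r * sin(u[i]), r * cos(u[i]), z)
    }
  }
  idx <- function(i, j) (i - 1L) * n_profile + j
  faces <- NULL
  for (i in seq_len(n_arc - 1)) {
    j <- seq_len(n_profile - 1)
    faces <- rbind(faces,
                   cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  tri_mesh(verts, faces)
}
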