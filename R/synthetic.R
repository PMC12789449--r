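#' Guide-seating / drilling error model
#'
#' Two-level stochastic model of implant placement error. Each model
#' (mandible) draws one shared rigid "guide seating" error — isotropic
#' translation with per-axis SD `guide_translation_sd` and a rotation about
#' a uniformly random axis through the guide centre with angle
#' `|N(0, guide_rotation_sd)|` — applied to all four implants, reflecting
#' that the four positions share the same seated guide and are therefore
#' not independent. Each implant then draws an independent perturbation of
#' the same form (`implant_*`, rotation about its own coronal centre) plus
#' a deterministic depth shift `depth_bias` along its long axis.
#'
#' @param guide_translation_sd per-axis SD of the shared guide translation,
#'   mm.
#' @param guide_rotation_sd SD of the shared guide rotation angle, degrees.
#' @param implant_translation_sd per-axis SD of the per-implant
#'   translation, mm.
#' @param implant_rotation_sd SD of the per-implant rotation angle,
#'   degrees.
#' @param depth_bias deterministic extra seating depth along the implant
#'   axis, mm (positive = deeper, i.e. toward apical).
#' @return An object of class `error_model`.
#' @export
error_model <- function(guide_translation_sd = 0, guide_rotation_sd = 0,
                        implant_translation_sd = 0, implant_rotation_sd = 0,
                        depth_bias = 0) {
  vals <- c(guide_translation_sd, guide_rotation_sd,
            implant_translation_sd, implant_rotation_sd)
  if (any(!is.finite(vals)) || any(vals < 0) || !is.finite(depth_bias)) {
    stop("error-model SDs must be finite and >= 0", call. = FALSE)
  }
  structure(list(guide_translation_sd = guide_translation_sd,
                 guide_rotation_sd = guide_rotation_sd,
                 implant_translation_sd = implant_translation_sd,
                 implant_rotation_sd = implant_rotation_sd,
                 depth_bias = depth_bias),
            class = "error_model")
}

#' Calibrated default error models
#'
#' Illustrative error models for the two guide concepts, calibrated so the
#' simulated group means and SDs bracket the published group statistics:
#' the screw-retained guide is dominated by small, comparable guide and
#' drilling errors, while the mucosa-supported guide carries a dominant
#' shared guide-seating error.
#'
#' @return An [error_model()].
#' @export
screw_guide_error_model <- function() {
  error_model(guide_translation_sd = 0.18, guide_rotation_sd = 1.3,
              implant_translation_sd = 0.18, implant_rotation_sd = 2.7)
}

#' @rdname screw_guide_error_model
#' @export
mucosa_guide_error_model <- function() {
  error_model(guide_translation_sd = 0.72, guide_rotation_sd = 2.4,
              implant_translation_sd = 0.20, implant_rotation_sd = 3.5)
}

#' Default planned implant positions
#'
#' Four parallel interforaminal implants on a mandibular arch: coronal
#' centres on a 15 mm arc (positions a-d at -54, -18, +18, +54 degrees from
#' the midline), long axes pointing apically (-z). Centre spacing (9.3 mm)
#' comfortably exceeds the implant diameter.
#'
#' @param spec an [implant_spec()].
#' @param arch_radius arc radius of the planned positions, mm.
#' @return Named list of four [implant_pose()] objects (`a`..`d`).
#' @export
default_planned_poses <- function(spec = implant_spec(), arch_radius = 15) {
  ang <- c(a = -54, b = -18, c = 18, d = 54) * pi / 180
  lapply(ang, function(t_) {
    coronal <- c(arch_radius * sin(t_), arch_radius * cos(t_), 0)
    implant_pose(coronal, coronal + c(0, 0, -spec$length))
  })
}

#' Synthetic study layout
#'
#' The in-silico counterpart of the bench study: `n_models_per_method`
#' mandible models per guide method (default 5, i.e. ten models in all),
#' four implant positions per model, one implant spec, and the planned pose
#' of each position (shared across models, as one virtual plan was used per
#' model type).
#'
#' @param n_models_per_method models per method (default 5).
#' @param positions position labels (default `"a".."d"`).
#' @param implant an [implant_spec()].
#' @param planned_poses named list of [implant_pose()] per position.
#' @param seed integer RNG seed recorded with the design.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_models_per_method = 5,
                         positions = c("a", "b", "c", "d"),
                         implant = implant_spec(),
                         planned_poses = default_planned_poses(implant),
                         seed = 1L) {
  stopifnot(inherits(implant, "implant_spec"), n_models_per_method >= 1)
  positions <- as.character(positions)
  if (anyDuplicated(positions)) stop("positions must be distinct", call. = FALSE)
  if (!all(positions %in% names(planned_poses))) {
    stop("planned_poses must name every position", call. = FALSE)
  }
  cent <- vapply(planned_poses[positions], function(p) p$coronal, numeric(3))
  if (length(positions) > 1) {
    dmin <- min(stats::dist(t(cent)))
    if (dmin <= implant$diameter) {
      stop("planned implants intersect: minimum centre spacing ",
           sprintf("%.2f", dmin), " mm <= diameter", call. = FALSE)
    }
  }
  structure(list(n_models_per_method = as.integer(n_models_per_method),
                 positions = positions, implant = implant,
                 planned_poses = planned_poses[positions],
                 seed = as.integer(seed)),
            class = "study_design")
}

# one shared guide-seating error: rotation about `centre`, then translation
sample_guide_error <- function(model, centre = c(0, 0, 0)) {
  stopifnot(inherits(model, "error_model"))
  angle <- abs(stats::rnorm(1, 0, model$guide_rotation_sd))
  axis <- random_unit_vector()
  shift <- stats::rnorm(3, 0, model$guide_translation_sd)
  base <- rotation_about_point(axis, angle, centre)
  rigid_transform(base$rotation, base$translation + shift)
}

#' Sample one placed implant pose
#'
#' Applies the model-shared guide error, then an independent per-implant
#' perturbation: rotation about a uniformly random axis through the
#' (guide-displaced) coronal centre with angle
#' `|N(0, implant_rotation_sd)|`, an isotropic translation with per-axis SD
#' `implant_translation_sd`, and a deterministic `depth_bias` shift along
#' the implant axis. Consumes the global RNG, so results are reproducible
#' under [set.seed()].
#'
#' @param planned the planned [implant_pose()].
#' @param guide_error shared [rigid_transform()] of the model's guide.
#' @param model an [error_model()].
#' @return The placed [implant_pose()].
#' @export
sample_placed_pose <- function(planned, guide_error, model) {
  stopifnot(is_implant_pose(planned), is_rigid_transform(guide_error),
            inherits(model, "error_model"))
  pose <- transform_pose(guide_error, planned)
  angle <- abs(stats::rnorm(1, 0, model$implant_rotation_sd))
  axis <- random_unit_vector()
  pose <- transform_pose(rotation_about_point(axis, angle, pose$coronal), pose)
  shift <- stats::rnorm(3, 0, model$implant_translation_sd) +
    model$depth_bias * pose$axis
  implant_pose(pose$coronal + shift, pose$apical + shift)
}

# centre the shared guide rotation acts about: centroid of the planned
# coronal centres (where the guide sits over the arch)
guide_centre <- function(design) {
  rowMeans(vapply(design$planned_poses, function(p) p$coronal, numeric(3)))
}

#' Simulate a complete study at pose level
#'
#' Draws every placed pose of a two-method study (blocks `1..n` = method 1,
#' `n+1..2n` = method 2) and returns the ground-truth manifest: per implant,
#' the planned and placed poses and the true deviation record computed with
#' [compare_implants()]. No meshes are written; see [generate_study()] for
#' the on-disk version.
#'
#' @param design a [study_design()].
#' @param model1,model2 [error_model()] for methods 1 and 2.
#' @param seed RNG seed (default: the design's).
#' @return A data frame: `block`, `position`, `method`, the deviation
#'   record columns, and planned/placed pose columns
#'   (`planned_coronal_x` ... `placed_axis_z`).
#' @export
simulate_study <- function(design, model1 = screw_guide_error_model(),
                           model2 = mucosa_guide_error_model(),
                           seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_models_per_method
  centre <- guide_centre(design)
  rows <- vector("list", 2 * n * length(design$positions))
  k <- 0
  for (block in seq_len(2 * n)) {
    method <- if (block <= n) 1L else 2L
    model <- if (method == 1L) model1 else model2
    gerr <- sample_guide_error(model, centre)
    for (pos in design$positions) {
      planned <- design$planned_poses[[pos]]
      placed <- sample_placed_pose(planned, gerr, model)
      rec <- compare_implants(planned, placed, block = block, position = pos)
      rec$method <- method
      for (nm in c("coronal", "apical", "axis")) {
        rec[paste0("planned_", nm, "_", c("x", "y", "z"))] <-
          as.list(planned[[nm]])
        rec[paste0("placed_", nm, "_", c("x", "y", "z"))] <-
          as.list(placed[[nm]])
      }
      k <- k + 1
      rows[[k]] <- rec
    }
  }
  do.call(rbind, rows)
}

# rigid transform placing the canonical implant template at `pose`
# (roll about the long axis is arbitrary and irrelevant to every metric)
pose_placement_transform <- function(pose) {
  r <- rotation_between(c(0, 0, -1), pose$axis)
  rigid_transform(r, pose$coronal)
}

#' Generate an on-disk synthetic study
#'
#' Writes a complete synthetic study under `out_dir`: per implant, the
#' planned and placed implant meshes as ASCII STL named
#' `{block}{position}_{pre|post}.stl` (e.g. `3b_pre.stl`), optionally a
#' scan-body mesh seated at each placed pose
#' (`{block}{position}_scanbody.stl`), plus `manifest.csv` (the
#' ground-truth table of [simulate_study()]) and `config.txt` (flat
#' key-value record of the design, error models and seed). Byte-identical
#' output for the same seed.
#'
#' @inheritParams simulate_study
#' @param out_dir output directory (created if needed).
#' @param segments cylinder discretisation of the written meshes.
#' @param scan_bodies also write scan-body meshes at the placed poses.
#' @return The manifest data frame, invisibly.
#' @export
generate_study <- function(design, model1 = screw_guide_error_model(),
                           model2 = mucosa_guide_error_model(),
                           out_dir, segments = 32, scan_bodies = FALSE,
                           seed = design$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  manifest <- simulate_study(design, model1, model2, seed = seed)
  template <- implant_template(design$implant, segments = segments)$mesh
  sb_lib <- if (scan_bodies) scan_body_library(spec = design$implant)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    planned <- implant_pose(
      unlist(row[paste0("planned_coronal_", c("x", "y", "z"))]),
      unlist(row[paste0("planned_apical_", c("x", "y", "z"))]))
    placed <- implant_pose(
      unlist(row[paste0("placed_coronal_", c("x", "y", "z"))]),
      unlist(row[paste0("placed_apical_", c("x", "y", "z"))]))
    stem <- file.path(out_dir, paste0(row$block, row$position))
    write_stl(transform_mesh(pose_placement_transform(planned), template),
              paste0(stem, "_pre.stl"))
    write_stl(transform_mesh(pose_placement_transform(placed), template),
              paste0(stem, "_post.stl"))
    if (scan_bodies) {
      # scan body sits on the placed implant: library frame -> placed frame
      seat <- transform_compose(pose_placement_transform(placed),
                                transform_invert(sb_lib$implant_offset))
      write_stl(transform_mesh(seat, sb_lib$template_mesh),
                paste0(stem, "_scanbody.stl"))
    }
  }
  num <- vapply(manifest, is.numeric, logical(1))
  out <- manifest
  out[num] <- lapply(out[num], function(x) formatC(x, format = "g", digits = 17))
  utils::write.csv(out, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = TRUE)
  cfg <- c(
    seed = seed, n_models_per_method = design$n_models_per_method,
    positions = paste(design$positions, collapse = ""),
    implant_diameter = design$implant$diameter,
    implant_length = design$implant$length, segments = segments,
    stats::setNames(unlist(model1), paste0("method1_", names(unlist(model1)))),
    stats::setNames(unlist(model2), paste0("method2_", names(unlist(model2)))))
  writeLines(sprintf("%s = %s", names(cfg), as.character(cfg)),
             file.path(out_dir, "config.txt"))
  invisible(manifest)
}

# E||x|| for x ~ N(mu, Sigma): (1/(2 sqrt(pi))) Int t^{-3/2} (1 - E exp(-t Q)) dt
# with E exp(-t||x||^2) = prod (1+2 t l_i)^{-1/2} exp(-sum t m_i^2/(1+2 t l_i)),
# l_i the eigenvalues of Sigma and m the mean in the eigenbasis
expected_norm_gaussian <- function(sigma, mu = c(0, 0, 0)) {
  sigma <- as.matrix(sigma)
  eg <- eigen(sigma, symmetric = TRUE)
  l <- pmax(eg$values, 0)
  m <- drop(t(eg$vectors) %*% mu)
  if (sum(l) < 1e-30) return(sqrt(sum(mu^2)))
  integrand <- function(t_) {
    lap <- exp(-rowSums(sweep(outer(t_, m^2), c(1, 2),
                              1 + 2 * outer(t_, l), "/"))) /
      sqrt(apply(1 + 2 * outer(t_, l), 1, prod))
    (1 - lap) / t_^1.5
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)$value / (2 * sqrt(pi))
}

# characteristic factor of one model rotation term along a probe direction:
# E_{u,theta} cos(theta * u.b) for theta = sd*|Z| (Z standard normal) and u
# uniform on the sphere is sqrt(pi/2)*erf(x/sqrt(2))/x at x = sd*|b|
# (erf(x/sqrt(2)) = 2*pnorm(x) - 1); -> 1 as x -> 0
cf_uniform_axis <- function(x) {
  out <- rep(1, length(x))
  nz <- x > 1e-10
  xs <- x[nz]
  out[nz] <- sqrt(pi / 2) * (2 * stats::pnorm(xs) - 1) / xs
  out
}

# Expected Euclidean norm of  X = T + sum_j theta_j (u_j x r_j) + mu, where
# T ~ N(0, trans_sd^2 I3), theta_j = rot_sd_j * |Z| (radians) about uniform
# axes u_j. Uses E|X| = (1/pi^2) Int (1 - Re cf_X(k)) / |k|^4 d3k with the
# closed-form characteristic function, evaluated by Gauss-Legendre
# quadrature over the half-sphere and a mapped radial grid.
expected_norm_displacement <- function(trans_sd, rot_sd = numeric(0),
                                       levers = list(), mu = c(0, 0, 0),
                                       n_dir = 20, n_rad = 120) {
  scale2 <- trans_sd^2 + sum(mu^2)
  for (j in seq_along(rot_sd)) scale2 <- scale2 + (rot_sd[j]^2) * sum(levers[[j]]^2)
  if (scale2 < 1e-30) return(0)
  # full-sphere direction grid: Gauss-Legendre in cos(theta), periodic
  # trapezoid in phi
  gl <- gauss_legendre(n_dir)
  ct <- gl$nodes
  wt <- gl$weights
  phi <- pi * (seq_len(2 * n_dir) - 0.5) / n_dir   # periodic trapezoid, [0, 2pi)
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- cbind(rep(st, each = 2 * n_dir) * cos(phi),
                rep(st, each = 2 * n_dir) * sin(phi),
                rep(ct, each = 2 * n_dir))
  wdir <- rep(wt, each = 2 * n_dir) * (pi / n_dir)   # d(cos t) d(phi), total 4*pi
  # radial grid: k = s * t / (1 - t), t in (0,1); s sets the scale
  s <- 2 / sqrt(scale2)
  glr <- gauss_legendre(n_rad)
  t_ <- (glr$nodes + 1) / 2
  wr0 <- glr$weights / 2
  k <- s * t_ / (1 - t_)
  jac <- s / (1 - t_)^2
  # inner radial integral per direction: Int (1 - Re cf(k d)) / k^2 dk
  inner <- vapply(seq_len(nrow(dirs)), function(i) {
    d <- dirs[i, ]
    cf <- exp(-0.5 * trans_sd^2 * k^2) * cos(k * sum(d * mu))
    for (j in seq_along(rot_sd)) {
      r <- levers[[j]]
      b <- sqrt(max(0, sum(r^2) - sum(d * r)^2))   # |r x d|
      cf <- cf * cf_uniform_axis(rot_sd[j] * b * k)
    }
    sum(wr0 * jac * (1 - cf) / k^2)
  }, numeric(1))
  sum(wdir * inner) / pi^2
}

# Expected angle (radians) between planned and placed axes: the norm of the
# in-plane component of the combined small-rotation vector; its 2D
# characteristic function is isotropic and separable, so a single radial
# integral suffices: E = Int (1 - prod_j cf(sd_j k)) / k^2 dk.
expected_angle_smallrot <- function(rot_sd, n_rad = 400) {
  rot_sd <- rot_sd[rot_sd > 0]
  if (length(rot_sd) == 0) return(0)
  scale <- 2 / sqrt(sum(rot_sd^2))
  gl <- gauss_legendre(n_rad)
  t_ <- (gl$nodes + 1) / 2
  w <- gl$weights / 2
  k <- scale * t_ / (1 - t_)
  jac <- scale / (1 - t_)^2
  cf <- rep(1, length(k))
  for (s in rot_sd) cf <- cf * cf_uniform_axis(s * k)
  sum(w * jac * (1 - cf) / k^2)
}

# Gauss-Legendre nodes/weights on (-1, 1) (Golub-Welsch, base R eigen)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  m <- matrix(0, n, n)
  m[cbind(i, i + 1)] <- b
  m[cbind(i + 1, i)] <- b
  e <- eigen(m, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' Semi-analytic expected deviations under an error model
#'
#' Expectation of the three deviation metrics for each planned position
#' under an [error_model()], used as the independent reference in
#' parameter-recovery checks. Rotations are linearised (small-angle): the
#' displacement of a point at lever arm r from a rotation centre is
#' `theta (u x r)` for angle `theta = |N(0, sd)|` about a uniform random
#' axis u. That displacement is spherically structured but not Gaussian;
#' the expected norm of the total displacement (translations + rotation
#' terms + depth bias) is computed exactly from its closed-form
#' characteristic function by numerical quadrature, and the expected
#' angular deviation likewise from the in-plane component of the combined
#' rotation vector.
#'
#' @param design a [study_design()].
#' @param model an [error_model()].
#' @return A data frame with one row per position: expected `deviation_a`,
#'   `deviation_b` (mm) and `angle_error` (degrees).
#' @export
expected_deviations <- function(design, model) {
  stopifnot(inherits(design, "study_design"), inherits(model, "error_model"))
  centre <- guide_centre(design)
  t_sd <- sqrt(model$guide_translation_sd^2 + model$implant_translation_sd^2)
  rad <- pi / 180
  ang <- expected_angle_smallrot(
    c(model$guide_rotation_sd, model$implant_rotation_sd) * rad) / rad
  rows <- lapply(design$positions, function(pos) {
    p <- design$planned_poses[[pos]]
    mu <- model$depth_bias * p$axis
    dev_a <- expected_norm_displacement(
      t_sd, rot_sd = model$guide_rotation_sd * rad,
      levers = list(p$coronal - centre), mu = mu)
    dev_b <- expected_norm_displacement(
      t_sd,
      rot_sd = c(model$guide_rotation_sd, model$implant_rotation_sd) * rad,
      levers = list(p$apical - centre, p$apical - p$coronal), mu = mu)
    data.frame(position = pos, deviation_a = dev_a, deviation_b = dev_b,
               angle_error = ang)
  })
  do.call(rbind, rows)
}

#' Read a flat key-value config file
#'
#' Parses lines of the form `key = value` (text after `#` ignored) into a
#' named character vector.
#'
#' @param path file path.
#' @return Named character vector.
#' @export
read_flat_config <- function(path) {
  lines <- sub("#.*", "", readLines(path, warn = FALSE))
  lines <- lines[grepl("=", lines)]
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(vals, keys)
}
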