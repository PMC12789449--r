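test_that("scan-body library round-trips through its on-disk form", {
  lib <- scan_body_library(
    implant_offset = rigid_transform(rotation_about_axis(c(0, 0, 1), 30),
                                     c(0.5, -0.2, -1.5)),
    spec = implant_spec(4, 10))
  stl <- withr::local_tempfile(fileext = ".stl")
  cfg <- withr::local_tempfile(fileext = ".txt")
  write_scan_body_library(lib, stl, cfg)
  back <- read_scan_body_library(stl, cfg)
  expect_equal(back$implant_offset$rotation, lib$implant_offset$rotation,
               tolerance = 1e-12)
  expect_equal(back$implant_pose$coronal, lib$implant_pose$coronal,
               tolerance = 1e-12)
  expect_equal(nrow(back$template_mesh$vertices),
               nrow(lib$template_mesh$vertices))
})

test_that("implant pose round-trips through scan-body inference", {
  lib <- scan_body_library()
  # scan equals the template: the pose is the library's own implant pose
  ident <- infer_implant_pose(lib$template_mesh, lib)
  expect_equal(ident$pose$coronal, lib$implant_pose$coronal,
               tolerance = 1e-9)
  expect_lt(ident$fit_rmsd, 1e-9)
  expect_false(ident$poor_fit)
  # 100 seeded poses, noiseless, small displacement (identity init regime)
  set.seed(53)
  for (i in 1:100) {
    tf <- random_rigid(max_angle = 2, max_trans = 1)
    inf <- infer_implant_pose(transform_mesh(tf, lib$template_mesh), lib)
    truth <- transform_pose(tf, lib$implant_pose)
    expect_lt(max(abs(inf$pose$coronal - truth$coronal)), 0.05)
    expect_lt(max(abs(inf$pose$apical - truth$apical)), 0.05)
    expect_lt(angular_deviation(inf$pose$axis, truth$axis), 0.1)
  }
})

test_that("large displacements are recoverable given landmarks", {
  lib <- scan_body_library()
  set.seed(59)
  tf <- random_rigid(max_angle = 40, max_trans = 15)
  scan <- transform_mesh(tf, lib$template_mesh)
  lm <- lib$template_mesh$vertices[c(1, 60, 150, 220), ]
  inf <- infer_implant_pose(scan, lib,
                            landmarks = list(source = lm,
                                             target = transform_points(tf, lm)))
  truth <- transform_pose(tf, lib$implant_pose)
  expect_lt(max(abs(inf$pose$coronal - truth$coronal)), 1e-6)
})

test_that("vertex jitter degrades the inferred pose gracefully", {
  lib <- scan_body_library()
  set.seed(61)
  jitter_err <- function(sd) {
    mean(replicate(8, {
      tf <- random_rigid(max_angle = 1, max_trans = 0.5)
      scan <- transform_mesh(tf, lib$template_mesh)
      scan$vertices <- scan$vertices +
        matrix(rnorm(length(scan$vertices), 0, sd), ncol = 3)
      inf <- infer_implant_pose(scan, lib, rmsd_threshold = Inf,
                                min_coverage = 0)
      truth <- transform_pose(tf, lib$implant_pose)
      sqrt(sum((inf$pose$coronal - truth$coronal)^2))
    }))
  }
  e_small <- jitter_err(0.02)
  e_large <- jitter_err(0.2)
  expect_lt(e_small, 0.1)          # 0.02 mm jitter: pose within 0.1 mm
  expect_gt(e_large, e_small)      # error grows with jitter amplitude
})

test_that("a scan that misses most of the template is rejected", {
  lib <- scan_body_library()
  keep <- lib$template_mesh$vertices[, 3] > 6.5    # only the very top
  v <- lib$template_mesh$vertices[keep, ]
  f <- matrix(seq_len(3 * (nrow(v) %/% 3))[1:(3 * max(4, nrow(v) %/% 3))],
              ncol = 3)
  f <- f[f[, 1] <= nrow(v) & f[, 2] <= nrow(v) & f[, 3] <= nrow(v), ,
         drop = FALSE]
  partial <- tri_mesh(v, f)
  expect_error(infer_implant_pose(partial, lib), "covers only")
})
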