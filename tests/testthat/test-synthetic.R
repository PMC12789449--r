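test_that("zero-error models reproduce the plan exactly", {
  des <- study_design(n_models_per_method = 1, seed = 5)
  null <- error_model()
  sim <- simulate_study(des, null, null)
  expect_equal(max(sim$deviation_a), 0)
  expect_equal(max(sim$deviation_b), 0)
  expect_equal(max(sim$angle_error), 0)
})

test_that("a pure shared guide translation moves all four implants alike", {
  planned <- default_planned_poses()
  guide <- rigid_transform(diag(3), c(0.3, 0, 0.4))   # |t| = 0.5
  null <- error_model()
  recs <- lapply(planned, function(p) {
    compare_implants(p, sample_placed_pose(p, guide, null))
  })
  for (r in recs) {
    expect_equal(r$deviation_a, 0.5, tolerance = 1e-12)
    expect_equal(r$deviation_b, 0.5, tolerance = 1e-12)
    expect_equal(r$angle_error, 0, tolerance = 1e-9)
  }
})

test_that("depth bias seats implants deeper along their own axis", {
  planned <- default_planned_poses()$a
  deep <- error_model(depth_bias = 0.4)
  placed <- sample_placed_pose(planned, rigid_transform(), deep)
  rec <- compare_implants(planned, placed)
  expect_equal(rec$deviation_a, 0.4, tolerance = 1e-12)
  expect_equal(rec$dz_coronal, -0.4, tolerance = 1e-12)  # apically downward
  expect_equal(rec$angle_error, 0, tolerance = 1e-9)
})

test_that("expected norms agree with closed forms and Monte Carlo", {
  # isotropic Gaussian: chi_3 mean
  expect_equal(implacc:::expected_norm_displacement(0.3),
               0.3 * sqrt(2) * gamma(2) / gamma(1.5), tolerance = 1e-7)
  # single uniform-axis rotation: E = sd |r| sqrt(2/pi) * pi/4
  r <- c(5, -3, 2)
  expect_equal(
    implacc:::expected_norm_displacement(0, rot_sd = 0.03, levers = list(r)),
    0.03 * sqrt(sum(r^2)) * sqrt(2 / pi) * pi / 4, tolerance = 1e-5)
  expect_equal(implacc:::expected_angle_smallrot(0.03),
               0.03 * sqrt(2 / pi) * pi / 4, tolerance = 1e-5)
  # full displacement model vs 2e5-sample Monte Carlo
  set.seed(97)
  n <- 2e5
  rg <- c(3, 10, -2); ri <- c(0, 0, -10)
  ts <- 0.25; sg <- 0.02; si <- 0.035; mu <- c(0, 0, 0.2)
  cross_r <- function(u, rr) cbind(u[, 2] * rr[3] - u[, 3] * rr[2],
                                   u[, 3] * rr[1] - u[, 1] * rr[3],
                                   u[, 1] * rr[2] - u[, 2] * rr[1])
  ug <- matrix(rnorm(3 * n), n, 3); ug <- ug / sqrt(rowSums(ug^2))
  ui <- matrix(rnorm(3 * n), n, 3); ui <- ui / sqrt(rowSums(ui^2))
  x <- matrix(rnorm(3 * n, 0, ts), n, 3) +
    abs(rnorm(n, 0, sg)) * cross_r(ug, rg) +
    abs(rnorm(n, 0, si)) * cross_r(ui, ri)
  x <- sweep(x, 2, mu, "+")
  mc <- mean(sqrt(rowSums(x^2)))
  quad <- implacc:::expected_norm_displacement(ts, c(sg, si), list(rg, ri), mu)
  expect_equal(quad, mc, tolerance = 0.005)
})

test_that("sampled deviations match their semi-analytic expectations", {
  des <- study_design()
  model <- screw_guide_error_model()
  exp_dev <- expected_deviations(des, model)
  set.seed(103)
  centre <- implacc:::guide_centre(des)
  n <- 2500   # models; 4 positions each -> 1e4 implants
  devs <- matrix(0, n, 4)
  angs <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    g <- implacc:::sample_guide_error(model, centre)
    for (j in 1:4) {
      p <- des$planned_poses[[j]]
      placed <- sample_placed_pose(p, g, model)
      devs[i, j] <- sqrt(sum((placed$coronal - p$coronal)^2))
      angs[i, j] <- angular_deviation(p$axis, placed$axis)
    }
  }
  expect_equal(colMeans(devs), exp_dev$deviation_a, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(colMeans(angs), exp_dev$angle_error, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("generated studies are reproducible and self-consistent", {
  des <- study_design(n_models_per_method = 2, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_study(des, out_dir = d1, segments = 16)
  m2 <- generate_study(des, out_dir = d2, segments = 16)
  # same seed -> byte-identical manifest
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_setequal(c("1a_pre.stl", "1a_post.stl", "4d_pre.stl", "4d_post.stl"),
                  intersect(list.files(d1),
                            c("1a_pre.stl", "1a_post.stl",
                              "4d_pre.stl", "4d_post.stl")))
  # ground-truth consistency: manifest record equals compare_implants on
  # the manifest's own poses
  for (i in seq_len(nrow(m1))) {
    row <- m1[i, ]
    planned <- implant_pose(
      unlist(row[paste0("planned_coronal_", c("x", "y", "z"))]),
      unlist(row[paste0("planned_apical_", c("x", "y", "z"))]))
    placed <- implant_pose(
      unlist(row[paste0("placed_coronal_", c("x", "y", "z"))]),
      unlist(row[paste0("placed_apical_", c("x", "y", "z"))]))
    rec <- compare_implants(planned, placed)
    expect_equal(rec$deviation_a, row$deviation_a, tolerance = 1e-9)
    expect_equal(rec$deviation_b, row$deviation_b, tolerance = 1e-9)
    expect_equal(rec$angle_error, row$angle_error, tolerance = 1e-9)
  }
  # mesh-path consistency: measuring the written STLs reproduces the manifest
  layout <- study_layout(d1)
  measured <- measure_study(layout)
  joined <- merge(m1, measured, by = c("block", "position"),
                  suffixes = c("_true", "_meas"))
  expect_lt(max(abs(joined$deviation_a_true - joined$deviation_a_meas)), 0.05)
  expect_lt(max(abs(joined$deviation_b_true - joined$deviation_b_meas)), 0.05)
  expect_lt(max(abs(joined$angle_error_true - joined$angle_error_meas)), 0.1)
})

test_that("variance decomposes into guide and implant levels", {
  des <- study_design(n_models_per_method = 30, seed = 17)
  # no per-implant error: within-model deviation variance is zero
  guide_only <- error_model(guide_translation_sd = 0.4)
  sim_g <- simulate_study(des, guide_only, guide_only, seed = 19)
  within <- tapply(sim_g$deviation_a, sim_g$block, var)
  expect_lt(max(within), 1e-18)
  # no guide error: between-model variance indistinguishable from within
  impl_only <- error_model(implant_translation_sd = 0.3)
  sim_i <- simulate_study(des, impl_only, impl_only, seed = 23)
  fit <- anova(lm(deviation_a ~ factor(block), data = sim_i))
  expect_gt(fit$`Pr(>F)`[1], 0.01)
})
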