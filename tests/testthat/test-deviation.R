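test_that("deviation_magnitude is the Euclidean norm", {
  expect_equal(deviation_magnitude(3, 4, 0), 5)
  expect_equal(deviation_magnitude(0, 0, 0), 0)
  expect_equal(deviation_magnitude(0.5, 0.5, 0.5), sqrt(0.75))
  expect_equal(round(deviation_magnitude(0.5, 0.5, 0.5), 4), 0.8660)
  expect_error(deviation_magnitude(NaN, 0, 0), "finite")
  expect_error(deviation_magnitude(Inf, 0, 0), "finite")
})

test_that("angular_deviation measures the unsigned 3D angle in degrees", {
  expect_equal(angular_deviation(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angular_deviation(c(0, 0, 1), c(1, 0, 0)), 90)
  expect_equal(angular_deviation(c(0, 0, 1), c(0, 0, -1)), 180)
  a <- 2 * pi / 180
  expect_equal(angular_deviation(c(0, 0, 1), c(0, sin(a), cos(a))), 2,
               tolerance = 1e-9)
  expect_error(angular_deviation(c(0, 0, 2), c(0, 0, 1)), "unit")
})

test_that("compare_implants reproduces closed-form deviation cases", {
  planned <- implant_pose(c(0, 0, 0), c(0, 0, -10))
  # identical poses
  z <- compare_implants(planned, planned)
  expect_equal(z$deviation_a, 0)
  expect_equal(z$deviation_b, 0)
  expect_equal(z$angle_error, 0)
  # rigid translation: A = B = |shift|, no angle
  shift <- transform_pose(rigid_transform(diag(3), c(0.3, 0.4, 0)), planned)
  r <- compare_implants(planned, shift)
  expect_equal(r$deviation_a, 0.5)
  expect_equal(r$deviation_b, 0.5)
  expect_equal(r$angle_error, 0)
  expect_equal(c(r$dx_coronal, r$dy_coronal, r$dz_coronal), c(0.3, 0.4, 0))
  # 2-degree hinge at the coronal centre, perpendicular axis:
  # A = 0, B = chord = 2 * L * sin(1 degree), angle = 2
  hinge <- transform_pose(rotation_about_point(c(1, 0, 0), 2, c(0, 0, 0)),
                          planned)
  h <- compare_implants(planned, hinge)
  expect_equal(h$deviation_a, 0)
  expect_equal(h$deviation_b, 2 * 10 * sin(pi / 180), tolerance = 1e-9)
  expect_equal(round(h$deviation_b, 4), 0.3490)
  expect_equal(h$angle_error, 2, tolerance = 1e-9)
})

test_that("deviation records are frame-invariant and symmetric", {
  set.seed(71)
  for (i in 1:30) {
    planned <- random_pose()
    placed <- random_pose()
    rec <- compare_implants(planned, placed)
    # one common rigid transform leaves every value unchanged
    tf <- random_rigid()
    rec2 <- compare_implants(transform_pose(tf, planned),
                             transform_pose(tf, placed))
    expect_equal(rec2$deviation_a, rec$deviation_a, tolerance = 1e-9)
    expect_equal(rec2$deviation_b, rec$deviation_b, tolerance = 1e-9)
    expect_equal(rec2$angle_error, rec$angle_error, tolerance = 1e-7)
    # swapping planned and placed negates components, keeps magnitudes
    rev <- compare_implants(placed, planned)
    expect_equal(rev$deviation_a, rec$deviation_a)
    expect_equal(rev$deviation_b, rec$deviation_b)
    expect_equal(rev$angle_error, rec$angle_error)
    expect_equal(rev$dx_coronal, -rec$dx_coronal)
  }
})

test_that("deviation tables round-trip through the published CSV layout", {
  planned <- implant_pose(c(0, 0, 0), c(0, 0, -10))
  placed <- transform_pose(rigid_transform(diag(3), c(0.1, -0.2, 0.05)),
                           planned)
  records <- rbind(compare_implants(planned, placed, block = 1, position = "a"),
                   compare_implants(planned, planned, block = 1, position = "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_deviation_table(records, f)
  back <- read_deviation_table(f)
  expect_equal(back$deviation_a, records$deviation_a, tolerance = 1e-12)
  expect_equal(back$position, c("a", "b"))
  expect_equal(names(read.csv(f, check.names = FALSE))[1:5],
               c("Block", "Position", "Coronal Deviation A (mm)",
                 "Apical Deviation B (mm)", "Angle Error (Degrees)"))
})

test_that("the packaged study table has the published shape", {
  d <- example_deviation_table()
  expect_equal(nrow(d), 40)
  expect_equal(sort(unique(d$block)), 1:10)
  expect_equal(sort(unique(d$position)), c("a", "b", "c", "d"))
  expect_true(all(d$deviation_a >= 0 & d$deviation_b >= 0))
  expect_true(all(d$angle_error >= 0 & d$angle_error <= 180))
})
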