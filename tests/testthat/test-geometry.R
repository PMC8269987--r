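test_that("calibration scale is marker diameter over pixel distance", {
  m <- calibration_marker("scaling_ball", 25, point2d(0, 0), point2d(50, 0))
  expect_equal(compute_scale(m)$scale_mm_per_px, 0.5)

  m <- calibration_marker("femoral_head", 28, point2d(0, 0), point2d(28, 0))
  expect_equal(compute_scale(m)$scale_mm_per_px, 1.0)

  # 3-4-5 triangle scaled: distance (3,4)-(33,44) = 50
  m <- calibration_marker("scaling_ball", 25, point2d(3, 4), point2d(33, 44))
  expect_equal(compute_scale(m)$scale_mm_per_px, 0.5)

  degen <- calibration_marker("scaling_ball", 25, point2d(7, 7), point2d(7, 7))
  expect_error(compute_scale(degen), "degenerate")
})

test_that("anteversion is arcsin of the axis ratio in degrees", {
  expect_equal(anteversion(ellipse(point2d(0, 0), 10, 5, 0)), 30)
  expect_equal(anteversion(ellipse(point2d(0, 0), 10, 10, 0,
                                   orientation_indeterminate = TRUE)), 90)
  expect_equal(anteversion(ellipse(point2d(0, 0), 25, 12.5 * sqrt(2), 0)), 45)
})

test_that("anteversion is strictly increasing in the axis ratio", {
  ratios <- seq(0.05, 1, by = 0.05)
  v <- vapply(ratios, function(r)
    anteversion(ellipse(point2d(0, 0), 10, 10 * r, 0)), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("inclination is the acute angle to the reference line", {
  ref_x <- reference_line(point2d(0, 0), point2d(100, 0))
  expect_equal(inclination(ellipse(point2d(0, 0), 10, 5, 45), ref_x), 45)
  expect_equal(inclination(ellipse(point2d(0, 0), 10, 5, 0), ref_x), 0)

  # psi = 80, reference direction at 170 degrees -> exactly perpendicular
  ref_170 <- reference_line(point2d(0, 0),
                            point2d(cos(170 * pi / 180), sin(170 * pi / 180)))
  expect_equal(inclination(ellipse(point2d(0, 0), 10, 5, 80), ref_170), 90)

  # acute-angle folding over enumerated axis/reference angle pairs
  for (psi in seq(-85, 90, by = 19)) {
    for (th in seq(0, 355, by = 37)) {
      ref <- reference_line(point2d(0, 0),
                            point2d(cos(th * pi / 180), sin(th * pi / 180)))
      got <- inclination(ellipse(point2d(0, 0), 10, 5, psi), ref)
      d <- abs(psi - th) %% 180
      expected <- min(d, 180 - d)
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }

  # vertical reference lines are legal
  ref_v <- reference_line(point2d(5, 0), point2d(5, 10))
  expect_equal(inclination(ellipse(point2d(0, 0), 10, 5, 0), ref_v), 90)

  # circle: orientation carries no information
  circ <- ellipse(point2d(0, 0), 10, 10, 0, orientation_indeterminate = TRUE)
  expect_true(is.na(inclination(circ, ref_x)))
})

test_that("leg length is the calibrated signed perpendicular distance", {
  cal05 <- compute_scale(calibration_marker("scaling_ball", 25,
                                            point2d(0, 0), point2d(50, 0)))
  cal1 <- compute_scale(calibration_marker("scaling_ball", 25,
                                           point2d(0, 0), point2d(25, 0)))
  ref <- reference_line(point2d(0, 0), point2d(100, 0))
  expect_equal(leg_length(ref, point2d(30, 40), cal05), 20)
  expect_equal(leg_length(ref, point2d(70, 0), cal05), 0)

  diag <- reference_line(point2d(0, 0), point2d(100, 100))
  expect_equal(leg_length(diag, point2d(100, 0), cal1), -100 / sqrt(2),
               tolerance = 1e-9)

  # sign is a property of the inferior side, not of point order
  ref_rev <- reference_line(point2d(100, 0), point2d(0, 0))
  expect_equal(leg_length(ref_rev, point2d(30, 40), cal05), 20)

  # doubling the scale doubles leg length
  cal2 <- structure(list(scale_mm_per_px = 2 * cal05$scale_mm_per_px),
                    class = "calibration")
  expect_equal(leg_length(ref, point2d(30, 40), cal2),
               2 * leg_length(ref, point2d(30, 40), cal05))
})

test_that("leg length discrepancy is antisymmetric", {
  expect_equal(leg_length_discrepancy(12, 12), 0)
  expect_equal(leg_length_discrepancy(15, 10), 5)
  set.seed(3)
  a <- runif(50, -30, 30); b <- runif(50, -30, 30)
  expect_equal(leg_length_discrepancy(a, b), -leg_length_discrepancy(b, a))
})

test_that("measure_radiograph recovers known truth at zero noise", {
  rec <- make_record(v_deg = 30, i_deg = 45, ll_mm = 12, scale = 0.5)
  m <- measure_radiograph(rec)
  expect_equal(m$measurements$anteversion_deg, 30, tolerance = 1e-6)
  expect_equal(m$measurements$inclination_deg, 45, tolerance = 1e-6)
  expect_equal(m$measurements$leg_length_mm, 12, tolerance = 1e-6)
  expect_equal(m$scale_mm_per_px, 0.5, tolerance = 1e-12)
})

test_that("angles are invariant to image scale; leg length scales with it", {
  r1 <- make_record(scale = 0.25, v_deg = 22, i_deg = 38, ll_mm = 9)
  r2 <- make_record(scale = 0.5, v_deg = 22, i_deg = 38, ll_mm = 9)
  m1 <- measure_radiograph(r1)$measurements
  m2 <- measure_radiograph(r2)$measurements
  expect_equal(m1$anteversion_deg, m2$anteversion_deg, tolerance = 1e-7)
  expect_equal(m1$inclination_deg, m2$inclination_deg, tolerance = 1e-7)
  expect_equal(m1$leg_length_mm, m2$leg_length_mm, tolerance = 1e-7)
})

test_that("bilateral records yield two measurements with distinct sides", {
  cfg <- sim_config(n_images = 1, bilateral_prob = 1, replicates = 1,
                    rim_noise_sd_px = 0, landmark_noise_sd_px = 0, seed = 11)
  sc <- generate_scene(cfg, 1)
  m <- measure_radiograph(sc$records[[1]])
  expect_equal(nrow(m$measurements), 2L)
  expect_setequal(m$measurements$side, c("left", "right"))
})

test_that("batch measurement skips invalid records without failing", {
  good <- make_record(image_id = "ok")
  bad <- make_record(image_id = "bad")
  bad$calibration$edge_point_b <- bad$calibration$edge_point_a
  out <- measure_annotation_set(annotation_set(list(good, bad)))
  expect_equal(nrow(out), 1L)
  errs <- attr(out, "errors")
  expect_equal(errs$image_id, "bad")
  expect_match(errs$error, "DEGENERATE_MARKER")
})
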