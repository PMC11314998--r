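test_that("parabolic vertex refinement matches a dense-grid quadratic oracle", {
  # oracle: argmax of the interpolating parabola evaluated on a fine grid
  dense_vertex <- function(ym, yc, yp) {
    xs <- seq(-1, 1, by = 1e-5)
    co <- solve(rbind(c(1, -1, 1), c(1, 0, 0), c(1, 1, 1)), c(ym, yc, yp))
    ys <- co[1] + co[2] * xs + co[3] * xs^2
    xs[if (yc >= ym) which.max(ys) else which.min(ys)]
  }
  expect_equal(as.numeric(subpixel_refine(3, 4, 3)), 0)
  expect_equal(as.numeric(subpixel_refine(1, 4, 3)), dense_vertex(1, 4, 3),
               tolerance = 1e-4)
  expect_equal(as.numeric(subpixel_refine(1, 4, 3)), 0.25)
  # scale + offset invariance of the vertex
  expect_equal(as.numeric(subpixel_refine(10, 40, 30)), 0.25)
  # works identically on minima
  expect_equal(as.numeric(subpixel_refine(-1, -4, -3)), dense_vertex(-1, -4, -3),
               tolerance = 1e-4)
  withr::with_seed(5, {
    for (i in 1:25) {
      y <- sort(runif(3, -5, 5))
      tri <- c(y[1], y[3], y[2])  # strict max in the middle
      expect_lt(abs(as.numeric(subpixel_refine(tri[1], tri[2], tri[3])) -
                      dense_vertex(tri[1], tri[2], tri[3])), 1e-4)
    }
  })
})

test_that("refinement flags flat triples and rejects non-extrema", {
  off <- subpixel_refine(4, 4, 4)
  expect_equal(as.numeric(off), 0)
  expect_true(attr(off, "flat"))
  expect_error(subpixel_refine(1, 2, 3), class = "critfocus_error_invalid")
})

test_that("edge pair of a noiseless default render recovers the field width", {
  cfg <- optics_config(noise_sd = 0)
  img <- render_field(cfg, 0, rows = 512)
  pair <- locate_edge_pair(gradient_1d(extract_profile(img)))
  expect_lt(abs(pair$d - cfg$w0), 1)
  expect_lt(abs(pair$d - half_max_width(img)), 1)  # independent oracle
  expect_gt(pair$g_max, 0)
  expect_lt(pair$g_min, 0)
  expect_lt(pair$x_rise, pair$x_fall)
})

test_that("the separation d is immune to lateral displacement of the field", {
  cfg <- small_config()
  for (z in c(0, 10, -15)) {
    ref <- measure_image(render_field(cfg, z))
    for (s in c(-23, -5, 3, 17)) {
      shifted <- measure_image(render_field(cfg, z, offset = s))
      # both edge positions move with the field ...
      expect_equal(shifted$x_rise - ref$x_rise, s, tolerance = 0.02)
      expect_equal(shifted$x_fall - ref$x_fall, s, tolerance = 0.02)
      # ... so their separation does not
      expect_lt(abs(shifted$d_px - ref$d_px), 0.05)
    }
  }
})

test_that("the separation d is exactly invariant under positive intensity scaling", {
  cfg <- small_config(peak_intensity = 20000)
  img <- render_field(cfg, 8)
  ref <- locate_edge_pair(gradient_1d(extract_profile(img)))
  for (c_ in c(0.5, 2.5, 3.2)) {
    scaled <- locate_edge_pair(gradient_1d(extract_profile(unclass(img) * c_)))
    # invariant up to floating-point rounding of the rescaled arithmetic
    expect_equal(scaled$x_rise, ref$x_rise, tolerance = 1e-12)
    expect_equal(scaled$x_fall, ref$x_fall, tolerance = 1e-12)
    expect_equal(scaled$d, ref$d, tolerance = 1e-12)
  }
})

test_that("degenerate gradient profiles are reported as such", {
  expect_error(locate_edge_pair(gradient_1d(rep(5, 20))),
               class = "critfocus_error_no_field")
  # falling edge before rising edge: inverted geometry
  v <- c(10, 10, 0, 0, 0, 10, 10)
  expect_error(locate_edge_pair(gradient_1d(v)),
               class = "critfocus_error_inverted_edges")
  expect_error(locate_edge_pair(gradient_1d(c(1, 2)), refine = FALSE),
               class = "critfocus_error_invalid")
})

test_that("evaluation value is the separation relative to its reference", {
  expect_equal(evaluation_value(3333, 3333), 0)
  expect_equal(evaluation_value(3333 - 24.103, 3333), -24.103)
  expect_equal(evaluation_value(120.5, 0), 120.5)
  expect_error(evaluation_value(Inf, 10), class = "critfocus_error_invalid")
  expect_error(evaluation_value(-5, 10), class = "critfocus_error_invalid")
})

test_that("metric variants behave as the simulation benchmark predicts", {
  cfg <- small_config()
  zs <- seq(-20, 20, by = 5)
  mv <- purrr::map_dfr(zs, function(z) {
    metric_variants(extract_profile(render_field(cfg, z)))
  })
  # position-difference metric is strictly monotone in defocus
  expect_true(all(diff(mv$grad_pos_diff) < 0))
  # gradient-magnitude metric peaks at focus and falls both ways
  i0 <- which(zs == 0)
  expect_equal(which.max(mv$grad_extreme_mag), i0)
  expect_true(all(diff(mv$grad_extreme_mag[1:i0]) > 0))
  expect_true(all(diff(mv$grad_extreme_mag[i0:length(zs)]) < 0))
  # second-derivative localization agrees with the gradient-extremum separation
  expect_true(all(abs(mv$second_pos_diff - mv$grad_pos_diff) < 1))
  expect_true(all(mv$second_extreme_mag >= 0))

  expect_error(metric_variants(new_profile <- extract_profile(matrix(7, 10, 30))),
               class = "critfocus_error_no_field")
})

test_that("magnification follows from the measured separation", {
  expect_equal(estimate_magnification(2000, pixel_pitch = 5, source_width = 1), 10)
  expect_error(estimate_magnification(2000, 5, -1), class = "critfocus_error_invalid")

  # in focus, the recovered magnification is the paraxial product (8/12)*(200/8)
  cfg <- optics_config(noise_sd = 0)
  m <- measure_image(render_field(cfg, 0, rows = 512), smooth_sigma = 0,
                     source_width = cfg$source_width)
  expect_equal(m$mag, (8 / 12) * (200 / 8), tolerance = 1e-3)

  # magnification shrinks with z for a width model with negative alpha
  cfg2 <- small_config()
  mags <- vapply(seq(-20, 20, 10), function(z) {
    measure_image(render_field(cfg2, z), source_width = cfg2$source_width)$mag
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
  # oracle: the width model itself
  expect_equal(mags,
               field_width(cfg2, seq(-20, 20, 10)) * pixel_pitch(cfg2) /
                 (cfg2$source_width * 1000),
               tolerance = 1e-3)
})
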