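# Calibrated scaled-down instrument shared by the controller tests.
ctrl_cfg <- small_config(noise_sd = 10)
ctrl_curve <- calibrate_simulated(ctrl_cfg, seq(-25, 25, 1), seed = 31, rows = 256)
clean_cfg <- small_config()
clean_curve <- calibrate_simulated(clean_cfg, seq(-25, 25, 1), seed = 32, rows = 256)

test_that("single-shot estimates recover the true defocus", {
  for (z in c(0, 10, -15)) {
    est <- single_shot_estimate(render_field(clean_cfg, z), clean_curve)
    expect_lt(abs(est$z_um - z), 0.2)
    expect_false(est$extrapolated)
  }
})

test_that("single-shot estimates are unaffected by lateral field displacement", {
  ref <- single_shot_estimate(render_field(clean_cfg, 10), clean_curve)
  sh <- single_shot_estimate(render_field(clean_cfg, 10, offset = 17), clean_curve)
  expect_lt(abs(sh$z_um - ref$z_um), sensitivity(clean_curve))
})

test_that("estimates outside the calibrated range carry the extrapolation flag", {
  narrow <- calibrate_simulated(clean_cfg, seq(-5, 5, 1), seed = 9, rows = 256)
  est <- single_shot_estimate(render_field(clean_cfg, 20), narrow)
  expect_true(est$extrapolated)
  expect_lt(abs(est$z_um - 20), 1)
})

test_that("multi-frame averaging behaves like a mean of single shots", {
  img <- render_field(ctrl_cfg, 5, seed = 77)
  rep10 <- multi_frame_estimate(rep(list(img), 10), ctrl_curve)
  single <- single_shot_estimate(img, ctrl_curve)
  expect_equal(rep10$z_um, single$z_um)
  expect_equal(rep10$sd_um, 0)
  expect_equal(rep10$n_used, 10L)

  expect_error(multi_frame_estimate(list(), ctrl_curve),
               class = "critfocus_error_invalid")
  # frames without a detectable field are dropped and counted
  flat <- matrix(500, 64, 512)
  mixed <- multi_frame_estimate(list(img, flat), ctrl_curve)
  expect_equal(mixed$n_used, 1L)
  expect_equal(mixed$n_failed, 1L)
  expect_error(multi_frame_estimate(list(flat, flat), ctrl_curve),
               class = "critfocus_error_no_field")
})

test_that("multi-frame error shrinks like one over root n", {
  cfg <- small_config(noise_sd = 250)
  curve <- calibrate_simulated(cfg, seq(-25, 25, 1), seed = 41, rows = 256)
  z_true <- 4
  singles <- vapply(1:30, function(i) {
    single_shot_estimate(render_field(cfg, z_true, seed = 5000 + i), curve)$z_um
  }, numeric(1))
  means16 <- vapply(1:18, function(g) {
    frames <- lapply(1:16, function(i) {
      render_field(cfg, z_true, seed = 90000 + g * 100 + i)
    })
    multi_frame_estimate(frames, curve)$z_um
  }, numeric(1))
  ratio <- sd(means16) / sd(singles)
  expect_gt(ratio, 0.10)   # consistent with 1/4 given the sampling error on sd
  expect_lt(ratio, 0.50)
})

test_that("a stage only moves in exact multiples of the actuator step", {
  act <- actuator_model(min_step = 0.078)
  st <- virtual_stage(ctrl_cfg, start_z = 3.21, actuator = act, seed = 2, rows = 128)
  moves <- vapply(c(-1.9, 0.0339, 2.5001, -0.078), function(dz) stage_move(st, dz),
                  numeric(1))
  expect_true(all(abs(moves / 0.078 - round(moves / 0.078)) < 1e-9))
  expect_equal(stage_position(st),
               3.21 + sum(round(c(-1.9, 0.0339, 2.5001, -0.078) / 0.078) * 0.078),
               tolerance = 1e-12)
  expect_error(stage_move(virtual_stage(ctrl_cfg, actuator = actuator_model(travel = 5)), 20),
               class = "critfocus_error_travel_exceeded")
})

test_that("closed-loop focusing converges and records its trajectory", {
  st <- virtual_stage(ctrl_cfg, start_z = 20, seed = 8, rows = 256)
  res <- closed_loop_focus(st, ctrl_curve, schedule = c(1, 1, 8))
  it <- tidy(res)
  expect_lte(nrow(it), 3)
  expect_equal(it$true_z_before_um[1], 20)
  expect_lt(abs(it$true_z_after_um[1]), 1)            # first correction lands close
  expect_lt(res$final_residual_um, 0.078 + 1e-9)
  expect_true(all(abs(it$move_um / 0.078 - round(it$move_um / 0.078)) < 1e-9))
  gl <- glance(res)
  expect_equal(gl$start_z_um, 20)
  expect_equal(gl$final_residual_um, res$final_residual_um)
})

test_that("an in-focus noiseless start converges immediately without moving", {
  st <- virtual_stage(clean_cfg, start_z = 0, seed = 3, rows = 256)
  res <- closed_loop_focus(st, clean_curve)
  expect_true(res$converged)
  expect_equal(nrow(res$iterations), 1L)
  expect_lte(abs(res$iterations$move_um), 0.078)
  expect_equal(stage_position(st), 0)
})

test_that("the true defocus contracts monotonically down to the actuator floor", {
  # strict non-increase holds above one actuator step; below it the residual
  # may dither by up to half a step, the floor a quantized actuator permits
  starts <- seq(-29, 29, length.out = 100)
  for (i in seq_along(starts)) {
    st <- virtual_stage(ctrl_cfg, start_z = starts[i], seed = 10000 + i, rows = 128)
    res <- closed_loop_focus(st, ctrl_curve, schedule = c(1, 1, 8))
    it <- res$iterations
    expect_true(all(abs(it$true_z_after_um) <=
                      pmax(abs(it$true_z_before_um) + 1e-9, res$min_step)))
  }
})

test_that("the residual floor is set by actuator quantization", {
  # noiseless runs from a dense grid of sub-micron starts: the worst final
  # residual cannot be better than half a step
  starts <- seq(0, 0.468, by = 0.078 / 12)  # includes half-step remainders
  finals <- vapply(seq_along(starts), function(i) {
    st <- virtual_stage(clean_cfg, start_z = starts[i], seed = i, rows = 128)
    closed_loop_focus(st, clean_curve, schedule = c(1, 1, 1))$final_residual_um
  }, numeric(1))
  expect_gte(max(finals), 0.078 / 2 - 0.002)  # noiseless estimator bias margin
  expect_lte(max(finals), 0.078 + 1e-9)
})

test_that("schedules shorter than the iteration budget are rejected", {
  st <- virtual_stage(ctrl_cfg, start_z = 5, seed = 1, rows = 128)
  expect_error(closed_loop_focus(st, ctrl_curve, schedule = c(1, 1), max_iter = 3),
               class = "critfocus_error_invalid")
})

test_that("focus runs serialize as JSON-lines", {
  st <- virtual_stage(ctrl_cfg, start_z = 12, seed = 4, rows = 128)
  res <- closed_loop_focus(st, ctrl_curve, schedule = c(1, 2))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_focus_log(res, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(res$iterations) + 1L)
  header <- jsonlite::fromJSON(lines[1])
  expect_equal(header$min_step, 0.078)
  expect_equal(header$final_residual_um, res$final_residual_um, tolerance = 1e-12)
})
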