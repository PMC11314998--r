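#' Actuator model for the virtual focusing stage
#'
#' @param min_step Smallest commandable displacement, um (default 0.078, i.e.
#'   78 nm).
#' @param travel Commandable range, um.
#' @param latency Informational move latency, ms (never asserted).
#' @return An `actuator_model`.
#' @export
actuator_model <- function(min_step = 0.078, travel = 1e5, latency = 100) {
  check_number(min_step, "min_step", positive = TRUE)
  check_number(travel, "travel", positive = TRUE)
  structure(list(min_step = min_step, travel = travel, latency = latency),
            class = "actuator_model")
}

#' Virtual stage holding a simulated specimen at some true defocus
#'
#' A mutable stand-in for the camera + z-actuator pair: `stage_capture()`
#' renders seeded frames at the current true defocus and `stage_move()`
#' displaces the specimen by a command quantized to integer multiples of the
#' actuator minimum step. The true defocus is simulation ground truth; a real
#' instrument never observes it.
#'
#' @param optics An [optics_config()].
#' @param start_z Initial true defocus, um.
#' @param actuator An [actuator_model()].
#' @param seed Master seed for the stage's frame-seed stream.
#' @param rows Central detector rows rendered per captured frame.
#' @return A `virtual_stage` (environment).
#' @export
virtual_stage <- function(optics, start_z = 0, actuator = actuator_model(),
                          seed = 1, rows = 1024) {
  stopifnot(inherits(optics, "optics_config"), inherits(actuator, "actuator_model"))
  check_number(start_z, "start_z")
  env <- new.env(parent = emptyenv())
  env$true_z <- start_z
  env$optics <- optics
  env$actuator <- actuator
  env$seed <- as.integer(seed)
  env$counter <- 0L
  env$rows <- rows
  class(env) <- "virtual_stage"
  env
}

#' @export
print.virtual_stage <- function(x, ...) {
  cat(sprintf("<virtual_stage> true z = %.4f um, min step %g um, %d frames captured\n",
              x$true_z, x$actuator$min_step, x$counter))
  invisible(x)
}

#' @rdname virtual_stage
#' @param stage A `virtual_stage`.
#' @param n Number of frames to capture.
#' @return `stage_capture()`: a list of `field_image`s at the current true
#'   defocus (seeds advance deterministically).
#' @export
stage_capture <- function(stage, n = 1) {
  stopifnot(inherits(stage, "virtual_stage"))
  lapply(seq_len(n), function(i) {
    stage$counter <- stage$counter + 1L
    render_field(stage$optics, stage$true_z,
                 seed = derive_seed(stage$seed, stage$counter),
                 rows = stage$rows)
  })
}

#' @rdname virtual_stage
#' @param dz Commanded displacement of the specimen's defocus, um; the
#'   executed move is `round(dz / min_step) * min_step`.
#' @return `stage_move()`: the executed (quantized) move in um, invisibly.
#' @export
stage_move <- function(stage, dz) {
  stopifnot(inherits(stage, "virtual_stage"))
  check_number(dz, "dz")
  step <- stage$actuator$min_step
  executed <- round(dz / step) * step
  if (abs(executed) > stage$actuator$travel) {
    stop_travel(sprintf("travel-exceeded: commanded move %.3f um exceeds travel %g um",
                        executed, stage$actuator$travel))
  }
  stage$true_z <- stage$true_z + executed
  invisible(executed)
}

#' @rdname virtual_stage
#' @export
stage_position <- function(stage) {
  stopifnot(inherits(stage, "virtual_stage"))
  stage$true_z
}

#' Single-shot defocus estimate from one image
#'
#' The full detection pipeline: band profile, optional matched-filter
#' smoothing, forward-difference gradient, sub-pixel edge-pair localization,
#' evaluation value `t = d - d0`, inversion through the calibrated standard
#' evaluation curve.
#'
#' @param image A `field_image`.
#' @param curve An `evaluation_curve`.
#' @inheritParams measure_image
#' @return A one-row tibble: `z_um` (the estimate), `extrapolated`, `d_px`,
#'   `t_px`, `x_rise`, `x_fall`, `g_max`, `g_min`, `flat`.
#' @export
single_shot_estimate <- function(image, curve, band_fraction = 0.5,
                                 smooth_sigma = 8, refine = TRUE) {
  stopifnot(inherits(curve, "evaluation_curve"))
  m <- measure_image(image, band_fraction = band_fraction,
                     smooth_sigma = smooth_sigma, refine = refine)
  t_px <- evaluation_value(m$d_px, curve$d0)
  inv <- invert_curve(curve, t_px)
  tibble(
    z_um = inv$z_um, extrapolated = inv$extrapolated,
    d_px = m$d_px, t_px = t_px,
    x_rise = m$x_rise, x_fall = m$x_fall,
    g_max = m$g_max, g_min = m$g_min, flat = m$flat
  )
}

#' Multi-frame averaged defocus estimate
#'
#' Per-frame single-shot estimates are averaged; under frame-independent
#' noise the standard error shrinks as 1/sqrt(n). Frames on which edge
#' detection fails are dropped and counted.
#'
#' @param images A non-empty list of `field_image`s.
#' @param curve An `evaluation_curve`.
#' @inheritParams measure_image
#' @return A one-row tibble: `z_um` (mean estimate), `sd_um` (per-frame
#'   spread; `NA` for a single frame), `n_used`, `n_failed`, `extrapolated`
#'   (any frame flagged).
#' @export
multi_frame_estimate <- function(images, curve, band_fraction = 0.5,
                                 smooth_sigma = 8, refine = TRUE) {
  if (!is.list(images) || length(images) == 0L) {
    stop_invalid("`images` must be a non-empty list of field images")
  }
  ests <- purrr::map(images, function(img) {
    tryCatch(
      single_shot_estimate(img, curve, band_fraction = band_fraction,
                           smooth_sigma = smooth_sigma, refine = refine),
      critfocus_error_no_field = function(e) NULL,
      critfocus_error_inverted_edges = function(e) NULL
    )
  })
  ok <- !vapply(ests, is.null, logical(1))
  if (!any(ok)) {
    stop_no_field("no-field-detected: edge detection failed on every frame")
  }
  z <- vapply(ests[ok], function(e) e$z_um, numeric(1))
  tibble(
    z_um = mean(z),
    sd_um = if (length(z) > 1L) sd(z) else NA_real_,
    n_used = length(z),
    n_failed = sum(!ok),
    extrapolated = any(vapply(ests[ok], function(e) e$extrapolated, logical(1)))
  )
}

#' Closed-loop iterative autofocus against a virtual stage
#'
#' Each iteration captures `schedule[i]` frames at the stage's current state,
#' estimates the defocus (multi-frame averaged when `schedule[i] > 1`),
#' commands the actuator by the quantized negative of the estimate
#' (proportional gain 1; the evaluation curve is effectively linear, so no
#' damping is needed; estimates below half a step quantize to no move), and
#' then stops once the estimate magnitude is within `stop_tol`. The default
#' schedule `c(1, 1, 16)` performs two fast single-frame corrections that
#' bring a start anywhere in the calibrated wide range down to the
#' quantization scale, then one 16-frame averaged trim whose 1/sqrt(n) noise
#' reduction sits below the actuator minimum step. A frame on which edge
#' detection fails is retried once; a second failure aborts the run.
#'
#' @param stage A [virtual_stage()].
#' @param curve An `evaluation_curve`.
#' @param schedule Frames per iteration; `length(schedule) >= max_iter`.
#' @param max_iter Maximum iterations.
#' @param stop_tol Stop when |estimate| falls at or below this, um; defaults
#'   to the actuator minimum step.
#' @inheritParams measure_image
#' @return A `focus_result`: list with `iterations` (tibble: `iteration`,
#'   `frames_used`, `z_estimate_um`, `estimate_sd_um`, `true_z_before_um`,
#'   `move_um`, `true_z_after_um`, `extrapolated`, `retried`, `stopped`),
#'   `final_residual_um` (|true z| after the last move — ground truth, known
#'   only in simulation), `converged`, `stop_tol`, `min_step`. Methods:
#'   [tidy()], [glance()], [autoplot()], `print()`.
#' @export
closed_loop_focus <- function(stage, curve, schedule = c(1, 1, 16),
                              max_iter = length(schedule),
                              stop_tol = stage$actuator$min_step,
                              band_fraction = 0.5, smooth_sigma = 8,
                              refine = TRUE) {
  stopifnot(inherits(stage, "virtual_stage"), inherits(curve, "evaluation_curve"))
  if (max_iter < 1 || length(schedule) < max_iter) {
    stop_invalid("`schedule` must provide a frame count for each of `max_iter` iterations")
  }
  rows <- vector("list", max_iter)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    est <- NULL
    retried <- FALSE
    for (attempt in 1:2) {
      est <- tryCatch({
        frames <- stage_capture(stage, schedule[i])
        multi_frame_estimate(frames, curve, band_fraction = band_fraction,
                             smooth_sigma = smooth_sigma, refine = refine)
      },
      critfocus_error_no_field = function(e) NULL,
      critfocus_error_inverted_edges = function(e) NULL)
      if (!is.null(est)) break
      retried <- TRUE
    }
    if (is.null(est)) {
      stop_no_field(sprintf(
        "no-field-detected: detection failed twice at iteration %d (true z = %.2f um)", i, stage$true_z))
    }
    before <- stage$true_z
    # always command the quantized correction (a sub-half-step estimate
    # quantizes to no move), then stop once the estimate is within tolerance:
    # the last executed iteration thereby always leaves a fresh quantization
    # remainder rather than an unverified earlier residual
    move <- stage_move(stage, -est$z_um)
    stopped <- abs(est$z_um) <= stop_tol
    rows[[i]] <- tibble(
      iteration = i, frames_used = est$n_used,
      z_estimate_um = est$z_um, estimate_sd_um = est$sd_um,
      true_z_before_um = before, move_um = move,
      true_z_after_um = stage$true_z,
      extrapolated = est$extrapolated, retried = retried, stopped = stopped
    )
    if (stopped) {
      converged <- TRUE
      break
    }
  }
  iterations <- dplyr::bind_rows(rows)
  structure(
    list(
      iterations = iterations,
      final_residual_um = abs(stage$true_z),
      converged = converged,
      stop_tol = stop_tol,
      min_step = stage$actuator$min_step
    ),
    class = "focus_result"
  )
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("<focus_result> %d iteration(s), converged: %s\n",
              nrow(x$iterations), x$converged))
  cat(sprintf("  final residual %.4f um (stop tolerance %g um, actuator step %g um)\n",
              x$final_residual_um, x$stop_tol, x$min_step))
  invisible(x)
}

#' @rdname closed_loop_focus
#' @param x,object A `focus_result`.
#' @param ... Unused.
#' @export
tidy.focus_result <- function(x, ...) {
  x$iterations
}

#' @rdname closed_loop_focus
#' @export
glance.focus_result <- function(x, ...) {
  tibble(
    n_iterations = nrow(x$iterations),
    frames_total = sum(x$iterations$frames_used),
    start_z_um = x$iterations$true_z_before_um[1],
    final_residual_um = x$final_residual_um,
    converged = x$converged
  )
}

#' Write a focus run as JSON-lines
#'
#' One JSON object per iteration (index, frames, estimate, move, flags),
#' preceded by a header object carrying the stop tolerance and actuator step.
#'
#' @param result A `focus_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_focus_log <- function(result, path) {
  stopifnot(inherits(result, "focus_result"))
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(type = "header", stop_tol = result$stop_tol,
                 min_step = result$min_step, converged = result$converged,
                 final_residual_um = result$final_residual_um)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(result$iterations))) {
    writeLines(jsonlite::toJSON(as.list(result$iterations[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
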