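#' Sub-pixel refinement of a sampled extremum
#'
#' Parabolic-vertex interpolation through three consecutive samples around a
#' strict local extremum: the returned offset,
#' \deqn{\delta = \frac{1}{2}\,\frac{y_- - y_+}{y_- - 2 y_c + y_+} \in (-0.5, 0.5],}
#' is added to the integer index of the central sample. The formula is
#' invariant under positive scaling and offset of the three values.
#'
#' @param y_minus,y_center,y_plus Sample values at indices i-1, i, i+1;
#'   `y_center` must be a strict extremum of the triple.
#' @return The sub-pixel offset in px, with attribute `flat = TRUE` when the
#'   triple is degenerate (zero curvature; offset 0 is returned).
#' @examples
#' subpixel_refine(3, 4, 3)   # 0
#' subpixel_refine(1, 4, 3)   # 0.25
#' @export
subpixel_refine <- function(y_minus, y_center, y_plus) {
  check_number(y_minus, "y_minus")
  check_number(y_center, "y_center")
  check_number(y_plus, "y_plus")
  is_max <- y_center >= y_minus && y_center >= y_plus
  is_min <- y_center <= y_minus && y_center <= y_plus
  if (!is_max && !is_min) {
    stop_invalid("`y_center` must be a local extremum of the triple")
  }
  denom <- y_minus - 2 * y_center + y_plus
  if (denom == 0) {
    return(structure(0, flat = TRUE))
  }
  structure(0.5 * (y_minus - y_plus) / denom, flat = FALSE)
}

refine_at <- function(values, x, i, refine) {
  n <- length(values)
  flat <- FALSE
  off <- 0
  if (refine && i > 1L && i < n) {
    off <- subpixel_refine(values[i - 1L], values[i], values[i + 1L])
    flat <- isTRUE(attr(off, "flat"))
  } else if (refine) {
    flat <- TRUE  # extremum at the array boundary cannot be refined
  }
  list(x = x[i] + as.numeric(off), flat = flat)
}

#' Locate the rising/falling edge-gradient extremum pair
#'
#' The square field has exactly one rising and one falling edge, so the
#' rising-edge position is taken from the global maximum of the first-order
#' gradient profile and the falling-edge position from the global minimum
#' (ties resolve to the smaller index), each refined to sub-pixel precision
#' with [subpixel_refine()] when `refine = TRUE`. Their separation
#' `d = x_fall - x_rise` is the defocus metric; it is unchanged by lateral
#' displacement of the field and by positive intensity scaling.
#'
#' @param grad A `gradient_profile` of order 1 with at least 3 samples.
#' @param refine Apply parabolic sub-pixel refinement (default `TRUE`).
#' @return A one-row tibble: `x_rise`, `x_fall`, `g_max`, `g_min`, `d`
#'   (all px or counts/px) and `flat` (whether either refinement was
#'   degenerate).
#' @examples
#' cfg <- optics_config(detector_pixels = 400, source_width = 0.1,
#'                      noise_sd = 0, z_range = c(-30, 30))
#' prof <- extract_profile(render_field(cfg, 0))
#' locate_edge_pair(gradient_1d(prof))
#' @export
locate_edge_pair <- function(grad, refine = TRUE) {
  ord <- attr(grad, "order")
  if (!is.null(ord) && ord != 1L) {
    stop_invalid("`grad` must be a first-order gradient profile")
  }
  v <- profile_values(grad)
  x <- profile_x(grad)
  if (length(v) < 3L) stop_invalid("`grad` must have at least 3 samples")
  i_max <- which.max(v)
  i_min <- which.min(v)
  if (!(v[i_max] > 0) || !(v[i_min] < 0)) stop_no_field()
  if (i_max >= i_min) stop_inverted()
  rise <- refine_at(v, x, i_max, refine)
  fall <- refine_at(v, x, i_min, refine)
  tibble(
    x_rise = rise$x, x_fall = fall$x,
    g_max = v[i_max], g_min = v[i_min],
    d = fall$x - rise$x,
    flat = rise$flat || fall$flat
  )
}

#' Defocus evaluation value
#'
#' The evaluation value is the measured edge separation relative to its
#' in-focus reference: `t = d - d0`. At best focus `t = 0`; over the working
#' range `t` is linear in defocus with slope `k` (the standard evaluation
#' curve).
#'
#' @param d Measured edge separation, px (> 0).
#' @param d0 Reference (in-focus) separation, px (>= 0); normally the fitted
#'   value at z = 0 from [fit_evaluation_curve()].
#' @return `t` in px (vectorised).
#' @export
evaluation_value <- function(d, d0) {
  if (!is.numeric(d) || !is.numeric(d0) || !all(is.finite(d)) || !all(is.finite(d0))) {
    stop_invalid("`d` and `d0` must be finite numbers")
  }
  if (any(d <= 0)) stop_invalid("`d` must be strictly positive")
  if (any(d0 < 0)) stop_invalid("`d0` must be non-negative")
  d - d0
}

# Sub-pixel zero-crossing of the second-derivative profile nearest `near_x`,
# with the requested sign change ("down" = + to -, at a rising edge; "up" =
# - to +, at a falling edge). This is Laplacian zero-crossing edge
# localization: the crossing between the two second-derivative lobes of a
# blurred edge coincides with the first-derivative extremum.
zero_crossing_near <- function(g2, near_x, direction = c("down", "up")) {
  direction <- match.arg(direction)
  v <- profile_values(g2)
  x <- profile_x(g2)
  n <- length(v)
  s <- if (direction == "down") v else -v
  idx <- which(s[-n] > 0 & s[-1L] <= 0)
  if (length(idx) == 0L) stop_no_field()
  xc <- x[idx] + (x[idx + 1L] - x[idx]) * s[idx] / (s[idx] - s[idx + 1L])
  xc[which.min(abs(xc - near_x))]
}

#' Alternative defocus metrics from one profile
#'
#' Computes the four scalar evaluation-metric candidates from the same
#' profile: the mean absolute first-order gradient extremum
#' (`grad_extreme_mag`), the gradient extremum position difference
#' (`grad_pos_diff`, i.e. `d`), the mean absolute second-derivative extremum
#' (`second_extreme_mag`) and the separation of the second-derivative edge
#' localizations (`second_pos_diff`). The second-derivative edge position is
#' taken as the zero-crossing between the two second-derivative lobes of each
#' edge, which coincides with the gradient extremum of that edge; raw
#' second-derivative extrema straddle the edge at plus/minus one blur width
#' and do not measure the field width. The gradient-magnitude metric peaks at
#' focus and falls both ways (direction-blind); the position-difference
#' metrics are monotone in defocus.
#'
#' @param profile An `intensity_profile`.
#' @param refine Apply sub-pixel refinement to the gradient extrema.
#' @return A one-row tibble: `grad_extreme_mag` (counts/px),
#'   `grad_pos_diff` (px), `second_extreme_mag` (counts/px^2),
#'   `second_pos_diff` (px).
#' @export
metric_variants <- function(profile, refine = TRUE) {
  g1 <- gradient_1d(profile)
  pair <- locate_edge_pair(g1, refine = refine)
  g2 <- second_derivative_1d(profile)
  x_rise2 <- zero_crossing_near(g2, pair$x_rise, "down")
  x_fall2 <- zero_crossing_near(g2, pair$x_fall, "up")
  v2 <- profile_values(g2)
  tibble(
    grad_extreme_mag = mean(c(abs(pair$g_max), abs(pair$g_min))),
    grad_pos_diff = pair$d,
    second_extreme_mag = mean(c(abs(max(v2)), abs(min(v2)))),
    second_pos_diff = x_fall2 - x_rise2
  )
}

#' System magnification from the measured edge separation
#'
#' Under defocus the usual conjugate relations no longer give the
#' magnification, but the imaged field width still does: comparing the
#' measured inter-edge distance with the known source size yields the total
#' source-to-detector magnification at the current focus state,
#' `M = d * pixel_pitch / source_width`.
#'
#' @param pair An edge-pair tibble from [locate_edge_pair()], or a numeric
#'   separation `d` in px.
#' @param pixel_pitch Detector pixel pitch, um/px.
#' @param source_width Source side, mm.
#' @return Magnification (unitless, vectorised).
#' @examples
#' estimate_magnification(2000, pixel_pitch = 5, source_width = 1)  # 10
#' @export
estimate_magnification <- function(pair, pixel_pitch, source_width) {
  d <- if (is.data.frame(pair)) pair$d else pair
  if (!is.numeric(d) || !all(is.finite(d))) stop_invalid("`pair` must carry a finite separation d")
  check_number(pixel_pitch, "pixel_pitch", positive = TRUE)
  check_number(source_width, "source_width", positive = TRUE)
  d * pixel_pitch / (source_width * 1000)
}

#' Edge metrics of a single field image
#'
#' Runs the measurement pipeline profile -> (optional smoothing) -> gradient
#' -> edge pair on one image and returns a one-row record.
#'
#' @param image A `field_image`.
#' @param band_fraction Passed to [extract_profile()].
#' @param smooth_sigma Gaussian pre-smoothing scale in px (0 disables); the
#'   default 8 px is matched to the defocused edge blur of the default optics.
#' @param refine Sub-pixel refinement flag.
#' @param source_width Source side in mm for the magnification column;
#'   `NULL` omits it.
#' @return One-row tibble: `true_z_um` (NA when unknown), `x_rise`, `x_fall`,
#'   `d_px`, `g_max`, `g_min`, `flat`, and `mag` when `source_width` is given.
#' @export
measure_image <- function(image, band_fraction = 0.5, smooth_sigma = 8,
                          refine = TRUE, source_width = NULL) {
  prof <- extract_profile(image, band_fraction = band_fraction)
  if (smooth_sigma > 0) prof <- smooth_profile(prof, smooth_sigma)
  pair <- locate_edge_pair(gradient_1d(prof), refine = refine)
  out <- tibble(
    true_z_um = attr(image, "true_z") %||% NA_real_,
    x_rise = pair$x_rise, x_fall = pair$x_fall, d_px = pair$d,
    g_max = pair$g_max, g_min = pair$g_min, flat = pair$flat
  )
  if (!is.null(source_width)) {
    pitch <- attr(image, "pixel_pitch")
    out$mag <- estimate_magnification(pair$d, pitch, source_width)
  }
  out
}

#' Simulate a defocus series and measure its edge metrics (streaming)
#'
#' Renders one frame at a time from the simulator, measures it, and discards
#' the raster, so arbitrarily long stacks can be processed in constant
#' memory. This is the workhorse behind calibration and the benchmark
#' tables.
#'
#' @inheritParams render_stack
#' @inheritParams measure_image
#' @param rows Central detector rows to render per frame (the analysis band);
#'   default 1024.
#' @param variants Also compute [metric_variants()] per frame.
#' @return A tibble with one row per frame: `z_um`, `frame`, `seed`, the
#'   [measure_image()] columns, `mag`, and the variant metrics when requested.
#' @export
simulate_edge_metrics <- function(config, z_values, frames_per_z = 1,
                                  seed = NULL, rows = 1024,
                                  band_fraction = 0.5, smooth_sigma = 8,
                                  refine = TRUE, offset = 0,
                                  intensity_scale = 1, variants = FALSE) {
  stopifnot(inherits(config, "optics_config"))
  if (length(z_values) == 0L || !is.numeric(z_values)) {
    stop_invalid("`z_values` must be a non-empty numeric vector")
  }
  if (frames_per_z < 1) stop_invalid("`frames_per_z` must be >= 1")
  grid <- tidyr::expand_grid(z_um = as.numeric(z_values),
                             frame = seq_len(frames_per_z))
  master <- if (is.null(seed)) sample.int(2147483646, 1) else as.integer(seed)
  grid$seed <- vapply(seq_len(nrow(grid)), function(i) derive_seed(master, i),
                      numeric(1))
  res <- purrr::pmap(list(grid$z_um, grid$seed), function(z, s) {
    img <- render_field(config, z, offset = offset,
                        intensity_scale = intensity_scale, seed = s,
                        rows = rows)
    m <- measure_image(img, band_fraction = band_fraction,
                       smooth_sigma = smooth_sigma, refine = refine,
                       source_width = config$source_width)
    if (variants) {
      prof <- extract_profile(img, band_fraction = band_fraction)
      if (smooth_sigma > 0) prof <- smooth_profile(prof, smooth_sigma)
      m <- dplyr::bind_cols(m, metric_variants(prof, refine = refine))
    }
    m
  })
  res <- dplyr::bind_rows(res)
  res$true_z_um <- NULL
  dplyr::bind_cols(grid, res)
}
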