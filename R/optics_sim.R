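#' Optics and detector configuration for the field simulator
#'
#' Describes the critical-illumination geometry of a sequencing microscope and
#' the phenomenological defocus model used by [render_field()]. The square
#' source (a multimode fiber end-face) is imaged onto the specimen by the
#' collimator/objective pair and re-imaged onto the detector by the
#' objective/tube-lens pair, so the in-focus field width on the detector is
#'
#' \deqn{w_0 = \mathrm{source\_width} \cdot \frac{f_{tube}}{f_{col}} / \mathrm{pixel\ pitch}.}
#'
#' Defocus `z` (micrometres; negative toward the objective) changes the
#' conjugate width as \eqn{w(z) = w_0 (1 + \alpha z + \gamma z^2)} and blurs
#' each edge with a Gaussian of scale \eqn{\sigma(z) = \sigma_0 + \beta |z|}.
#'
#' @param f_obj Objective focal length, mm.
#' @param f_col Collimator focal length, mm.
#' @param f_tube Tube-lens focal length, mm.
#' @param source_width Side of the square source, mm.
#' @param detector_side Detector side, mm.
#' @param detector_pixels Pixels per detector axis.
#' @param w0 In-focus field width on the detector, px. Defaults to the
#'   paraxial value `source_width * (f_tube / f_col) / pixel pitch`.
#' @param alpha Fractional field-width change per micrometre of defocus
#'   (1/um). Negative: the field shrinks as `z` increases away from the lens.
#'   The default -1e-3/um corresponds to a 0.1%/um width change, the scale set
#'   by the illumination numerical aperture of the modelled geometry.
#' @param gamma Quadratic width-nonlinearity coefficient (1/um^2), emulating
#'   the mild departure from linearity seen at large defocus.
#' @param sigma0 In-focus edge blur, px.
#' @param beta Edge-blur growth with defocus, px/um.
#' @param peak_intensity Plateau level over background, detector counts.
#' @param background Offset level, counts.
#' @param noise_sd Additive Gaussian read-noise standard deviation, counts.
#' @param shot_noise If `TRUE`, also draw per-pixel Poisson shot noise on the
#'   expected counts (default off).
#' @param z_range Declared simulation range `c(min, max)` in um; renders are
#'   refused outside it.
#'
#' @return An object of class `optics_config`.
#' @examples
#' cfg <- optics_config()
#' field_width(cfg, 0)      # ~3333 px on the default geometry
#' pixel_pitch(cfg)         # 5 um/px
#' @export
optics_config <- function(f_obj = 8, f_col = 12, f_tube = 200,
                          source_width = 1, detector_side = 20,
                          detector_pixels = 4000L,
                          w0 = NULL,
                          alpha = -1e-3, gamma = 6e-8,
                          sigma0 = 2, beta = 0.5,
                          peak_intensity = 60000, background = 500,
                          noise_sd = 250, shot_noise = FALSE,
                          z_range = c(-100, 100)) {
  for (nm in c("f_obj", "f_col", "f_tube", "source_width", "detector_side",
               "peak_intensity", "sigma0")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  check_number(detector_pixels, "detector_pixels", positive = TRUE)
  check_number(background, "background")
  check_number(noise_sd, "noise_sd")
  check_number(beta, "beta")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (beta < 0) stop_invalid("`beta` must be >= 0")
  if (length(z_range) != 2L || !all(is.finite(z_range)) || z_range[1] >= z_range[2]) {
    stop_invalid("`z_range` must be c(min, max) with min < max")
  }
  detector_pixels <- as.integer(detector_pixels)
  pitch_um <- detector_side / detector_pixels * 1000
  if (is.null(w0)) {
    w0 <- source_width * (f_tube / f_col) * 1000 / pitch_um
  }
  check_number(w0, "w0", positive = TRUE)

  cfg <- structure(
    list(
      f_obj = f_obj, f_col = f_col, f_tube = f_tube,
      source_width = source_width, detector_side = detector_side,
      detector_pixels = detector_pixels,
      w0 = w0, alpha = alpha, gamma = gamma,
      sigma0 = sigma0, beta = beta,
      peak_intensity = peak_intensity, background = background,
      noise_sd = noise_sd, shot_noise = isTRUE(shot_noise),
      z_range = as.numeric(z_range)
    ),
    class = "optics_config"
  )

  # the field (plateau plus blurred skirts) must stay on the detector over the
  # declared range; check the endpoints and the vertex of the width parabola
  zs <- cfg$z_range
  if (gamma != 0) {
    zv <- -alpha / (2 * gamma)
    if (zv > zs[1] && zv < zs[2]) zs <- c(zs, zv)
  }
  for (z in zs) {
    check_field_bounds(cfg, z, offset = 0)
  }
  cfg
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  lenses: f_obj %g mm, f_col %g mm, f_tube %g mm\n",
              x$f_obj, x$f_col, x$f_tube))
  cat(sprintf("  source %g mm square -> w0 = %.1f px on %d x %d px detector (%g um/px)\n",
              x$source_width, x$w0, x$detector_pixels, x$detector_pixels,
              pixel_pitch(x)))
  cat(sprintf("  width model: alpha %.3g /um, gamma %.3g /um^2; blur sigma0 %g px + %g px/um\n",
              x$alpha, x$gamma, x$sigma0, x$beta))
  cat(sprintf("  plateau %g counts over %g, noise sd %g; z range [%g, %g] um\n",
              x$peak_intensity, x$background, x$noise_sd,
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' Detector pixel pitch
#'
#' @param config An [optics_config()].
#' @return Pixel pitch in micrometres per pixel.
#' @export
pixel_pitch <- function(config) {
  stopifnot(inherits(config, "optics_config"))
  config$detector_side / config$detector_pixels * 1000
}

#' Modelled field width and edge blur at a given defocus
#'
#' `field_width()` evaluates \eqn{w(z) = w_0(1 + \alpha z + \gamma z^2)} and
#' `edge_blur()` evaluates \eqn{\sigma(z) = \sigma_0 + \beta |z|}, both in
#' detector pixels.
#'
#' @param config An [optics_config()].
#' @param z Defocus in micrometres (vectorised).
#' @return Numeric vector, px.
#' @export
field_width <- function(config, z) {
  stopifnot(inherits(config, "optics_config"))
  config$w0 * (1 + config$alpha * z + config$gamma * z^2)
}

#' @rdname field_width
#' @export
edge_blur <- function(config, z) {
  stopifnot(inherits(config, "optics_config"))
  config$sigma0 + config$beta * abs(z)
}

# The edge position plus three blur widths (and any lateral offset) must stay
# inside the detector, otherwise the edge extrema are not measurable.
check_field_bounds <- function(config, z, offset = 0) {
  half <- field_width(config, z) / 2
  margin <- half + 3 * edge_blur(config, z) + abs(offset)
  if (margin > config$detector_pixels / 2) {
    stop_out_of_bounds(sprintf(
      "field-out-of-bounds: at z = %g um the field (half-width %.1f px + blur) leaves the %d px detector",
      z, half, config$detector_pixels))
  }
  invisible(TRUE)
}

new_field_image <- function(pixels, pixel_pitch, true_z = NA_real_,
                            lateral_offset = 0, band = NULL) {
  structure(
    pixels,
    pixel_pitch = pixel_pitch,
    true_z = true_z,
    lateral_offset = lateral_offset,
    band = band,
    class = c("field_image", "matrix", "array")
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px, %g um/px", nrow(x), ncol(x),
              attr(x, "pixel_pitch")))
  if (!is.na(attr(x, "true_z"))) cat(sprintf(", true z = %g um", attr(x, "true_z")))
  cat(sprintf(", range [%g, %g] counts\n", min(x), max(x)))
  invisible(x)
}

#' Render a defocused critical-illumination field image
#'
#' Generates the conjugate image of the square excitation field as seen by the
#' detector at defocus `z`: a plateau of width `field_width(config, z)` px
#' centred at the detector centre plus `offset`, each edge convolved with a
#' Gaussian of scale `edge_blur(config, z)`, at level
#' `peak_intensity * intensity_scale` over `background`, with additive Gaussian
#' noise of standard deviation `noise_sd` (and optional Poisson shot noise).
#' Identical `(config, z, offset, intensity_scale, seed)` give a bit-identical
#' raster.
#'
#' @param config An [optics_config()].
#' @param z Defocus, um; must lie within `config$z_range`.
#' @param offset Lateral (x) shift of the field centre, px.
#' @param intensity_scale Multiplier on the plateau level (laser power
#'   fluctuation); must be > 0.
#' @param seed Integer seed for the noise draw; `NULL` uses the current RNG
#'   state (renders are then not reproducible).
#' @param rows Number of central detector rows to render; `NULL` renders the
#'   full frame. The 1-D analysis only uses a central band, and a cropped
#'   render is marked by its `band` attribute (rows of the full frame).
#' @return A `field_image`: a numeric matrix of detector counts (clamped to
#'   the 16-bit range) with `pixel_pitch`, `true_z`, `lateral_offset` and
#'   `band` attributes.
#' @examples
#' cfg <- optics_config(detector_pixels = 400, source_width = 0.1,
#'                      noise_sd = 0, z_range = c(-30, 30))
#' img <- render_field(cfg, z = 0, seed = 1)
#' dim(img)
#' @export
render_field <- function(config, z, offset = 0, intensity_scale = 1,
                         seed = NULL, rows = NULL) {
  stopifnot(inherits(config, "optics_config"))
  check_number(z, "z")
  check_number(offset, "offset")
  check_number(intensity_scale, "intensity_scale", positive = TRUE)
  if (z < config$z_range[1] || z > config$z_range[2]) {
    stop_out_of_bounds(sprintf(
      "field-out-of-bounds: z = %g um outside the declared simulation range [%g, %g]",
      z, config$z_range[1], config$z_range[2]))
  }
  check_field_bounds(config, z, offset)

  n <- config$detector_pixels
  rows <- if (is.null(rows)) n else min(as.integer(rows), n)
  if (rows < 1L) stop_invalid("`rows` must be >= 1")
  r0 <- (n - rows) %/% 2L           # 0-based first row of the crop
  row_idx <- r0 + seq_len(rows) - 1 # 0-based row coordinates

  half <- field_width(config, z) / 2
  sig <- edge_blur(config, z)
  cx <- (n - 1) / 2 + offset
  cy <- (n - 1) / 2
  xs <- seq_len(n) - 1

  ex <- pnorm((xs - (cx - half)) / sig) - pnorm((xs - (cx + half)) / sig)
  ey <- pnorm((row_idx - (cy - half)) / sig) - pnorm((row_idx - (cy + half)) / sig)

  img <- config$background +
    (config$peak_intensity * intensity_scale) * outer(ey, ex)

  add_noise <- function(m) {
    if (config$shot_noise) {
      m[] <- rpois(length(m), lambda = pmax(m, 0))
    }
    if (config$noise_sd > 0) {
      m <- m + rnorm(length(m), sd = config$noise_sd)
    }
    m
  }
  if (!is.null(seed)) {
    img <- withr::with_seed(as.integer(seed), add_noise(img))
  } else if (config$noise_sd > 0 || config$shot_noise) {
    img <- add_noise(img)
  }

  img[img < 0] <- 0
  img[img > 65535] <- 65535
  new_field_image(img, pixel_pitch(config), true_z = z,
                  lateral_offset = offset,
                  band = c(r0 + 1L, r0 + rows))
}

#' Render a seeded stack of field images over a defocus grid
#'
#' One image per `(z, frame)` combination, with per-frame seeds derived
#' deterministically from the master seed, so the full stack is reproducible
#' from `(config, seed)`.
#'
#' @inheritParams render_field
#' @param z_values Defocus values, um (non-empty).
#' @param frames_per_z Frames per defocus value (>= 1).
#' @param seed Master seed.
#' @return A tibble with columns `z_um`, `frame`, `seed` and a list-column
#'   `image` of `field_image` objects. For large stacks at full detector size
#'   prefer the streaming [simulate_edge_metrics()], which never holds more
#'   than one frame.
#' @export
render_stack <- function(config, z_values, frames_per_z = 1, seed = NULL,
                         rows = NULL, offset = 0, intensity_scale = 1) {
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
  grid$image <- purrr::pmap(
    list(grid$z_um, grid$seed),
    function(z, s) render_field(config, z, offset = offset,
                                intensity_scale = intensity_scale,
                                seed = s, rows = rows)
  )
  grid
}
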