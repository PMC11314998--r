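#' Write a field image as 16-bit grayscale TIFF
#'
#' Counts are rounded and clamped to the 16-bit range; a round trip through
#' [load_image()] is bit-exact on integer-valued rasters.
#'
#' @param image A `field_image` or numeric matrix of counts.
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path) {
  if (!is.matrix(image)) stop_invalid("`image` must be a matrix")
  m <- pmin(pmax(round(unclass(image)), 0), 65535)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Load a grayscale field image from TIFF or PNG
#'
#' @param path Path to an 8- or 16-bit single-channel TIFF or PNG.
#' @param pixel_pitch Pixel pitch in um/px to attach (e.g. from the optics
#'   config); `NA` when unknown.
#' @param true_z Known true defocus in um (e.g. from a stack manifest).
#' @return A `field_image` with counts on the 16-bit scale.
#' @export
load_image <- function(path, pixel_pitch = NA_real_, true_z = NA_real_) {
  if (!file.exists(path)) stop_io(sprintf("cannot read image: no such file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path) * 65535,
    stop_format(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  )
  if (length(dim(px)) == 3L) {
    stop_format(sprintf("'%s' is multi-channel; a grayscale image is required", path))
  }
  new_field_image(px * 1.0, pixel_pitch = pixel_pitch, true_z = true_z)
}

#' Write a rendered stack as TIFF files plus a CSV manifest
#'
#' One 16-bit TIFF per frame plus `manifest.csv` with columns `filename`,
#' `true_z_um`, `frame_index`, `seed` and `config_hash`, so a stack can be
#' re-identified and re-loaded later.
#'
#' @param stack A tibble from [render_stack()].
#' @param dir Output directory (created if needed).
#' @param config The generating [optics_config()] (hashed into the manifest
#'   and written alongside as `config.yaml`).
#' @param prefix Filename prefix.
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir, config = NULL, prefix = "field") {
  if (!is.data.frame(stack) || !all(c("z_um", "frame", "image") %in% names(stack))) {
    stop_invalid("`stack` must be a tibble from render_stack()")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- sprintf("%s_%04d.tif", prefix, seq_len(nrow(stack)))
  for (i in seq_len(nrow(stack))) {
    write_field_image(stack$image[[i]], file.path(dir, fn[i]))
  }
  manifest <- data.frame(
    filename = fn,
    true_z_um = stack$z_um,
    frame_index = stack$frame,
    seed = stack$seed,
    config_hash = if (is.null(config)) NA_character_ else config_hash(unclass(config))
  )
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  if (!is.null(config)) write_optics_config(config, file.path(dir, "config.yaml"))
  invisible(path)
}

#' Read a stack manifest and load its images
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_stack()].
#' @param pixel_pitch Pixel pitch to attach to the loaded images, um/px.
#' @return A tibble with the manifest columns plus an `image` list-column.
#' @export
read_stack <- function(manifest_path, pixel_pitch = NA_real_) {
  if (!file.exists(manifest_path)) {
    stop_io(sprintf("cannot read manifest: no such file '%s'", manifest_path))
  }
  man <- as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
  dir <- dirname(manifest_path)
  man$image <- purrr::map2(man$filename, man$true_z_um, function(f, z) {
    load_image(file.path(dir, f), pixel_pitch = pixel_pitch, true_z = z)
  })
  man
}

#' Read/write an optics configuration as YAML
#'
#' The YAML mirrors the [optics_config()] field names; unknown keys are
#' rejected. `w0` is recomputed from the geometry unless given explicitly.
#'
#' @param path YAML file path.
#' @return `read_optics_config()`: an `optics_config`.
#' @export
read_optics_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read config: no such file '%s'", path))
  fields <- yaml::read_yaml(path)
  allowed <- names(formals(optics_config))
  bad <- setdiff(names(fields), allowed)
  if (length(bad)) {
    stop_format(sprintf("unknown optics config field(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(fields$z_range)) fields$z_range <- as.numeric(unlist(fields$z_range))
  do.call(optics_config, fields)
}

#' @rdname read_optics_config
#' @param config An `optics_config`.
#' @return `write_optics_config()`: `path`, invisibly.
#' @export
write_optics_config <- function(config, path) {
  stopifnot(inherits(config, "optics_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Measure every image listed in a stack manifest
#'
#' Loads each frame in turn (constant memory), measures its edge metrics and
#' returns the calibration-ready table.
#'
#' @inheritParams read_stack
#' @inheritParams measure_image
#' @return A tibble: manifest columns plus `z_um`, `d_px`, `x_rise`,
#'   `x_fall`, `g_max`, `g_min`, `flat`.
#' @export
measure_stack <- function(manifest_path, pixel_pitch = NA_real_,
                          band_fraction = 0.5, smooth_sigma = 8,
                          refine = TRUE) {
  if (!file.exists(manifest_path)) {
    stop_io(sprintf("cannot read manifest: no such file '%s'", manifest_path))
  }
  man <- as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
  dir <- dirname(manifest_path)
  res <- purrr::map2(man$filename, man$true_z_um, function(f, z) {
    img <- load_image(file.path(dir, f), pixel_pitch = pixel_pitch, true_z = z)
    measure_image(img, band_fraction = band_fraction,
                  smooth_sigma = smooth_sigma, refine = refine)
  })
  res <- dplyr::bind_rows(res)
  res$true_z_um <- NULL
  man$z_um <- man$true_z_um
  dplyr::bind_cols(man, res)
}
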