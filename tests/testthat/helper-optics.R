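# Scaled-down instrument used by the unit tests: same pixel pitch and width
# model as the default geometry, but a 512 px detector with a 0.1 mm source
# (w0 = 333.3 px) and a +/-30 um simulation range, so single frames render in
# milliseconds. Noiseless by default; pass noise_sd to add detector noise.
small_config <- function(noise_sd = 0, ...) {
  optics_config(
    detector_pixels = 512L, detector_side = 2.56, source_width = 0.1,
    noise_sd = noise_sd, z_range = c(-30, 30), ...
  )
}

# Independent width oracle: half-maximum crossings of a single-row profile,
# located by linear interpolation. Deliberately avoids the gradient path.
half_max_width <- function(image) {
  v <- as.numeric(image[ceiling(nrow(image) / 2), ])
  half <- (max(v) + min(v)) / 2
  above <- v >= half
  i1 <- which(above)[1]
  i2 <- tail(which(above), 1)
  x1 <- (i1 - 1) - (v[i1] - half) / (v[i1] - v[i1 - 1])
  x2 <- (i2 - 1) + (v[i2] - half) / (v[i2] - v[i2 + 1])
  x2 - x1
}
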