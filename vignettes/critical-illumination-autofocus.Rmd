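---
title: "Critical-illumination autofocus: model, estimator and controller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critical-illumination autofocus: model, estimator and controller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement principle

Sequencing microscopes that use critical illumination project a square source
(a multimode fiber end-face) through a collimator and the objective onto the
chip surface; the chip reflects the excitation field back through the
objective and tube lens onto the camera. When the chip sits exactly in the
focal plane, the conjugate image of the source has a fixed width set by the
relay magnification. When the chip is defocused by `z` micrometres, the image
distance no longer matches the (fixed) detector position, so the conjugate
image changes size — and its edges blur. The field's size is therefore an
optical encoder for defocus that needs no extra hardware: the same camera
that images fluorescence reads it through an empty filter position.

The field width is measured from the one-dimensional intensity profile
`g(x)` across the field. Each edge of the square plateau is a "ridge" — the
fastest grayscale transition in the image — so its first forward difference
`G(x) = g(x+1) - g(x)` has a positive extremum at the rising edge and a
negative extremum at the falling edge. The package's defocus metric is the
separation of those two extrema,

    d = x_fall - x_rise,

and the *evaluation value* is `t = d - d0`, where `d0` is the separation at
best focus. Two properties make `d` a good observable:

* **Shift immunity.** A lateral displacement of the field (shock, thermal
  drift of the fiber) moves both edges by the same amount and leaves `d`
  unchanged.
* **Intensity immunity.** Multiplying the image by any positive constant
  (laser power fluctuation) scales the gradient profile without moving its
  extrema, so `d` is unchanged.

Calibration fits `t` against known stage positions `z`; the slope `k`
(px/µm) is the focus sensitivity and `1/|k|` — the defocus that moves the
metric by one pixel — is the detection limit at native pixel resolution.
Estimation inverts the curve: `z = t / k`.

Alternative metrics are provided for benchmarking (`metric_variants()`): the
gradient extremum *magnitude* peaks at focus and falls both ways, which makes
it direction-blind and flat exactly where sensitivity matters most; the
second-derivative extremum magnitude is steeper but noisier. Only the
position-difference metrics are monotone through focus. For the
second-derivative position metric, note that the second derivative of a
blurred edge has two lobes at roughly one blur width either side of the edge;
the package therefore localizes the edge at the zero-crossing *between* the
lobes (the Laplacian zero-crossing), which coincides with the
first-derivative extremum — taking raw global second-derivative extrema would
measure the edge separation plus or minus two blur widths instead.

## The synthetic optics model

`optics_config()` + `render_field()` replace both the instrument camera and a
ray-traced simulation with a phenomenological model of the conjugate image:

* plateau width `w(z) = w0 (1 + alpha * z + gamma * z^2)` px,
* edge blur `sigma(z) = sigma0 + beta * |z|` px (each edge is an error
  function, i.e. a hard edge convolved with a Gaussian),
* plateau `peak_intensity * intensity_scale` counts over `background`,
* additive Gaussian read noise of `noise_sd` counts (optional Poisson shot
  noise), clamped to the 16-bit detector range.

Defaults model a sequencing microscope with an 8 mm objective, 12 mm
collimator and 200 mm tube lens, a 1 mm square source and a 20 mm, 4000 px
detector (5 µm pitch). The in-focus width then follows from the paraxial
chain: the source is relayed at `f_obj/f_col` onto the chip and re-imaged at
`f_tube/f_obj`, so the detector-plane width is
`1 mm * (200/12) = 16.67 mm = 3333.3 px = w0`.

Parameter choices that the geometry alone does not fix:

* `alpha = -1e-3 /µm`. The width change per micrometre of defocus is set by
  the illumination cone: with a fiber NA of ~0.2 the collimated beam is
  ~2.4 mm across, giving an object-side illumination NA of ~0.3 and a
  per-side width change of ~0.3 µm per µm of defocus on a 667 µm field —
  about 0.1 %/µm. This also keeps the whole ±100 µm simulation range on the
  detector (at `alpha = -1e-3`, `w(-100) ≈ 3669 px` plus blurred skirts still
  fits in 4000 px), which any usable instrument must arrange. The sign
  convention is negative-z-toward-the-lens with the field shrinking as `z`
  increases. The native-pixel slope of the default instrument is
  `k = w0 * alpha ≈ -3.33 px/µm`; instruments that upsample
  (interpolate) their images before the gradient step report
  correspondingly larger slopes in interpolated-pixel units.
* `gamma = 6e-8 /µm²` adds the mild departure from linearity that real
  magnification curves show at large defocus — about 2 px of bow at
  ±100 µm — while leaving a ±50 µm calibration effectively straight.
* `sigma0 = 2 px`, `beta = 0.5 px/µm`: edges stay resolvable across
  ±100 µm (blur grows to ~52 px at the range ends).
* `peak_intensity = 60000`, `background = 500` counts on a 16-bit scale;
  `noise_sd = 250` counts, the shot-noise scale at a 60000-count plateau
  (`sqrt(60000) ≈ 245`).

Large stacks are processed streaming (`simulate_edge_metrics()`), one frame
at a time; protocol-scale stacks render a 1024-row central band of the
detector, since the 1-D profile only ever consumes a centred band and full
4000×4000 frames would cost ~128 MB each.

What the generator deliberately does **not** emulate: wave-optical PSFs and
aberrations, laser speckle and the de-speckler, fiber mode structure, surface
texture of the chip, mechanical vibration during exposure, and thermal drift
of the calibration between capture and use. Consequently, passing the
simulation protocols shows that the estimator and controller are correct and
efficient *given* an error-function edge model with stationary Gaussian
noise; it does not bound the accuracy on a real instrument, where edge-shape
systematics and drift would add to the error budget and the calibration
would need periodic refresh.

## The estimator

`measure_image()` reduces a frame to the metric in four steps.

1. **Band averaging** (`extract_profile()`, `band_fraction = 0.5`): the mean
   of the central half of the rows suppresses detector noise by
   `sqrt(n_rows)` without touching the x-structure. A single-line cut — what
   a minimal implementation would use — is available by shrinking
   `band_fraction` until one row remains.
2. **Matched-filter smoothing** (`smooth_profile()`, `smooth_sigma = 8` px by
   default in the pipeline). A defocused edge gradient is a Gaussian bump of
   scale `sigma(z)` (up to ~50 px here). Locating such a broad extremum by
   raw integer argmax plus a three-point parabola is noise-limited: the
   parabola's curvature term shrinks like `1/sigma^2`, so px-scale errors
   result under any realistic noise — orders of magnitude above the
   Cramér–Rao bound for the same data. Convolving the profile with a
   Gaussian near the blur scale is a matched filter for the edge; the
   argmax-plus-parabola estimator on the smoothed gradient then operates at
   ~0.02–0.07 px, close to the bound. Smoothing is symmetric, so it does not
   displace a symmetric edge; `smooth_sigma = 0` disables it.
3. **Forward differences** (`gradient_1d()`), with sample `i` assigned
   coordinate `i + 0.5` so that symmetric edges give symmetric extrema.
4. **Sub-pixel refinement** (`subpixel_refine()`): the parabolic vertex
   through the extremum and its neighbours, `0.5 (y_- - y_+)/(y_- - 2 y_c +
   y_+)`, which is invariant under scaling and offset of the values. Ties at
   the integer argmax resolve to the smaller index; a zero-curvature triple
   returns offset 0 with a `flat` flag; boundary extrema are not refined and
   are flagged.

Degenerate inputs raise typed conditions: a profile with no positive maximum
or no negative minimum in its gradient is `no-field-detected`; a maximum
located after the minimum is `inverted-edges`; renders whose field (half
width plus three blur widths plus lateral offset) would leave the detector
are `field-out-of-bounds`.

## Calibration

`fit_evaluation_curve()` regresses the measured `d` on the known `z` by
ordinary least squares and defines `d0` as the fitted value at `z = 0`, so
`t = d - d0` is zero at focus by construction and is robust to the noise of
any single in-focus frame. The curve stores `k`, `d0`, `R²`, the validity
range and the sample table; `invert_curve()` maps `t` back to `z`, flagging
estimates outside the calibrated range; `sensitivity()` returns `1/|k|`.

The default family is a quadratic in `z` rather than a straight line, and
the reason is the reference point, not the slope: on a symmetric calibration
grid a straight-line fit absorbs any curvature of `w(z)` into its intercept,
shifting `d0` by the quadratic coefficient times the mean of `z²`. On the
default instrument that is ~0.17 px ≈ 0.05 µm — negligible for µm-scale
estimation but comparable to the 78 nm actuator step, which would defeat the
final trim of the closed-loop protocol. The quadratic intercept is unbiased;
for truly linear data the quadratic coefficient fits to ~0 and the two
families agree (the inversion uses the cancellation-free root
`2t / (k + sign(k) sqrt(k² + 4qt))`, which degrades gracefully to `t/k` as
`q -> 0`). `family = "linear"` reproduces the conventional straight-line
calibration and is what the R² quality checks quote.

The calibration protocol mirrors instrument practice: a coarse curve at 5 µm
steps over ±100 µm to cover the full travel, then a fine curve at 1 µm steps
over ±50 µm where the response is most linear. No outlier rejection is
applied. A slope magnitude below `k_floor` (0.05 px/µm) is rejected as
`degenerate-curve` rather than inverted into wild estimates.

## The closed-loop controller

`virtual_stage()` models the camera + z-actuator pair: captures render
seeded frames at the current true defocus; moves execute
`round(dz / min_step) * min_step` with `min_step = 0.078 µm` (78 nm), the
smallest commandable displacement of the modelled linear stage.

`closed_loop_focus()` runs the iterative protocol: each iteration estimates
the defocus from `schedule[i]` frames, commands the quantized negative of
the estimate (proportional gain 1 — the evaluation curve is effectively
linear, so damping would only slow convergence), and stops once the
estimate magnitude is within `stop_tol` (default one actuator step). The
move is commanded *before* the stop check, so the last executed iteration
always leaves a fresh quantization remainder (at most half a step plus
estimator noise) rather than an unverified earlier residual; an estimate
below half a step simply quantizes to no move. One consequence of a
quantized actuator is that strict iteration-to-iteration contraction of
|true z| holds only down to the step scale: once the residual is below one
step, a noise-triggered move can dither it by up to half a step, which is
the physical floor (`final residual <= min_step/2 + noise` in the mean, and
the worst case over a dense grid of starts cannot be better than
`min_step/2`).

The default schedule `c(1, 1, 16)` reflects the three-stage protocol: a
single-frame wide-range correction (the ±50 µm calibration extrapolates
usefully across ±100 µm, leaving well under 10 µm), a second single-frame
correction down to the quantization scale, and one 16-frame averaged trim.
Sixteen frames were chosen so the `1/sqrt(n)` reduction puts the averaged
estimator noise safely below the 78 nm step; frames with failed detection
are dropped and counted, a failed iteration is retried once, and a second
failure aborts the run. Timing figures of the modelled hardware (40 ms
exposure, <160 ms per iteration) are informational metadata only: nothing
in the package asserts them.

## Problem sizes used by the checks

The shipped test suite and the acceptance script exercise the default
geometry with: a 101-point fine calibration (±50 µm, 1 µm steps, default
noise); 17 × 3 single-shot estimates at 5 µm spacing across ±40 µm; 41
single-shot estimates across ±100 µm; and 21 closed-loop starts at 10 µm
spacing across ±100 µm with the `c(1, 1, 16)` schedule — sizes chosen to
estimate worst-case errors stably while keeping a full run in minutes on one
core. Unit tests use a scaled instrument (512 px detector, 0.1 mm source,
±30 µm range) with the same pixel pitch and width model.

## Known limitations

* The error-function edge model makes sub-pixel refinement essentially
  unbiased; real edge profiles (speckle, aberrations, surface structure)
  will add shape systematics that calibration absorbs only to first order.
* Calibration is assumed stationary; thermal drift between calibration and
  use is not modelled and would appear directly as estimation bias.
* The metric needs both edges on the detector, which bounds the usable
  defocus range by the detector size; the simulator refuses such renders
  rather than extrapolating.
* Only a single square field is supported — no multi-ROI tracking, color
  channels or fluorescence-spot analysis.
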