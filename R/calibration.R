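#' Fit the standard evaluation curve
#'
#' Ordinary least squares of the measured edge separation `d` against the
#' known defocus `z` of a calibration stack. The slope is the focus
#' sensitivity `k` (px/um); the reference separation `d0` is the fitted value
#' at z = 0, so the evaluation value `t = d - d0` is zero at best focus by
#' construction and the curve passes through the origin in t-space.
#'
#' Two curve families are available. The quadratic family (default) adds a
#' small `z^2` term that absorbs the mild width-nonlinearity present at large
#' defocus; `k` is then the slope at z = 0. The default matters for `d0`: on
#' a symmetric calibration grid a purely linear fit folds any curvature into
#' its intercept (`d0` shifts by the quadratic coefficient times the mean of
#' `z^2`), a systematic origin offset that can rival the actuator minimum
#' step, whereas the quadratic intercept is unbiased. Use
#' `family = "linear"` to reproduce a plain straight-line calibration.
#'
#' @param samples A data frame with columns `z_um` and `d_px` (one row per
#'   calibration frame), e.g. from [simulate_edge_metrics()]; at least 3 rows
#'   spanning a non-zero z range.
#' @param family `"quadratic"` (default) or `"linear"`.
#' @param k_floor Minimum usable |slope| in px/um; below it the curve is
#'   rejected as degenerate.
#' @return An `evaluation_curve` object with elements `k` (px/um), `b`
#'   (intercept in t-space, 0 by construction), `d0` (px), `q` (quadratic
#'   coefficient, px/um^2), `r_squared`, `z_min`, `z_max`, `n`, `family`,
#'   `samples` (tibble with `z_um`, `d_px`, `t_px`) and a coefficient table.
#'   Methods: [tidy()], [glance()], [autoplot()], `print()`, `predict()`.
#' @examples
#' s <- tibble::tibble(z_um = -50:50, d_px = 3333 - 24.103 * (-50:50))
#' curve <- fit_evaluation_curve(s)
#' glance(curve)
#' @export
fit_evaluation_curve <- function(samples, family = c("quadratic", "linear"),
                                 k_floor = 0.05) {
  family <- match.arg(family)
  if (!is.data.frame(samples) || !all(c("z_um", "d_px") %in% names(samples))) {
    stop_invalid("`samples` must be a data frame with columns `z_um` and `d_px`")
  }
  z <- as.numeric(samples$z_um)
  d <- as.numeric(samples$d_px)
  keep <- is.finite(z) & is.finite(d)
  z <- z[keep]; d <- d[keep]
  if (length(z) < 3L) stop_invalid("at least 3 calibration samples are required")
  if (var(z) == 0) stop_invalid("calibration samples must span a non-zero z range")

  fit <- if (family == "linear") lm(d ~ z) else lm(d ~ z + I(z^2))
  cf <- coef(fit)
  d0 <- unname(cf[1])
  k <- unname(cf[2])
  q <- if (family == "quadratic") unname(cf[3]) else 0
  if (!is.finite(k) || abs(k) < k_floor) {
    stop_degenerate(sprintf(
      "degenerate-curve: fitted |slope| %.4g px/um is below the floor %g", abs(k), k_floor))
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((d - mean(d))^2)
  r2 <- 1 - ss_res / ss_tot

  sm <- suppressWarnings(summary(fit))$coefficients  # exact synthetic data trips the perfect-fit warning
  coef_table <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )

  structure(
    list(
      k = k, b = 0, d0 = d0, q = q, family = family,
      r_squared = r2, z_min = min(z), z_max = max(z), n = length(z),
      k_floor = k_floor,
      samples = tibble(z_um = z, d_px = d, t_px = d - d0),
      coef_table = coef_table
    ),
    class = "evaluation_curve"
  )
}

#' @export
print.evaluation_curve <- function(x, ...) {
  cat("<evaluation_curve>\n")
  cat(sprintf("  t = d - d0 with d0 = %.3f px; %s fit over z in [%g, %g] um (n = %d)\n",
              x$d0, x$family, x$z_min, x$z_max, x$n))
  cat(sprintf("  slope k = %.4f px/um", x$k))
  if (x$family == "quadratic") cat(sprintf(" (+ %.3g px/um^2 z^2)", x$q))
  cat(sprintf("\n  R^2 = %.6f; sensitivity 1/|k| = %.4f um/px\n",
              x$r_squared, 1 / abs(x$k)))
  invisible(x)
}

#' @export
predict.evaluation_curve <- function(object, z, ...) {
  object$d0 + object$k * z + object$q * z^2
}

#' @rdname fit_evaluation_curve
#' @param x,object An `evaluation_curve`.
#' @param ... Unused.
#' @export
tidy.evaluation_curve <- function(x, ...) {
  x$coef_table
}

#' @rdname fit_evaluation_curve
#' @export
glance.evaluation_curve <- function(x, ...) {
  tibble(
    k_px_per_um = x$k, d0_px = x$d0, q_px_per_um2 = x$q,
    r_squared = x$r_squared, sensitivity_um_per_px = sensitivity(x),
    z_min_um = x$z_min, z_max_um = x$z_max, n = x$n, family = x$family
  )
}

#' Theoretical defocus sensitivity of a calibrated system
#'
#' The smallest discernible change in the extremum separation is one pixel,
#' so the detection limit at native pixel resolution is the defocus that
#' moves `t` by one pixel: `1/|k|` micrometres.
#'
#' @param curve An `evaluation_curve`, or a numeric slope `k` in px/um.
#' @return Sensitivity in um per px.
#' @examples
#' sensitivity(-24.103)  # ~0.041 um
#' @export
sensitivity <- function(curve) {
  k <- if (inherits(curve, "evaluation_curve")) curve$k else curve
  check_number(k, "k")
  floor_ <- if (inherits(curve, "evaluation_curve")) curve$k_floor else 1e-12
  if (abs(k) < max(floor_, 1e-12)) {
    stop_degenerate("degenerate-curve: slope too small for a sensitivity estimate")
  }
  1 / abs(k)
}

#' Invert the evaluation curve: evaluation value to defocus estimate
#'
#' For the linear family `z = t / k`; for the quadratic family the root of
#' `q z^2 + k z = t` closer to `t / k` is taken. Estimates outside the
#' calibrated range are returned with `extrapolated = TRUE`.
#'
#' @param curve An `evaluation_curve`.
#' @param t Evaluation value(s), px.
#' @return A tibble with columns `t_px`, `z_um`, `extrapolated`.
#' @export
invert_curve <- function(curve, t) {
  stopifnot(inherits(curve, "evaluation_curve"))
  if (!is.numeric(t) || !all(is.finite(t))) stop_invalid("`t` must be finite")
  if (abs(curve$k) < curve$k_floor) stop_degenerate("degenerate-curve")
  if (curve$family == "linear" || curve$q == 0) {
    z <- t / curve$k
  } else {
    # root of q z^2 + k z - t = 0 continuous with the linear solution t/k,
    # computed in the cancellation-free form z = 2t / (k + sign(k) sqrt(disc))
    # so that q -> 0 degrades gracefully to t/k
    disc <- curve$k^2 + 4 * curve$q * t
    lin <- t / curve$k
    ok <- disc >= 0
    z <- lin
    denom <- curve$k + sign(curve$k) * sqrt(disc[ok])
    z[ok] <- 2 * t[ok] / denom
  }
  tibble(t_px = t, z_um = z,
         extrapolated = z < curve$z_min | z > curve$z_max)
}

#' Calibrate an evaluation curve on a simulated stack
#'
#' Convenience wrapper: renders a seeded calibration stack with
#' [simulate_edge_metrics()] and fits the standard evaluation curve. The
#' default grids mirror the usual protocol: a fine curve at 1 um steps over
#' +/-50 um (or pass `z_values = seq(-100, 100, 5)` for the coarse curve).
#'
#' @inheritParams simulate_edge_metrics
#' @inheritParams fit_evaluation_curve
#' @return An `evaluation_curve`.
#' @export
calibrate_simulated <- function(config, z_values = seq(-50, 50, by = 1),
                                frames_per_z = 1, seed = NULL, rows = 1024,
                                band_fraction = 0.5, smooth_sigma = 8,
                                refine = TRUE,
                                family = c("quadratic", "linear")) {
  metrics <- simulate_edge_metrics(config, z_values,
                                   frames_per_z = frames_per_z, seed = seed,
                                   rows = rows, band_fraction = band_fraction,
                                   smooth_sigma = smooth_sigma, refine = refine)
  fit_evaluation_curve(metrics, family = family)
}

#' Serialize an evaluation curve to JSON (and back)
#'
#' The JSON carries the fitted parameters, validity range, coefficient table
#' and the calibration sample table, so a curve can be re-used across
#' sessions and by the command-line front end.
#'
#' @param curve An `evaluation_curve`.
#' @param path File path.
#' @return `write_evaluation_curve()` returns `path` invisibly;
#'   `read_evaluation_curve()` returns the restored `evaluation_curve`.
#' @export
write_evaluation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "evaluation_curve"))
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_evaluation_curve
#' @export
read_evaluation_curve <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read curve file '%s'", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$samples <- as_tibble(as.data.frame(obj$samples))
  obj$coef_table <- as_tibble(as.data.frame(obj$coef_table))
  structure(obj, class = "evaluation_curve")
}

#' @rdname write_evaluation_curve
#' @export
write_curve_samples <- function(curve, path) {
  stopifnot(inherits(curve, "evaluation_curve"))
  write.csv(curve$samples, path, row.names = FALSE)
  invisible(path)
}
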