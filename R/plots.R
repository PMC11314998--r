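#' Plot an intensity or gradient profile
#'
#' @param object An `intensity_profile` or `gradient_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "detector column (px)", y = "intensity (counts)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.intensity_profile
#' @export
autoplot.gradient_profile <- function(object, ...) {
  ord <- attr(object, "order") %||% 1L
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "detector column (px)",
                  y = if (ord == 1L) "gradient (counts/px)" else "2nd derivative (counts/px²)") +
    ggplot2::theme_minimal()
}

#' Plot a standard evaluation curve with its calibration samples
#'
#' Evaluation value `t = d - d0` against defocus, with the fitted line
#' (or parabola) overlaid.
#'
#' @param object An `evaluation_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_curve <- function(object, ...) {
  zz <- seq(object$z_min, object$z_max, length.out = 200)
  fitted <- tibble(z_um = zz, t_px = object$k * zz + object$q * zz^2)
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$z_um, y = .data$t_px)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = fitted, colour = "red", linewidth = 0.4) +
    ggplot2::labs(x = "defocus z (µm)", y = "evaluation value t (px)",
                  title = sprintf("k = %.3f px/µm, R² = %.5f",
                                  object$k, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a closed-loop focus trajectory
#'
#' Absolute true defocus before and after each iteration, on a log scale,
#' with the actuator minimum step marked.
#'
#' @param object A `focus_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.focus_result <- function(object, ...) {
  it <- object$iterations
  traj <- tibble(
    iteration = c(0, it$iteration),
    residual_um = abs(c(it$true_z_before_um[1], it$true_z_after_um))
  )
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$iteration, y = pmax(.data$residual_um, 1e-4))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$min_step, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "|true defocus| (µm)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
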