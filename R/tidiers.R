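#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cylinder fit
#'
#' @param x A `cylinder_fit`.
#' @param ... Unused.
#' @return One-row tibble with the axis, mean radius and fit quality.
#' @method tidy cylinder_fit
#' @export
tidy.cylinder_fit <- function(x, ...) {
  tibble::tibble(
    segment_start_index = x$segment_start_index %||% NA_integer_,
    axis_x = x$axis_direction[1], axis_y = x$axis_direction[2],
    axis_z = x$axis_direction[3],
    point_x = x$axis_point[1], point_y = x$axis_point[2],
    point_z = x$axis_point[3],
    mean_radius = x$mean_radius, r = x$r
  )
}

#' @rdname tidy.cylinder_fit
#' @method glance cylinder_fit
#' @export
glance.cylinder_fit <- function(x, ...) {
  tibble::tibble(mean_radius = x$mean_radius, r = x$r)
}

#' Tidy a kink error model
#'
#' `tidy()` returns one row per coefficient; `glance()` returns the model
#' in one row (plus calibration-bin count when present).
#'
#' @param x A `kink_error_model`.
#' @param ... Unused.
#' @method tidy kink_error_model
#' @export
tidy.kink_error_model <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "floor_sum_r"),
                 estimate = c(x$a, x$b, x$c, x$floor_sum_r),
                 unit = c("deg", "deg", "A", "A"))
}

#' @rdname tidy.kink_error_model
#' @method glance kink_error_model
#' @export
glance.kink_error_model <- function(x, ...) {
  bins <- attr(x, "bins")
  tibble::tibble(a = x$a, b = x$b, c = x$c, floor_sum_r = x$floor_sum_r,
                 provenance = x$provenance,
                 n_bins = if (is.null(bins)) NA_integer_ else nrow(bins))
}

#' Plot an angle profile
#'
#' Kink angle per site with the 95% confidence band `theta +/- epsilon`
#' and the kink threshold as a dashed line.
#'
#' @param object An `angle_profile` from [measure_angles()].
#' @param kink_threshold Degrees. Default 20.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot angle_profile
#' @export
autoplot.angle_profile <- function(object, kink_threshold = 20, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$site_index,
                                       y = .data$theta_deg)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$theta_deg - .data$epsilon_deg),
      ymax = .data$theta_deg + .data$epsilon_deg), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = kink_threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "site (0-based residue index)",
                  y = "kink angle (degrees)",
                  title = object$helix_id[1])
}

#' Plot the per-site angle distributions of a family
#'
#' Boxplots of smoothed angles at each alignment column, with the most
#' disrupted site shaded.
#'
#' @param smoothed Output of [smooth_family()].
#' @param classification Optional [classify_family()] row (computed when
#'   `NULL`).
#' @param kink_threshold Degrees. Default 20.
#' @return A ggplot.
#' @export
plot_family_profile <- function(smoothed, classification = NULL,
                                kink_threshold = 20) {
  if (is.null(classification)) classification <- classify_family(smoothed)
  ggplot2::ggplot(smoothed, ggplot2::aes(x = factor(.data$column),
                                         y = .data$theta_smoothed)) +
    ggplot2::annotate("rect",
                      xmin = match(classification$column,
                                   sort(unique(smoothed$column))) - 0.5,
                      xmax = match(classification$column,
                                   sort(unique(smoothed$column))) + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = kink_threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "alignment column", y = "smoothed angle (degrees)",
                  subtitle = sprintf("%s  sigma = %.1f deg, mean eps = %.1f deg",
                                     classification$class,
                                     classification$sigma_theta,
                                     classification$mu_eps))
}

#' @importFrom rlang .data %||%
NULL
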