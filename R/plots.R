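#' Plot a mid-plane density profile
#'
#' @param object A profile from [nominal_profile()], [scale_profile()] or
#'   [fd_reference_solver()].
#' @param ... Unused.
#' @return A ggplot: density (A/cm\eqn{^2}) against radial offset, with
#'   the paddle rim marked.
#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  geo <- attr(object, "geometry")
  ipk <- attr(object, "peak_current")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x_mm, y = .data$j_a_per_cm2)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = geo$radius, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::annotate("text", x = geo$radius, y = max(object$j_a_per_cm2),
                      label = "paddle rim", hjust = -0.1, vjust = 1,
                      size = 3, colour = "grey40") +
    ggplot2::labs(
      x = "radial offset x (mm)",
      y = if (ipk == 1) expression(J[nominal] ~ (A / cm^2 ~ "per A"))
          else expression(J ~ (A / cm^2)),
      title = sprintf("Mid-plane current density (a = %.3g mm, h = %.3g mm, I = %.4g A)",
                      geo$radius, geo$separation, ipk),
      subtitle = sprintf("method: %s", attr(object, "method"))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.density_profile
#' @param profile A density profile.
#' @export
plot_profile <- function(profile, ...) autoplot.density_profile(profile, ...)

#' Plot group threshold estimates
#'
#' @param group_estimates Output of [group_thresholds()].
#' @return A ggplot of group means with +/- 1 SD error bars.
#' @export
plot_group_thresholds <- function(group_estimates) {
  ggplot2::ggplot(group_estimates,
                  ggplot2::aes(x = .data$group, y = .data$mean_a_cm2)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_a_cm2 - .data$sd_a_cm2,
      ymax = .data$mean_a_cm2 + .data$sd_a_cm2)) +
    ggplot2::labs(
      x = NULL, y = expression(threshold ~ (A / cm^2)),
      title = "Current-density threshold by application group",
      subtitle = sprintf("estimator: %s; sites: %s",
                         group_estimates$estimator[1], group_estimates$filter[1])
    ) +
    ggplot2::theme_minimal()
}
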