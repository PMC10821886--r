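#' Plot a community trajectory
#'
#' Species abundances over time, one line per species.
#'
#' @param object a [simulate_community()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot community_sim
#' @export
autoplot.community_sim <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$abundance,
                                 colour = factor(.data$species))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "abundance (fraction of carrying capacity)",
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot a two-species phase diagram
#'
#' @param object a [phase_diagram()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mu1, .data$mu2, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(mu[1] ~ (h^-1)), y = expression(mu[2] ~ (h^-1)),
                  fill = "outcome") +
    ggplot2::theme_minimal()
}

#' Plot feasibility against the gene transfer rate
#'
#' @param object a [feasibility_vs_transfer_rate()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot feasibility_scan
#' @export
autoplot.feasibility_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$eta, .data$feasibility)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$feasibility - 2 * .data$se, 0),
                                      ymax = pmin(.data$feasibility + 2 * .data$se, 1)),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(eta ~ (h^-1)), y = "coexistence feasibility") +
    ggplot2::theme_minimal()
}

#' Plot feasibility against species number per transfer rate
#'
#' @param object a [feasibility_vs_species_number()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot feasibility_curve
#' @export
autoplot.feasibility_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$m, .data$feasibility,
                                       colour = factor(.data$eta))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$feasibility - 2 * .data$se, 0),
                                      ymax = pmin(.data$feasibility + 2 * .data$se, 1),
                                      fill = factor(.data$eta)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "species number m", y = "coexistence feasibility",
                  colour = expression(eta ~ (h^-1)), fill = expression(eta ~ (h^-1))) +
    ggplot2::theme_minimal()
}

#' Plot diversity against the realized growth-rate spread
#'
#' @param object a [diversity_vs_rate_spread()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot spread_experiment
#' @export
autoplot.spread_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$sd_mu, .data$shannon)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = expression(sd(mu) ~ (h^-1)),
                  y = "steady-state diversity (effective species)") +
    ggplot2::theme_minimal()
}

#' Plot mean diversity trajectories of a fluctuation ensemble
#'
#' @param object a [run_fluctuation_ensemble()] result.
#' @param dt summary-grid spacing (h).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fluctuation_ensemble
#' @export
autoplot.fluctuation_ensemble <- function(object, dt = 50, ...) {
  summarize_fluctuation_ensemble(object, dt = dt) |>
    ggplot2::ggplot(ggplot2::aes(.data$time, .data$mean_shannon,
                                 colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_shannon - .data$sd_shannon,
                                      ymax = .data$mean_shannon + .data$sd_shannon),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "diversity (effective species)") +
    ggplot2::theme_minimal()
}
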