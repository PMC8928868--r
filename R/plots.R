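#' Plot a within-season trajectory
#'
#' Hosts, infecting parasites and parasite progeny over one season, on a
#' log10 y scale (zeros dropped).
#'
#' @param object A `season_trajectory` from [within_season()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.season_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("s", "v1", "v2"),
                            names_to = "compartment", values_to = "density")
  df <- dplyr::filter(df, .data$density > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$density,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time within season", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a multi-season series
#'
#' Host cohort and season-start parasite density against season, stacked
#' in facets.
#'
#' @param object A `season_series` from [iterate_seasons()].
#' @param from First season shown (use e.g. `from = 800` to show the
#'   attractor only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.season_series <- function(object, from = 0, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$season >= from)
  df <- tidyr::pivot_longer(df, c("s_hat", "v_hat"),
                            names_to = "population", values_to = "density")
  df$population <- dplyr::recode(df$population, s_hat = "host cohort",
                                 v_hat = "parasite")
  ggplot2::ggplot(df, ggplot2::aes(.data$season, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~population, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "season", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation scan
#'
#' End-of-season parasite densities over the classification window,
#' against the incubation delay: an equilibrium collapses to a single
#' point per `tau`; a quasiperiodic orbit fills a vertical band.
#'
#' @param object A `bifurcation_scan` from [bifurcation_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bifurcation_scan <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$tau, .data$v_hat,
                               colour = .data$label)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::labs(x = expression(tau), y = "season-start parasite density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an adaptive walk
#'
#' Dominant incubation delay after each mutant event, with the optimum as
#' a dashed line; invaded mutants are marked.
#'
#' @param object An `adaptive_walk` from [adaptive_walk()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adaptive_walk <- function(object, ...) {
  df <- object$events
  ggplot2::ggplot(df, ggplot2::aes(.data$event_index,
                                   .data$dominant_tau_after)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(y = .data$mutant_tau,
                                     shape = .data$outcome), alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$tau_star, linetype = "dashed") +
    ggplot2::labs(x = "mutant events (evolutionary time)",
                  y = expression(tau), shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phenological phase diagram
#'
#' Attractor label over the (season length, emergence window) grid for
#' parasites at their locally optimal virulence.
#'
#' @param object A tibble from [phase_boundary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_phase_boundary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$T, .data$t_l,
                                       fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "season length T", y = expression(t[l]), fill = NULL) +
    ggplot2::theme_minimal()
}
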