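#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation run
#'
#' One row per tick with time converted to hours and days alongside the raw
#' per-tick observables.
#'
#' @param x A `cv_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cv_run <- function(x, ...) {
  m <- x$metrics
  tibble::add_column(m, time_h = m$time_min / 60, time_d = m$time_min / 1440,
                     .after = "time_min")
}

#' One-row summary of a simulation run
#'
#' Steady-state means over the final simulated day (populations,
#' architecture), totals of the event ledger, and the scenario name.
#'
#' @param x A `cv_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cv_run <- function(x, ...) {
  m <- x$metrics
  w <- m$time_min > max(m$time_min) - 1440
  tibble::tibble(
    scenario = if (is.null(x$scenario)) "baseline" else x$scenario$name,
    days = max(m$time_min) / 1440,
    crypt_mean = mean(m$crypt_alive[w]),
    villus_mean = mean(m$villus_alive[w]),
    ratio_mean = mean(m$ratio[w], na.rm = TRUE),
    villus_height_mean_um = mean(m$villus_height_um[w]),
    crypt_depth_mean_um = mean(m$crypt_depth_um[w]),
    necrotic_final = m$necrotic[nrow(m)],
    births = sum(m$births), apoptoses = sum(m$apoptoses),
    necroses = sum(m$necroses), sloughs = sum(m$sloughs),
    tip_exits = sum(m$tip_exits), cleared = sum(m$cleared))
}

#' Plot population and architecture trajectories of a run
#'
#' Crypt, villus and necrotic population curves over time (the standard
#' readout of the perturbation experiments).
#'
#' @param object A `cv_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_run <- function(object, ...) {
  m <- object$metrics
  df <- rbind(
    data.frame(time_h = m$time_min / 60, population = m$crypt_alive,
               compartment = "crypt"),
    data.frame(time_h = m$time_min / 60, population = m$villus_alive,
               compartment = "villus"),
    data.frame(time_h = m$time_min / 60, population = m$necrotic,
               compartment = "necrotic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$population,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "cells",
                  title = if (is.null(object$scenario)) "baseline"
                          else object$scenario$name) +
    ggplot2::theme_minimal()
}

#' Plot an axial gradient profile
#'
#' @param profile A tibble from [gradient_profile()].
#' @param label Species/signal label for the y axis.
#' @return A ggplot.
#' @export
plot_gradient <- function(profile, label = "level") {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$axial_pos,
                                        y = .data$mean_level)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position (um, crypt base -> villus tip)",
                  y = label) +
    ggplot2::theme_minimal()
}

#' Render a state snapshot
#'
#' Tile map of the unwrapped lattice: cell types, necrotic debris and Wnt
#' activity shading, the view used throughout to read the architecture.
#'
#' @param state A `cv_state`.
#' @return A ggplot.
#' @export
plot_state <- function(state) {
  n <- state$n
  df <- data.frame(
    row = state$row_of, col = state$col_of,
    what = ifelse(state$debris, "necrotic debris",
           ifelse(state$type == CV_STEM, "stem",
           ifelse(state$type == CV_TA, "TA",
           ifelse(state$type == CV_ENT, "enterocyte", "empty")))),
    wnt = state$f$WNT)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = .data$wnt), fill = "red") +
    ggplot2::geom_point(data = df[df$what != "empty", ],
                        ggplot2::aes(colour = .data$what), size = 1) +
    ggplot2::scale_colour_manual(values = c(
      "stem" = "darkgreen", "TA" = "green3", "enterocyte" = "grey90",
      "necrotic debris" = "black")) +
    ggplot2::scale_alpha_continuous(range = c(0, 0.9), guide = "none") +
    ggplot2::labs(x = "circumference", y = "axial row (base -> tip)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
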