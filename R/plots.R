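#' Plot a potential landscape
#'
#' Raster of the generalized potential `U = -ln Pss` over the gating
#' plane, with the classified minima overlaid; optionally clipped at a
#' potential ceiling to keep the basin structure visible.
#'
#' @param object a `potential_landscape`.
#' @param u_max clip `U` at this value for display.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.potential_landscape <- function(object, u_max = 30, ...) {
  df <- tidy(object)
  df$U <- pmin(df$U, u_max)
  mins <- landscape_minima(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$S1, .data$S2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$U)) +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "U") +
    ggplot2::geom_point(data = mins, colour = "red", size = 2) +
    ggplot2::geom_text(data = mins,
                       ggplot2::aes(label = .data$state),
                       nudge_y = 0.05, colour = "red", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(S[1]), y = expression(S[2]))
}

#' Plot a rule-module trajectory
#'
#' @param object a `rule_trajectory` (see [simulate_rule()]).
#' @param type `"time"` (gating variables against time) or `"phase"`
#'   (S2 against S1).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rule_trajectory <- function(object, type = c("time", "phase"),
                                     ...) {
  type <- match.arg(type)
  if (type == "phase") {
    return(
      ggplot2::ggplot(object, ggplot2::aes(.data$S1, .data$S2)) +
        ggplot2::geom_path(alpha = 0.7) +
        ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
        ggplot2::labs(x = expression(S[1]), y = expression(S[2]))
    )
  }
  df <- tidyr::pivot_longer(object[, c("t", "S1", "S2")], -"t",
                            names_to = "population")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "synaptic gating S")
}

#' Plot a minimal-action result on its landscape
#'
#' @param object an `action_result`.
#' @param landscape the `potential_landscape` it was computed from
#'   (optional background).
#' @param ... passed to [autoplot.potential_landscape()].
#' @return A ggplot object.
#' @export
autoplot.action_result <- function(object, landscape = NULL, ...) {
  paths <- tidy(object)
  p <- if (!is.null(landscape)) autoplot(landscape, ...) else
    ggplot2::ggplot() + ggplot2::coord_equal() +
      ggplot2::labs(x = expression(S[1]), y = expression(S[2]))
  p + ggplot2::geom_path(
    data = paths,
    ggplot2::aes(.data$S1, .data$S2, colour = .data$direction),
    linewidth = 0.8
  ) +
    ggplot2::scale_colour_manual(
      values = c(rule1_to_rule2 = "green3", rule2_to_rule1 = "red2"))
}

#' Plot a BOLD regressor
#'
#' @param object a `bold_regressor`.
#' @param ... unused.
#' @return A ggplot object showing the fine-grid convolution and the
#'   TR-sampled regressor points.
#' @export
autoplot.bold_regressor <- function(object, ...) {
  fine <- attr(object, "fine")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$value))
  if (!is.null(fine)) {
    p <- p + ggplot2::geom_line(data = fine, alpha = 0.4)
  }
  p + ggplot2::geom_point(size = 0.6, colour = "blue") +
    ggplot2::labs(x = "time (s)", y = "predicted BOLD (a.u.)")
}

#' Trace plot of a Metropolis-Hastings chain
#'
#' @param object an `mh_chain`.
#' @param params which parameters to show (default all).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mh_chain <- function(object, params = NULL, ...) {
  df <- tidy(object)
  if (!is.null(params)) df <- df[df$param %in% params, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    ggplot2::labs(x = "MCMC step", y = "parameter value")
}
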