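#' @importFrom ggplot2 autoplot
NULL

#' Plot a trajectory
#'
#' Amplitude and (wrapped or unwrapped) phase against time, one colour per
#' mode.
#'
#' @param object A `wetcow_trajectory`.
#' @param wrap Show wrapped phases in \eqn{(-\pi, \pi]} (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wetcow_trajectory
#' @export
autoplot.wetcow_trajectory <- function(object, wrap = FALSE, ...) {
  df <- tibble::as_tibble(object)
  if (wrap) df$phase <- wrap_phase(df$phase)
  long <- tidyr::pivot_longer(df, c("amplitude", "phase"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = factor(.data$mode))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (arbitrary units)", y = NULL, colour = "mode") +
    ggplot2::theme_minimal()
}

#' Plot a synchronization report
#'
#' Order-parameter time series with the synchronization threshold and the
#' detected synchronization time.
#'
#' @param object A `wetcow_sync_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wetcow_sync_report
#' @export
autoplot.wetcow_sync_report <- function(object, ...) {
  p <- ggplot2::ggplot(object$order_parameter,
                       ggplot2::aes(x = .data$time, y = .data$R)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$order_threshold,
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (arbitrary units)",
                  y = "phase order parameter R(t)") +
    ggplot2::theme_minimal()
  if (is.finite(object$sync_time)) {
    p <- p + ggplot2::geom_vline(xintercept = object$sync_time,
                                 linetype = "dotted")
  }
  p
}

#' Analytic versus measured spiking-frequency sweep
#'
#' Integrates a mode over a grid of criticality values and plots the
#' measured peak-to-peak effective frequency against the closed-form
#' prediction \eqn{\omega_s = \omega\sqrt{1 - c_r^2}}.
#'
#' @param params Base [mode_params()]; `gamma` is swept.
#' @param c_r Criticality grid.
#' @param t_end Integration horizon per point (default adapts to the
#'   analytic period).
#' @return A ggplot object; the data are in its `data` element.
#' @export
plot_frequency_sweep <- function(params = mode_params(),
                                 c_r = seq(0.1, 0.95, by = 0.05),
                                 t_end = NULL) {
  gamma_c <- critical_thresholds(params)[["gamma_c"]]
  df <- purrr::map_dfr(c_r, function(cr) {
    p <- params
    p$gamma <- cr * gamma_c
    rep <- criticality(p)
    horizon <- t_end %||% (30 * rep$T_s + 50)
    traj <- integrate_mode(p, t_end = horizon)
    late <- traj[traj$time >= horizon / 4, ]
    attr(late, "params") <- NULL
    est <- estimate_effective_frequency(detect_spikes(late))
    tibble::tibble(c_r = cr, analytic = rep$omega_s,
                   measured = est$omega_s_hat[1])
  })
  long <- tidyr::pivot_longer(df, c("analytic", "measured"),
                              names_to = "source", values_to = "omega_s")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$c_r, y = .data$omega_s,
                                     colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(c[r]), y = expression(omega[s])) +
    ggplot2::theme_minimal()
}
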