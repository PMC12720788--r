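#' Wood's plot of differential uptake
#'
#' Horizontal bars spanning each peptide's residue range, one colour per
#' exposure time, with dotted lines at +/- the significance threshold.
#'
#' @param object A [woods_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdx_woods <- function(object, ...) {
  thr <- object$threshold_pct[1]
  states <- attr(object, "states")
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end,
      y = .data$delta_pct, yend = .data$delta_pct,
      colour = factor(.data$exposure_s)), linewidth = 1.2) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(
      x = "Residue", y = expression(Delta * "HDX (%)"), colour = "Time (s)",
      title = if (!is.null(states))
        sprintf("%s vs %s", states[["b"]], states[["a"]]) else NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hdx_woods
#' @param table A [woods_table()] result.
#' @export
plot_woods <- function(table) autoplot.hdx_woods(table)

#' Uptake curve with its one-exponential fit
#'
#' Observed points and the fitted `A (1 - exp(-k t))` curve on a log-scaled
#' time axis.
#'
#' @param object An `hdx_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdx_fit <- function(object, ...) {
  obs <- object$data
  tmax <- max(obs$exposure_s)
  grid <- tibble::tibble(exposure_s = exp(seq(log(1), log(tmax), length.out = 200)))
  grid$fitted <- predict(object, grid)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(.data$exposure_s, .data$fitted)) +
    ggplot2::geom_point(data = obs[obs$exposure_s > 0, ],
                        ggplot2::aes(.data$exposure_s, .data$uptake)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Exposure (s)", y = "Relative uptake (%)",
                  subtitle = sprintf("k = %.3g 1/s (%.3g 1/min)",
                                     object$k_hdx, object$k_hdx_per_min)) +
    ggplot2::theme_minimal()
}

#' Uptake curves for every peptide and state
#'
#' @param records An uptake-record tibble.
#' @return A ggplot object, faceted by peptide.
#' @export
plot_uptake_curves <- function(records) {
  r <- records |>
    dplyr::mutate(peptide = sprintf("%d-%d", .data$start, .data$end)) |>
    dplyr::filter(.data$exposure_s > 0)
  ggplot2::ggplot(r, ggplot2::aes(.data$exposure_s, .data$relative_uptake_pct,
                                  colour = .data$state)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~peptide) +
    ggplot2::labs(x = "Exposure (s)", y = "Relative uptake (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
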