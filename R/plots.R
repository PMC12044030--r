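#' Plot a gaze towardness time course
#'
#' Group mean ± SEM of towardness over time; positive values indicate gaze
#' biased toward the cued item.
#'
#' @param object A `towardness` tibble from [towardness()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.towardness <- function(object, ...) {
  summ <- object |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(m = mean(.data$towardness),
                     sem = sd(.data$towardness) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_ms, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$sem,
                                      ymax = .data$m + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from retro-cue (ms)",
                  y = "Towardness (deg)")
}

#' Plot a band-lateralization time course
#'
#' Group mean ± SEM of the contra-vs-ipsi band power index over time;
#' negative values indicate contralateral attenuation.
#'
#' @param object A `band_course` tibble from [band_course()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_course <- function(object, ...) {
  band <- attr(object, "band")
  summ <- object |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(m = mean(.data$index),
                     sem = sd(.data$index) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_ms, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$sem,
                                      ymax = .data$m + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)",
                  y = sprintf("Lateralization index, %g-%g Hz (%%)",
                              band[1], band[2]))
}

#' Plot a response-bias curve
#'
#' Group mean ± SEM of the demeaned signed report error as a function of
#' the target-interrupter angular difference; a curve whose sign follows
#' the difference sign indicates an attractive bias.
#'
#' @param object A `bias_curve` tibble from [response_bias_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bias_curve <- function(object, ...) {
  summ <- object |>
    dplyr::filter(!is.na(.data$bias)) |>
    dplyr::group_by(.data$bin_center) |>
    dplyr::summarise(m = mean(.data$bias),
                     sem = sd(.data$bias) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$bin_center, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$sem,
                                      ymax = .data$m + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Target - interrupter difference (deg)",
                  y = "Response bias (deg)")
}

#' Plot a cross-correlation function
#'
#' Coefficients over lag (ms); unreliable lags (below the minimum overlap
#' fraction) are drawn lighter.
#'
#' @param object An `xcorr_result` from [normalized_xcorr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xcorr_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms,
                                       y = .data$coefficient,
                                       alpha = .data$reliable)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Lag (ms)", y = "Normalized cross-correlation")
}
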