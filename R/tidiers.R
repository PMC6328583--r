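#' @export
tidy.rp_result <- function(x, ...) {
  x$steps
}

#' @export
glance.rp_result <- function(x, ...) {
  tibble(refractory_period = x$refractory_period, censored = x$censored,
         precision = x$precision,
         n_steps = nrow(x$steps),
         reference_amplitude = x$reference_amplitude)
}

#' Plot methods
#'
#' `autoplot.myo_trace` shows the calibrated force series with stimulus
#' markers; `autoplot.rp_result` the per-interval pair classification with
#' the determined refractory period.
#'
#' @param object A `myo_trace` or `rp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name myoslice-autoplot
NULL

#' @rdname myoslice-autoplot
#' @export
autoplot.myo_trace <- function(object, ...) {
  d <- trace_to_force(object)
  stim <- d[d$stim_current > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_rug(data = stim, sides = "b", colour = "steelblue") +
    ggplot2::labs(x = "time [s]", y = "force [mN]") +
    ggplot2::theme_minimal()
}

#' @rdname myoslice-autoplot
#' @export
autoplot.rp_result <- function(object, ...) {
  s <- object$steps
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$interval_ms,
                                       y = .data$n_two / .data$n_pairs,
                                       colour = .data$classification)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "extra-stimulus interval [ms]",
                  y = "fraction of pairs with two contractions",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (object$censored == "none") {
    p <- p + ggplot2::geom_vline(xintercept = object$refractory_period,
                                 linetype = "dashed") +
      ggplot2::labs(subtitle = sprintf("refractory period %g ms",
                                       object$refractory_period))
  }
  p
}
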