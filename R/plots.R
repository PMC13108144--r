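#' Diagnostic plots
#'
#' `autoplot()` methods give the standard diagnostics: the raw
#' photomultiplier trace with its peak/valley structure, the processed
#' normalized uptake series, a fit overlay of observed and fitted curves, and
#' the two SASCA phases side by side. `plot_uptake_curves()` draws a family
#' of model curves produced by [simulate_grid()].
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name sck-plots
NULL

#' @rdname sck-plots
#' @export
autoplot.raw_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$intensity_au)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname sck-plots
#' @export
autoplot.processed_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$f)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "normalized fluorescence f") +
    ggplot2::theme_minimal()
}

#' @rdname sck-plots
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "normalized fluorescence f",
                  title = sprintf("%s fit (R = %.4f)", object$model, object$R)) +
    ggplot2::theme_minimal()
}

#' @rdname sck-plots
#' @export
autoplot.sasca_result <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$fit_control$data, phase = "control"),
    dplyr::mutate(object$fit_inhibitor$data, phase = "inhibitor (incremental)")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = "time within phase (s)", y = "normalized fluorescence f",
                  title = sprintf("%s: fold_B = %.3g", object$cell_id, object$fold_B)) +
    ggplot2::theme_minimal()
}

#' @rdname sck-plots
#' @param curves A tibble from [simulate_grid()] (`label`, `time_s`, `f`).
#' @export
plot_uptake_curves <- function(curves, ...) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_s, y = .data$f,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalized fluorescence f", colour = NULL) +
    ggplot2::theme_minimal()
}
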