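#' Trace containers
#'
#' A *raw trace* is the uninterpreted photomultiplier recording: a tibble with
#' columns `time_s` (seconds, strictly increasing) and `intensity_au`
#' (arbitrary units), carrying acquisition metadata as an attribute. Traces
#' produced by [simulate_raw_trace()] additionally hold an `in_window` column
#' with the generator's ground-truth cell-in-window indicator, used only for
#' validation. A *processed trace* is the background-subtracted, despiked and
#' normalized intracellular uptake series: columns `time_s`, `f`
#' (dimensionless normalized fluorescence) and `baseline` (a.u.).
#'
#' @param data A data frame with numeric columns `time_s` and `intensity_au`.
#' @param metadata Named list of acquisition metadata (cell id, condition
#'   label, optional phase-switch time `t_switch`, optional ground truth).
#' @return `raw_trace()` returns a tibble of class `raw_trace`.
#' @examples
#' raw_trace(data.frame(time_s = 0:30, intensity_au = rep(100, 31)))
#' @export
raw_trace <- function(data, metadata = list()) {
  if (!is.data.frame(data) || !all(c("time_s", "intensity_au") %in% names(data))) {
    stop_sck("`data` must have columns `time_s` and `intensity_au`.")
  }
  t <- data$time_s
  x <- data$intensity_au
  if (length(t) != length(x)) stop_sck("`time_s` and `intensity_au` lengths differ.")
  if (anyNA(t) || any(!is.finite(t))) stop_sck("`time_s` contains non-finite values.")
  if (anyNA(x) || any(!is.finite(x))) stop_sck("`intensity_au` contains non-finite values.")
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop_sck(sprintf("`time_s` must be strictly increasing (violated at sample %d).", bad))
  }
  out <- tibble::as_tibble(data)
  new_raw_trace(out, metadata)
}

new_raw_trace <- function(data, metadata = list()) {
  structure(data,
    class = c("raw_trace", class(tibble::tibble())),
    metadata = metadata
  )
}

new_processed_trace <- function(data, metadata = list()) {
  structure(tibble::as_tibble(data),
    class = c("processed_trace", class(tibble::tibble())),
    metadata = metadata
  )
}

#' Retrieve trace metadata
#'
#' @param x A `raw_trace` or `processed_trace`.
#' @return The metadata list stored on the trace (possibly empty).
#' @export
trace_meta <- function(x) {
  attr(x, "metadata") %||% list()
}

#' @export
print.raw_trace <- function(x, ...) {
  meta <- trace_meta(x)
  cat(sprintf(
    "<raw_trace> %d samples over [%.6g, %.6g] s%s\n",
    nrow(x), min(x$time_s), max(x$time_s),
    if (!is.null(meta$cell_id)) paste0(" | ", meta$cell_id) else ""
  ))
  NextMethod()
}

#' @export
print.processed_trace <- function(x, ...) {
  meta <- trace_meta(x)
  cat(sprintf(
    "<processed_trace> %d samples | normalization %.6g a.u. | %d spikes removed\n",
    nrow(x),
    meta$normalization_constant %||% NA_real_,
    meta$n_spikes_removed %||% 0L
  ))
  NextMethod()
}
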