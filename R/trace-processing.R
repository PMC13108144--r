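#' Label peak and valley samples of a raw trace
#'
#' A windowed single-cell recording alternates between *peak* segments (cell
#' inside the detection window; intracellular plus background signal) and
#' *valley* segments (background only). Samples are first split by a rolling
#' quantile rule: within a centered rolling window, the midpoint between the
#' lower and upper quantiles (default 10th/90th) is the local threshold.
#' Because the uptake signal starts at zero, peaks and valleys are
#' indistinguishable near t = 0; when the alternation is periodic (the
#' default acquisition geometry), the period, phase and duty estimated from
#' the well-separated part of the trace are used to classify every sample,
#' which resolves the ambiguous leading region. The data-driven labels are
#' kept whenever no reliable periodic structure is found.
#'
#' @param trace A [raw_trace()] (or data frame with `time_s`, `intensity_au`).
#' @param threshold_quantile Lower quantile of the rolling split; the upper
#'   quantile is its complement. Default 0.1.
#' @param window Rolling window length in samples; default five
#'   window-crossing periods (from acquisition metadata when available,
#'   otherwise about a tenth of the trace).
#' @param refine_periodic Apply the periodic refinement (default `TRUE`).
#' @return The input tibble with an added `label` column (`"peak"`/`"valley"`)
#'   and a `segmentation` attribute recording `no_structure`, the estimated
#'   period/duty/phase (in samples) and whether refinement was applied. A
#'   constant trace yields the explicit no-structure outcome: all samples
#'   labelled `"peak"`, `no_structure = TRUE`, with a warning; the caller may
#'   then supply an external background.
#' @export
segment_peaks_valleys <- function(trace, threshold_quantile = 0.1,
                                  window = NULL, refine_periodic = TRUE) {
  x <- trace$intensity_au
  n <- length(x)
  if (n < 20) stop_sck("Segmentation requires at least 20 samples.")
  if (threshold_quantile <= 0 || threshold_quantile >= 0.5) {
    stop_sck("`threshold_quantile` must lie in (0, 0.5).")
  }
  if (is.null(window)) {
    meta <- trace_meta(trace)
    acq <- meta$acquisition
    window <- if (!is.null(acq$window_period) && !is.null(acq$sample_interval)) {
      round(5 * acq$window_period / acq$sample_interval)
    } else {
      max(21, round(n / 10))
    }
  }
  window <- max(5L, min(as.integer(window), n))

  gq <- quantile(x, c(0.1, 0.9), names = FALSE)
  eps <- 1e-8 * max(1, median(abs(x)))
  seg <- list(no_structure = FALSE, refined = FALSE,
              period = NA_real_, duty = NA_real_, phase = NA_real_)
  if (gq[2] - gq[1] <= eps) {
    warn("No peak/valley structure detected; treating the whole trace as peak.")
    seg$no_structure <- TRUE
    out <- dplyr::mutate(trace, label = "peak")
    attr(out, "segmentation") <- seg
    attr(out, "metadata") <- trace_meta(trace)
    return(out)
  }

  half <- window %/% 2L
  probs <- c(threshold_quantile, 1 - threshold_quantile)
  lo <- numeric(n)
  hi <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half):min(n, i + half)]
    q <- quantile(w, probs, names = FALSE)
    lo[i] <- q[1]
    hi[i] <- q[2]
  }
  is_peak <- x > (lo + hi) / 2
  informative <- (hi - lo) > 0.25 * (gq[2] - gq[1])

  if (refine_periodic) {
    ref <- periodic_label_refinement(is_peak, informative)
    if (!is.null(ref)) {
      is_peak <- ref$pred
      seg$refined <- TRUE
      seg$period <- ref$period
      seg$duty <- ref$duty
      seg$phase <- ref$phase
    }
  }

  out <- dplyr::mutate(trace, label = ifelse(is_peak, "peak", "valley"))
  attr(out, "segmentation") <- seg
  attr(out, "metadata") <- trace_meta(trace)
  out
}

# Estimate square-wave period/phase/duty (in samples) from the labels of the
# well-separated tail region; return predicted labels for the whole trace, or
# NULL when no reliable periodic structure is present.
periodic_label_refinement <- function(is_peak, informative) {
  n <- length(is_peak)
  i0 <- if (all(informative)) 1L else max(which(!informative)) + 1L
  if (i0 > n - 20L) return(NULL)
  r <- rle(is_peak[i0:n])
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L) + (i0 - 1L)
  pk <- which(r$values)
  if (length(pk) < 4L) return(NULL)
  s0 <- starts[pk] - 1L # 0-based sample index of each peak-run start
  gaps <- diff(s0)
  period <- median(gaps)
  if (period <= 1 || mad(gaps, constant = 1) / period > 0.15) return(NULL)
  # interior runs only for the duty length (boundary runs may be truncated)
  interior <- pk[pk > 1 & pk < length(r$values)]
  if (!length(interior)) return(NULL)
  duty <- median(r$lengths[interior])
  phi <- s0 %% period
  if (length(phi) > 1 && (max(phi) - min(phi)) > period / 2) {
    phi <- ifelse(phi > period / 2, phi - period, phi)
  }
  phase <- median(phi) %% period
  pred <- ((seq_len(n) - 1 - phase) %% period) < duty
  agree <- mean(pred[informative] == is_peak[informative])
  if (agree < 0.8) return(NULL)
  list(pred = pred, period = period, duty = duty, phase = phase)
}

#' Estimate the background baseline from valley segments
#'
#' The background curve is a piecewise-linear interpolation through the
#' per-valley-segment medians (robust to residual spikes), anchored at each
#' segment's median time, and extrapolated flat beyond the outermost
#' segments. It is defined at every sample of the trace.
#'
#' @param trace A labelled trace from [segment_peaks_valleys()].
#' @return The input tibble with an added `baseline` column (a.u.).
#' @export
estimate_baseline <- function(trace) {
  if (!"label" %in% names(trace)) {
    stop_sck("`trace` must carry a `label` column; run segment_peaks_valleys() first.")
  }
  valley <- trace$label == "valley"
  r <- rle(valley)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  vseg <- which(r$values)
  if (length(vseg) < 2) {
    stop_sck(paste(
      "Fewer than 2 valley segments: cannot interpolate a baseline.",
      "Supply a constant background externally (see process_trace(background=))."
    ))
  }
  anchor_t <- vapply(vseg, function(k) median(trace$time_s[starts[k]:ends[k]]), numeric(1))
  anchor_v <- vapply(vseg, function(k) median(trace$intensity_au[starts[k]:ends[k]]), numeric(1))
  base <- approx(anchor_t, anchor_v, xout = trace$time_s, rule = 2)$y
  out <- dplyr::mutate(trace, baseline = base)
  attr(out, "segmentation") <- attr(trace, "segmentation")
  attr(out, "metadata") <- trace_meta(trace)
  out
}

#' Subtract the background from the total signal
#'
#' Computes the intracellular contribution `F_cell = F_total - F_background`
#' at peak-labelled samples; valley samples are dropped from the series.
#'
#' @param trace A labelled trace with a `baseline` column.
#' @return A tibble with columns `time_s`, `f_cell`, `baseline` (peak samples
#'   only), metadata preserved.
#' @export
subtract_background <- function(trace) {
  if (!all(c("label", "baseline") %in% names(trace))) {
    stop_sck("`trace` needs `label` and `baseline` columns.")
  }
  out <- trace |>
    dplyr::filter(.data$label == "peak") |>
    dplyr::transmute(time_s = .data$time_s,
                     f_cell = .data$intensity_au - .data$baseline,
                     baseline = .data$baseline)
  attr(out, "metadata") <- trace_meta(trace)
  out
}

#' Remove transient spikes with a rolling median/MAD filter
#'
#' A sample is flagged as a spike when its deviation from the centered rolling
#' median exceeds `k` times the scaled rolling MAD (1.4826 * MAD); flagged
#' samples are replaced by the rolling median. Windows shrink at the series
#' ends.
#'
#' @param data A data frame; the filter runs on column `col`.
#' @param col Name of the value column (default `"f_cell"`).
#' @param window Odd rolling window length in samples, >= 3. Default 7.
#' @param k Deviation multiplier. Default 6.
#' @return `data` with the column despiked; attribute `n_spikes_removed`
#'   carries the count.
#' @export
remove_spikes <- function(data, col = "f_cell", window = 7, k = 6) {
  if (window < 3 || window %% 2 == 0) stop_sck("`window` must be odd and >= 3.")
  if (!col %in% names(data)) stop_sck(sprintf("Column `%s` not found.", col))
  x <- data[[col]]
  n <- length(x)
  half <- window %/% 2L
  med <- numeric(n)
  madv <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half):min(n, i + half)]
    m <- median(w)
    med[i] <- m
    madv[i] <- median(abs(w - m))
  }
  # floor the local MAD at the series-wide median MAD: a handful of samples
  # gives unstable scale estimates, and an unlucky tight window must not turn
  # ordinary noise into spikes
  madv <- pmax(madv, median(madv))
  eps <- 1e-10 * max(1, median(abs(x)))
  dev <- abs(x - med)
  flag <- dev > pmax(k * 1.4826 * madv, eps)
  # edge samples only have asymmetric windows, where a legitimate jump across
  # a sampling gap mimics a spike; never flag them
  if (n > 2 * half) {
    flag[c(seq_len(half), (n - half + 1L):n)] <- FALSE
  }
  x[flag] <- med[flag]
  out <- data
  out[[col]] <- x
  attr(out, "metadata") <- trace_meta(data)
  attr(out, "n_spikes_removed") <- sum(flag)
  out
}

#' Normalize the intracellular signal
#'
#' Divides the background-subtracted intracellular signal by the known
#' extracellular fluorescence scale, yielding the dimensionless uptake series
#' `f(t)` used for kinetic fitting.
#'
#' @param data A tibble with `time_s` and `f_cell` (from
#'   [subtract_background()], typically after [remove_spikes()]).
#' @param normalization_constant Positive scale in a.u.
#' @param metadata Optional metadata list to attach; defaults to the input's.
#' @return A `processed_trace` tibble with columns `time_s`, `f`, `baseline`.
#' @export
normalize_trace <- function(data, normalization_constant, metadata = NULL) {
  if (!is.numeric(normalization_constant) || length(normalization_constant) != 1 ||
      !is.finite(normalization_constant) || normalization_constant <= 0) {
    stop_sck("`normalization_constant` must be a single positive number.")
  }
  meta <- metadata %||% trace_meta(data)
  meta$normalization_constant <- normalization_constant
  meta$n_spikes_removed <- meta$n_spikes_removed %||%
    attr(data, "n_spikes_removed") %||% 0L
  new_processed_trace(
    tibble::tibble(time_s = data$time_s,
                   f = data$f_cell / normalization_constant,
                   baseline = data$baseline %||% NA_real_),
    metadata = meta
  )
}

#' Process a raw trace into a normalized uptake series
#'
#' Chains the full trace-processing pipeline: peak/valley segmentation,
#' baseline estimation from valley medians, background subtraction, spike
#' removal, and normalization. The time origin is kept at the first sample
#' (drug introduction).
#'
#' @param raw A [raw_trace()].
#' @param normalization_constant Scale in a.u.; `NULL` takes it from the
#'   trace's acquisition metadata. When absent there too, the late-plateau
#'   level of the background-subtracted signal (median over the last 10% of
#'   the trace) is used as a fallback so that the plateau sits near 1; this is
#'   always flagged (`normalization_fallback`) and messaged.
#' @param background Optional externally supplied background (scalar or a
#'   vector over samples). When given, segmentation is skipped, every sample
#'   is treated as peak, and this background is subtracted; this is the escape
#'   hatch for traces without peak/valley structure.
#' @param threshold_quantile,window Passed to [segment_peaks_valleys()].
#' @param spike_window,spike_k Passed to [remove_spikes()].
#' @return A `processed_trace`; metadata records the spike count, the
#'   normalization constant, any flags, and the raw trace's metadata
#'   (cell id, condition, `t_switch`, ground truth when synthetic).
#' @examples
#' tr <- simulate_raw_trace(
#'   ground_truth("one_exp", c(P = 2.8, Q = 0.001)),
#'   acquisition_config(noise_sd = 0, sample_interval = 10)
#' )
#' pt <- process_trace(tr)
#' @export
process_trace <- function(raw, normalization_constant = NULL, background = NULL,
                          threshold_quantile = 0.1, window = NULL,
                          spike_window = 7, spike_k = 6) {
  meta <- trace_meta(raw)
  flags <- character()
  if (is.null(background)) {
    lab <- segment_peaks_valleys(raw, threshold_quantile = threshold_quantile,
                                 window = window)
    seg <- attr(lab, "segmentation")
    if (isTRUE(seg$no_structure)) {
      stop_sck(paste(
        "No peak/valley structure detected.",
        "Re-run with an externally supplied `background`."
      ))
    }
    lab <- estimate_baseline(lab)
  } else {
    lab <- dplyr::mutate(raw, label = "peak", baseline = background)
    attr(lab, "metadata") <- meta
  }
  sub <- subtract_background(lab)
  des <- remove_spikes(sub, col = "f_cell", window = spike_window, k = spike_k)
  nc <- normalization_constant %||% meta$acquisition$normalization_constant
  if (is.null(nc)) {
    tail_idx <- des$time_s >= quantile(des$time_s, 0.9)
    nc <- median(des$f_cell[tail_idx])
    if (!is.finite(nc) || nc <= 0) {
      stop_sck("Normalization fallback failed (non-positive plateau); supply `normalization_constant`.")
    }
    flags <- c(flags, "normalization_fallback")
    message(sprintf(
      "No normalization constant supplied; using late-plateau level %.4g a.u. (flagged).", nc))
  }
  out_meta <- meta
  out_meta$n_spikes_removed <- attr(des, "n_spikes_removed")
  out_meta$flags <- flags
  normalize_trace(des, nc, metadata = out_meta)
}
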