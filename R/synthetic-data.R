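#' Ground-truth kinetic parameter set
#'
#' Bundles a model kind with its parameter vector for use by the simulators:
#' either the one-exponential saturating uptake model `f(t) = P (1 - e^(-Q t))`
#' or the two-exponential model `f(t) = A (1 - e^(-B t)) + C (1 - e^(-D t))`.
#' Amplitudes are dimensionless normalized fluorescence, rates are in s^-1.
#' Two-exponential parameters are canonicalized so the fast rate comes first
#' (`B >= D`).
#'
#' @param model `"one_exp"` or `"two_exp"`.
#' @param params Named numeric vector: `c(P, Q)` or `c(A, B, C, D)`. Unnamed
#'   vectors of the right length are accepted in that order.
#' @return An object of class `ground_truth`.
#' @examples
#' ground_truth("two_exp", c(A = 0.4378, B = 0.0556, C = 0.4905, D = 0.0046))
#' @export
ground_truth <- function(model = c("one_exp", "two_exp"), params) {
  model <- match.arg(model)
  params <- unlist(params)
  need <- if (model == "one_exp") c("P", "Q") else c("A", "B", "C", "D")
  if (is.null(names(params)) && length(params) == length(need)) {
    names(params) <- need
  }
  if (!setequal(names(params), need) || length(params) != length(need)) {
    stop_sck(sprintf("`params` for %s must be named %s.",
                     model, paste(need, collapse = ", ")))
  }
  params <- params[need]
  bad <- names(params)[!is.finite(params)]
  if (length(bad)) {
    stop_sck(sprintf("Non-finite parameter value for field `%s`.", bad[1]))
  }
  amps <- params[names(params) %in% c("P", "A", "C")]
  rates <- params[names(params) %in% c("Q", "B", "D")]
  if (any(amps < 0)) {
    stop_sck(sprintf("Amplitude `%s` must be >= 0.",
                     names(amps)[which(amps < 0)[1]]))
  }
  if (any(rates <= 0)) {
    stop_sck(sprintf("Rate `%s` must be > 0.",
                     names(rates)[which(rates <= 0)[1]]))
  }
  if (model == "two_exp" && params[["B"]] < params[["D"]]) {
    params <- params[c("C", "D", "A", "B")]
    names(params) <- c("A", "B", "C", "D")
  }
  structure(list(model = model, params = params), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %s\n", x$model,
              paste(sprintf("%s=%.6g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

# evaluate a ground truth curve at times t
eval_truth <- function(truth, t) {
  p <- truth$params
  if (truth$model == "one_exp") {
    eval_one_exp(p[["P"]], p[["Q"]], t)
  } else {
    eval_two_exp(p[["A"]], p[["B"]], p[["C"]], p[["D"]], t)
  }
}

truth_plateau <- function(truth) {
  p <- truth$params
  if (truth$model == "one_exp") p[["P"]] else p[["A"]] + p[["C"]]
}

#' Acquisition configuration for the trace simulators
#'
#' Describes a photomultiplier-style acquisition: a fixed-interval sampling
#' grid; a square-wave alternation between *peak* segments (cell inside the
#' detection window: background + scaled intracellular signal) and *valley*
#' segments (background only); an optionally drifting background; additive
#' Gaussian noise; and sparse isolated single-sample spikes.
#'
#' Defaults reflect the measurement this generator emulates: 1 s sampling over
#' 3000 s (uptake plateaus are reached within roughly 2000-3000 s at the
#' published rate constants), a 60 s window-crossing period with 50% duty, a
#' 100 a.u. background, a 100 a.u. normalization constant (extracellular DNR
#' fluorescence scale), and noise of 2 a.u. (2% of the normalization scale).
#' Spikes are off by default; set `spike_rate > 0` to superpose them.
#'
#' @param duration Trace length, s.
#' @param sample_interval Sampling interval, s.
#' @param background_level Background fluorescence at t = 0, a.u.
#' @param background_drift_slope Linear background drift, a.u./s.
#' @param window_period Period of the peak/valley alternation, s.
#' @param window_duty Fraction of each period spent in the peak state, (0, 1).
#' @param spike_rate Expected isolated spike events per second.
#' @param spike_amplitude Added intensity of a spike, a.u.
#' @param noise_sd Gaussian noise standard deviation, a.u.
#' @param normalization_constant Scale mapping normalized fluorescence f to
#'   a.u. (the known extracellular DNR fluorescence intensity).
#' @param seed Integer seed; simulation is bitwise reproducible for a fixed
#'   seed.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(duration = 3000, sample_interval = 1,
                               background_level = 100,
                               background_drift_slope = 0,
                               window_period = 60, window_duty = 0.5,
                               spike_rate = 0, spike_amplitude = 50,
                               noise_sd = 2, normalization_constant = 100,
                               seed = 1L) {
  num_fields <- list(
    duration = duration, sample_interval = sample_interval,
    background_level = background_level,
    background_drift_slope = background_drift_slope,
    window_period = window_period, window_duty = window_duty,
    spike_rate = spike_rate, spike_amplitude = spike_amplitude,
    noise_sd = noise_sd, normalization_constant = normalization_constant
  )
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop_sck(sprintf("Acquisition field `%s` must be a finite number.", nm))
    }
  }
  if (duration <= 0) stop_sck("`duration` must be > 0.")
  if (sample_interval <= 0 || sample_interval >= duration) {
    stop_sck("`sample_interval` must satisfy 0 < sample_interval < duration.")
  }
  if (noise_sd < 0) stop_sck("`noise_sd` must be >= 0.")
  if (spike_rate < 0) stop_sck("`spike_rate` must be >= 0.")
  if (window_duty <= 0 || window_duty >= 1) {
    stop_sck("`window_duty` must lie strictly in (0, 1).")
  }
  if (window_period <= 0) stop_sck("`window_period` must be > 0.")
  if (normalization_constant <= 0) stop_sck("`normalization_constant` must be > 0.")
  structure(c(num_fields, list(seed = as.integer(seed))),
            class = "acquisition_config")
}

#' Two-phase schedule for a same-single-cell (SASCA) simulation
#'
#' Describes a sequential experiment on one cell: uptake follows `phase1`
#' kinetics until `t_switch` (the inhibitor introduction), after which the
#' normalized signal is `phase2_offset + f2(t - t_switch)` with `phase2`
#' kinetics re-zeroed at the switch. By default `phase2_offset` is the phase-1
#' value at `t_switch`, making the composite curve continuous.
#'
#' @param t_switch Solution-switch time, s; must lie on the sampling grid and
#'   strictly inside the acquisition window.
#' @param phase1,phase2 [ground_truth()] objects for the two phases. The
#'   phase-2 truth describes the *incremental* rise above the carried-over
#'   level.
#' @param phase2_offset Dimensionless level carried over from phase 1;
#'   `NULL` (default) means the phase-1 curve value at `t_switch`.
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(t_switch, phase1, phase2, phase2_offset = NULL) {
  if (!inherits(phase1, "ground_truth") || !inherits(phase2, "ground_truth")) {
    stop_sck("`phase1` and `phase2` must be ground_truth objects.")
  }
  if (!is.numeric(t_switch) || length(t_switch) != 1 || !is.finite(t_switch) ||
      t_switch <= 0) {
    stop_sck("`t_switch` must be a positive finite number.")
  }
  if (!is.null(phase2_offset)) {
    if (!is.numeric(phase2_offset) || phase2_offset < 0) {
      stop_sck("`phase2_offset` must be >= 0.")
    }
  }
  structure(list(t_switch = t_switch, phase1 = phase1, phase2 = phase2,
                 phase2_offset = phase2_offset),
            class = "phase_schedule")
}

#' Heterogeneous cell population specification
#'
#' Parameter heterogeneity across cells is modeled as independent lognormal
#' spread around per-parameter medians (positivity plus the right skew seen in
#' measured resistant-cell cohorts). A geometric CV of 0 collapses the
#' population onto identical parameters.
#'
#' @param n_cells Number of cells (>= 1).
#' @param model `"one_exp"` or `"two_exp"`.
#' @param medians Named vector of per-parameter medians. `NULL` uses the
#'   medians of the matching published reference cohort ([cem_vlb_fits()] for
#'   `two_exp`, [cem_wt_fits()] for `one_exp`).
#' @param gcv Geometric coefficient of variation, a scalar or named per
#'   parameter; the lognormal sdlog is `sqrt(log(1 + gcv^2))`.
#' @param condition_label Text label attached to every cell.
#' @param seed Integer seed for the population draw.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, model = c("one_exp", "two_exp"),
                            medians = NULL, gcv = 0.5,
                            condition_label = "control", seed = 1L) {
  model <- match.arg(model)
  if (!is.numeric(n_cells) || n_cells < 1) stop_sck("`n_cells` must be >= 1.")
  need <- if (model == "one_exp") c("P", "Q") else c("A", "B", "C", "D")
  if (is.null(medians)) {
    medians <- if (model == "two_exp") {
      ref <- cem_vlb_fits()
      vapply(need, function(p) median(ref[[p]]), numeric(1))
    } else {
      ref <- dplyr::filter(cem_wt_fits(), .data$model == "one_exp")
      vapply(need, function(p) median(ref[[p]]), numeric(1))
    }
  }
  medians <- unlist(medians)[need]
  if (anyNA(medians) || any(medians <= 0)) {
    stop_sck("`medians` must be positive and cover all model parameters.")
  }
  if (length(gcv) == 1 && is.null(names(gcv))) gcv <- setNames(rep(gcv, length(need)), need)
  gcv <- unlist(gcv)[need]
  if (anyNA(gcv) || any(gcv < 0)) stop_sck("`gcv` must be >= 0 for every parameter.")
  structure(list(n_cells = as.integer(n_cells), model = model,
                 medians = medians, gcv = gcv,
                 condition_label = condition_label, seed = as.integer(seed)),
            class = "population_spec")
}

#' Simulate a raw photomultiplier uptake trace
#'
#' Generates the square-wave peak/valley structure of a windowed single-cell
#' recording: during peak segments the intensity is
#' `background(t) + normalization_constant * f(t) + noise`, during valley
#' segments `background(t) + noise`, where `f(t)` is the ground-truth uptake
#' curve. Optional spikes are isolated positive single-sample excursions.
#'
#' @param truth A [ground_truth()] object.
#' @param acq An [acquisition_config()].
#' @param cell_id,condition Metadata labels recorded on the trace.
#' @return A [raw_trace()] tibble with columns `time_s`, `intensity_au` and the
#'   ground-truth `in_window` indicator; metadata carries the configuration,
#'   seed and ground truth.
#' @examples
#' tr <- simulate_raw_trace(
#'   ground_truth("one_exp", c(P = 2.8010, Q = 0.0008)),
#'   acquisition_config(noise_sd = 0, seed = 7)
#' )
#' @export
simulate_raw_trace <- function(truth, acq = acquisition_config(),
                               cell_id = "cell-1", condition = "control") {
  if (!inherits(truth, "ground_truth")) stop_sck("`truth` must be a ground_truth object.")
  if (!inherits(acq, "acquisition_config")) stop_sck("`acq` must be an acquisition_config.")
  f_fun <- function(t) eval_truth(truth, t)
  sim_trace_impl(f_fun, acq, cell_id = cell_id, condition = condition,
                 extra_meta = list(ground_truth = unclass(truth)))
}

#' Simulate a two-phase same-single-cell (SASCA) trace
#'
#' @param schedule A [phase_schedule()].
#' @param acq An [acquisition_config()]; `t_switch` must fall on its sampling
#'   grid and strictly inside the acquisition window.
#' @param cell_id,condition Metadata labels.
#' @return A [raw_trace()] whose metadata records `t_switch` and both phase
#'   ground truths.
#' @export
simulate_sasca_trace <- function(schedule, acq = acquisition_config(duration = 3000),
                                 cell_id = "cell-1", condition = "sasca") {
  if (!inherits(schedule, "phase_schedule")) stop_sck("`schedule` must be a phase_schedule.")
  if (!inherits(acq, "acquisition_config")) stop_sck("`acq` must be an acquisition_config.")
  ts <- schedule$t_switch
  if (ts <= 0 || ts >= acq$duration) {
    stop_sck("`t_switch` must lie strictly inside the acquisition window.")
  }
  grid_pos <- ts / acq$sample_interval
  if (abs(grid_pos - round(grid_pos)) > 1e-9) {
    stop_sck("`t_switch` must fall on the sampling grid.")
  }
  offset <- schedule$phase2_offset %||% eval_truth(schedule$phase1, ts)
  f_fun <- function(t) {
    ifelse(t < ts,
           eval_truth(schedule$phase1, t),
           offset + eval_truth(schedule$phase2, pmax(t - ts, 0)))
  }
  sim_trace_impl(f_fun, acq, cell_id = cell_id, condition = condition,
                 extra_meta = list(
                   t_switch = ts,
                   phase2_offset = offset,
                   ground_truth_phase1 = unclass(schedule$phase1),
                   ground_truth_phase2 = unclass(schedule$phase2)
                 ))
}

# shared simulator core; f_fun maps time -> normalized signal
sim_trace_impl <- function(f_fun, acq, cell_id, condition, extra_meta = list()) {
  withr::with_seed(acq$seed, {
    t <- seq(0, acq$duration, by = acq$sample_interval)
    n <- length(t)
    in_window <- (t %% acq$window_period) < acq$window_duty * acq$window_period
    background <- acq$background_level + acq$background_drift_slope * t
    f <- f_fun(t)
    x <- background + ifelse(in_window, acq$normalization_constant * f, 0)
    if (acq$noise_sd > 0) x <- x + rnorm(n, 0, acq$noise_sd)
    if (acq$spike_rate > 0) {
      p <- min(1, acq$spike_rate * acq$sample_interval)
      idx <- which(runif(n) < p)
      if (length(idx) > 1) {
        # keep only isolated events: drop any event within one sample of the
        # previously kept one
        keep <- idx[1]
        for (i in idx[-1]) if (i - keep[length(keep)] > 1) keep <- c(keep, i)
        idx <- keep
      }
      x[idx] <- x[idx] + acq$spike_amplitude
    }
  })
  meta <- c(list(cell_id = cell_id, condition = condition,
                 seed = acq$seed, acquisition = unclass(acq)),
            extra_meta)
  new_raw_trace(tibble::tibble(time_s = t, intensity_au = x, in_window = in_window),
                metadata = meta)
}

#' Simulate a heterogeneous single-cell cohort
#'
#' Draws `n_cells` ground-truth parameter sets from the population lognormals
#' and simulates one raw trace per cell. Parameter draws depend only on the
#' population seed (one vectorized draw per parameter), so the multiset of
#' drawn parameters is invariant to cell ordering; each cell's trace uses its
#' own derived seed `spec$seed + i`.
#'
#' @param spec A [population_spec()].
#' @param acq An [acquisition_config()] shared by all cells (per-cell seeds are
#'   derived from `spec$seed`).
#' @return A tibble with one row per cell: `cell_id`, `condition`, list-columns
#'   `truth` ([ground_truth()]) and `trace` ([raw_trace()]).
#' @examples
#' coh <- simulate_cohort(
#'   population_spec(3, "two_exp", gcv = 0, seed = 2),
#'   acquisition_config(sample_interval = 10, noise_sd = 0)
#' )
#' @export
simulate_cohort <- function(spec, acq = acquisition_config()) {
  if (!inherits(spec, "population_spec")) stop_sck("`spec` must be a population_spec.")
  n <- spec$n_cells
  sdlog <- sqrt(log(1 + spec$gcv^2))
  draws <- withr::with_seed(spec$seed, {
    vapply(seq_along(spec$medians), function(j) {
      rlnorm(n, meanlog = log(spec$medians[j]), sdlog = sdlog[j])
    }, numeric(n))
  })
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, names(spec$medians)))
  purrr::map_dfr(seq_len(n), function(i) {
    truth_i <- ground_truth(spec$model, draws[i, ])
    acq_i <- acq
    acq_i$seed <- spec$seed + i
    cell_id <- sprintf("cell-%03d", i)
    trace_i <- simulate_raw_trace(truth_i, acq_i, cell_id = cell_id,
                                  condition = spec$condition_label)
    tibble::tibble(
      cell_id = cell_id,
      condition = spec$condition_label,
      truth = list(truth_i),
      trace = list(trace_i)
    )
  })
}
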