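#' Split a two-phase trace at the inhibitor switch
#'
#' Same-single-cell analysis (SASCA) records two sequential uptake phases in
#' one cell: drug alone, then drug plus an efflux inhibitor. Because the
#' exponential uptake models force `f(0) = 0`, the second phase is analyzed
#' on the *incremental* scale: its samples are re-zeroed in time at
#' `t_switch` and offset-subtracted by the phase-1 fitted plateau (the steady
#' state carried over from phase 1).
#'
#' @param trace A `processed_trace` (or data frame with `time_s`, `f`)
#'   covering both phases.
#' @param t_switch Switch time in seconds; taken from the trace metadata when
#'   `NULL`. Must lie strictly inside the observed span.
#' @param offset Steady-state level to subtract from phase 2; `NULL` (default)
#'   fits the two-exponential model to phase 1 and uses its plateau.
#' @param min_samples Minimum samples required in each phase (default 12,
#'   the two-exponential fitting minimum).
#' @return A list: `phase1` and `phase2` (tibbles with `time_s`, `f`; phase 2
#'   re-zeroed and offset-subtracted), `offset`, and `fit1` (the phase-1
#'   `kinetic_fit` when it was computed here, else `NULL`).
#' @export
split_phases <- function(trace, t_switch = NULL, offset = NULL, min_samples = 12) {
  d <- as_fit_data(trace)
  ts <- t_switch %||% trace_meta(trace)$t_switch
  if (is.null(ts)) stop_sck("`t_switch` not supplied and absent from metadata.")
  if (ts <= min(d$time_s) || ts > max(d$time_s) ||
      ts >= max(d$time_s) - sqrt(.Machine$double.eps)) {
    stop_sck("`t_switch` must lie strictly inside the observation span.")
  }
  i1 <- d$time_s < ts
  i2 <- !i1
  if (sum(i1) < min_samples || sum(i2) < min_samples) {
    stop_sck(sprintf("Each phase needs at least %d samples.", min_samples))
  }
  phase1 <- d[i1, ]
  fit1 <- NULL
  if (is.null(offset)) {
    fit1 <- fit_two_exp(phase1)
    offset <- derived_metrics(fit1)$plateau
  }
  phase2 <- tibble::tibble(time_s = d$time_s[i2] - ts, f = d$f[i2] - offset)
  list(phase1 = phase1, phase2 = phase2, offset = offset, fit1 = fit1)
}

#' Same-single-cell before/after-inhibitor comparison
#'
#' Fits the two-exponential model separately to the control and inhibitor
#' phases of one cell and reports within-cell fold changes, the quantity that
#' survives the cell-to-cell heterogeneity which defeats cross-cell
#' comparison. `fold_B` is the ratio of fast uptake rate constants
#' (inhibitor / control). Two plateau folds are reported: the *incremental*
#' fold `(A+C)_2 / (A+C)_1` compares the second rise to the first, while the
#' *cumulative* fold `((A+C)_1 + (A+C)_2) / (A+C)_1` compares the final to
#' the first steady state.
#'
#' @inheritParams split_phases
#' @param cell_id Label for the result; taken from metadata when `NULL`.
#' @return A `sasca_result`: `cell_id`, `fit_control`, `fit_inhibitor`,
#'   `fold_B`, `fold_plateau` (incremental), `fold_plateau_cumulative`,
#'   `t_switch`, `flags`. Flagged phase fits flag the result but folds are
#'   still reported.
#' @examples
#' ctrl <- ground_truth("two_exp", c(A = 0.4378, B = 0.0556, C = 0.4905, D = 0.0046))
#' inh <- ground_truth("two_exp", c(A = 0.1614, B = 0.0973, C = 0.3972, D = 0.0053))
#' tr <- simulate_sasca_trace(phase_schedule(1500, ctrl, inh),
#'                            acquisition_config(duration = 4500, sample_interval = 10,
#'                                               noise_sd = 0))
#' res <- sasca_compare(process_trace(tr))
#' res$fold_B
#' @export
sasca_compare <- function(trace, t_switch = NULL, cell_id = NULL, min_samples = 12) {
  meta <- trace_meta(trace)
  cell_id <- cell_id %||% meta$cell_id %||% "cell"
  sp <- split_phases(trace, t_switch = t_switch, min_samples = min_samples)
  fit1 <- sp$fit1 %||% fit_two_exp(sp$phase1)
  # negative incremental samples (noise around the carried-over level) are
  # admissible for least squares; fit as-is
  fit2 <- fit_two_exp(sp$phase2)
  p1 <- derived_metrics(fit1)$plateau
  p2 <- derived_metrics(fit2)$plateau
  rate1 <- if (fit1$model == "two_exp") fit1$params[["B"]] else fit1$params[["Q"]]
  rate2 <- if (fit2$model == "two_exp") fit2$params[["B"]] else fit2$params[["Q"]]
  flags <- unique(c(fit1$flags, fit2$flags))
  structure(list(
    cell_id = cell_id,
    fit_control = fit1,
    fit_inhibitor = fit2,
    fold_B = rate2 / rate1,
    fold_plateau = p2 / p1,
    fold_plateau_cumulative = (p1 + p2) / p1,
    t_switch = t_switch %||% meta$t_switch,
    flags = flags
  ), class = "sasca_result")
}

#' Cross-cell (DISCA) cohort summary
#'
#' Different-single-cell analysis compares conditions across distinct cells.
#' For each kinetic parameter this summarizes the per-group range, whether
#' the two groups' ranges intersect (the heterogeneity-masking signature:
#' overlapping ranges mean no between-group difference can be resolved from
#' ranges alone), and a descriptive two-sided Mann-Whitney rank-test p-value.
#'
#' @param cohort A data frame with one row per cell carrying the parameter
#'   columns and a grouping column. A `plateau` column is derived as `A + C`
#'   when absent.
#' @param group Grouping column (unquoted or a string); exactly two groups.
#' @param params Parameter columns to summarize. Default
#'   `c("A", "B", "C", "D", "plateau")`.
#' @return A `disca_summary`: `ranges` (long tibble of per-group min/max),
#'   `comparison` (per-parameter overlap flag and rank-test p), and
#'   `group_sizes`.
#' @examples
#' coh <- dplyr::bind_rows(cem_vlb_fits(), cem_vlb_csa_fits())
#' disca_summarize(coh, condition, params = "plateau")
#' @export
disca_summarize <- function(cohort, group, params = c("A", "B", "C", "D", "plateau")) {
  gcol <- as_name(enquo(group))
  if (!gcol %in% names(cohort)) stop_sck(sprintf("Grouping column `%s` not found.", gcol))
  if ("plateau" %in% params && !"plateau" %in% names(cohort)) {
    cohort <- dplyr::mutate(cohort, plateau = .data$A + .data$C)
  }
  missing_p <- setdiff(params, names(cohort))
  if (length(missing_p)) {
    stop_sck(sprintf("Parameter column(s) not found: %s.", paste(missing_p, collapse = ", ")))
  }
  g <- as.character(cohort[[gcol]])
  levels <- unique(g)
  if (length(levels) != 2) stop_sck("disca_summarize() compares exactly two groups.")
  sizes <- table(factor(g, levels = levels))
  if (any(sizes < 1)) stop_sck("Each group needs at least one cell.")

  ranges <- cohort |>
    dplyr::mutate(.group = g) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$parameter, .data$.group) |>
    dplyr::summarise(n = dplyr::n(), min = min(.data$value), max = max(.data$value),
                     .groups = "drop") |>
    dplyr::rename(group = ".group")

  comparison <- purrr::map_dfr(params, function(p) {
    v1 <- cohort[[p]][g == levels[1]]
    v2 <- cohort[[p]][g == levels[2]]
    ov <- max(min(v1), min(v2)) <= min(max(v1), max(v2))
    pv <- if (length(v1) >= 1 && length(v2) >= 1) {
      suppressWarnings(wilcox.test(v1, v2, exact = FALSE)$p.value)
    } else NA_real_
    tibble::tibble(parameter = p, overlap = ov, p_value = pv)
  })

  structure(list(ranges = ranges, comparison = comparison,
                 groups = levels, group_sizes = as.integer(sizes)),
            class = "disca_summary")
}

#' @export
print.sasca_result <- function(x, ...) {
  cat(sprintf("<sasca_result> %s (t_switch = %s s)\n", x$cell_id,
              format(x$t_switch %||% NA)))
  cat(sprintf("  fold_B = %.4g | fold_plateau (incremental) = %.4g | (cumulative) = %.4g\n",
              x$fold_B, x$fold_plateau, x$fold_plateau_cumulative))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' @export
print.disca_summary <- function(x, ...) {
  cat(sprintf("<disca_summary> groups: %s (n = %s)\n",
              paste(x$groups, collapse = " vs "),
              paste(x$group_sizes, collapse = ", ")))
  print(x$comparison)
  invisible(x)
}
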