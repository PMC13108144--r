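#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return `tidy()` gives one row per parameter (`term`, `estimate`);
#'   `glance()` a one-row model summary; `augment()` the observed series with
#'   `.fitted` and `.resid`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  dm <- derived_metrics(x)
  tibble::tibble(model = x$model, R = x$R, rss = x$rss, n_obs = x$n_obs,
                 plateau = dm$plateau, half_time_s = dm$half_time_s,
                 converged = x$converged,
                 flags = if (length(x$flags)) paste(x$flags, collapse = ";") else NA_character_)
}

#' @rdname tidy.kinetic_fit
#' @export
augment.kinetic_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = .data$fitted, .resid = .data$observed - .data$fitted,
                fitted = NULL)
}

#' Tidy an F-test result
#'
#' @param x An `f_test_result`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, degrees of freedom, p-value,
#'   threshold and selection.
#' @export
tidy.f_test_result <- function(x, ...) {
  tibble::tibble(F_stat = x$F_stat, df_num = x$df_num, df_den = x$df_den,
                 p_value = x$p_value, alpha = x$alpha, selected = x$selected,
                 flags = if (length(x$flags)) paste(x$flags, collapse = ";") else NA_character_)
}

#' @rdname tidy.f_test_result
#' @export
glance.model_selection <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(selected = x$test$selected),
                   tidy(x$test)[c("F_stat", "p_value", "alpha")],
                   rss_one = x$fit_one$rss, rss_two = x$fit_two$rss)
}

#' Tidy a SASCA result
#'
#' @param x A `sasca_result`.
#' @param ... Unused.
#' @return `tidy()` gives per-phase parameter rows; `glance()` the one-row
#'   fold-change summary.
#' @export
tidy.sasca_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$fit_control), cell_id = x$cell_id, phase = "control"),
    dplyr::mutate(tidy(x$fit_inhibitor), cell_id = x$cell_id, phase = "inhibitor")
  ) |>
    dplyr::select("cell_id", "phase", "term", "estimate")
}

#' @rdname tidy.sasca_result
#' @export
glance.sasca_result <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_id, t_switch = x$t_switch %||% NA_real_,
                 fold_B = x$fold_B, fold_plateau = x$fold_plateau,
                 fold_plateau_cumulative = x$fold_plateau_cumulative,
                 flags = if (length(x$flags)) paste(x$flags, collapse = ";") else NA_character_)
}

#' Tidy a DISCA cohort summary
#'
#' @param x A `disca_summary`.
#' @param ... Unused.
#' @return One row per parameter: per-group min/max, the overlap flag and the
#'   rank-test p-value.
#' @export
tidy.disca_summary <- function(x, ...) {
  wide <- x$ranges |>
    tidyr::pivot_wider(names_from = "group", values_from = c("n", "min", "max"))
  dplyr::left_join(x$comparison, wide, by = "parameter")
}
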