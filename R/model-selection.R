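#' Extra-sum-of-squares F statistic for nested exponential models
#'
#' The one-exponential model is the two-exponential model with the second
#' component removed (two fewer parameters), so the models are nested and the
#' improvement in residual sum of squares can be tested with
#' `F = ((rss1 - rss2) / 2) / (rss2 / (n - 4))`, referred to the
#' `F(2, n - 4)` upper tail.
#'
#' @param rss1,rss2 Residual sums of squares of the one- and two-exponential
#'   fits on the same data (`rss1 >= rss2`).
#' @param n Number of observations (> 4).
#' @return The F statistic.
#' @examples
#' f_statistic(2, 1, 104) # 50
#' @export
f_statistic <- function(rss1, rss2, n) {
  if (n <= 4) stop_sck("The F-test needs more than 4 observations.")
  ((rss1 - rss2) / 2) / (rss2 / (n - 4))
}

#' Nested-model F-test between one- and two-exponential fits
#'
#' Decides whether the second exponential component significantly improves
#' the fit. Both fits must be on the identical observation vector; if the
#' two-exponential fit is worse (a failed optimization), it is first refit
#' from the one-exponential solution so that `rss1 >= rss2` holds. A
#' two-exponential fit with essentially zero residual (noiseless input) makes
#' the statistic undefined; such cases select the two-exponential model with
#' `p = 0` and the `degenerate_perfect_fit` flag.
#'
#' @param fit1 One-exponential `kinetic_fit`.
#' @param fit2 Two-exponential `kinetic_fit` on the same observations.
#' @param alpha Significance level; the two-exponential model is selected iff
#'   `p < alpha`. Default 0.05.
#' @return An `f_test_result`: `F_stat`, `df_num` (2), `df_den` (n - 4),
#'   `p_value`, `alpha`, `selected` and `flags`.
#' @export
f_test_nested <- function(fit1, fit2, alpha = 0.05) {
  if (!inherits(fit1, "kinetic_fit") || !inherits(fit2, "kinetic_fit")) {
    stop_sck("`fit1` and `fit2` must be kinetic_fit objects.")
  }
  if (fit1$model != "one_exp") stop_sck("`fit1` must be a one-exponential fit.")
  if (fit2$model != "two_exp" && !"rate_collapse" %in% fit2$flags) {
    stop_sck("`fit2` must be a two-exponential fit (or its flagged collapse).")
  }
  if (fit1$n_obs != fit2$n_obs ||
      max(abs(fit1$data$observed - fit2$data$observed)) > 1e-9) {
    stop_sck("Both fits must be computed on the identical observation vector.")
  }
  n <- fit1$n_obs
  rss1 <- fit1$rss
  rss2 <- fit2$rss
  flags <- character()
  if (rss2 > rss1) {
    refit <- refit_two_from_one(fit1)
    if (!is.null(refit) && refit$rss < rss2) {
      fit2 <- refit
      rss2 <- refit$rss
    }
    rss2 <- min(rss2, rss1)
    flags <- c(flags, "refit_from_nested")
  }
  if (rss2 <= 1e-16 * sum(fit1$data$observed^2) || rss2 == 0) {
    res <- list(F_stat = Inf, df_num = 2L, df_den = n - 4L, p_value = 0,
                alpha = alpha, selected = "two_exp",
                flags = c(flags, "degenerate_perfect_fit"),
                fit2 = fit2)
    return(structure(res, class = "f_test_result"))
  }
  F_stat <- f_statistic(rss1, rss2, n)
  p <- pf(F_stat, 2, n - 4, lower.tail = FALSE)
  structure(list(F_stat = F_stat, df_num = 2L, df_den = n - 4L, p_value = p,
                 alpha = alpha,
                 selected = if (p < alpha) "two_exp" else "one_exp",
                 flags = flags, fit2 = fit2),
            class = "f_test_result")
}

# LM refinement of the two-exponential model seeded at the one-exponential
# solution (C = 0), used to enforce rss2 <= rss1
refit_two_from_one <- function(fit1) {
  d <- tibble::tibble(time_s = fit1$data$time_s, f = fit1$data$observed)
  start <- c(fit1$params[["P"]], fit1$params[["Q"]], 0, fit1$params[["Q"]] / 20)
  resid_fn <- function(p) {
    d$f - (p[1] * (1 - exp(-p[2] * d$time_s)) + p[3] * (1 - exp(-p[4] * d$time_s)))
  }
  cand <- lm_refine(pmax(start, c(0, 1e-10, 0, 1e-10)), resid_fn,
                    lower = c(0, 1e-12, 0, 1e-12))
  if (is.null(cand)) return(NULL)
  par <- cand$par
  if (par[2] < par[4]) par <- par[c(3, 4, 1, 2)]
  params <- setNames(par, c("A", "B", "C", "D"))
  fitted <- eval_two_exp(params[["A"]], params[["B"]], params[["C"]],
                         params[["D"]], d$time_s)
  new_kinetic_fit("two_exp", params, d, fitted, cand$converged)
}

#' Fit both uptake models and select between them
#'
#' The per-cell workflow: fit the one- and two-exponential models on the same
#' processed trace, run the nested F-test, and report the selected fit
#' together with the full test record. The non-selected fit is retained.
#'
#' @param data A `processed_trace` or data frame with `time_s` and `f`.
#' @param alpha Significance level of the F-test. Default 0.05.
#' @return A `model_selection` object: `fit` (the selected `kinetic_fit`),
#'   `test` (`f_test_result`), `fit_one`, `fit_two`.
#' @examples
#' tt <- seq(0, 3000, 10)
#' d <- tibble::tibble(time_s = tt,
#'                     f = eval_two_exp(0.44, 0.056, 0.49, 0.0046, tt))
#' sel <- select_model(d)
#' sel$test$selected
#' @export
select_model <- function(data, alpha = 0.05) {
  fit1 <- fit_one_exp(data)
  fit2 <- fit_two_exp(data)
  if (!fit1$converged || !fit2$converged) {
    stop_sck(
      sprintf(paste("Model selection aborted: non-convergent fit",
                    "(one_exp converged: %s, two_exp converged: %s)."),
              fit1$converged, fit2$converged),
      one_exp = fit1, two_exp = fit2
    )
  }
  test <- f_test_nested(fit1, fit2, alpha = alpha)
  fit2 <- test$fit2 # possibly refit to restore nesting
  structure(list(
    fit = if (test$selected == "two_exp") fit2 else fit1,
    test = test, fit_one = fit1, fit_two = fit2
  ), class = "model_selection")
}

#' @export
print.f_test_result <- function(x, ...) {
  cat(sprintf(
    "<f_test_result> F(%d, %d) = %.4g, p = %.4g (alpha = %g) -> %s%s\n",
    x$df_num, x$df_den, x$F_stat, x$p_value, x$alpha, x$selected,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""
  ))
  invisible(x)
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> selected: %s\n", x$test$selected))
  print(x$test)
  print(x$fit)
  invisible(x)
}
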