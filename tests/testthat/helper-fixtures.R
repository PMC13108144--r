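# reference parameter shorthands used across the suite
wt148 <- c(P = 2.8010, Q = 0.0008)
vlb58 <- c(A = 0.4378, B = 0.0556, C = 0.4905, D = 0.0046)
inh58 <- c(A = 0.1614, B = 0.0973, C = 0.3972, D = 0.0053)

# noiseless model curve on a regular grid, as fitting input
clean_curve <- function(params, dt = 1, duration = 3000) {
  tt <- seq(0, duration, by = dt)
  f <- if (length(params) == 2) {
    eval_one_exp(params[["P"]], params[["Q"]], tt)
  } else {
    eval_two_exp(params[["A"]], params[["B"]], params[["C"]], params[["D"]], tt)
  }
  tibble::tibble(time_s = tt, f = f)
}

# the same curve with seeded additive Gaussian noise
noisy_curve <- function(params, sd, seed, dt = 10, duration = 3000) {
  d <- clean_curve(params, dt = dt, duration = duration)
  withr::with_seed(seed, dplyr::mutate(d, f = f + rnorm(dplyr::n(), 0, sd)))
}

noiseless_acq <- function(...) {
  acquisition_config(noise_sd = 0, spike_rate = 0, ...)
}
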