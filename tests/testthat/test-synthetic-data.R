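test_that("noiseless trace carries only background in valleys and background + scaled f in peaks", {
  truth <- ground_truth("one_exp", c(P = 1, Q = 0.001))
  acq <- noiseless_acq(background_level = 100, normalization_constant = 100)
  tr <- simulate_raw_trace(truth, acq)
  valleys <- tr[!tr$in_window, ]
  expect_true(all(valleys$intensity_au == 100))
  peaks <- tr[tr$in_window, ]
  expect_equal(peaks$intensity_au,
               100 + 100 * (1 - exp(-0.001 * peaks$time_s)),
               tolerance = 1e-12)
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  truth <- ground_truth("two_exp", vlb58)
  acq <- acquisition_config(noise_sd = 3, spike_rate = 0.002, seed = 7)
  tr1 <- simulate_raw_trace(truth, acq)
  tr2 <- simulate_raw_trace(truth, acq)
  expect_identical(tr1$intensity_au, tr2$intensity_au)
  acq$seed <- 8L
  tr3 <- simulate_raw_trace(truth, acq)
  expect_false(identical(tr1$intensity_au, tr3$intensity_au))
})

test_that("invalid ground-truth parameters are rejected with the offending field named", {
  expect_error(ground_truth("one_exp", c(P = NaN, Q = 0.001)), "P")
  expect_error(ground_truth("one_exp", c(P = 1, Q = 0)), "Q")
  expect_error(ground_truth("two_exp", c(A = -0.1, B = 0.1, C = 0.2, D = 0.01)), "A")
  # canonical fast-rate-first ordering
  gt <- ground_truth("two_exp", c(A = 0.2, B = 0.001, C = 0.5, D = 0.05))
  expect_gte(gt$params[["B"]], gt$params[["D"]])
  expect_equal(unname(gt$params), c(0.5, 0.05, 0.2, 0.001))
})

test_that("spikes are isolated single-sample positive excursions", {
  truth <- ground_truth("one_exp", c(P = 1, Q = 0.001))
  acq <- acquisition_config(noise_sd = 0, spike_rate = 0.01,
                            spike_amplitude = 50, seed = 11)
  tr <- simulate_raw_trace(truth, acq)
  base <- simulate_raw_trace(truth, noiseless_acq(seed = 11))
  spiked <- which(tr$intensity_au != base$intensity_au)
  expect_gt(length(spiked), 0)
  expect_true(all(diff(spiked) > 1))
  expect_equal(tr$intensity_au[spiked] - base$intensity_au[spiked],
               rep(50, length(spiked)), tolerance = 1e-12)
})

test_that("two-phase trace follows the piecewise schedule with continuity by default", {
  p1 <- ground_truth("two_exp", vlb58)
  p2 <- ground_truth("two_exp", inh58)
  acq <- noiseless_acq(duration = 4000, sample_interval = 10)
  tr <- simulate_sasca_trace(phase_schedule(1000, p1, p2), acq)
  pk <- tr[tr$in_window, ]
  expected <- ifelse(
    pk$time_s < 1000,
    eval_two_exp(vlb58[["A"]], vlb58[["B"]], vlb58[["C"]], vlb58[["D"]], pk$time_s),
    eval_two_exp(vlb58[["A"]], vlb58[["B"]], vlb58[["C"]], vlb58[["D"]], 1000) +
      eval_two_exp(inh58[["A"]], inh58[["B"]], inh58[["C"]], inh58[["D"]],
                   pmax(pk$time_s - 1000, 0))
  )
  expect_equal(pk$intensity_au, 100 + 100 * expected, tolerance = 1e-12)
  # the second rise continues upward toward a second steady state
  expect_true(all(diff(pk$intensity_au) >= -1e-9))
  expect_gt(max(pk$intensity_au), 100 + 100 * eval_two_exp(
    vlb58[["A"]], vlb58[["B"]], vlb58[["C"]], vlb58[["D"]], 1000))
})

test_that("an excess phase-2 offset produces exactly that upward jump at the switch", {
  p1 <- ground_truth("one_exp", c(P = 1, Q = 0.01))
  continuity <- eval_one_exp(1, 0.01, 600)
  excess <- 0.25
  acq <- noiseless_acq(duration = 1200, sample_interval = 10)
  tr <- simulate_sasca_trace(
    phase_schedule(600, p1, p1, phase2_offset = continuity + excess), acq)
  pk <- tr[tr$in_window, ]
  before <- max(pk$time_s[pk$time_s < 600])
  at <- min(pk$time_s[pk$time_s >= 600])
  jump <- (pk$intensity_au[pk$time_s == at] - pk$intensity_au[pk$time_s == before])
  smooth <- 100 * (eval_one_exp(1, 0.01, at) - eval_one_exp(1, 0.01, before))
  expect_equal(jump - smooth, 100 * excess, tolerance = 1e-9)
})

test_that("t_switch off the grid or outside the window is rejected", {
  p <- ground_truth("one_exp", c(P = 1, Q = 0.01))
  acq <- noiseless_acq(duration = 1000, sample_interval = 10)
  expect_error(simulate_sasca_trace(phase_schedule(505, p, p), acq), "grid")
  expect_error(simulate_sasca_trace(phase_schedule(1500, p, p), acq), "inside")
})

test_that("cohort draws honor size, spread, and reproducibility", {
  acq <- noiseless_acq(sample_interval = 50)
  # zero geometric CV collapses all cells onto identical parameters
  coh0 <- simulate_cohort(population_spec(5, "two_exp", gcv = 0, seed = 4), acq)
  pars <- purrr::map(coh0$truth, "params")
  expect_true(all(purrr::map_lgl(pars, ~ identical(.x, pars[[1]]))))
  # single cell
  coh1 <- simulate_cohort(population_spec(1, "one_exp", seed = 4), acq)
  expect_equal(nrow(coh1), 1)
  # 20-cell resistant-like cohort: plateau spread overlaps the published range
  coh <- simulate_cohort(population_spec(20, "two_exp", seed = 10), acq)
  plateaus <- purrr::map_dbl(coh$truth, ~ sum(.x$params[c("A", "C")]))
  expect_lt(min(plateaus), 1.50)
  expect_gt(max(plateaus), 0.26)
  # same seed, same multiset of parameters
  coh2 <- simulate_cohort(population_spec(20, "two_exp", seed = 10), acq)
  expect_identical(sort(purrr::map_dbl(coh$truth, ~ .x$params[["B"]])),
                   sort(purrr::map_dbl(coh2$truth, ~ .x$params[["B"]])))
})
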