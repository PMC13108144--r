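make_sasca_processed <- function(phase1, phase2, t_switch = 1500, duration = 4500,
                                 dt = 10, sd = 0, seed = 1, offset = NULL) {
  tt <- seq(0, duration, dt)
  off <- offset %||% eval_two_exp(phase1[["A"]], phase1[["B"]], phase1[["C"]],
                                  phase1[["D"]], t_switch)
  f <- ifelse(tt < t_switch,
              eval_two_exp(phase1[["A"]], phase1[["B"]], phase1[["C"]], phase1[["D"]], tt),
              off + eval_two_exp(phase2[["A"]], phase2[["B"]], phase2[["C"]], phase2[["D"]],
                                 pmax(tt - t_switch, 0)))
  if (sd > 0) f <- withr::with_seed(seed, f + rnorm(length(tt), 0, sd))
  tibble::tibble(time_s = tt, f = f)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("phase splitting is exact at the switch and re-zeroes the second phase", {
  d <- make_sasca_processed(vlb58, inh58, t_switch = 1500)
  sp <- split_phases(d, t_switch = 1500)
  expect_true(all(sp$phase1$time_s < 1500))
  expect_equal(min(sp$phase2$time_s), 0)
  # with a noiseless trace the first incremental phase-2 sample is ~0
  expect_lt(abs(sp$phase2$f[1]), 1e-3)
  # t_switch at the last sample is rejected
  expect_error(split_phases(d, t_switch = max(d$time_s)), "inside")
  expect_error(split_phases(d, t_switch = 5000), "inside")
  # too-short phases are rejected
  expect_error(split_phases(d, t_switch = 50), "at least")
})

test_that("same-cell comparison reproduces the published within-cell rate fold", {
  # the protocol switches solutions only once the first phase has reached
  # steady state, so the carried-over level is the phase-1 plateau
  ctrl <- ground_truth("two_exp", vlb58)
  inh <- ground_truth("two_exp", inh58)
  tr <- simulate_sasca_trace(phase_schedule(2000, ctrl, inh),
                             noiseless_acq(duration = 5000), cell_id = "58")
  res <- sasca_compare(process_trace(tr))
  expect_equal(res$fold_B, 0.0973 / 0.0556, tolerance = 1e-3)
  expect_equal(res$fit_control$params[["B"]], 0.0556, tolerance = 1e-3)
  expect_equal(res$fit_inhibitor$params[["B"]], 0.0973, tolerance = 1e-3)
  # both plateau-fold conventions are reported
  p1 <- 0.4378 + 0.4905
  p2 <- 0.1614 + 0.3972
  expect_equal(res$fold_plateau, p2 / p1, tolerance = 1e-2)
  expect_equal(res$fold_plateau_cumulative, (p1 + p2) / p1, tolerance = 1e-2)
})

test_that("identical phases give unit folds and doubled rates double fold_B", {
  d_same <- make_sasca_processed(vlb58, vlb58, t_switch = 2500, duration = 5500)
  res_same <- sasca_compare(d_same, t_switch = 2500)
  expect_equal(res_same$fold_B, 1, tolerance = 1e-3)
  expect_equal(res_same$fold_plateau, 1, tolerance = 1e-3)

  doubled <- vlb58 * c(1, 2, 1, 2)
  res2 <- sasca_compare(make_sasca_processed(vlb58, doubled, t_switch = 2500,
                                             duration = 5500),
                        t_switch = 2500)
  expect_equal(res2$fold_B, 2, tolerance = 1e-3)
})

test_that("null SASCA folds center on 1 under 2% noise", {
  folds <- vapply(1:40, function(s) {
    d <- make_sasca_processed(vlb58, vlb58, sd = 0.02 * 0.9283, seed = s)
    sasca_compare(d, t_switch = 1500)$fold_B
  }, numeric(1))
  expect_gte(median(folds), 0.95)
  expect_lte(median(folds), 1.05)
})

test_that("fitting a concatenated trace equals fitting its phases independently", {
  # two independently generated phases stacked at the phase-1 asymptote
  p1_plateau <- vlb58[["A"]] + vlb58[["C"]]
  d <- make_sasca_processed(vlb58, inh58, t_switch = 1500, offset = p1_plateau)
  res <- sasca_compare(d, t_switch = 1500)
  ind1 <- fit_two_exp(clean_curve(vlb58, dt = 10, duration = 1490))
  ind2 <- fit_two_exp(clean_curve(inh58, dt = 10, duration = 3000))
  expect_equal(unname(res$fit_control$params), unname(ind1$params), tolerance = 1e-6)
  expect_equal(unname(res$fit_inhibitor$params), unname(ind2$params), tolerance = 1e-6)
})

test_that("cross-cell summary flags the published range overlap and detects disjoint groups", {
  coh <- dplyr::bind_rows(cem_vlb_fits(), cem_vlb_csa_fits())
  ds <- disca_summarize(coh, condition)
  cmp <- ds$comparison
  expect_true(cmp$overlap[cmp$parameter == "plateau"])
  rng <- dplyr::filter(ds$ranges, parameter == "plateau")
  expect_equal(sort(rng$min), c(0.2642, 0.6943))
  expect_equal(sort(rng$max), c(1.2744, 1.4980))

  toy <- tibble::tibble(
    A = c(1, 2, 10, 11), B = c(1, 1, 1, 1), C = c(0, 0, 0, 0), D = c(1, 1, 1, 1),
    grp = c("x", "x", "y", "y")
  )
  ds2 <- disca_summarize(toy, grp, params = "A")
  expect_false(ds2$comparison$overlap)
  expect_error(disca_summarize(toy, missing_col), "not found")
})

test_that("identical groups give a rank-test p near 1, agreeing with a permutation oracle", {
  vals <- cem_vlb_fits()$plateau[1:8]
  coh <- tibble::tibble(plateau = rep(vals, 2),
                        grp = rep(c("g1", "g2"), each = 8))
  ds <- disca_summarize(coh, grp, params = "plateau")
  expect_gte(ds$comparison$p_value, 0.9)
  # permutation oracle on the rank-sum statistic
  obs_stat <- sum(rank(coh$plateau)[coh$grp == "g1"])
  perm <- withr::with_seed(1, vapply(1:2000, function(i) {
    g <- sample(coh$grp)
    sum(rank(coh$plateau)[g == "g1"])
  }, numeric(1)))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs_stat - mean(perm)) - 1e-9)
  expect_gte(p_perm, 0.9)
})

test_that("sasca tidiers expose per-phase parameters and folds", {
  res <- sasca_compare(make_sasca_processed(vlb58, inh58), t_switch = 1500,
                       cell_id = "58")
  td <- tidy(res)
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$phase), c("control", "inhibitor"))
  gl <- glance(res)
  expect_equal(gl$cell_id, "58")
  expect_gt(gl$fold_B, 1)
})
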