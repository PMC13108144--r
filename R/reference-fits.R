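#' Published single-cell uptake kinetic parameter sets
#'
#' Curated reference values for daunorubicin (DNR) uptake kinetics measured in
#' single CCRF-CEM leukemia cells on a microfluidic biochip. These tables are
#' the fitted-parameter summaries for drug-sensitive (CEM/WT) and
#' multidrug-resistant (CEM/VLB) cells and serve as realistic parameter
#' anchors for simulation, as worked examples for the fitters, and as inputs
#' to cross-cell (DISCA) summaries.
#'
#' * `cem_wt_fits()` — five drug-sensitive cells, each fitted with both the
#'   one-exponential model (parameters `P`, `Q`) and the two-exponential model
#'   (`A`, `B`, `C`, `D`); one row per cell and model.
#' * `cem_vlb_fits()` — twenty multidrug-resistant cells, two-exponential fits
#'   under DNR alone.
#' * `cem_vlb_csa_fits()` — four multidrug-resistant cells measured with the
#'   P-glycoprotein inhibitor cyclosporine A co-perfused.
#' * `cem_sasca_fits()` — paired same-single-cell (SASCA) fits: for each of
#'   three cells, a control phase and an inhibitor-treated phase. The
#'   inhibitor-phase parameters describe the incremental second rise above the
#'   first steady state.
#'
#' Amplitudes (`P`, `A`, `C`) are dimensionless normalized fluorescence; rates
#' (`Q`, `B`, `D`) are in s^-1; `R` is the Pearson correlation between data
#' and fit; `plateau` is the asymptotic accumulation (`P` or `A + C`).
#'
#' @return A tibble, one row per cell (and model or phase).
#' @examples
#' cem_vlb_fits() |> dplyr::summarise(range(plateau))
#' @name reference_fits
NULL

#' @rdname reference_fits
#' @export
cem_wt_fits <- function() {
  one <- tibble::tribble(
    ~cell_id, ~P,     ~Q,     ~R,
    "146",    2.7140, 0.0007, 0.9812,
    "147",    3.7468, 0.0002, 0.9241,
    "148",    2.8010, 0.0008, 0.9715,
    "149",    2.8184, 0.0004, 0.9685,
    "154",    2.3556, 0.0007, 0.9490
  )
  two <- tibble::tribble(
    ~cell_id, ~A,     ~B,     ~C,     ~D,     ~R,
    "146",    2.7000, 0.0007, 0.1000, 0.0002, 0.9778,
    "147",    2.8000, 0.0002, 0.3000, 0.0003, 0.9230,
    "148",    3.0700, 0.0004, 0.5000, 0.0025, 0.9712,
    "149",    3.0376, 0.0003, 0.3150, 0.0006, 0.9665,
    "154",    3.3500, 0.0003, 0.3500, 0.0006, 0.9306
  )
  dplyr::bind_rows(
    dplyr::mutate(one,
      model = "one_exp", A = NA_real_, B = NA_real_, C = NA_real_, D = NA_real_,
      plateau = .data$P
    ),
    dplyr::mutate(two,
      model = "two_exp", P = NA_real_, Q = NA_real_,
      plateau = .data$A + .data$C
    )
  ) |>
    dplyr::mutate(cell_type = "CEM/WT", condition = "DNR") |>
    dplyr::select("cell_id", "cell_type", "condition", "model",
                  "P", "Q", "A", "B", "C", "D", "R", "plateau") |>
    dplyr::arrange(.data$cell_id, .data$model)
}

#' @rdname reference_fits
#' @export
cem_vlb_fits <- function() {
  tibble::tribble(
    ~cell_id, ~A,     ~B,     ~C,     ~D,     ~R,     ~plateau,
    "10",     0.0768, 0.0442, 0.4581, 0.0020, 0.9757, 0.5349,
    "11",     0.4455, 0.0400, 0.6000, 0.0010, 0.9520, 1.0455,
    "24",     0.7980, 0.0100, 0.7000, 0.0051, 0.9306, 1.4980,
    "56",     0.3272, 0.0405, 0.2000, 0.0003, 0.8597, 0.5272,
    "58",     0.4378, 0.0556, 0.4905, 0.0046, 0.9865, 0.9283,
    "69",     0.3495, 0.0517, 0.1563, 0.0017, 0.8774, 0.5058,
    "70-01",  0.1495, 0.0143, 0.1147, 0.0013, 0.7012, 0.2642,
    "70-03",  0.2011, 0.1483, 0.3897, 0.0032, 0.8513, 0.5908,
    "70-07",  0.1150, 0.2720, 0.5339, 0.0026, 0.8878, 0.6489,
    "70-08",  0.3540, 0.0264, 0.4782, 0.0011, 0.8894, 0.8322,
    "70-11",  0.3000, 0.0864, 0.4000, 0.0014, 0.8551, 0.7000,
    "70-12",  0.3145, 0.0815, 0.3005, 0.0006, 0.7385, 0.6150,
    "70-18",  0.4303, 0.0269, 0.3182, 0.0009, 0.8770, 0.7485,
    "70-19",  0.3191, 0.1375, 0.2646, 0.0022, 0.7717, 0.5837,
    "70-23",  0.6220, 0.0100, 0.4000, 0.0023, 0.9095, 1.0220,
    "70-25",  0.6922, 0.1792, 0.8048, 0.0016, 0.8822, 1.4970,
    "76",     0.1975, 0.0835, 0.2269, 0.0134, 0.7056, 0.4244,
    "77",     0.3040, 0.0894, 0.3337, 0.0081, 0.7817, 0.6377,
    "88",     0.4827, 0.2513, 0.4565, 0.0037, 0.8593, 0.9392,
    "95",     0.2510, 0.0040, 0.1352, 0.0007, 0.9140, 0.3862
  ) |>
    dplyr::mutate(cell_type = "CEM/VLB", condition = "DNR", model = "two_exp",
                  P = NA_real_, Q = NA_real_) |>
    dplyr::select("cell_id", "cell_type", "condition", "model",
                  "P", "Q", "A", "B", "C", "D", "R", "plateau")
}

#' @rdname reference_fits
#' @export
cem_vlb_csa_fits <- function() {
  # final column of the source summary is labelled "A + B" but tabulates A + C;
  # stored here as the plateau A + C
  tibble::tribble(
    ~cell_id, ~A,     ~B,     ~C,     ~D,     ~R,     ~plateau,
    "150",    0.6109, 0.1526, 0.6066, 0.0014, 0.8682, 1.2175,
    "151",    0.5281, 0.0150, 0.7463, 0.0070, 0.8911, 1.2744,
    "152",    0.7277, 0.0293, 0.2146, 0.0015, 0.7740, 0.9423,
    "153",    0.4251, 0.0446, 0.2692, 0.0014, 0.7730, 0.6943
  ) |>
    dplyr::mutate(cell_type = "CEM/VLB", condition = "DNR+CsA",
                  model = "two_exp", P = NA_real_, Q = NA_real_) |>
    dplyr::select("cell_id", "cell_type", "condition", "model",
                  "P", "Q", "A", "B", "C", "D", "R", "plateau")
}

#' @rdname reference_fits
#' @export
cem_sasca_fits <- function() {
  tibble::tribble(
    ~cell_id, ~phase,      ~A,     ~B,     ~C,     ~D,
    "58",     "control",   0.4378, 0.0556, 0.4905, 0.0046,
    "58",     "inhibitor", 0.1614, 0.0973, 0.3972, 0.0053,
    "70-08",  "control",   0.3540, 0.0264, 0.4782, 0.0011,
    "70-08",  "inhibitor", 0.2055, 0.0371, 0.2454, 0.0060,
    "95",     "control",   0.2510, 0.0040, 0.1352, 0.0007,
    "95",     "inhibitor", 0.2681, 0.0050, 0.1000, 0.0080
  ) |>
    dplyr::mutate(cell_type = "CEM/VLB", model = "two_exp",
                  plateau = .data$A + .data$C)
}
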