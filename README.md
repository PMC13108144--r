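# sckinetics

Real-time single-cell drug-uptake kinetics from fluorescence traces.

Multidrug resistance (MDR) in leukemia is driven largely by P-glycoprotein
efflux, which lowers intracellular accumulation of anthracyclines such as
daunorubicin (DNR). Microfluidic biochips can hold one cell under continuous
perfusion while a point detector records its DNR fluorescence in real time —
but the raw recording is a train of peaks (cell in the detection window) and
valleys (background), cells differ wildly from one another, and the question
"did the efflux inhibitor work?" hides inside that heterogeneity.
`sckinetics` is the analysis side of that experiment, for anyone modeling
saturating uptake kinetics in single cells:

* **trace processing** — peak/valley segmentation, valley-median baseline
  (`F_cell = F_total − F_background`), spike removal, normalization to the
  dimensionless uptake series `f(t)`;
* **kinetic modeling** — bounded nonlinear least squares for the
  one-exponential model `f = P(1 − e^(−Qt))` and the two-exponential model
  `f = A(1 − e^(−Bt)) + C(1 − e^(−Dt))` (fast rate first, `B ≥ D`), with
  plateau (`P` or `A + C`), half-time and component shares;
* **model selection** — extra-sum-of-squares F-test between the nested
  models, `F = ((rss₁ − rss₂)/2)/(rss₂/(n − 4))` on `F(2, n − 4)`;
* **heterogeneity analysis** — cross-cell (DISCA) range/rank-test summaries
  that show how cell-to-cell spread masks inhibitor effects, and
  same-single-cell (SASCA) before/after-inhibitor comparison with
  within-cell fold changes that recover them;
* **synthetic data** — a seeded generator for raw detector traces, two-phase
  SASCA traces and heterogeneous cohorts with known ground truth, plus
  curated published parameter tables for sensitive (CEM/WT) and resistant
  (CEM/VLB) cells.

Everything is tibble-first and pipe-friendly, with broom-style `tidy()` /
`glance()` / `augment()` methods and `autoplot()` diagnostics.

## Worked example

Simulate a resistant-like cell (published cell-58 parameters), process the
raw trace, and let the F-test pick the model:

```r
library(sckinetics)
library(dplyr)

truth <- ground_truth("two_exp", c(A = 0.4378, B = 0.0556, C = 0.4905, D = 0.0046))
tr <- simulate_raw_trace(truth, acquisition_config(seed = 7), cell_id = "58")
pt <- process_trace(tr)
pt
#> <processed_trace> 1501 samples | normalization 100 a.u. | 0 spikes removed

sel <- select_model(pt)
glance(sel)
#> # A tibble: 1 × 6
#>   selected F_stat p_value alpha rss_one rss_two
#>   <chr>     <dbl>   <dbl> <dbl>   <dbl>   <dbl>
#> 1 two_exp   1890.       0  0.05    2.20   0.623

tidy(sel$fit)
#> # A tibble: 4 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 A      0.427
#> 2 B      0.0613
#> 3 C      0.499
#> 4 D      0.00470

derived_metrics(sel$fit)
#> # A tibble: 1 × 4
#>   plateau half_time_s share_fast share_slow
#>     <dbl>       <dbl>      <dbl>      <dbl>
#> 1   0.926        37.2      0.461      0.539
```

At 2% noise the second exponential term is decisively required
(`F(2, 1497) ≈ 1890`), and the fitted parameters land on the generating
truth: plateau `A + C ≈ 0.926` versus the true 0.9283, with the fast
component carrying about half the accumulation.

The published cohorts show why cross-cell comparison cannot resolve
inhibition — the plateau ranges with and without cyclosporine A overlap:

```r
disca_summarize(bind_rows(cem_vlb_fits(), cem_vlb_csa_fits()),
                condition, params = "plateau") |> tidy()
#> # A tibble: 1 × 9
#>   parameter overlap p_value n_DNR `n_DNR+CsA` min_DNR `min_DNR+CsA` max_DNR `max_DNR+CsA`
#>   <chr>     <lgl>     <dbl> <int>       <int>   <dbl>         <dbl>   <dbl>         <dbl>
#> 1 plateau   TRUE     0.0814    20           4   0.264         0.694    1.50          1.27
```

whereas a same-cell comparison (`sasca_compare()`) on a two-phase trace
recovers the within-cell rate fold `B₂/B₁ = 0.0973/0.0556 = 1.750` directly
(see the vignette in `vignettes/uptake-kinetics.Rmd`).

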