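# speckleflow

Laser speckle contrast imaging (LSCI) maps microcirculatory blood flow from
the blur of time-integrated speckle patterns: scatterer motion during the
camera exposure `T` lowers the spatial speckle contrast
`Ks = sd/mean`, computed over small sliding windows (5×5 or 7×7 pixels).
Flow is then quantified either by the single-exposure asymptotic blood flow
index `BFI = 1/(T·Ks²)` (valid for `T/τc > 100`) or by fitting the
multi-exposure speckle imaging (MESI) model

    K(T)² = β ρ² (e^(−2x) − 1 + 2x)/(2x²)
          + 4 β ρ (1−ρ) (e^(−x) − 1 + x)/x²
          + v_ne + v_noise,        x = T/τc

to `Ks(T)` to estimate the decorrelation time `τc` (inverse to flow speed).

The catch this package addresses: the *numerical implementation* of the
sliding-window statistic — kernel shape (square vs circular), window size,
border padding, variance divisor — differs between software stacks, and
those differences propagate into `Ks`, `τc` and the flow index. speckleflow
bundles everything needed to quantify that propagation on data with known
ground truth:

* **specklesim** — a dynamic speckle simulator: complex Gaussian fields
  band-limited to a prescribed pixels-per-speckle ratio, temporally evolved
  so the field autocorrelation `g1(τ)` is exactly the prescribed
  negative-exponential (Siegert relation `g2 − 1 = |g1|²` holds by
  construction), then time-integrated per exposure and optionally quantized
  to camera bit depth.
* **contrast** — a deliberately naive nested-loop reference estimator
  (`contrast_direct`) plus fast compiled "sums algorithm" engines
  (`contrast_sums`, `contrast_variant`) covering square and disc kernels
  (both Euclidean and ImageJ-style inclusive disc masks), four border
  modes, and both variance divisors; equal to the reference within 1e−9 on
  the valid interior.
* **flowmodels** — the MESI model with bounded multi-start
  Levenberg–Marquardt fitting (`fit_mesi`) and the asymptotic estimators
  (`lsci_asymptotic_tau`, `bfi`).
* **pipeline** — `run_simulated_comparison()` (variant × exposure
  comparison tables with per-variant MESI and per-exposure asymptotic τc),
  `average_mesi_sequences()` and `roi_mean_contrast()` for exposure-cycled
  stacks with ROI masks.
* **io** — multi-page TIFF stacks with JSON sidecars, CSV/JSON reports, and
  a thin command-line front end (`inst/cli/speckleflow.R`).

## Worked example

Simulate a 15-exposure MESI ladder (τc = 1 ms, 3 px/speckle, 128×128),
compare the 7×7 square and circular estimators, and fit the MESI model:

```r
library(speckleflow)

cfg <- simulation_config(
  image_shape   = c(128, 128),
  decorrelation = decorrelation_spec("neg_exponential", tau_c = 1),
  seed          = 42)

cmp <- run_simulated_comparison(cfg, list(
  kernel_spec("square", 7, engine = "sums_uniform"),
  kernel_spec("disc", 7, engine = "sums_disc", disc_rule = "inclusive")),
  quantize = FALSE)
cmp
#> <speckle_comparison> 2 variant(s) x 15 exposure(s)
#>   sums_uniform_sq7       MESI tau_c = 1.031 ms
#>   sums_disc_di7          MESI tau_c = 1.027 ms

subset(cmp$table, T_ms %in% c(0.05, 1, 60) & shape == "disc",
       c(T_ms, mean_Ks, rel_err_pct, lsci_tau_ms))
#> # A tibble: 3 × 4
#>    T_ms mean_Ks rel_err_pct lsci_tau_ms
#>   <dbl>   <dbl>       <dbl>       <dbl>
#> 1  0.05   0.822       -3.45      0.0511
#> 2  1      0.606       -3.70      0.556
#> 3 60      0.111       -3.13      1.12
```

Reading: the fitted MESI `τc` recovers the simulated 1 ms within ~3% for
both kernel shapes; the circular (ImageJ-mask) estimator's mean `Ks` stays
within ~4% of the square estimator at every exposure; the single-exposure
asymptotic estimate (each row's `lsci_tau_ms`, normalized by the variant's
own fitted β) is hopeless at short exposures (0.05 ms at `T` = 0.05 ms,
where `T/τc ≪ 100`) and approaches truth only at the longest exposure —
the textbook argument for multi-exposure acquisition.

The numbers above are what the code prints at these exact settings; at this
small frame size the Monte-Carlo uncertainty of each `mean_Ks` is a few
tenths of a percent.

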