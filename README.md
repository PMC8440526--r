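# osmofret

Quantitative analysis for genetically encoded FRET biosensors whose sensory
domain is an intrinsically disordered protein (IDP). Hyperosmotic stress
pulls water out of a cell, raises macromolecular crowding, and compacts a
disordered linker sandwiched between a cyan donor and a yellow acceptor —
which shortens the donor–acceptor distance and raises transfer efficiency.
`osmofret` turns the raw readouts of that experiment family — plate-reader
channel intensities, emission spectra, TCSPC photon-arrival histograms and
multi-channel microscopy stacks — into calibrated, statistically summarized
results, and ships synthetic-data generators with known ground truth so the
entire pipeline is testable end to end.

## What it computes

| Stage | Core quantity |
|---|---|
| Plate ratiometrics | raw ratio R = DxAm/DxDm; normalized ratio R/mean(R, control); OLS dose sensitivity with compaction/expansion calls; loess-smoothed time courses |
| Spectra | anchor normalization at 515 nm; acceptor/donor band ratio (Σ I, 500–600 nm)/(Σ I, 460–499 nm); bleedthrough slope β from photobleached cells |
| FLIM | Poisson-MLE mono-exponential lifetime τ̂ of the period-wrapped model; E = 1 − τ_DA/τ_D; phasor (g, s) at ω = 2π/T |
| Single cells | ratiometric image (blur → AxAm mask → masked ratio); cell/vacuole segmentation; vacuolar ratio = vacuole area / cell area; Pearson correlations with exact t-test p-values; Δlifetime = (τ_final − τ_initial)/τ_initial |
| Sequence design | charge patterning κ = mean_g δ_g/δ_g^max over blobs g ∈ {5,6}; helix and charge–hydropathy disorder proxies; scramble selection (same composition, larger κ, lower helix score) |
| Chain ensembles | Metropolis MC of a bead-per-residue chain, E = W_solv + U_LJ + W_el; per-condition mean radius of gyration over 5 repeats; normalized Rg and scan sensitivity 1 − min(Rg/Rg_max) |

All user-facing functions take a data frame (or a light image/decay
container) first and return tibbles, so analyses chain with the pipe;
fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` visualizations.

## Worked example

Simulate a 9-replicate NaCl dose plate, normalize to the in-run controls,
and score the dose response; then fit a simulated sensor FLIM acquisition
and convert it to a FRET efficiency against the donor-only lifetime:

```r
library(osmofret)

wells <- gen_plate_dataset(plate_truth(slope_per_M = 0.5, noise_cv = 0.05,
                                       seed = 42))
norm  <- fret_ratio_normalize(wells)
dose_response_sensitivity(norm)
#> # A tibble: 1 × 4
#>   slope direction  r_squared     n
#>   <dbl> <chr>          <dbl> <int>
#> 1 0.422 compaction     0.837    45

decay <- gen_decay(decay_truth(lifetimes = 3.04, total_photons = 1e5,
                               seed = 42))
fit   <- fit_monoexp(decay)
glance(fit)
#> # A tibble: 1 × 7
#>     tau tau_stderr reduced_chi2 converged  logLik n_bins total_counts
#>   <dbl>      <dbl>        <dbl> <lgl>       <dbl>  <int>        <dbl>
#> 1  3.03     0.0107        0.993 TRUE      608067.    256       100000

fret_efficiency(fit$tau, 3.62)
#> # A tibble: 1 × 4
#>   efficiency tau_DA tau_D out_of_range
#>        <dbl>  <dbl> <dbl> <lgl>
#> 1      0.164   3.03  3.62 FALSE
```

The plate slope (0.42 ± sampling error against a planted 0.5/M, read as
"compaction") is the per-molar fractional rise of the normalized FRET
ratio. The lifetime fit recovers the planted 3.04 ns within its reported
standard error and a reduced χ² near 1 (the Poisson model fits); against
an unquenched donor lifetime of 3.62 ns that quenching corresponds to a
16% transfer efficiency. `autoplot(decay, fit = fit)`,
`autoplot(phasor_transform(decay))`, `plot_dose_response(norm)` and
`autoplot(solution_scan(...))` draw the standard figures for each stage.

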