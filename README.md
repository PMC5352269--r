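# gatedflim

Analysis of wide-field **time-gated FLIM** (fluorescence lifetime imaging)
data from automated multiwell-plate microscopes, aimed at FRET-based
high-content screening: plates of cells expressing donor/acceptor constructs
or biosensors, imaged as series of nanosecond-gated intensity frames, reduced
to per-pixel lifetimes, FRETing-donor fractions, and plate-level screening
statistics.

The package covers the full analysis chain of such an instrument:

* **Calibration** — camera background frames, a time-varying background (TVB)
  model from a medium-only well, the measured instrument response function
  (IRF) profile from a scattered-light delay scan, a per-pixel IRF *shift
  map*, and the global timing correction *t0* fitted against a
  monoexponential reference dye (Coumarin 6, τ ≈ 2.43 ns).
* **Decay fitting** — the FRET donor model
  `I(t) = I0 [ (1 − β) e^(−t/τ1) + β e^(−t/τ2) ]`
  convolved with the measured IRF (exact per-bin integration of the
  piecewise-constant profile), fitted per pixel, on globally binned ROI
  decays, or *globally* (shared lifetimes across pixels/FOVs) by separable
  nonlinear least squares / Poisson maximum likelihood with the linear
  amplitudes profiled out. The two-stage FRET workflow — binned
  double-exponential fit for (τ1, τ2), then pixel-wise refit of β with the
  lifetimes fixed — is built in.
* **Screening statistics** — well/column/condition summaries (mean lifetime,
  between-FOV STD and SE), the Z′ factor
  `Z′ = 1 − 3(σ+ + σ−)/|μ+ − μ−|`, FRET efficiency `E = 1 − τ_FRET/τ_D`,
  logistic dose–response IC50 (Hill coefficient fixed to 1, asymptotes fixed
  from control wells), and biosensor time-course summarization.
* **Simulation** — a synthetic-data generator standing in for the
  instrument: gate-width-dominated IRF (4 ns square with Gaussian edge
  blur), Poisson photon noise, camera offset, time-varying background,
  a spatial gradient of IRF arrival times, and multiwell layouts with the
  standard control wells. Ground truth is returned alongside every
  simulated acquisition, so the whole pipeline can be validated by
  parameter recovery.

Results are tibbles throughout; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Simulate a scaled-down FRET construct plate (four constructs with per-well
mean lifetimes 4008 / 2717 / 3004 / 3133 ps, ~500 detected photons per
in-cell pixel), calibrate it from its own control wells, fit every pixel and
summarize:

```r
library(gatedflim)

plate <- simulate_construct_plate(sim_config(seed = 1))
cal   <- calibrate_simulated_plate(plate)   # TVB, IRF, shift map, t0
fit   <- fit_pixelwise(plate$fovs$stack[plate$fovs$role == "sample"], cal)
aggregate_plate(fit, plate$layout, level = "condition")
#> # A tibble: 4 x 6
#>   condition mean_tau_ps n_pixels   std n_fov   err
#>   <chr>           <dbl>    <int> <dbl> <int> <dbl>
#> 1 mTq17V          3010.    13648 10.5     12  3.03
#> 2 mTq32V          3135.    14694  9.75    12  2.82
#> 3 mTq5A           4009.    13667  8.13    12  2.35
#> 4 mTq5V           2719.    14164  8.69    12  2.51
```

`mean_tau_ps` is the mean fitted lifetime over all thresholded pixels of a
construct (pooled across its wells and fields of view), `std` the standard
deviation between field-of-view means — the replicate unit for plate
statistics — and `err` the corresponding standard error. All four construct
means land within a few picoseconds of the simulation ground truths.

The same objects drive the screening outputs:

```r
plot_plate_map(aggregate_plate(fit, plate$layout, "well"))   # heat map
z_prime(pos_fov_means, neg_fov_means)                        # assay quality
fit_dose_response(curve, y0, yinf)                           # IC50, Hill = 1
time_course(stacks, times, cal, mask)                        # biosensor kinetics
```

A thin command-line wrapper (`inst/cli/gatedflim.R`) exposes
`simulate`, `calibrate`, `fit`, `plate-report`, `dose-response`,
`time-course` and `run` for shell pipelines.

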