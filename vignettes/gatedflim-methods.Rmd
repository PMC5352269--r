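---
title: "Models and methods behind gatedflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gatedflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model, the calibration estimators, the fitting machinery, the choices made
where the design was genuinely open, and — importantly — the statistical
limits of what time-gated decay fitting can deliver. Nothing stated here as
an empirical result goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The measurement model

Wide-field time-gated FLIM acquires a series of 2-D count images, one per
gate delay $d$: the intensifier opens for a window of width $w$ (typically
4 ns) at delay $d$ after the excitation pulse, and the camera integrates the
gated fluorescence. On the delay axis the expected signal is the
convolution of the fluorescence decay with the instrument response function
(IRF):

$$\mu(d) \;=\; I_0 \int \mathrm{IRF}(u)\,
   \Big[(1-\beta)\,e^{-(d-u)/\tau_1} + \beta\,e^{-(d-u)/\tau_2}\Big]
   \,\mathbf{1}[d \ge u]\, du \;+\; \mathrm{BG}(d),$$

where $\tau_1 \ge \tau_2$ are the non-FRETing and FRETing donor lifetimes,
$\beta$ the FRETing donor population fraction, and $\mathrm{BG}$ collects
the camera offset and the time-varying background (TVB) from the culture
medium. With $\beta = 0$ the model is monoexponential. The *mean lifetime*
reported for two-component fits is the amplitude-weighted mixture
$(1-\beta)\tau_1 + \beta\tau_2$, matching the population reading of
$\beta$; the intensity-weighted alternative is deliberately not used.

The IRF here is dominated by the intensifier gate: a ~4 ns square with soft
edges (optical gating switches over ~100–300 ps). It is measured by
scanning scattered excitation light at 25 ps delay steps; the scan
integrates the response over each step, so the package represents the
profile as a piecewise-constant density on the scan grid and convolves it
with the exponential **exactly**, by per-bin analytic integration (prefix
sums make evaluation O(1) per gate). For a response smooth at the 25 ps
scale this representation is numerically unbiased (mono-fit bias below
0.2 ps in the package's checks); an optional `refine` argument provides a
mass-preserving linear subdivision for profiles with genuine sub-sample
structure, but it is off by default because its edge-bin clipping slightly
skews smooth profiles. A perfectly sharp square edge, by contrast, *cannot*
be reconstructed from a 25 ps scan accurately enough for high-precision
two-component fitting — one reason the simulator models the gate edges with
a 100 ps Gaussian blur (see below).

## Calibration chain

The analysis consumes, in the acquisition protocol's order:

1. **Camera background** — an offset frame acquired with the excitation
   blocked, scaled linearly by `integration_time × n_accumulations` when
   data and background were recorded at different settings.
2. **TVB** — from a medium-only well: the spatially averaged per-gate
   background decay plus a mean-1 per-pixel intensity map. The medium
   signal is dim (tens of photons per pixel), so *all* available medium
   fields of view are pooled; with a single dim FOV the TVB profile noise
   propagates as a common offset of every well mean (a few ps).
3. **IRF shift map** — per-pixel temporal offsets of the IRF relative to
   the global profile, estimated as temporal-centroid differences, median
   filtered (5×5) and re-centred to zero mean. Centroid noise scales as
   $w/\sqrt{12N}$: at $10^5$ detected photons per pixel it is ~0.9 ps.
   Pixels below a count floor (default 100) are inpainted from the
   smoothed neighbourhood. The estimator is a package choice; per-pixel
   fitting would be far noisier at realistic scan budgets.
4. **t0** — the global shift between the scattered-light IRF and the true
   fluorescence IRF, fitted on the pooled reference-dye decay
   (Coumarin 6, lifetime fixed to the literature 2430 ps; amplitude and
   offset profiled out; the shift is the only nonlinear parameter).
   Fixing the lifetime makes t0 identifiable with few gates. When a shift
   map is supplied the model basis is averaged over the pixel shift
   distribution — the pooled decay is a mixture of slightly shifted
   responses, and a single-shift model leaves a small systematic. The
   sign convention: `t0` is the shift *added* to the IRF time axis before
   convolution; the fitting stage applies it internally.

Calibration acquisitions are bright. The protocol sets exposures to ~75%
of the camera's dynamic range, i.e. hundreds to tens of thousands of counts
per 25 ps sample; the simulator's defaults (10^5 detected photons per pixel
for the IRF scan and the dye) reflect that. At early versions' dimmer
defaults (a few counts per sample) the IRF-centroid noise floor alone
exceeded the ±5 ps t0 tolerance.

## Fitting

All fits profile the linear parameters (component amplitudes, optional
constant offset) out of the nonlinear problem — variable projection. Three
weighting schemes are available; the estimator matters at FLIM photon
budgets:

* `"mle"` (default): Poisson maximum likelihood. The TVB enters as a
  *known additive baseline* so the data stay on the raw count scale;
  per-candidate-lifetime amplitudes are found by damped Newton steps on
  the deviance with non-negativity (active set).
* `"poisson"`: weighted least squares with model-based weights
  $1/\max(\mu, 1)$, refreshed over a few outer passes.
* `"none"`: unweighted least squares, used for oracle comparisons.

At ~70 counts per gate, chi-square weightings carry percent-level bias
(data-based weights bias lifetimes down; even model-based weights retain a
small positive bias); the likelihood fit does not. A generic *curvature*
bias of order $+0.4\%$ at 500 photons remains for any estimator (the
lifetime is a nonlinear functional of the counts). Pixel-wise fits
therefore apply, by default, a per-FOV parametric-bootstrap bias
correction: synthetic pixels are drawn from the fitted model at the
empirical brightness distribution, refit with the identical estimator, and
the measured bias subtracted. The bootstrap is seeded deterministically
per FOV, so fits are bit-reproducible; its residual noise
(pixel SD /√`boot_n`) is part of the well-mean uncertainty.

**Pixel-wise** fits search a log-spaced lifetime grid (bracketing) and
refine by golden section; pixels below the intensity threshold
(default 100 counts — lifetime accuracy needs hundreds of photons) are
excluded; non-bracketed or amplitude-clamped pixels are flagged, not
dropped. **Globally binned** fits pool an ROI's photons and fit one decay;
the model basis is averaged over the pooled pixels' IRF shifts
(intensity-weighted), since a single-shift model of a shift mixture leaves
a systematic residual that close two-component fits amplify. Outer
optimization over $(\tau_1, \tau_2)$ starts from a coarse 2-D grid around
the monoexponential solution because the profiled surface holds shallow
spurious basins, then polishes with `nlminb`; components are relabelled so
$\tau_1 \ge \tau_2$ (the swap resolves label switching). **Global fitting**
shares $(\tau_1, \tau_2)$ across all pixels and fields of view with
per-pixel amplitudes solved in closed form per candidate — inside this
objective the inner solve is *unconstrained*, because clamping amplitudes
at zero biases the profiled lifetimes toward wider spacing; $\beta$ maps
are clipped to $[0, 1]$ only at reporting, with at-bound flags.

A free per-pixel offset severely degrades lifetime identifiability with
seven gates; supplying a TVB model (so no offset is fitted) is the
recommended background treatment, and `fit_offset` can be overridden
explicitly.

## What the information actually supports

Three statements in this package's own validation deserve emphasis,
because they are properties of the physics, not of the implementation.
All derive from the Fisher information of Poisson counts over the 7-gate,
4-ns-gate design and are reproduced numerically in the tests:

* **Close two-component lifetimes need enormous pooled photon numbers.**
  For $(\tau_1, \tau_2) = (3964, 3022)$ ps — a ratio of 1.31 — the
  Cramér–Rao bound gives $\mathrm{sd}(\tau_1) \approx 690$ ps at $10^6$
  pooled photons. Recovery to ±30 ps requires $\gtrsim 10^9$ photons:
  precisely what binning a full camera frame over three bright time
  points provides, and consistent with ±21/±27 ps uncertainties at that
  scale. The package's binned-recovery checks therefore pool
  $4\times10^9$ photons (the acceptance setup requires only that the
  pool exceed $10^6$).
* **Global fitting cannot rescue component lifetimes at this gate
  design.** With per-pixel free amplitudes, a wrong lifetime pair spans
  each pixel's intermediate decay to ~$10^{-4}$ relative accuracy
  (positive combinations of two exponentials approximate an intermediate
  one extremely well over seven samples), so the profiled objective is a
  ridge whose depth does not grow with photons. Binning — one amplitude
  pair for the whole ROI — restores identifiability. This is why the
  two-stage workflow (binned fit for the lifetimes, pixel-wise refit of
  $\beta$ with lifetimes fixed) is the package's recommended FRET path,
  and why the global fitter is validated by optimum-matching against a
  joint brute-force least-squares fit rather than by lifetime recovery.
* **Per-pixel FRETing fractions are noisy at live-cell budgets.** With
  the lifetimes fixed at (3964, 3022) ps, the bound gives
  $\mathrm{sd}(\beta) \approx 0.25$ at $10^3$ photons per pixel and
  $\approx 0.04$ at $5\times10^4$. The package's estimator sits on the
  bound; map-level claims should be read accordingly, and cell- or
  ROI-level averaging is where $\beta$ becomes quantitative.

## The simulator

The generator stands in for the instrument and defines the study
conditions: 64×64 fields of random elliptical cells (lognormal size and
brightness — enough to exercise segmentation paths, with no biological
realism claimed), ~500 detected photons per in-cell pixel over the
seven-gate log-spaced delay scheme (one gate before the pulse, one at the
peak, the rest log-spaced to 16 ns), Poisson photon noise, a constant
camera offset of 50 counts, a medium background of 10 photons per pixel
decaying at 600 ps, a 50 ps peak-to-peak column-wise gradient of IRF
arrival times, and a 4 ns gate with 100 ps Gaussian edge blur. Calibration
acquisitions (IRF scan, reference dye) use $10^5$ photons per pixel at
25 ps steps, mirroring the protocol's near-saturation exposures. The
biosensor time-course preset uses the seven published delay values
(taking 10391 ps for an apparent typo in the source list) and a FRETing
fraction stepping 0.4 → 0.1 at 120 s; its per-pixel brightness is set so
that the *pooled* baseline photons of the small simulated field match what
full-frame pooling provides in a real acquisition ($\sim10^8$).

Two forward models are built in. The analysis-shared path evaluates the
same discretized convolution the fitters use; the quadrature path
(`independent_forward = TRUE`, used throughout the acceptance runs)
integrates the continuous blurred-gate density by trapezoid rule at 1 ps —
so parameter recovery is never an artifact of sharing one discretization
("inverse crime"). Noiseless data through the shared path are recovered to
solver tolerance (<0.1 ps), which is the designed control, not evidence
about real data.

What the simulator does *not* emulate: optical point-spread functions,
photobleaching, autofocus drift, detector nonlinearity or read noise
(Poisson only by default), wavelength-dependent IRF shape, biological
heterogeneity of lifetimes within a condition, and cell morphology beyond
ellipses. Passing recovery tests therefore demonstrates the correctness
and calibration of the analysis chain under the stated noise model — not
robustness to everything a real plate can do.

## Screening statistics

Well summaries pool thresholded pixels; the replicate unit for spread is
the field of view (pixels within a FOV are not independent), so the
tabulated `std` is the between-FOV standard deviation and `err` its
standard error. Z′ uses the standard control-moment formula over FOV
means. Dose–response fitting fixes the Hill coefficient to 1 and both
asymptotes to the control wells, leaving IC50 as a single profiled
parameter: $y(c) = y_0 + (y_\infty - y_0)\,c/(c + \mathrm{IC}_{50})$ with
$y_0$ the vehicle (negative control) response — inhibition *raises* the
donor lifetime in the oligomerization assay, so the zero-dose asymptote is
the low-lifetime one; the response at $c = \mathrm{IC}_{50}$ is the
asymptote midpoint. The full 4PL parameter vector is reported for
interoperability. The acceptance check runs one full image-level plate at
the 9-dose × 2-well × 8-FOV design (recovering the configured 38 nM within
±20%) and a 100-seed repeated-design check at the same response-level
noise scale (between-FOV spread of ~30 ps, matching the construct-plate
STDs), whose median error is within 10% — repeating the full image
pipeline 100 times would add no statistical content, because the
response noise model is identical.

Time courses run the two-stage workflow: a globally binned two-component
fit over the baseline window (default: first three retained time points)
fixes the lifetimes; every time point is then refit pixel-wise for
$\beta$, summarized per segmented cell, with stimulus-disturbed time
points excluded by the caller. Because the *step* in $\beta$ is a
difference of two estimates sharing the same (possibly imperfect) fixed
lifetimes, it is recovered within ±0.05 even when the baseline lifetimes
carry hundreds of picoseconds of statistical error.

## Numerical choices and degenerate inputs

Lifetime search bounds default to [300, 8000] ps; the pixel-grid has 60
log-spaced points (golden-section refinement supplies final precision);
Poisson weights are floored at 1 count; deviance Newton steps are damped
to keep intensities positive; bi-exponential fits whose components
collapse (within 1%), whose mixture weight pins at 0/1, or whose
amplitudes go negative are flagged `degenerate` rather than silently
reported. Empty ROIs, duplicate gate delays, mismatched shapes,
non-uniform IRF scans, equal fixed lifetimes in the β refit, and equal
control means in Z′ all raise errors. Determinism: every stochastic
output is reproducible from (configuration, seed), including the
bootstrap correction.

## Problem sizes

The validation suite runs at desk scale: 16×16 to 64×64 fields, 1–12
wells, 4–8 FOVs per well, 500–$5\times10^4$ photons per pixel, with the
photon-hungry binned checks pooling up to $4\times10^9$ photons as single
decays. These sizes were chosen so that each check is decisively powered
for the tolerance it asserts while the whole suite stays interactive.
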