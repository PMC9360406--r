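---
title: "Thrombin dynamics: model, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thrombin dynamics: model, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombodyn)
```

## The problem

A thrombin generation (TG) assay records the concentration of free thrombin
in clotting plasma over time. That curve is the *net* of two opposing
processes: prothrombin is converted to thrombin by the prothrombinase
complex (the pro-coagulant input), and thrombin is simultaneously removed by
its plasma inhibitors (the anticoagulant drain). Two plasmas can produce
similar TG curves for very different reasons — weak conversion with weak
inhibition, or strong conversion with strong inhibition — so decomposing the
curve into its two sides carries clinically relevant information the TG
parameters alone do not.

Thrombin dynamics (TD) analysis performs that decomposition. It requires,
per sample, the TG curve plus three measured plasma quantities:
antithrombin (AT, % of normal activity), alpha-2-macroglobulin (a2M, µM)
and fibrinogen (g/L).

## The inactivation model

During TG, thrombin is inactivated mainly by AT and, to a smaller extent, by
a2M. Both reactions are second order:

$$\frac{d[\mathrm{T\!-\!AT}]}{dt} = k_{AT}\,[\mathrm{AT}]_t\,[\mathrm{T}]_t,
\qquad
\frac{d[\mathrm{T\!-\!a2M}]}{dt} = k_{a2M}\,[\mathrm{a2M}]_t\,[\mathrm{T}]_t,$$

$$-\frac{d[\mathrm{T}]}{dt} =
  \left(k_{AT}\,[\mathrm{AT}]_t + k_{a2M}\,[\mathrm{a2M}]_t\right)[\mathrm{T}]_t .$$

Fibrin(ogen) binds thrombin and shields it from both inhibitors, so the
effective constants decrease with the fibrinogen level: $k_i =
k_i^{ref}\,g(\mathrm{fib})$ with $g$ non-increasing and $g = 1$ at the
reference fibrinogen. Two forms of $g$ ship: a constant form ($g \equiv 1$)
and a saturating decrease $g(\mathrm{fib}) = 1/(1 + \beta\,(\mathrm{fib} -
\mathrm{fib}_{ref}))$ clipped to $(0, 1]$.

The inhibitor pools carry the subscript $t$: by default complex formation
consumes AT and a2M stoichiometrically (1:1), which matters at healthy
conversion totals — roughly 900 nM of thrombin is formed against an AT pool
of only ~2700 nM, so the effective decay rate falls by about a third over a
run. An "excess" mode holds the pools constant; in that mode the free
thrombin from a bolus decays *exactly* exponentially, which the test suite
exploits as a closed-form oracle.

The total inhibitory capacity of a plasma is summarized by the **thrombin
decay capacity**,

$$\mathrm{TDC} = k_{AT}(\mathrm{fib})\,[\mathrm{AT}]_0 +
  k_{a2M}(\mathrm{fib})\,[\mathrm{a2M}]_0 \quad [\mathrm{min}^{-1}],$$

a pseudo-first-order constant independent of conversion.

### Rate-constant calibration

The numeric values of $k_{AT}$, $k_{a2M}$, the fibrinogen dependence and the
AT %-to-molar conversion are instrument- and assay-calibration data, not
universal constants; this package does not assert published values for them.
The shipped defaults (`rate_model()`: $k_{AT} = 3.2\times10^{-4}$,
$k_{a2M} = 9.7\times10^{-6}$ nM$^{-1}$min$^{-1}$ at 2.9 g/L fibrinogen,
24 nM AT per % activity) are **calibration placeholders** chosen once so
that median healthy plasma (AT 113%, a2M 2.6 µM) gives:

* TDC $\approx 0.9$ min$^{-1}$ initially, decaying toward ~0.6 as AT is
  consumed — consistent with healthy-donor curves where the ETP
  (~1100 nM·min) times the average decay rate must equal the total
  complexes formed (~890 nM);
* an initial AT:a2M flux ratio of ~33:1, so end-point complex totals land
  near the ~860:28 nM split reported for healthy donors.

All constants live in a plain-text configuration
(`read_rate_model()`/`write_rate_model()`, see
`inst/extdata/rate_model_default.yaml`) so a laboratory can substitute its
own calibration without touching code.

## Extracting prothrombin conversion

Since the TG curve is the net of conversion and inactivation,

$$-\frac{dP}{dt} = \frac{dT}{dt}
  + k_{AT}[\mathrm{AT}]_t[\mathrm{T}]_t
  + k_{a2M}[\mathrm{a2M}]_t[\mathrm{T}]_t ,$$

i.e. the conversion rate is the measured slope plus the model-implied
inactivation flux. `extract_conversion()` implements this inverse step:

1. **Smoothing.** The thrombin signal is smoothed with a Savitzky–Golay
   (local cubic least-squares) filter; the same filter provides $dT/dt$,
   exactly for polynomials up to the cubic and with one-sided fits at the
   endpoints.
2. **Clipping after smoothing.** The model needs $[\mathrm{T}]_t \ge 0$, so
   the smoothed curve is clipped at zero. Order matters: clipping *raw*
   noisy samples first would add $E[\max(\varepsilon,0)] \approx
   0.4\,\sigma$ per baseline sample, which integrated over a ~25-minute
   near-zero baseline biases the cumulative complexes by ~2% at 5 nM noise.
   Clipping the smoothed signal reduces that bias by roughly the square
   root of the window length.
3. **Inhibitor depletion in closed form.** Given the measured thrombin
   course, $d[\mathrm{AT}]/dt = -k_{AT}[\mathrm{AT}]\,[\mathrm{T}]_t$ is
   *linear* in AT, so
   $[\mathrm{AT}]_t = [\mathrm{AT}]_0\exp(-k_{AT}\int_0^t T\,ds)$ exactly,
   and cumulative complexes are $[\mathrm{AT}]_0 - [\mathrm{AT}]_t$. The
   integral is a cumulative trapezoid on the grid; no ODE stepping is
   needed on the inverse path.
4. **Tail completion.** T-AT and T-a2M are end-point totals. If the record
   ends with residual free thrombin above 1% of the peak, the model-implied
   exponential tail (at the *end-of-record* inhibitor levels) is appended
   for ten half-lives so the residual thrombin completes its complex
   formation. The extension is recorded in provenance.

### Summary parameters

* `pc_tot` — total prothrombin converted, the area under the conversion
  curve. It is evaluated through the identity it telescopes to,
  $(T_{end} - T_0) + \mathrm{T\!-\!AT} + \mathrm{T\!-\!a2M}$: negative noise
  excursions of the rate are *not* clipped out of the area (they cancel;
  one-sided clipping inflates it), and the clipped-away negative mass plus
  the trapezoid-vs-mass-balance gap are reported as diagnostics instead.
  In the no-inactivation limit ($k = 0$) `pc_tot` equals the final thrombin
  concentration exactly.
* `pc_max` — peak of the smoothed conversion rate (clipped at zero).
* `t_at`, `t_a2m` — final cumulative complexes including any appended tail.
* `tdc` — the decay capacity from the plasma factors alone.

### The noise-adaptive derivative window

The variance of a local-polynomial derivative falls roughly with the cube of
the window length while its bias grows with it, and the right trade-off
depends on the noise actually present. The noise level is estimated
robustly from second differences (`estimate_noise_sd()`:
$\mathrm{MAD}(\Delta^2 y)/\sqrt 6$), and the window is stepped:

| estimated noise | window | rationale |
|---|---|---|
| < 0.05 nM | 0.25 min | essentially noise-free (e.g. simulated) records; tracks the sharpest peaks to < 1% of PCmax |
| 0.05–0.5 nM | 0.5 min | quiet instrument records |
| > 0.5 nM | 2.0 min | keeps derivative noise to a few nM/min at 5 nM signal noise; PCmax bias from the wider window stays ≈ 1% on healthy-donor pulse widths |

The same rule governs the smoothing used by `tg_parameters()` on noisy
curves (flagged `"smoothed"`); quiet curves are used raw so exact geometric
inputs yield exact descriptive parameters. Negative baseline samples are
clipped only inside computations, never in the stored curve. The chosen
window is a provenance field of every result.

## Forward simulation and the synthetic cohort

The inverse step can only be validated against curves whose true
decomposition is known, so the package includes the forward direction:
`forward_simulate_tg()` integrates $dT/dt = \mathrm{rate}(t) -
\mathrm{inactivation\ flux}$ with a classical fixed-step 4th-order
Runge–Kutta scheme on the sampling grid (sub-stepping if the fastest rate
times the step exceeds 0.1). The system is non-stiff at physiological
constants; a deterministic fixed-step scheme makes every simulation exactly
reproducible. Because the cumulative source is integrated as part of the
state, the mass balance $T + \mathrm{T\!-\!AT} + \mathrm{T\!-\!a2M} =
\mathrm{bolus} + \int \mathrm{source}$ holds to round-off at every step, and
`conservation_gap()` verifies it.

`generate_cohort()` builds a full virtual study:

* **True conversion pulses** are delayed gamma-density pulses
  (`conversion_shape()`): a two-parameter unimodal shape with closed-form
  area (PCtot) and peak (PCmax), spanning realistic parameter combinations.
* **Reagent presets** place the median pulses at PCtot/PCmax of 902/172
  (low-TF "bleed"), 933/206 (intermediate "thrombo") and 988/508 nM/min
  (high-TF "drug"), with onset delays 2.7/2.1/1.1 min — the healthy-donor
  regime of automated TG systems, with the gamma scale solved in closed
  form from each PCtot/PCmax pair. These are generator calibration targets,
  not a reproduction of any measured cohort.
* **Plasma factors** are truncated normals around AT 113% (IQR ≈ 108–118),
  a2M 2.6 µM (≈ 2.2–3.1), fibrinogen 2.9 g/L (≈ 2.6–3.2).
* **Between-subject variation** uses a shared log-normal conversion
  strength (sdlog 0.17) and pulse width (sdlog 0.25) per subject plus
  smaller per-condition multipliers (0.06/0.15); the shared component gives
  the within-subject correlation across reagents that paired tests rely
  on, and the combined spreads reproduce a healthy-cohort 2.5th–97.5th
  percentile span (about ±35% for PCtot, ±(50–110)% for PCmax).
* **Thrombomodulin** is modelled as a pure input effect: each subject's
  intermediate-trigger pulse is scaled by $1 - f$ with $f$ truncated-normal
  around 0.44 (sd 0.10). This propagates one-to-one into extracted PCtot,
  T-AT and T-a2M (the acceptance suite checks −44% ± 1% at fixed
  $f = 0.44$). It deliberately does *not* reproduce the empirical
  observation that PCmax is less TM-sensitive (≈ −24%) than PCtot: a pure
  scaling reduces both equally, whereas in plasma TM acts through activated
  protein C with a delay that spares the early conversion peak. Modelling
  that kinetics is out of scope; TM-condition PCmax from this generator
  should be read accordingly.
* **Noise** is additive i.i.d. Gaussian (default 5 nM) on every sample;
  instrument noise structure (heteroscedasticity, drift, correlated
  residuals) is not published and not modelled. The generator/extraction
  round trip therefore demonstrates correctness of the *inversion*, not
  robustness to every real-world artifact.
* **Covariates** (sex, oral-contraceptive use) default to *off* so the null
  cohort is exchangeable — type-I-error simulations of the statistics layer
  need that. A `"demo"` profile enables a plausible effect pattern (higher
  a2M in women; higher, faster conversion and a blunted TM response in OC
  users) for power exploration.

Everything is deterministic given the configuration seed (factor draws,
pulse draws and noise use seed, seed+1, seed+2 respectively).

## Statistics layer

Reference ranges are the 2.5th/97.5th percentiles with linear interpolation
between order statistics at position $1 + (n-1)p$ (R's `type = 7`); the
interpolation rule is fixed and documented because published reference
ranges rarely state one. Paired conditions are compared with the Friedman
test plus Dunn's z-tests on within-block mean ranks; independent groups
(men / women without OC / women with OC) with Kruskal–Wallis plus
tie-corrected Dunn z-tests; the family-wise adjustment defaults to
Bonferroni (the common "Dunn's multiple comparison" convention) and is
configurable. Normality screening uses Shapiro–Wilk, with a flagged (not
error) result for constant vectors. Degenerate all-tied inputs report a
zero statistic and p = 1 rather than the NaN of the raw tests.

## Numerical choices and degenerate inputs

* Integration: fixed-step RK4, relative conservation < 10⁻⁶ required by the
  test suite; excess-mode decay matches the closed form to < 10⁻⁶ relative.
* Percentile and IQR conventions: quantile `type = 7` throughout.
* Lag time: first crossing of max(2 nM, 5% of peak), linearly interpolated;
  both knobs configurable (instrument-internal definitions are
  proprietary).
* All-zero (never-above-threshold) curves return flagged-NA parameters, not
  errors; truncated records (peak on the last sample) must be acknowledged
  at construction and are flagged through the pipeline.
* A record is resampled by monotone (Fritsch–Carlson) piecewise-cubic
  interpolation, which cannot overshoot between samples.
* Default problem sizes: 0.05-min grid over 40 min per curve; validation
  cohorts of 112 subjects × 4 conditions. These match the scale of a real
  TG plate run and keep the full test suite in the minutes range.

## Known limitations

* The kinetic constants are calibration placeholders (see above); absolute
  TD parameters from real instrument exports require a laboratory
  calibration of `rate_model()`.
* The model includes only AT and a2M; minor inhibitors (e.g. heparin
  cofactor II) are outside the two-inhibitor equations and contribute to
  model mismatch on real plasma.
* Prothrombin level is not an input: conversion is reported in cumulative
  nM, never as % of prothrombin consumed.
* The TM condition of the generator scales the whole pulse; see above.
* a2M-bound thrombin retains amidolytic activity on small substrates.
  Input curves are assumed to be already corrected free-thrombin
  concentrations, as automated TG software reports them; no correction
  stage is provided.
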