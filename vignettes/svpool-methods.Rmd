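---
title: "Quantifying synaptic-vesicle super-pool dynamics: models and methods"
author: "svpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic-vesicle super-pool dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpool)
```

## The problem

Presynaptic boutons hold clusters of synaptic vesicles (SVs) that are not
static: vesicles exchange continuously with a mobile axonal population,
the *super-pool*. Three complementary measurements quantify this
exchange:

1. **FRAP at boutons.** After bleaching the fluorescent SV cluster of a
   bouton, recovery of fluorescence reports import of unbleached vesicles
   from the super-pool. The asymptotic recovered fraction is the *mobile
   fraction*; its kinetics are biexponential.
2. **Axonal time-lapse imaging.** Moving SV clusters appear as sloped
   lines on a kymograph (speed = slope); the total material passing a
   cross-section of the axon is summarized by a cumulative traffic
   statistic.
3. **Miniature postsynaptic currents.** Quantal event frequency indexes
   release-site activity; amplitude indexes quantal size. Cells are
   screened by passive-property quality control.

None of the primary recordings are distributed with the package; instead
a seeded synthetic-data generator produces inputs with known ground
truth for every stage, so the whole pipeline is testable end to end.

## The recovery model

Fluorescence recovery after photobleaching is modeled as

$$R(t) = P\left[f\,(1 - 2^{-t/h_f}) + (1-f)\,(1 - 2^{-t/h_s})\right]$$

with mobile fraction (plateau) $P$, fast-component share $f$, and
component half-lives $h_f < h_s$ in seconds. Half-life
parameterization is used throughout because that is how recovery
kinetics are conventionally reported; `tau_to_halflife()` converts from
rate-constant form ($h = \tau\ln 2$). This is the closed-form solution
of a two-compartment exchange between the bouton cluster and an
effectively infinite unbleached super-pool with two kinetically distinct
exchange routes; the package exposes only the solution, not a separate
ODE simulator, because the biexponential form is exactly equivalent for
an infinite reservoir.

Defaults in the generator are $P = 0.7$, $f = 0.4$, $h_f = 60$ s,
$h_s = 1200$ s — a fast minutes-scale component and a slow tens-of-
minutes component, in the range where the 73-minute protocol constrains
both half-lives.

## Acquisition schedule

The standard protocol images a 3-min baseline every 30 s, bleaches
(removing 50% of the bouton signal on average), then samples recovery
every 30 s for 3 min and every 5 min up to 73 min. The protocol does not
fix a baseline frame count; the package uses 7 frames including $t = 0$,
which is what a 30-s interval over 3 min implies. Recovery timestamps
are 30–180 s in 30-s steps, then 480–4380 s in 300-s steps, so the two
canonical reporting times — 68 min (4080 s) and 73 min (4380 s) — fall
exactly on samples. A fast mode with 5-s sampling resolves the fast
component.

**Time origin.** The model clock starts at the *first post-bleach
acquisition*: the laser pass and the first post-bleach frame are treated
as coincident, the trace is normalized to 0 there, and fitting uses
$t - t_{\text{first post}}$. With this convention a noiseless simulated
trace normalizes exactly onto $R(t)$. Whether the original experiments
acquired a frame immediately at bleach end is not recoverable; the
convention is applied consistently to simulation and analysis, so fitted
parameters are internally consistent.

## Trace processing

`normalize_trace()` implements the standard chain:

1. subtract the per-pixel background (scaled by ROI area) from bouton
   and whole-cell series;
2. divide the bouton by the cell reference rescaled to its own
   pre-bleach mean. This *ratio correction* cancels acquisition
   photobleaching exactly when it acts multiplicatively and equally on
   bouton and cell — the generator applies exactly such a shared
   per-frame retention factor, and a package test verifies cancellation
   to 1e-9;
3. full-scale normalize: pre-bleach mean to 1, first post-bleach sample
   to 0.

Experiments whose cell reference lost more than 60% of its signal are
discarded (phototoxicity risk); "exceeded 60%" is read strictly, so
exactly 60% passes.

## Fitting and the extra sum-of-squares F test

`fit_double_exponential()` minimizes least squares on the post-bleach
samples by *variable projection*: for fixed $(h_f, h_s)$ the two
component amplitudes enter linearly and are solved exactly under
nonnegativity, leaving a smooth 2-D problem in the log half-lives that
Nelder-Mead solves from 8 fixed log-spaced starts (ties broken by lowest
SS, then lowest fast half-life). Search bounds are $h \in [1, 10^5]$ s
and $P \le 1.2$; a component whose share falls below 1% (or above 99%)
flags the other half-life as unidentifiable. Approximate standard errors
come from the residual Jacobian at the optimum. On noiseless data the
fitter recovers generating parameters to better than 1e-6 relative
error, and a test verifies it never loses to a $20^4$ exhaustive grid.

Two fit modes are exposed. *Pooled* (default) fits all per-trace points,
which gives well-defined residual degrees of freedom; *averaged* fits
the mean trace, matching the classical description of fitting the
average of all normalized traces. The original convention behind
published F ratios is not recoverable, so both are available and the
degrees of freedom are always reported.

`extra_ss_f_test()` compares one shared fit against per-group fits:

$$F = \frac{(SS_{\text{shared}} - SS_{\text{sep}})/(df_{\text{shared}} - df_{\text{sep}})}{SS_{\text{sep}}/df_{\text{sep}}},\qquad df_{\text{shared}} = N - 4,\; df_{\text{sep}} = N - 4k.$$

Each per-group fit is seeded with the shared solution as an extra start,
which guarantees the nesting $SS_{\text{shared}} \ge SS_{\text{sep}}$
structurally rather than hoping the optimizer finds it.

**Calibration and the noise model.** The F test assumes independent
residuals. Calibration and power studies therefore draw traces from
`simulate_normalized_traces()`: $R(t)$ plus iid Gaussian noise on the
normalized scale. Under those conditions the type-I error at
$\alpha = 0.05$ sits inside the binomial interval over 500 replicates,
and a plateau contrast of 0.73 vs 0.53 (sd 0.05, 20 traces/group) is
rejected in essentially every replicate. Running raw traces through the
full normalization instead anchors each trace to its own noisy first
post-bleach sample; that single-sample anchor is shared by every
residual of the trace, correlates them, and genuinely inflates the F
test (we measure roughly 6x the nominal type-I error at these noise
levels). This is a property of full-scale FRAP normalization worth
knowing when interpreting published F ratios, and it is why the
package's statistical validation is performed at the normalized level
while the imaging validation (registration, extraction, normalization
identity) is performed on rendered stacks.

The fixed-timepoint comparison (`recovery_at_timepoint()`, default
4080 s = 68 min) reads each trace at the nearest post-bleach sample
(within half a sampling interval) and applies a pooled-variance t test
or Mann-Whitney; with more than two groups each is tested against a
reference, with no multiple-testing correction (none is part of the
emulated protocol; $\alpha$ is configurable).

## Synthetic imaging and its limits

`render_frap_stack()` draws boutons as isotropic Gaussian spots
(sd 2 px) whose integrated intensity follows the simulated traces, a
broad cell blob carrying the same acquisition-bleach factor, constant
background, optional global drift and Gaussian or Poisson camera noise.
Ground-truth circular ROIs use radius 3.5 spot-sd, capturing 99.8% of
the Gaussian mass, so extraction reproduces traces within 1%; because
mask truncation is a constant multiplicative factor, it cancels exactly
in normalization. Registration estimates per-frame translation by phase
cross-correlation with the correlation surface re-evaluated on a
10x-upsampled grid around the integer peak (0.1-px steps), recovering
injected drifts within 0.25 px on the synthetic fields.

What the generator does **not** emulate: a realistic PSF (spots are
ideal Gaussians), reversible fluorophore dark states, focus drift,
heterogeneous per-bouton kinetics within a trace group, and structured
(non-white) noise. Passing tests therefore demonstrate correctness of
the measurement machinery, not robustness to every optical artifact of
real recordings.

## Kymographs, tracks and cumulative traffic

`build_kymograph()` resamples the axon polyline at 1-px arc steps and
reads intensity over a configurable-width normal segment per path
position (bilinear interpolation), reduced by maximum by default —
boutons are imaged saturated in this protocol, and the maximum preserves
dim moving puncta beside them; mean reduction is available.

`detect_tracks()` exists so that speed extraction can be tested in a
closed loop (manual tracing in an interactive tool is the field
practice). It takes per-row local maxima above a threshold, refines them
to subpixel positions by parabolic interpolation (after optional
Gaussian smoothing), and links them across consecutive frames to the
nearest active track within the displacement reachable at a maximum
speed (default 3 um/s). This is deliberately simple; crossing-track
disambiguation is out of scope, and the speed-accuracy contract (5% over
0.5-2.5 um/s) is met on non-crossing synthetic movies. `track_speed()`
is the segmental mean of |dx|/dt, so pauses count as zero-speed
segments, and reported speeds are magnitudes with the sign available
separately (`track_velocity()`).

`cumulative_traffic()` follows the stated order of operations exactly:
integrate along the perpendicular line ROI per frame (width 1 px by
default; the protocol states none), subtract background, divide every
frame by the mean of the 10 lowest frame values of that line's sequence,
then sum over frames. A constant signal therefore gives exactly the
frame count (151 by default), global intensity rescaling cancels, and
each added transit raises the sum by its integral over the baseline.
Both per-line values and their sum across lines can be aggregated, since
it is ambiguous whether published values summed the eight line ROIs per
field or averaged them.

## Miniature currents

`simulate_mepsc_trace()` draws event onsets from a homogeneous Poisson
process and adds biexponential kernels
$A(e^{-t/\tau_d} - e^{-t/\tau_r})$ scaled to peak at the drawn
amplitude, plus Gaussian noise. `detect_events()` implements the
sliding scaled-template criterion (template optimally scaled and offset
at each lag; criterion = scale / SE of fit, threshold 4 by default),
computed in closed form over all lags via FFT cross-correlation.
Defaults: 0.5/5 ms rise/decay for mEPSCs, 1/10 ms for mIPSCs — typical
quantal kinetics standing in for templates that were originally taken
from a representative recording and are not published. Two guards make
the criterion usable on clean data: a minimum fitted amplitude (2 pA)
rejects degenerate near-zero-residual matches, and the refractory
interval defaults to half the template length so one event cannot be
counted twice along its own decay. At SNR 7.5 the detector recovers a
3 Hz Poisson rate within 15% with a false-positive rate below 0.1 Hz on
event-free noise.

`qc_cell()` reads the seal test: leak = pre-step holding current, access
resistance from the capacitive transient peak, membrane resistance from
the steady state, tau from a log-linear fit of the transient decay, and
capacitance as $C_m = \tau / R_a$ (the published description derives
capacitance "from the tau" without a formula; $\tau/R_a$ is exposed and
underestimates by the factor $R_m/(R_a+R_m)$, about 2% for typical
cells). The published exclusion sentence carries impossible signs
("leak over -200 pA, membrane resistance over -100 MOhm"); the only
physically coherent reading is implemented: exclude when the leak is
more negative than -200 pA or the membrane resistance is below 100 MOhm,
with both boundaries inclusive for the kept side.

## Reproducibility and problem sizes

Every stochastic operation is a pure function of its configuration,
including the seed; the pipeline runner (`run_pipeline()`) threads one
seed through all stages and writes provenance (config hash, seed,
versions) next to every output, and a test byte-compares two runs of the
demo configuration. Validation studies in the test suite use 100
two-group simulations for parameter recovery and power, 500 replicates
for type-I calibration, 20 traces per group at residual sd 0.05, and
movies/recordings at the protocol's native sizes (151-frame movies,
120-s recordings at 10 kHz) — sizes at which the Monte-Carlo intervals
quoted above are decisive for the properties being checked.

## Known limitations

- Reaction-diffusion FRAP (spot-size-dependent recovery) is out of
  scope; the model is pure exchange kinetics.
- The ImageJ ROI binary format is not parsed; ROIs travel as CSV/JSON
  circles and polygons.
- Electrophysiology I/O is CSV only; proprietary acquisition formats
  are not read.
- Track tracing does not resolve crossing trajectories and fragments
  them instead.
- The F test's iid-residual assumption is violated by full-scale
  normalization of noisy traces (see above); group comparisons on such
  data should prefer the fixed-timepoint tests or be interpreted with
  that inflation in mind.
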