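# svpool

Quantification of synaptic-vesicle (SV) super-pool dynamics for
presynaptic physiologists: FRAP-based measurement of vesicle exchange
between boutons and the mobile axonal pool, kymograph-based axonal
transport statistics, and miniature postsynaptic current analysis with
cell quality control — together with a seeded synthetic-data generator
that produces all three input modalities with known ground truth, so
every stage of the pipeline is validated end to end without primary
imaging data.

## The model and statistics at the core

Fluorescence recovery after photobleaching a bouton's SV cluster is
modeled as a double exponential in half-life form,

    R(t) = P * [ f * (1 - 2^(-t/h_f)) + (1 - f) * (1 - 2^(-t/h_s)) ],

where `P` is the mobile fraction (plateau), `f` the fast-component
share, and `h_f < h_s` the component half-lives (s) — the closed-form
recovery of a bouton exchanging vesicles with an effectively unbleached
super-pool through two kinetic routes. Traces are background-subtracted,
corrected for acquisition photobleaching by ratio against the whole-cell
reference, normalized to 1 before / 0 right after the bleach, and
screened by a 60% photobleaching cutoff. Groups of recovery curves are
compared with the **extra sum-of-squares F test**,

    F = ((SS_shared - SS_sep) / (df_shared - df_sep)) / (SS_sep / df_sep),

which asks whether separate per-group double-exponential fits reduce the
residual sum of squares enough, per extra parameter, to reject a single
shared fit. Axonal transport is read from kymographs (speed = ridge
slope; segmental mean speed with pauses included) and from a cumulative
cross-section traffic statistic (per-frame line integrals normalized by
the mean of the 10 lowest frames, summed over the 151-frame sequence).
Miniature events are detected by a sliding scaled-template criterion
(scale / SE of the local fit), and cells are screened on leak current
(≥ −200 pA) and membrane resistance (≥ 100 MΩ) from a seal-test
recording.

## Worked example

The `analysis/` scripts form a small simulation study. Step 01 simulates
two FRAP groups (20 boutons each, residual noise sd 0.05) with mobile
fractions 0.73 and 0.53 — a plateau contrast of the size reported
between permissive and restrictive synaptic conditions; step 02
normalizes, fits, and tests them:

```sh
Rscript analysis/01_simulate_frap_groups.R
Rscript analysis/02_fit_frap_kinetics.R
```

prints

```
-- high mobility group --
double-exponential FRAP fit (pooled, 400 points)
  plateau (mobile fraction) = 0.6736
  fast fraction             = 0.3445
  half-lives                = 35.29 s / 786.7 s
  residual SS               = 6.9704

-- low mobility group --
double-exponential FRAP fit (pooled, 400 points)
  plateau (mobile fraction) = 0.5741
  fast fraction             = 0.3913
  half-lives                = 58.76 s / 1566 s
  residual SS               = 10.9001

extra sum-of-squares F test (2 groups)
  F(4, 792) = 37.29, p = 1.344e-28 -> divergent
  SS shared = 21.2362, SS separate = 17.8705

recovery at 68 min: high 0.715 +/- 0.038 vs low 0.483 +/- 0.041 (t = 4.186, p = 0.000162)
```

The fitted plateaus bracket their generating values (0.73/0.53) within
sampling error, the F test rejects a shared recovery model decisively,
and the 68-min group means separate by about 0.23 — the single-timepoint
view of the same contrast. Steps 03 and 04 run the transport and mEPSC
analyses: traced kymograph speeds match injected speeds across
0.5–2.5 µm/s within 0.3%, cumulative traffic grows strictly with transit
density, and the mEPSC comparison recovers a frequency contrast
(p = 3.6e-05, Mann-Whitney) with unchanged amplitudes (p = 0.34).

Everything the scripts do is exposed as package functions
(`simulate_frap_trace()`, `normalize_trace()`,
`fit_double_exponential()`, `extra_ss_f_test()`, `build_kymograph()`,
`detect_tracks()`, `cumulative_traffic()`, `detect_events()`,
`qc_cell()`, …); `run_pipeline()` drives the FRAP chain from a single
YAML configuration with provenance records. See the methods vignette
(`vignettes/svpool-methods.Rmd`) for the model, the numerical choices
and the known limitations.

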