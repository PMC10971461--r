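# ofrkit — dichoptic ocular-following response analysis

Ocular-following responses (OFRs) are reflexive, short-latency eye
movements evoked by the sudden motion of a large textured pattern. Because
they are driven by cortical neurons that are almost invariably tuned to
binocular disparity, OFRs are sensitive to *interocular correlation*: in
stereo-competent observers a pattern drifting identically in both eyes
(correlation +1) evokes a larger response than the same pattern shown
contrast-reversed to one eye (correlation −1), whereas observers without
functioning disparity detectors (e.g. with amblyopia or strabismus)
respond equally to both. Comparing the two conditions therefore provides
an objective, report-free probe of stereo deficiency — attractive for
young children, for whom perceptual stereo tests are unreliable.

`ofrkit` implements the full analysis pipeline for such an experiment,
with a synthetic-data generator standing in for the clinical recordings
(facial images of children cannot be shared):

* **stimulus** — 1D random-line dichoptic stimuli: binary ±c blocks over
  pairs of pixel rows (0.06°), raised-cosine low-pass (gain 1 below
  0.375 cpd, 0 above 0.75 cpd), RMS contrast normalized to 30%, drifted
  up/down at 50°/s behind a 28° aperture at 144 Hz, red/blue channel
  encoding with the green channel always zero.
* **synthetic data** — simulated sessions (2 conditions × 2 directions ×
  30 trials) with known ground truth, at two tiers: per-trial displacement
  tables, and rendered near-IR camera-frame triplets at t₀ = 0, t₁ = 80,
  t₂ = 160 ms with a dark pupil and a head marker, including blink,
  saccade and head-jump contamination.
* **tracking** — subpixel dark-blob localization (Otsu threshold,
  connected components, darkness-weighted centroid) of pupil and marker;
  blink / out-of-frame trials are discarded at this stage.
* **trial QC** — eye-in-head = pupil − marker displacement, converted to
  degrees; iterative robust exclusion of trials deviating from the median
  by more than 3 robust SDs (1.4826 × MAD), applied to fixation-epoch eye
  and head and movement-epoch head channels, repeated until stable.
* **OFR statistics** — per condition, the OFR is the difference of mean
  vertical eye displacements in the open-loop movement window:

  OFR = ⟨Δy_up⟩ − ⟨Δy_down⟩,  SD = √(s²_up + s²_down),
  SEM = √(s²_up/n_up + s²_down/n_down)

  with pooled-variance t and Mann–Whitney U direction tests, and a
  four-cell bootstrap (resampling each condition × direction cell with
  replacement, default 10,000 replicates) for the correlated-vs-
  anticorrelated comparison, p = 2·min(#(Δ\*≤0)+1, #(Δ\*≥0)+1)/(B+1).
  Subjects with p < 0.05 are flagged as sensitive to interocular
  correlation.

A reference cohort of published per-subject summary statistics (6
stereo-normal controls, 6 amblyopic patients) ships as plain-text CSVs
(`inst/extdata/`) and drives the worked examples.

## Worked example

```r
library(ofrkit)
cfg <- pipeline_config(
  subject = subject_model(ofr_correlated_deg = 0.4,
                          ofr_anticorrelated_deg = 0.15),
  n_bootstrap = 10000, seed = 101)
run <- run_pipeline(cfg)
print(run)
#> OFR pipeline run (table tier)
#>   trials: 120 total, 92 kept (23% excluded)
#>   OFR correlated     0.430 +/- 0.215 deg (SEM 0.046)
#>   OFR anticorrelated 0.131 +/- 0.206 deg (SEM 0.041)
#>   delta = 0.299 deg, bootstrap p = 0.0002 -> sensitive to interocular correlation
```

The simulated observer has true amplitudes OFRc = 0.4°, OFRac = 0.15°.
QC excluded 23% of the 120 trials (blinks plus robust-outlier screening —
the range seen in clinical sessions is roughly 5–45%). The estimated OFRs
bracket the truth within their SEMs, and the bootstrap flags the
correlated response as significantly larger: this observer would be
classified as having functioning disparity detectors. Setting
`ofr_anticorrelated_deg = 0.4` simulates a stereo-deficient observer, for
whom the flag rate drops to the nominal α.

The numbered scripts under `analysis/` walk through the same stages as a
narrative: stimulus contract checks (`01`), table-tier sessions for a
stereo-normal and a stereo-deficient observer (`02`), frame-tier
rendering + tracking accuracy (`03`), the reference-cohort worked example
(`04`), and bootstrap calibration by replicate simulation (`05`). Each
writes its tables under `results/`.

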