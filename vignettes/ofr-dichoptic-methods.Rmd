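---
title: "Methods: dichoptic OFR analysis with ofrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dichoptic OFR analysis with ofrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofrkit)
```

## The measurement and its model

The ocular-following response (OFR) is a reflexive, conjugate eye movement
with a latency of about 80 ms, evoked by sudden motion of a large textured
pattern. The apparatus modelled here samples only three camera frames per
trial — at stimulus onset (t0 = 0 ms), at the typical human OFR latency
(t1 = 80 ms) and at the end of the open-loop phase (t2 = 160 ms) — so the
response is quantified as a *displacement* over the movement window
(t2 − t1), not as a velocity trace. The fixation window (t1 − t0) carries
no stimulus-driven movement and is used purely for quality control.

Per condition (correlated or anticorrelated dichoptic stimulation) the OFR
is the contrast between drift directions:

$$\mathrm{OFR} = \bar{y}_{up} - \bar{y}_{dw}, \qquad
\mathrm{SD} = \sqrt{s_{up}^2 + s_{dw}^2}, \qquad
\mathrm{SEM} = \sqrt{s_{up}^2/n_{up} + s_{dw}^2/n_{dw}},$$

where $y$ is the vertical eye-in-head displacement (deg) in the movement
window and the per-direction statistics use the $n-1$ SD. Taking the
up/down difference cancels direction-independent offsets (fixation drift,
residual head motion). The scientific question — does interocular
correlation modulate the OFR? — is answered per subject by a four-cell
bootstrap on $\Delta = \mathrm{OFR}_c - \mathrm{OFR}_{ac}$.

## Stimulus generation

The stimulus is a 1D vertical luminance profile: every block of two pixel
rows (0.06° at the 0.03°/px pitch) takes the value $+c$ or $-c$
independently with probability ½ (mean-relative units). The raw profile is
low-pass filtered with a raised-cosine gain — unity at or below 0.375
cycles/deg, zero at or above 0.75 cpd,
$G(f) = \tfrac12\!\left(1+\cos\pi\frac{f-0.375}{0.375}\right)$ in between —
and rescaled so its RMS (relative to mean luminance) is exactly 0.30.
Numerical choices:

* **Cyclic frequency-domain filtering.** The pattern wraps behind the
  static 28° aperture while drifting, so it is treated as cyclic and
  filtered by multiplying its DFT by $G$; this avoids edge artifacts and
  makes drift an exact rotation of the profile. The aperture height is
  rounded to a whole number of blocks (934 rows with the defaults) so the
  block structure tiles the cycle.
* **Transition-band formula.** The corner frequencies are given; the
  half-cosine interpolation between them is the standard raised cosine
  anchored at those corners.
* **RMS contrast convention.** Contrast is the RMS of the mean-relative
  profile (the usual convention for non-periodic noise stimuli), so
  normalization is a single linear rescale and is idempotent.
* **Subpixel drift.** The per-frame shift, 50/144 ≈ 0.347° = 11.574 px, is
  not an integer. Frames are rendered by integer rolls of an 8× super-
  sampled profile with the fractional residual accumulated across frames,
  so the mean speed is exact to one part in `8 * n_px` while each frame
  remains a plain pixel raster. The sequence length is
  `round(0.200 s × 144 Hz) = 29` frames.
* **Channel encoding.** Red carries one eye's pattern, blue the other's,
  and green is identically zero (it would pass both color filters in a
  dichoptic rig). The anticorrelated condition negates the profile, so
  both conditions share power spectrum and contrast exactly and differ
  only in interocular correlation (+1 vs −1, exact by construction).

## What the synthetic generator emulates — and what it does not

No clinical recordings can ship with the package, so every downstream
stage is exercised on simulated sessions with known ground truth, at two
fidelity tiers that emit the same table schema and therefore compose
interchangeably.

**Table tier.** Movement-window vertical eye displacement is drawn from
$\mathcal N(\pm A_{cond}/2, \sigma)$ (up/down), so the expected OFR equals
$A_{cond}$; fixation-epoch eye and all head-marker displacements are
zero-mean noise. Defaults: $A_c$ = 0.4°, $A_{ac}$ = 0.15°, σ = 0.15°,
fixation noise 0.05°, head noise 0.5 px, 30 trials/cell — magnitudes chosen
to sit in the middle of the per-subject ranges a school-age cohort shows
(OFRs of 0.1–0.7°, trial-to-trial SDs of 0.04–0.3°). A stereo-deficient
observer is simulated by $A_{ac} = A_c$. Contamination is at most one type
per trial: a fixation-epoch eye offset of 10× the fixation SD (saccade), a
head offset of 10× the head SD in a random epoch (head jump), or a
missing-pupil flag (blink); default rates 0.10 / 0.05 / 0.10 produce total
exclusion fractions inside the 5–45% range seen clinically.

**Frame tier.** Each trial renders three grayscale frames: an iris disc
with a darker pupil disc, and a separate dark head marker, all drawn as
anti-aliased discs (1 px soft edge) at continuous positions; a blink
removes iris and pupil (closed eyelid); pixel noise is optional additive
Gaussian. Eye rotation maps to pupil-image translation linearly at
`px_per_deg` (default 40 px/° — plausible for a 50 mm lens at
2448 × 2048; the true calibration of such a rig is a required config
input, not something the analysis can infer). Analysis-space vertical
displacement is positive-up; image rows grow downward; the sign flip is
applied exactly twice, once in rendering and once in tracking, and the
round-trip test pins it.

Not modelled: eyelids/eyelashes/glints, torsion, lens distortion,
photorealistic texture. Passing tests therefore demonstrate the
correctness of the *pipeline* (geometry, bookkeeping, statistics), not the
robustness of pupil segmentation to real-world image nuisances.

## Tracking

Features are localized per frame as dark blobs: Otsu's threshold (within a
configurable intensity window), connected-component labelling, components
filtered by area bounds and a circularity floor
(area / circumscribed-disc area), the largest taken. Two exactly equal
candidates are tie-broken deterministically (lower centroid y, then lower
x) with a halved quality score. The subpixel center is the
darkness-weighted centroid (weights `threshold − intensity`, clipped at
zero) over the component. Failures set `valid = FALSE`; they are never
errors. The marker search excludes a disc around the detected pupil and
treats border-touching components as invalid (partially out of frame).
Displacements are differences of per-frame absolute centers, not pairwise
image registration, matching a "displacement of the center" definition.
The accuracy contract is defined by render-and-recover: RMSE < 0.05 px
over 100 random subpixel shifts at zero noise, degrading monotonically
with pixel noise.

## Trial quality control

Eye-in-head displacement is pupil minus marker, per epoch and axis,
divided by `px_per_deg`. Screening then applies the iterative robust rule:
drop values deviating from the median by more than `k = 3` times the
robust SD, re-estimate, repeat until no trial is dropped. Design choices
the procedure's verbal description leaves open:

* **Robust SD = 1.4826 × MAD** — the canonical robust scale estimate,
  consistent for the SD under normality.
* **Degenerate rule**: when the MAD is zero (at least half the values
  identical) only values exactly equal to the median are kept.
* **Pooling**: channels are screened over all four condition × direction
  cells pooled, because fixation drift and head motion are
  condition-agnostic; screening the movement-epoch *eye* channel is
  deliberately omitted (it would clip the very response being measured),
  and the movement-epoch *head* channel is screened.
* **Axes**: both horizontal and vertical components are screened — a
  saccade in x is still poor fixation. Configurable.
* **Outer loop**: the whole multi-channel screening repeats until a full
  pass drops nothing, which makes the procedure idempotent (dropping a
  trial flagged on one channel changes the pooled sets of the others).
* Exclusion reasons are prioritized blink > out-of-frame > fixation-eye >
  fixation-head > movement-head.

## Statistics

Direction tests are the pooled-variance unpaired t-test (Welch available
by argument; pooled is the textbook default for "unpaired t-test") and the
Mann–Whitney U test — exact when both groups have ≤ 8 observations and no
ties, otherwise the normal approximation with tie and continuity
correction. With zero variance in both groups, p = 1 for equal means (by
convention) and 0 otherwise.

The bootstrap comparison resamples each of the four cells with
replacement at its own size (preserving the design), forms
$\Delta^* = \mathrm{OFR}_c^* - \mathrm{OFR}_{ac}^*$, and reports the
two-sided $p = \min\!\big(1,\ 2\min(\#(\Delta^*\le 0)+1,
\#(\Delta^*\ge 0)+1)/(B+1)\big)$ with $B = 10{,}000$ by default — the +1
correction keeps p off zero and inside $[1/(B+1), 1]$. Cell values are
sorted before resampling so the p-value is invariant to trial order and
bit-reproducible given the seed. No multiple-testing correction is applied
across subjects (tests are reported per subject at α = 0.05); cohort
classification simply counts flags.

## Reference cohort worked example

The package ships the published per-subject summary statistics of a
12-child cohort (6 stereo-normal, 6 amblyopic) as plain-text CSVs. The
derived columns (OFR, combined SD, SEM) recompute from the per-direction
columns to the printed precision (±0.001, plus the ±0.001 slack explained
by the inputs themselves being rounded to three decimals) for every
arithmetically consistent cell; three anticorrelated SEM cells (HC2, HC6,
P5) cannot be obtained from the printed inputs at any rounding and are
treated as printing inconsistencies. The published bootstrap p-values,
thresholded at 0.05, classify 5 of 6 controls as sensitive to interocular
correlation and 0 of 6 patients — the sensitivity/specificity pattern that
motivates the method. p-values printed as "<0.001" are stored at their
upper bound, which is immaterial for thresholding at conventional α.

## Problem sizes and runtime choices

The test-suite and analysis scripts choose sizes that make Monte-Carlo
checks sharp while keeping a full run in tens of seconds to a few
minutes: frame-tier tests use a 320 × 280 px camera with an 18 px pupil
(the tracker's subpixel contract does not depend on frame size), parameter
recovery uses 500 replicate table-tier sessions at 12–15 trials/cell,
type-I calibration 1,000 null sessions with 2,000 bootstrap draws, and the
oracle-equivalence checks 1,000 random inputs. The `analysis/05`
calibration script uses 400/200 sessions for the same quantities.

## Known limitations

* The pupil/marker detector is designed for the synthetic frames' clean
  dark-blob structure; real near-IR images would need the intensity
  window, area bounds and circularity floor tuned, and may defeat a
  centroid-based estimator in ways the generator does not model.
* `px_per_deg` is an external calibration; the pipeline treats it as
  exact, so its error propagates multiplicatively into all degree-valued
  outputs.
* The three-frame design cannot estimate latency or velocity; everything
  rests on the two displacement windows.
* A subject flagged "insensitive" is not automatically stereo-deficient:
  small OFRs reduce the detectable relative difference, and monocular
  blindness or large vertical strabismus can mimic insensitivity. The
  classification is a screening signal, not a diagnosis.
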