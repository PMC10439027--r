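---
title: "The dynamic pink-noise protocol: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dynamic pink-noise protocol: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the stimulus model, the analysis model, the parameters that matter, and
the numerical and design decisions taken where the protocol leaves the
implementation open.

## 1. The stimulus model

### Pink noise

A noise field is synthesized in the frequency domain: a white Gaussian
image is Fourier transformed (giving independent complex-Gaussian
coefficients with the Hermitian symmetry of a real image), amplitudes are
scaled by $1/f_r$ with $f_r = \sqrt{f_x^2 + f_y^2}$ in cycles/image, and
the inverse transform is taken. This yields Gaussian pink noise with
uniformly random phases. Two conventions required a decision:

* **DC.** $1/f_r$ is singular at zero frequency. The DC coefficient is
  zeroed and the target mean is imposed afterwards by the normalization
  step, which fixes the sample mean and the RMS contrast
  ($\mathrm{SD}/\mathrm{mean}$, population SD) exactly by an affine
  transform. Normalizing is idempotent, so stacked operations never drift.
* **Units.** All spectral computation is in cycles/image; conversion to
  cycles/degree happens only at the reporting layer through the
  pixels-per-degree (ppd) configuration. The core is therefore
  display-independent.

The defining property — equal energy in equal octaves, the reason the
embedded signal is about equally discriminable at any retinal eccentricity
once cortical magnification is taken into account — is exposed as a
directly testable diagnostic (`band_energy`, `octave_energy_ratio`) rather
than assumed.

The construction (phase randomization of scaled Gaussian spectra) is one
of several equivalent routes to pink noise; any construction passing the
spectral diagnostics would serve. We make no claim that it reproduces any
particular prior codebase bit-for-bit.

### Orientation filtering

The local signal is produced by multiplying the noise spectrum with a
Gaussian weight in orientation only,

$$ w(\phi) = \exp\!\left(-\frac{(\phi - \phi_0)^2}{\sigma^2}\right), $$

flat along the radial direction so the 1/f profile is untouched. Design
decisions:

* **Sign of the exponent.** The weighting must be a bounded Gaussian and
  narrower $\sigma$ must mean a *stronger* signal; only the negative
  exponent produces that behaviour, so that is what is implemented.
* **Angular distance.** $\phi - \phi_0$ is the minimal distance under
  180° periodicity (orientation, not direction), folded to $[-90°, 90°)$.
  Without folding, the filter would act asymmetrically on the spectrum's
  two half-planes. Whether an earlier implementation folded or used the
  raw arctangent difference is unknown to us; folding is the only choice
  consistent with an axial quantity.
* **No wrapping.** The Gaussian is not summed over 180° periods. For the
  widest task-relevant width ($\sigma = 70°$) the tail at the fold is
  $\exp(-(90/70)^2) \approx 0.19$ — not negligible, but the single
  Gaussian is the filter's definition, so it is kept and documented rather
  than "improved".
* **Nyquist aliasing.** On even-sized grids the row/column at $\pm N/2$ is
  self-aliased and carries two orientation readings. The weight there is
  the average of the Gaussian at both readings — the unique assignment
  compatible with Hermitian symmetry, hence with a real-valued filtered
  image (imaginary residue is checked and must stay below $10^{-8}$ of the
  output RMS).
* **DC weight is 1**, leaving the mean untouched; the mean is re-imposed
  downstream anyway.

Before embedding, the filtered image is affinely rescaled so its minimum
and maximum equal those of the unfiltered frame
(`match_amplitude_range`) — an order-preserving map, applied to the whole
field *before* windowing.

### Embedding window

The signal enters through a circular raised-cosine window: weight 1 out to
the plateau radius $r$, half-cosine ramp to 0 over $[r, r+w]$. The ramp is
placed *outside* $r$, so "radius" names the full-strength region; total
support is $r + w$. The composite is the pointwise convex combination
$W \cdot \text{signal} + (1-W) \cdot \text{background}$: bit-exact
background outside the support, bit-exact signal on the plateau, no
overshoot anywhere. Window centers are evaluated at real-valued positions
(no rounding to the pixel grid), so sub-pixel placement is exact. Any
weight map in $[0,1]$ can be passed in place of the circular window; only
the circular constructor is shipped.

### Dynamics

The movie steps from keyframe $A$ to $B$ to $C$… through $n$ hybrid steps
per pair (default 4). Hybrids are linear pixel mixes with weights
$((n-k)/n,\, k/n)$ — the compositional reading of the names AAB / AB /
ABB, generalized to arbitrary $n$ — and each hybrid is re-adjusted to the
keyframes' mean and contrast, since averaging two independent noises loses
about $1/\sqrt{2}$ of RMS contrast at the midpoint. Pure $A$ is emitted
once per movie (it belongs to the previous pair), avoiding duplicated
frames.

During the signal interval the orientation filter is applied to *each
underlying frame* — keyframes and hybrids alike — and embedded; the signal
patch is not a static overlay but updates with the background. After
embedding, each signal frame's global statistics are re-imposed with the
same affine adjustment used for hybrids, so *every* emitted frame carries
the target mean and contrast to numerical precision and there is no
global luminance or contrast flicker that could time-stamp the signal.
(The embedding operation itself remains an exact convex combination; the
statistics adjustment is a separate, subsequent step of the movie
assembly.)

Onsets and durations must be whole numbers of frames at the update rate.
Violations are hard errors that name the nearest valid durations — never
silent rounding. The shipped circular-field session runs the noise at
60 Hz on a 120 Hz display (each frame shown twice, stored once with a
repeat factor); its cue is 4 frames (66.7 ms), the nearest frame count
below the nominal 75 ms, with 100 ms cue–signal delay (6 frames), 50 ms
signal (3 frames), and 500 ms mask. The strip-field session runs at
120 Hz with a 5-frame (41.7 ms) signal.

Temporal concealment is quantified, not asserted: `concealment_ratio`
compares the mean frame-to-frame RMS difference during the signal interval
with that outside it; values near 1 mean the local signal's appearance is
buried in the ongoing full-field flux.

## 2. Protocol assembly

A `session_config` bundles display geometry, noise parameters, the signal
window and σ ladder, placement mode, the timing table, trial counts and
the master seed; it validates everything at once (all offending fields
reported together). Two YAML fixtures ship with the package:

* `exp1a.yaml` — circular field (plateau radius 14.32°, ramp 2.39°)
  spanning the display height, eccentricities 0/3.5/7/10.5°, cued and
  uncued trials, σ ladder of 9 linear steps over 30–70°, signal window
  $r = 1.75°$, $w = 0.875°$.
* `exp2.yaml` — rectangular 2.5° × 20° strip, nine horizontal positions
  (0, ±2, ±4, ±6, ±8°), signal window $r = 1.0°$, $w = 0.875°$, and five
  placeholder rings (radius 1°) drawable at 0, ±4, ±8°.

Decisions worth knowing:

* **Pixels per degree** is a required input; the fixtures use 26.8 px/deg,
  the nominal value implied by a 14.32°-radius field spanning half of a
  768-px screen height. No physical monitor dimensions are invented.
* **Placement.** Eccentricity mode draws the polar angle uniformly from
  the trial's placement substream; position mode puts the center on the
  horizontal midline. Placements whose window support would leave the
  field are errors, not clamped.
* **Uncued trials keep the cued timeline.** The cue interval simply shows
  plain background, so cued and uncued twins of the same seed share every
  frame; the pink cue ring (RGB 204/0/102) is rendered at export time
  only, keeping the stimulus core grayscale.
* **Fixation jitter** is uniform-continuous over the configured range,
  then quantized to whole frames (a distributional convention; nothing in
  the protocol constrains it further).
* **Strip field.** The visible strip (2.5° tall) is narrower than the
  signal window's support ($r + w = 1.875°$ > half-height). The pixel
  field is therefore taller than the strip and the rectangular aperture is
  applied at display/export time, mirroring a physical display where the
  window is clipped by the field edge. Stored frames remain full-field so
  the per-frame statistics invariant stays measurable. The placeholder
  rings are drawn dark (luminance 0.05): outlines described as "black" on
  a mid-gray field are rendered near zero.

## 3. The analysis model

### Psychometric fits

Responses are 2AFC, so accuracy follows
$\Psi(x) = 0.5 + (0.5 - \lambda)\,\Phi\!\left(s\,(x - \mu)/\sigma_s\right)$
with guess rate fixed at 0.5 and lapse rate $\lambda$ fixed at 0 by
default ($\lambda$ is exposed but off: the protocol's curves asymptote at
50% and 100%, and the simplest model consistent with that has no lapse).
$s = -1$ for filter width (accuracy falls as the filter widens), $s = +1$
for tilt angle. Fitting maximizes the Bernoulli likelihood with L-BFGS-B
from 10 starts over a coarse $(\mu, \log\sigma_s)$ grid, tolerance about
$10^{-8}$ relative on the log-likelihood. The 75% threshold is
analytically $\mu$; `threshold_at` inverts $\Psi$ at any criterion in
$(0.5, 1)$.

Degenerate data — at chance everywhere, saturated, or implying a threshold
outside the tested ladder — produce `converged = FALSE` with a diagnostic
note. A non-converged fit cannot be inverted; there is no silent estimate.

### Permutation tests

Condition contrasts are tested by within-observer label permutation
(equivalently, sign-flipping each observer's paired difference), two-sided
on the magnitude of the group-mean difference. Two conventions:

* **Sidedness.** "Below or above" is read as two-sided on
  $|\Delta|$, matching symmetric condition contrasts.
* **Small-sample correction.** $p = (1 + \#\{|\Delta^*| \ge
  |\Delta|\}) / (\text{iterations} + 1)$, so $p$ is never 0. The raw
  proportion (which admits $p = 0$) is available behind
  `plus_one = FALSE`.

Bonferroni correction is plain multiplication capped at 1. Calibration is
verified empirically in the acceptance suite: across 1000 simulated null
datasets of 12 paired observers with continuous accuracy values, the
type-I error at $\alpha = 0.05$ must land in $[0.03, 0.07]$. With few
observers and coarse (binomial) per-observer means, sign-pattern ties make
the test conservative — a well-known property of discrete permutation
distributions, worth remembering when six observers contribute means over
tens of trials.

### Spatial profiles

`summarize_by_location` aggregates per-observer mean accuracy per test
location, reports the across-observer mean ± SEM, and returns a
piecewise-linear interpolant across positions for plotting accuracy
profiles over space.

## 4. The synthetic observers

Two simulated observers close the loop without human data. Neither models
human vision; they validate the pipeline.

* **Psychometric simulator** (`observer_model`, `simulate_responses`): a
  ground-truth cumulative Gaussian of filter width (default
  $\mu = 50°$, $\sigma_s = 10°$, the center of the task's σ ladder)
  generates Bernoulli responses. Cued trials (and uncued trials at
  fixation) see the signal; uncued peripheral trials respond at chance —
  the response structure of an observer whose attention sits at fixation
  unless summoned, and the behavioral signature that the embedded signal
  does not capture attention by itself. An `attention_gain` multiplier
  scales effective signal strength (effective width $\sigma /
  \text{gain}$) at cued locations. What this simulator deliberately does
  *not* emulate: acuity falloff with eccentricity, criterion shifts,
  sequential effects, learning. Passing recovery tests therefore shows
  that the generator + fitting pipeline is unbiased at session scale, not
  that humans behave this way.
* **Image-computable decoder** (`decode_tilt`, `run_decoder_study`): a
  fixed orientation-energy model — no training, no tunable weights. Over
  the signal frames it windows the mean-subtracted frame with the analysis
  window's raised cosine and takes the difference of spectral energy
  within ±15° of the two candidate tilts; the decoded tilt is the sign.
  The ±15° half-width was fixed a priori (half the tilt separation);
  sensitivity to it can be examined by passing another value, but it is
  never optimized. As an ideal observer with exact knowledge of signal
  location and timing, it operates at ceiling across the human-threshold
  σ range at the tested geometry; the informative properties are the
  direction of its accuracy trend with σ, its collapse to chance at a
  displaced analysis window (the stimulus-level "no pop-out" check), and
  its indifference to eccentricity at matched σ (the stimulus-level
  scale-invariance check).

## 5. Numerical choices and problem sizes

* **Spectral slope estimator**: log–log regression of radially averaged
  amplitude over log2-spaced bins, excluding the lowest and highest
  half-octave (discretization artifacts at both edges), weighted by the
  coefficient count per bin (a bin's log-amplitude sampling variance
  scales inversely with its count; unweighted fits are dominated by the
  handful of low-frequency bins).
* **Quantization on export**: clip to $[0,1]$, round half-to-even at the
  target bit depth. Frames export as 16-bit grayscale TIFF (quantization
  step $1/65535$, far below every statistics tolerance) or 8-bit PNG;
  weight maps and single fields export as 8-bit PNG for documentation.
* **Seeding**: all randomness flows from a master seed through named
  substreams (`substream_seed`), one per stage (noise, placement,
  responses, permutation), so changing one stage's RNG consumption never
  shifts another's draws. Run manifests record the config hash, package
  version, master and stage seeds.
* **Problem sizes**: spectral diagnostics run at 512² (10–20 seeds);
  decoder studies at 256² with 8 px/deg (200 trials per condition), a
  geometry where the 10.5° eccentricity plus window support still fits
  the field; psychometric recovery at 1704 trials, the scale of one
  observer's session; permutation calibration over 1000 simulated
  datasets of 12 observers. Shipped session fixtures keep the full
  printed geometry (26.8 px/deg, 768-px field).

## 6. Known limitations

* No gamma calibration or chromatic noise: luminance is an abstract
  $[0,1]$ scale; display linearization is the user's problem.
* No real-time presentation, vsync, or gaze-contingent control; the
  package renders frame stacks and sidecars for a presentation layer to
  consume.
* The raised-cosine parameterization (ramp outside the plateau radius) is
  one of two defensible readings of "radius r with a cosine ramp of width
  w"; it is stated prominently because window sizes quoted elsewhere may
  assume the other convention.
* The Gaussian orientation filter's unwrapped tail at the 90° fold is
  kept by definition; at σ = 70° roughly a fifth of the peak weight leaks
  to the orthogonal orientation.
* Simulated observers validate the pipeline, not human vision; all claims
  about human performance belong to empirical work, not to this package.
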