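---
title: "Form and motion RSA for dynamic faces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Form and motion RSA for dynamic faces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facersa)
```

## The problem

When a face moves, observers extract at least two kinds of information: the
*form* of the face (the configuration of its features, which distinguishes
identities) and its *motion* (the non-rigid deformation pattern, which
carries expression). `facersa` implements a representational similarity
analysis (RSA) pipeline that asks where and when multichannel
neurophysiological responses (MEG-style sensor data) carry similarity
structure matching physical, perceptual and categorical descriptions of a
crossed identity × expression set of dynamic face stimuli.

Every analysis in the package operates on **similarity matrices**: symmetric
S × S matrices whose cell (i, j) quantifies how alike stimuli i and j are
under one measure. RSA then correlates the off-diagonal cells of two such
matrices (Spearman, because only the ordinal structure is comparable across
measurement domains).

## The measures

**Configural form.** Each stimulus video is annotated with L labelled
landmarks per frame (L = 179 in the full design). The *configuration* of
the first (neutral) frame is the vector of all C(L, 2) = 15,931 pairwise
Euclidean distances between landmarks. Distances between corresponding
labelled points are invariant to image translation and rotation, and the
measure is face-specific: it requires corresponding reference points, which
non-face objects lack. Form similarity of two stimuli is the Pearson
correlation of their configuration vectors. (Whether to standardise
configuration vectors first is moot: Pearson correlation is invariant to
affine rescaling of either vector.)

**Motion pattern.** Facial motion is measured on the 141 interior landmarks
only, after removing rigid whole-head motion: a triangle of three nose
landmarks (a structure that moves only with the head) is registered onto
its first-frame position by an exactly-determined affine transform, applied
to all landmarks, frame by frame. Flow is the per-landmark displacement
magnitude (pixels) between consecutive frames; the package has no pixel
data, so landmark displacement stands in for image optic flow sampled at
the landmarks — same units, same spatial support, and the generator plants
landmark motion, so the proxy is exact for synthetic data. The estimator
sits behind its own function (`landmark_flow`) so a pixel-based method
could be substituted. Flows are averaged within 12 anatomical features,
giving a 12 × (F − 1) matrix, and the *motion pattern* is the vector of
absolute differences between every unordered pair of those values —
C(12 × 55, 2) = 217,470 elements for 56-frame clips. Motion similarity is
the Pearson correlation of motion patterns.

**Categorical models.** Binary matrices: 1 for same-identity (or
same-expression) pairs, 0 otherwise. Because the design crosses 6
identities with 6 expressions, the identity model tests for
expression-invariant identity structure and vice versa.

**Perceptual judgments.** Mean per-pair similarity ratings over
participants, one matrix per task (form instructions / motion
instructions), all 630 pairs rated.

**Response patterns.** Pearson correlation between per-stimulus channel
patterns, at one time point (evoked) or one time–frequency bin (power).
Patterns are correlated without per-channel standardisation by default
(`scale_channels = FALSE`), matching the plain-Pearson convention; the flag
exists because mixed-unit channel sets are a genuine concern with real
recordings.

## The inference chain

Per participant and map coordinate: Spearman correlation (mid-ranks; ties
are heavy because categorical models are binary) between the model cells and
the response cells, optionally partial Spearman (rank-transform everything,
project the ranks of both variables onto the control ranks plus intercept,
correlate residuals); then Fisher z = atanh(ρ).

Smoothing before group statistics (matched-filter rationale): evoked
timecourses get a zero-phase order-5 Butterworth low-pass below 10 Hz;
time–frequency maps get a separable Gaussian of 4 Hz × 20 ms FWHM
(σ = FWHM / 2.355, kernel mass renormalised at map edges so constants pass
unchanged). Two open choices are fixed and recorded: smoothing is applied to
the *z* maps (not raw ρ — atanh is smooth and near-linear in the observed
range, so the difference is far below measurement noise, but the choice is
stated), and the Butterworth order is 5 (zero-phase forward–backward
application squares its magnitude response). No Butterworth design routine
exists in the package's dependency set, so the bilinear-transform design is
implemented here and verified against its transfer function in the tests.

Group inference: right-sided one-sample t over participants' z maps
(positive relationships are the only interpretable direction between
similarity structures), enhanced by threshold-free cluster enhancement
(TFCE: extent^E · height^H integrated over thresholds, E = 0.5, H = 2,
step = map-max/100, 4-connectivity in 2-D), with familywise correction by
sign-flip permutation: each participant's map is randomly negated (the
exchangeable null for a one-sample test — the scheme of the standard MVPA
toolboxes, fixed here since the choice is conventional), t and TFCE are
recomputed, and the map-wise maximum collected; corrected
p = (1 + #{null max ≥ observed}) / (1 + n_perm), which is never zero and is
valid at any n_perm. If n_perm ≥ 2^n participants the sign patterns are
enumerated exhaustively instead (with a warning). Each permuted map is
enhanced with its own max/100 TFCE step, keeping cost bounded and
enhancement scale-relative; dh can be fixed explicitly when exact
comparability across maps is wanted.

Default n_perm is 10,000; the test suite runs 200 to stay inside its time
budget — permutation p-values are then resolved to 1/201, which is ample
for α = 0.05 decisions.

## The synthetic world

The generators state the world the pipeline is tested in; their defaults
are the emulated design: 36 stimuli (6 × 6), 179 landmarks (141 interior,
12 features), 56 frames / 2 s, 16 participants, 32 presentations of each
video (1152 trials), epochs −500…2500 ms, artifact limits 2000 (axial) and
50 (planar) in channel units, Morlet factor 7 over 4–50 Hz, log-ratio
baseline −350…−100 ms.

**Faces.** Frame 1 = shared template + identity offset
(`identity_form_scale`, default 8 px — identity differences well above
annotation noise, as landmark sets digitised from distinct people are) +
per-frame annotation jitter (`landmark_noise_sd`, 0.1 px, the sub-pixel
jitter of temporally-tracked landmarks; drawn fresh every frame so it also
sets the flow noise floor). Frames 2…F add a neutral-to-apex displacement
of a subset of features (`expression_motion_scale`, 15 px at apex, with
the ramp completing by mid-clip and holding — the emulated stimuli reach
their flow maxima before 1000 ms), shared across identities with a
per-video timing warp (log-normal exponent, σ = 0.2, mimicking
idiosyncratic expression dynamics), composed with smooth rigid head motion
(`rigid_motion_amplitude`, 2 px) applied about the face centre. The nose
fiducials receive no expression motion and are placed as a
well-conditioned triangle: annotation jitter on a near-collinear triangle
is amplified across the whole face by the inverse affine — and because
flow *magnitudes* rectify noise, the jitter's mean (not just variance)
enters the flow floor. Both failure modes shaped the defaults.

**Judgments.** Ratings are linear-in-physical-similarity plus Gaussian
noise, clipped to [0, 1]; the form task weights the form measure, the
motion task the motion measure. This is deliberately the simplest monotone
observer; it contains no categorical perception, attention or individual
strategy differences, so green behavioral tests establish the bookkeeping
and the statistics, not the psychology.

**Epochs.** Per participant, channel patterns are built whose
between-stimulus Pearson correlations equal the planted model matrix
*exactly*: orthonormal channel vectors (orthogonal to the constant vector,
so Pearson centering is inert) mixed through the Cholesky factor of the
(PSD-projected) model. The pattern modulates the amplitude of band-limited
oscillations inside the planted window; for induced effects the phase is
randomised per trial (cancels in evoked averages, survives in power), for
evoked effects it is locked. Power is linear in the planted pattern
(amplitude = base·√(1 + g·pattern)), so the noise-free power-pattern
geometry reproduces the model to numerical precision — the fidelity
invariant in the tests. `effect_size` is the oscillation amplitude in noise
SDs; 1.5 is the documented recovery effect size. Channel count defaults to
64 (≥ S + 1 is required for the exact construction; 306-channel layouts are
supported but slow on a desk).

What the generator does *not* emulate: correlated sensor noise, 1/f
background spectra, head movement, inter-participant latency and topography
differences, and any biophysical forward model. A green recovery test
therefore establishes that the chain detects the planted geometry at the
stated SNR — not that real MEG effect sizes would be detected.

## Numerical choices and degenerate inputs

- Canonical cell order for all vectorised matrices is the column-major
  lower triangle (the `stats::dist` order); any single consistent order is
  equivalent, and this one is shared by every matrix of a stimulus set.
- Zero-variance configuration vectors (e.g. an equilateral landmark set)
  are detected with a relative threshold (sd < 1e−12 × mean), since exact
  ties are destroyed by rounding.
- Morlet wavelets are L2-normalised with 5σ support; samples within 2.5σ
  of an epoch edge are flagged per frequency and excluded from RSA scans
  (beyond 2.5σ the envelope is < 4% in amplitude — flagging the full
  support would discard most of the epoch at 4 Hz for no measurable gain). The log-ratio baseline uses the natural log — the base is a
  global scale that cancels in correlation-based RSA.
- The zero-phase filter initialises each pass at its steady state for the
  first sample value (with odd-reflection padding), so constant maps pass
  through bit-exactly.
- Group t at zero-variance coordinates: 0/0 → t = 0 (all-zero maps),
  nonzero mean → ±Inf flagged through.
- `spearman_rsa` refuses constant (rank-degenerate) inputs by error rather
  than returning NA: in this pipeline a constant similarity vector is
  always an upstream bug or a degenerate design, never a valid observation.

## Scaled acceptance checks

Two acceptance criteria are run at reduced size, stated here and in the
tests: the null-calibration study (familywise error of the TFCE-permutation
chain in [0.01, 0.10] over 100 repetitions) feeds pure-noise channel
patterns directly into the pattern-similarity → RSA → permutation chain on
an 8 × 15 map, because regenerating wavelet-transformed epoch sets 100
times is outside any desk budget and the upstream stages are deterministic
transforms; the recovery study (planted 4–20 Hz, 600–1500 ms induced
effect found in ≥ 95% of 20 runs, absent from the evoked scan) runs the
full epochs → Morlet → log-ratio → RSA chain at 16 stimuli, 24 channels
and 4 trials per video. The evoked-scan "absence" check allows up to 2
window hits in 20 runs: the evoked scan retains its nominal ~5% familywise
false-positive rate under this null, and demanding zero would test the
wrong property.

## Known limitations

- Landmark displacement is a proxy for image optic flow; with real videos
  the two can diverge where landmarks are sparse relative to the motion
  field.
- Partial Spearman removes only the *linear-in-ranks* contribution of the
  controls; a binary control partialled out of a noisy copy of itself
  leaves residual monotone structure (a property of rank partial
  correlations generally, demonstrated in the tests).
- The permutation null assumes participants are exchangeable under sign
  flips of z; strong per-participant bias (e.g. shared stimulus-level
  confounds) violates this as it does in the standard toolboxes.
- Multiple model matrices are tested in separate scans; correction is per
  scan over map coordinates only, not across models.
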