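---
title: "EchoDose: models, parameters and design choices"
author: "EchoDose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EchoDose: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EchoDose)
```

## The problem

Percutaneous electrolysis (PE) applies galvanic current through a needle
into muscle. On B-mode ultrasound the treated region develops hyperechoic
foci — hydrogen gas microbubbles formed by electrolysis — whose number and
extent grow with the applied current intensity (mA), plateauing at high
doses where accumulated gas additionally casts posterior acoustic shadows.
EchoDose implements the quantitative side of studying that dose-response:
a synthetic B-mode generator with known ground truth, extraction of the
region-level (`A_`) and whole-ROI echotexture (`B_`) feature families, and
the statistical stage that screens, regresses and compares those features
against dose, including the composite `Muscle_Electrolysis_Dose`
(`UZ_eDosis`) index.

Because the underlying cadaver images are not publicly deposited, every
empirical claim the package tests is made on synthetic data with known
generating parameters. What a passing suite shows is therefore (a) that
each operator computes exactly what its formula says, and (b) that the
full pipeline recovers the parameters and qualitative trends it was given
— not that it reproduces the original study's measurements.

## The dose schedule

`makeDoseSchedule()` returns the 29-step escalation protocol: 0.10 mA
increments from 0.00 to 1.00 mA, then 0.50 mA increments to 10.00 mA.
Application time is fixed at one second, so dose is indexed by intensity.

## Synthetic B-mode frames

**Speckle.** `simulateSpeckleBackground()` uses the canonical fully
developed speckle model: a Rayleigh-distributed echo envelope, normalized
to unit mean and scaled to `backgroundMean` (default 60 on the 8-bit
scale, a typical mid-dark muscle echogenicity), then rounded to integers.
`speckleScale` interpolates between a constant frame (0) and the pure
Rayleigh envelope (1, the default); this keeps the mean gray level fixed
while tuning speckle strength. RF-level physics (point-spread functions,
frequency-dependent attenuation) is deliberately out of scope: the purpose
of the background is to exercise the texture operators with a realistic
first-order amplitude distribution.

**Lesions.** `plantLesions()` plants a Poisson number of disc-shaped foci
with mean `fociRate(d) = rMax d^2 / (d^2 + halfDose^2)` (defaults
`rMax = 8`, `halfDose = 3` mA). The saturating form reproduces the three
qualitative regimes reported for muscle PE — minimal response below 1 mA,
clear growth over 1–4 mA, plateau above 4–6 mA; since no quantitative
lesion-growth law is available, the two constants were chosen once to
match those regimes and are not otherwise calibrated. Mean focus radius
follows the same saturating curve from `radiusBase` (0.04 cm) to
`radiusBase + radiusGain` (0.07 cm), with ±20% per-focus jitter. Focus
centers cluster around the needle-tip point at the frame center
(bivariate normal, `clusterSpread` = 0.12 cm): electrolytic gas forms at
the needle tip, and clustering makes focus coalescence — and with it the
progressive loss of convexity and homogeneity seen at high dose — emerge
naturally from overlap rather than being imposed.

A focus is rendered as a plateau `intensityBoost` (160) gray levels above
the robust background level with its speckle fluctuation damped by
`focusSpeckle` (0.3), reflecting the strong, relatively coherent echo of
a gas interface. Above `shadowThreshold` (4 mA) the column strip beneath
each focus is attenuated by `shadowAttenuation` (0.6), a deliberately
minimal model of posterior acoustic shadowing.

What the generator does *not* emulate: depth-dependent gain, anisotropic
muscle fiber texture, probe compression artifacts, reverberation, or
operator variability in plane selection. Conclusions about the pipeline's
behavior on real images must allow for all of these.

**Reproducibility.** Every generator takes an explicit seed;
`generateImageDataset()` derives per-frame seeds as master seed + frame
index, so datasets are bit-reproducible while frames remain mutually
independent.

## The tabular feature generator

For parameter-recovery experiments the imaging chain is bypassed:
`generateFeatureTable()` draws `(A_Area, A_Number, A_Perimeter)` from a
three-factor Gaussian model with means (0.030 cm², 2.0, 0.80 cm) and
lower-triangular loadings giving variances (1e-4, 0.64, 0.06125) and
positive cross-correlations, then doses through the fixed coefficient
vector of `doseModel()` plus `Normal(0, sigma)` residuals. Features are
left unclipped: truncating the rare negative draws (<0.2% at the default
means) would bias coefficient recovery, which is the one thing this
generator exists to test. With `sigma = 3.14` mA the implied population
R² of the three-feature regression is 0.667 (the linear predictor has
variance 19.76 under these loadings), matching the published proportion
of variance explained; `sigma = 0.3` is used for tight coefficient
recovery.

## Affected-area detection and the A_ features

The original acquisition software is proprietary and its detection rule
unpublished, so EchoDose uses a transparent parametric rule: affected
areas are connected components (8-connectivity by default) of ROI pixels
brighter than `median + k·SD`, with `k = 3` and the background statistics
taken as the ROI median and MAD-based SD so the lesions themselves cannot
inflate the threshold. Components below `minSize = 20` px are discarded,
which suppresses the isolated speckle-tail pixels that cross any
k·SD threshold by chance. Because the threshold is relative to the ROI's
own robust statistics, the detector — and with it every A_ feature — is
invariant to a constant echogenicity offset.

Geometry:

* `A_Area` — pixel count × spacing² (cm²; default spacing 0.01 cm/px,
  consistent with the sub-unit magnitudes of the published per-mA slopes).
* `A_Perimeter` — boundary length by Moore-neighbor contour tracing with
  chain-code weights (1 axial, √2 diagonal), summed over regions, × spacing
  (cm). On a digitized disc this estimator is within ~5% of the true
  perimeter; a raw crack-edge count would overestimate discs by 27%.
* `A_Convexity` — convex-hull perimeter over region perimeter, in (0, 1].
  The hull is taken over the pixel *corners* (the convex envelope of the
  occupied area), which makes digitized convex shapes score ≈1 instead of
  being penalized for staircase discretization; the ratio is capped at 1.
  Note the orientation: the published variable table words the ratio the
  other way around (region/hull, which would be ≥1 and *increase* with
  irregularity), but the reported values are near 1.00 and *decrease*
  with dose; EchoDose adopts the orientation consistent with the reported
  behavior.
* `A_Homogeneity`, `A_Contrast`, `A_ASM` — GLCM inverse difference
  moment, contrast and angular second moment over the union bounding
  window of the detected regions (where the treated-vs-healthy contrast
  lives; whether the original software used the mask, a box, or the whole
  frame is unstated). The window is recentered at its median gray level
  before quantization so these three features share the detector's
  offset invariance.

Degenerate conventions when nothing is detected: area, perimeter and
contrast 0; convexity, homogeneity and ASM 1 — matching the near-1.00
low-dose values of the study and keeping every feature defined on every
frame.

## The B_ echotexture features

All B_ features are computed on the whole ROI after uniform quantization
of [0, 255] into `levels = 32` gray levels (a standard compromise for
8-bit ultrasound texture; configurable).

* **GLCM (Haralick).** Co-occurrences at the four distance-1 directions
  (0°, 45°, 90°, 135°) are pooled into one symmetric normalized matrix,
  removing directional bias. Features: contrast, sum average,
  sum-of-squares variance, difference variance, correlation, inverse
  difference moment. Two conventions worth noting: correlation is defined
  as 0 when a marginal is degenerate (a constant window has no linear
  structure, and NaN would poison downstream tables); and difference
  variance is the variance of the *absolute*-difference distribution
  p(|i−j|) — for a symmetric matrix the signed-difference distribution is
  symmetric about zero, so its variance would be identical to the
  contrast and the feature would carry no independent information.
* **GLDS.** The histogram of absolute quantized differences at
  displacement δ = (0, 1): mean, contrast, ASM, entropy (natural log,
  0·log 0 := 0), homogeneity Σ g(k)/(1+k).
* **Haar.** One-level orthonormal 2-D Haar transform (odd trailing edges
  cropped); the three detail subbands are pooled and the mean and
  variance of their absolute values reported. Signs carry no echotexture
  meaning; discarding the approximation band makes both statistics
  offset-invariant.

The geometry parameters (32 levels, distance-1 offsets, δ = (0,1), one
Haar level) are package decisions — the source study names the features
but not their computation geometry — and are all configurable through
`textureConfig()`.

## The statistical stage

`runFullAnalysis()` reproduces the multi-phase plan on any per-frame
feature table:

1. **Spearman screen** (`spearmanRho()`): tie-corrected rank correlation
   of each feature with dose; two-tailed p from the t-approximation on
   n−2 df (identical to `cor.test(..., method = "spearman",
   exact = FALSE)`). An exact permutation p is available for n ≤ 8
   (enumeration beyond 8! is disproportionate for a fallback path).
2. **Per-feature OLS** (`simpleRegression()`): slope B with 95% CI,
   standardized beta, R², standard error of the estimate
   √(RSS/(n−2)), ANOVA F.
3. **Backward elimination** (`multipleRegressionBackward()`): iteratively
   removes the predictor with the largest partial-F p ≥ `pRemove`; the
   default 0.10 is the SPSS backward default ("probability of F-to-remove
   ≥ .10"), and for a single coefficient the partial F equals t², so
   coefficient p-values drive removal. Rank-deficient designs are
   rejected with the aliased columns named. Within `runFullAnalysis()`
   the predictors entering elimination are those passing the Spearman
   screen at p < 0.05, mirroring selection "based on statistical
   significance in prior analyses" and keeping the n ≈ 29 design away
   from near-singular 20-predictor fits; exactly aliased screened columns
   are dropped with a message rather than failing an automated run. A
   pure-noise predictor survives elimination with probability ≈ `pRemove`
   by construction (~10%), which is the correct null behavior of the
   procedure, not a defect.
4. **Composite index** (`muscleElectrolysisDose()`): the fixed published
   coefficients (intercept 0.542; area −316.88 mA/cm²; count −2.678
   mA/focus; perimeter 20.284 mA/cm) applied row-wise as `UZ_eDosis`.
   Fixed rather than refit coefficients are used so the column is an
   *index* comparable across datasets; the refit model is reported
   separately.
5. **Group comparison**: doses are partitioned into low [0, 1], medium
   (1, 4], high (4, ∞) mA (`segmentDoseGroups()`). The boundaries follow
   the body text and abstract of the source study; its Table 5 caption
   states 1–6/>6 instead — an internal inconsistency of the source, which
   is why the boundaries are an argument, not a constant. Boundary doses
   are assigned to the lower group (closed-left reading, keeping ">4"
   strict). Kruskal–Wallis (tie-corrected, χ² asymptotics, H := 0 when
   all values tie) is followed by pairwise Mann–Whitney U tests using the
   tie-corrected normal approximation without continuity correction (the
   SPSS "asymptotic two-tailed" convention) and Bonferroni adjustment
   min(1, 3p).

## Numerical choices and degenerate inputs

* Frames are integer matrices in [0, 255]; all randomness flows through
  explicit seeds (`withr::with_seed`), so every artifact is
  bit-reproducible.
* Quantization uses `floor(g/256·L)` — monotone, uniform, surjective for
  full-range input.
* A single-pixel region has no chain; its perimeter falls back to the
  unit-square crack length 4 (irrelevant at the default `minSize`).
* `kruskalWallis()` and the Mann–Whitney wrapper treat all-tied inputs as
  "no evidence" (H = 0, p = 1) instead of NaN.
* Near-exact simple-regression fits (RSS below 1e-12·TSS) are reported
  with σ = 0, F = ∞, p = 0 and a degenerate CI rather than relying on
  `summary.lm` warnings.

## Problem sizes

The test suite and the acceptance script run everything at the sizes the
analysis itself uses: 29-frame datasets at 256×256 px for imaging-based
checks (64×64 for pipeline round-trip tests), n = 2000 with 200
replicates for regression recovery and R² calibration, and 10⁵ rows for
the covariance check of the tabular generator. These sizes give
Monte-Carlo errors well inside the asserted tolerances.

## Known limitations

* The speckle and lesion models are first-order emulations; none of the
  acquisition-specific structure of real B-mode muscle images is present.
* The detection rule is a reasoned reconstruction, not the original
  software's algorithm; absolute feature values are not comparable to the
  original study's tables, only trend directions and model structure are.
* Shadowing is purely multiplicative and column-aligned; real shadows
  have soft lateral margins.
* The composite index's published coefficients are used as fixed
  constants; refitting them on synthetic images yields different values
  by construction (different units pipeline, different detector).
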