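---
title: "Detecting punctate white matter injury with an intensity-transition model"
author: "WMIdetect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting punctate white matter injury with an intensity-transition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WMIdetect)
```

## The problem

Punctate white matter injury (WMI) is the characteristic brain injury of
very preterm neonates. On early T1-weighted MRI the lesions are bright, but
their absolute intensity overlaps that of normal white matter, so simple
thresholding fails; what distinguishes injury is the *abrupt* intensity
change against the immediately surrounding tissue. WMIdetect implements a
detector built on exactly that observation: it models how much adjacent
white-matter pixels are allowed to differ, flags pixel pairs whose
difference the model deems very unlikely, and grows injury regions from
those rare transitions.

Detection is deliberately confined to a user-supplied binary white-matter
mask (in clinical use, a manual or semi-automatic delineation). Segmenting
white matter itself, 3D extensions, and outcome prediction are out of
scope; the package works on one 2D slice at a time.

## The transition model

In-mask intensities are histogram-stretched and quantized into a state
space $\{s_0, \dots, s_N\}$ of $N + 1$ equal-width intervals. For an
adjacent pixel pair (8-connectivity) whose brighter member is in state
$s_a$, the model assigns the conditional probability of the neighbour
sitting $k$ states lower a geometric form

$$P(\text{drop of } k) = q\,\alpha^k, \qquad k = 0, \dots, N,$$

with a single fitted parameter $q$, the probability that the two pixels
share a state. Because one of the $N + 1$ drops must occur, summing the
geometric series forces

$$q\,\alpha^{N+1} - \alpha + (1 - q) = 0 .$$

This degree-$(N{+}1)$ polynomial always has the root $\alpha = 1$, which
violates normalization; the remaining roots are mostly complex, and for
feasible $(q, N)$ exactly one real root lies in $(0, 1)$. `solveAlpha()`
finds it by a sign-change scan plus bracketed bisection — guaranteed to
converge on a bracketed monotone segment, with no companion-matrix
machinery and no complex roots to filter. Feasibility is detected rather
than assumed: when no sign change exists in the open interval (equivalently
$q \le 1/(N+1)$, where the geometric tail cannot absorb the residual mass)
the solver fails loudly with the offending $(q, n)$ pair, instead of
returning a boundary root.

Worked points of this law (computable with `transitionModel()`): at
$q = 0.4, N = 3$, $\alpha \approx 0.69141$; at $q = 0.8, N = 3$,
$\alpha \approx 0.20131$ with drop probabilities $0.8, 0.161, 0.032,
0.007$; at $q = 0.4, N = 6$, $\alpha \approx 0.61301$.

$q$ is estimated by `estimateQ()` as the fraction of unordered 8-connected
in-mask pixel pairs whose states are equal. The estimator is our design:
the model only needs the probability of a zero drop, and the pair fraction
is its direct empirical counterpart, using the same adjacency as detection.
A degenerate estimate of exactly 0 or 1 (constant slices, tiny masks) is
clamped into the open interval by $1/(P+1)$ with a warning, so the
polynomial stays solvable. The model treats only the brighter-to-darker
direction; the opposite direction is the mirrored event with the same
probability, which keeps the pair relation symmetric without a second
parameter.

## Detection

```{r detect-example}
ph <- generatePhantom(phantomSpec(
  lesions = list(lesionSpec(c(60, 60), 4), lesionSpec(c(72, 72), 3)),
  seed = 17))
det <- detectWMI(ph$image, ph$wmMask)
det
```

`detectWMI()` composes five stages, each exported on its own:

1. **Stretch and quantize** (`stretchAndQuantize()`): in-mask intensities
   are clipped to the (1, 99) percentile range, rescaled to $[0,1]$, and
   binned into $N + 1 = 7$ equal-width, half-open intervals (the last
   closed). Percentile clipping absorbs affine intensity differences
   between scans and is robust to hot pixels; equal-width (not
   equal-count) bins preserve the meaning of a "state drop" as an
   intensity jump. Stretching is per slice, consistent with the 2D scope.
   The default of 7 states matches the largest worked model above; the
   production value is a config parameter.
2. **Fit** the model: estimate $q$ (or accept a fixed value) and solve for
   $\alpha$.
3. **Mark boundaries** (`markBoundaries()`): every unordered 8-connected
   in-mask pair is evaluated once; a pair with state drop $d$ is *rare*
   iff $q\alpha^{d} <$ `threshold`. Both members become boundary pixels
   and the strictly brighter one becomes a seed — WMI is bright on T1, so
   growth starts on the bright side. The default threshold 0.01 follows
   the model's worked operating point: for the $q=0.8, N=3$ example only
   the full drop $s_3 \to s_0$ (probability 0.007) is rare at 1%, while at
   5% several more drops qualify. `calibrateThreshold()` offers the
   statistical alternative of taking the empirical $f$-quantile
   (default $f = 0.001$) of the observed pair probabilities.
4. **Filter false boundaries** (`removeMarginFalseBoundaries()`): two
   independently switchable filters, because "small neighbourhoods around
   boundaries" and "deleting small boundaries" are distinct readings —
   (a) boundary pixels within `marginPx` (default 2) of the nearest
   out-of-mask pixel are dropped (the image frame counts as out-of-mask),
   which suppresses the bright gray-matter rim produced by an imperfect
   white-matter segmentation; (b) surviving 8-connected boundary
   components smaller than `minBoundaryPx` (default 3) are dropped as
   noise.
5. **Grow regions** (`growRegions()`): seeds are processed in row-major
   order (a deterministic choice; multi-seed order is otherwise
   unspecified), each sweeping its 8-connected in-mask frontier repeatedly;
   a candidate joins when its stretched intensity deviates from the
   region's running mean by less than `growthFraction` (default 0.5)
   sample standard deviations. Statistics update after every accepted
   pixel. While the region holds fewer than 4 pixels or its sd is below
   $10^{-6}$ the ratio is undefined, and the rule degenerates to
   state-equality with the seed — the zero-tolerance reading of the
   criterion; with `growthFraction = 0` nothing at all is admitted, so the
   result is exactly the seeds. Touching regions merge, and components are
   labelled with 8-connectivity. A safety cap `maxRegionPx` (default 10%
   of the mask; not part of the published procedure) stops a mis-set
   fraction from flooding the mask and is always reported, never silent.
   The default `growthFraction = 0.5` is our choice: the published value
   was calibrated on expert delineations that are not available, and 0.5
   keeps grown regions tightly inside the bright lesion core, matching
   the reported tendency of automatic regions to under-cover the expert
   ground truth.

Determinism is a contract: two runs on identical inputs produce identical
masks and reports, and every report embeds the resolved configuration.

## Evaluation machinery

`accuracyDistanceHistogram()` histograms, for each detected pixel, the
Euclidean distance (distance transform of the truth mask, rounded half-up
to integers — the metric and rounding are our choices; ceiling binning
would shift mass between adjacent bars but not the shape) to the nearest
ground-truth pixel; distance 0 means inside the truth. An empty truth with
a non-empty detection is reported as a distinguished infinite-distance
bucket rather than silently dropped.

`blandAltman()` performs the limits-of-agreement analysis on per-case
areas with the fixed sign convention *reference − automatic*, so a method
that under-segments shows a positive bias; limits are bias ± 1.96 sample
standard deviations. `binnedDifferenceTable()` buckets the per-case points
by their mean-area axis into fixed-width bins (default 0.1 cm²) and
reports per-bin average difference and count. `areaCm2()` converts pixel
counts using the (row, col) pixel spacing in mm — taken from the NIfTI
header, or supplied explicitly for raster input.

## The phantom generator

`generatePhantom()` builds a synthetic slice with known ground truth: a
perturbed-ellipse white-matter blob (semi-axes 40 × 32 px in a 128 × 128
frame, low-frequency radial perturbation of amplitude 0.08), a linear
background gradient (amplitude 0.08 across the frame, random direction), a
Gaussian noise floor (sd 0.002), and bright punctate lesions — discs or
radially warped blobs — of specified center, radius and contrast, plus an
optional bright rim just inside the mask border that emulates gray-matter
contamination. Everything is deterministic given the spec's seed; the
truth mask depends only on lesion geometry (blob warps are keyed on the
lesion's center and radius), never on the noise realization.

The defaults are the package's reference study conditions and deserve
justification:

* **Noise sd 0.002** (0.4% of the white-matter base intensity) describes
  the image *after* the contrast-enhancement and median-filter
  pre-processing that precedes detection in the intended workflow — the
  detector never sees raw scanner noise.
* **Gradient 0.08** gives the smooth, anatomically plausible intensity
  variation (~16% peak-to-peak) that makes percentile stretching
  non-trivial.
* **Lesion contrast defaults to ~100 noise sd** (≈ 0.2 absolute, i.e.
  lesions ~40% brighter than the white-matter base), with suite draws in
  90–120. Punctate WMI on early T1 is markedly hyperintense; after light
  denoising its contrast-to-noise ratio is large. This value also matters
  structurally: the geometric law has a deliberately fat tail, so a
  transition is rare only when the lesion's state drop is several bins —
  which requires the lesion's absolute contrast to dominate the stretch
  range. A lesion only a few noise sd bright is *below the detectability
  floor of this model for any noise/gradient combination* (the drop in
  bins is contrast/bin-width while the fitted $q$ is set by
  noise/bin-width; working through the law shows the required drop always
  exceeds what a few sd provide). The phantom emulates the lesions the
  method is designed for, not that floor.

`generatePhantomSuite()` generates reproducible batches: a fixed fraction
of images carries 2–4 lesions of radius 3–5 px placed uniformly in the
eroded mask (clusters arise when draws land close), the rest are
lesion-free. The suite exhibits the detector's two regimes: in lesioned
slices the stretch range is dominated by the lesions, background occupies
few states, the estimated $q$ is high (≈ 0.9) and lesion boundaries drop
4–5 states — far beyond the minimal significant drop; in lesion-free
slices the stretch amplifies noise, $q$ drops to ≈ 0.7, the geometric tail
fattens, and no transition reaches the 1% threshold, so the mask stays
empty. That adaptive specificity is a property of the model itself, not of
a tuned setting.

What the phantom does **not** emulate: anatomy (no cortex, ventricles or
myelination gradients), MR physics (no bias field, no Rician noise —
Gaussian suffices for the detector's contract), partial-volume edges
(lesions are hard-edged), or multi-slice context. Passing phantom tests
therefore demonstrates the algorithmic contract — sensitivity to
hyperintense punctate lesions inside a mask, specificity on clean slices,
margin suppression of rim artefacts — not clinical performance, which
requires expert-delineated patient data.

## Numerical choices and degenerate inputs

* Root solving: 4096-point sign-change scan on $(10^{-12}, 1-10^{-12})$,
  then `uniroot` at tolerance $10^{-12}$; no sign change raises an
  infeasibility error naming $(q, n)$.
* Bin ties: half-open $[a, b)$ intervals with the final interval closed,
  stated so results are bit-reproducible.
* Constant in-mask intensity: all pixels go to state 0 with a warning
  (not an error) — detection then finds nothing, which is correct.
* Sample (ddof = 1) standard deviations throughout (region growing,
  Bland–Altman).
* Distance transforms are Euclidean (`EBImage::distmap`); component
  labelling is 8-connected via the pixel adjacency graph.
* Test problem sizes: oracle cross-checks run on 16 × 16 state images
  against exhaustive pair enumeration, and the phantom acceptance suite
  uses 40 slices at 128 × 128 — sizes at which exhaustive oracles are
  exact and the full suite runs in well under a minute.

## Known limitations

Strictly 2D and single-slice; white-matter segmentation quality directly
bounds specificity (a contaminated mask produces rim false positives —
mitigated, not eliminated, by the margin filter); the fitted law is
pairwise, with no spatial interaction beyond adjacency and no
distance-indexed generalization; grown regions deliberately under-cover
lesions relative to expert delineations, so area agreement should be read
through the Bland–Altman machinery rather than expected to be perfect; and
the detectability floor discussed above means low-contrast (few noise sd)
lesions are invisible to this model by design.
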