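---
title: "Methods: quantifying chronic tumor hypoxia from histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chronic tumor hypoxia from histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxiafeat)
```

## The biological picture and the modeling stance

Chronic tumor hypoxia is diffusion-limited: oxygen leaves a vessel, is
consumed as it diffuses outward, and beyond a critical distance cells
first become hypoxic and then die. On an anti-pimonidazole
immunohistochemistry section this produces a *tumor cord*: a viable (V)
sleeve around the vessel, a dark hypoxic (H) band whose stain density
rises with radial distance, and bright necrosis (N) outside. This package
takes the phenomenological route — it measures the geometry and intensity
structure of that pattern directly from images, and deliberately fits no
oxygen-transport model. Two assumptions carry most of the weight:

* **Darkness encodes hypoxia.** The stain is interpreted monotonically:
  the darker a pixel, the more hypoxic the tissue. Collagen violates this
  (it resembles necrosis in intensity); nothing in the pipeline corrects
  for it.
* **Ergodicity across lesions.** All inputs are single-time-point images.
  Treating many lesions, each at a different stage, as samples of one
  lesion's temporal trajectory is what licenses the temporal parts of the
  tissue grammar and the logic's temporal operator on static data.

## Preprocessing and segmentation

RGB images are converted with BT.601 luma weights (0.299, 0.587, 0.114) —
the common `rgb2gray` convention; the stain analyses only need a
consistent monotone intensity scale. Smoothing applies a 5×5 Gaussian mask
with σ = 5 px for 100 iterations (`smoothing_config()`). A 5-tap kernel at
σ = 5 is nearly flat, so each pass is close to a box blur of variance ≈ 2
px²; 100 passes give an effective blur of σ ≈ 14 px. There is no formal
criterion behind these values — consistency across images matters more
than the degree of smoothness, so they are fixed defaults. Internally
smoothed images stay in floating point; quantization to 8 bits happens
only in `write_image()`, avoiding 100-fold rounding drift. Convolution
uses replicate-edge padding, chosen once so results are reproducible.

Segmentation assigns H to intensities `<= t1`, V to `(t1, t2]`, N above
`t2` — closed upper boundaries, matching interval conventions like
\[0, 156\], \[157, 175\], \[176, 255\] for the fixed study thresholds
(`fixed_study_thresholds()`). `otsu_two_thresholds()` maximizes the
three-class between-class variance over all 0 ≤ t1 < t2 ≤ 255 on the
256-bin histogram (smoothed images are re-binned to integers first, since
the criterion is histogram-based). Ties take the lexicographically
smallest pair; images with fewer than three distinct levels are rejected
rather than answered arbitrarily. The area fractions H:I, V:I, N:I are
exact pixel-count fractions and sum to one by construction; H:V is flagged
`NA` (not an error) when no viable pixels exist.

## Radial gradient profiling

`sample_rays()` extends `n` equal-angle rays (default 80, i.e. one every
π/40 rad) from a vessel-centroid landmark, sampling every `d_s` px
(default 1) by nearest-pixel lookup; sample positions are computed in
continuous coordinates and never interpolated, because the image is
smoothed upstream and sub-pixel interpolation would add a second,
redundant smoothing. Radial index 1 is the first step *away* from the
center — the center pixel itself is not a sample. Samples past the image
edge are `Inf` sentinels; the matrix has `ceiling(hypot(w, h) / d_s)`
columns because a corner-placed landmark can need the full diagonal.
Statistics per radial index (mean, median, sd over each bundle's rays)
simply drop sentinels; an index is defined while at least one ray
survives. Bundles are half-open angular sectors, boundary rays belonging
to the lower-index sector.

The measurement radius `r_m` is the argmin of the median profile within
the first `l_t` indices (default 1000 px), ties to the smallest index —
the darkest point of the stain, read as the outer contour of the hypoxic
band. Mean and median profiles restricted to `[1, r_m]` are each fitted by
segmented least squares with C = 200; the fit with fewer segments is
selected, ties going to the mean fit.

`filter_spurious()` drops leading segments that are positive-sloped or
shorter than `min_len` (never the last segment), recording what it
removed. Landmarks sitting in a bright vessel lumen produce exactly such
segments. The default `min_len = 40` px is set to the effective blur
support of the default smoothing (≈ 3σ): a leading segment shorter than
the blur cannot be distinguished from kink-rounding. Tests on compact
lesions pass `min_len = 15` alongside lighter smoothing, for the same
reason scaled down.

## Segmented least squares

`segmented_least_squares()` solves the classical formulation: partition
the indices into contiguous segments of ≥ 2 points (single-point segments
would have undefined slope), fit each by OLS, minimize total SSE plus C
per segment via the Bellman recurrence. Segment error `e` is the sum of
squared residuals — the quantity the dynamic program actually minimizes; a
per-point `mse` field is also reported since normalization conventions
vary. Adjacent segments share no point. Tie-breaking is deterministic:
among equal-cost solutions, fewest segments, then the earliest last-segment
start at each recurrence step (tolerance 1e-9 on cost equality). Segment
length is reported as `end_x - start_x` in abscissa units. The same code
fits intensity profiles (C = 200) and Euler-characteristic curves
(C = 50000); C has the units of the squared ordinate and simply prices one
extra segment.

## Multiscale features

The quad-tree splits a frame while the coefficient of variation of its
intensities exceeds τ (default 0.02), into four near-halves (floor/ceil
for odd extents, so any aspect ratio works); 1-pixel frames, zero-mean
frames (CV defined as 0 to avoid 0/0) and frames at ply 12 are terminal.
The Euler–Poincaré characteristic is computed exactly from 2×2 quad counts
— χ = (C1 − C3 − 2·C_D)/4 on the zero-padded image — under 8-connected
foreground with 4-connected background, the standard pairing that avoids
the connectivity paradoxes of using one connectivity for both phases. The
quad-count route is O(pixels), exact, and is verified in the tests against
an independent flood-fill component/hole count. Signature curves binarize
at every threshold 1..255 without smoothing; the binarization direction
(foreground = bright by default) is a flag, since either direction yields
a valid signature and the choice is a convention.

Both feature families are *computed but not trusted*: their cross-image
variance makes them unusable as similarity features, so
`features_from_image()` excludes them by default. They remain available
for exploratory use.

## Registration

Displacements between matched vessel landmarks on Z-stack-adjacent
sections are modeled by two univariate quadratics: angle as a function of
x, magnitude as a function of y. With the three landmarks of a typical
section the fit interpolates exactly; with more it is ordinary least
squares. Angles are unwrapped to the branch nearest their circular mean
before fitting, otherwise a ±π cut through the data would destroy the
polynomial fit. The fitted field corrects landmark positions; it is not
used to resample images.

## The tissue grammar

Axiom A1 (V and N are invalid neighbors) and axiom A2 (V → H → N with N
absorbing) are encoded as a successor map plus an adjacency predicate, and
the twelve template rules (origination X → XYX, elimination XYX → X, over
distinct symbol pairs) are *classified* from the axioms: an origination is
valid iff Y is X's successor and the sandwich respects A1; an elimination
is valid iff X is Y's successor and the context respects A1. That exactly
4 rules are valid and 8 invalid is therefore a checkable consequence, not
a table. One attribution detail: when a rule violates both axioms the
classifier reports A1 whenever the sandwich itself places V beside N,
which is a fixed convention rather than a claim about which axiom is
"more" violated. Tissue strings are run-length encoded at every boundary,
so region widths are abstracted away at the symbolic level.

## The extended bounded temporal logic

Formulas are predicates `u ~ v` (with `u = v ± w` sugar for the interval
conjunction), Boolean connectives, and bounded until/finally/globally. A
bound is a named vector over accumulation dimensions: `x1`, `x2`, `x3`
accumulate *signed* per-step coordinate differences (their sums telescope),
`t` accumulates state durations, and `arc` accumulates Euclidean step
lengths — a diagonal pixel step contributes √2 — because the gradient
bounds are arc lengths along a curvilinear walk. Semantics are
finite-trace: an until with no witness before the trace end is false.

**The strict-until design choice.** Under the textbook until, `φ₁ U φ₂`
holds whenever φ₂ holds at the current state (witness i = 0). A
proposition like ¬\[(T=N) U (T=V)\], meant to assert "no necrotic run
leads directly into viable tissue", is then *vacuously false* on any trace
that starts in V — the inner until is satisfied immediately — and its
partner term fails on traces starting in N, so the conjunction could only
ever hold starting in H. The evaluator therefore implements the standard
semantics by default (and is tested against an exhaustive witness-search
oracle under exactly those semantics), while `bltl_until(..., strict =
TRUE)` requires the witness strictly ahead (i ≥ 1, so φ₁ must hold now).
`build_hypoxia_proposition()` uses strict untils for its region-transition
terms — the neighbor-axiom terms and the V-until-H-until-N order term —
because that is the only reading under which they express their evident
intent. Bound accumulations are re-tested per witness rather than used to
break out of the scan early, since signed spatial sums are not monotone in
the witness index.

The hypoxia proposition conjoins, under a temporal globally with bound τ:
the two neighbor-axiom terms along x₁ and x₂; the tissue-order term along
the gradient-ascent trajectory; the gradient term — finally(slope =
−0.21 ± 0.19) within arc 172 + 83 until finally(slope = −0.06 ± 0.03)
within arc 267 + 126, all within arc 648; and the ratio term C =
0.36 ± 0.24, where C is the image's hypoxic:viable pixel ratio. The
defaults are the measured two-segment low-concentration statistics and the
unsmoothed H:V mean; every constant is overridable. τ defaults to 0: a
histology image is one temporal snapshot, and with unit state durations a
zero bound makes the outer globally examine exactly the current state.
Trajectories come from `walk_gradient()` — steepest 8-neighbor
ascent/descent with a fixed clockwise-from-east tie-break, halting at a
plateau, the image edge, or a step budget — extended radially through the
necrotic rim so the trace actually witnesses N.

A note on the V/N-swap control: swapping the V and N labels of a rendered
lesion leaves the field A1-consistent (H still separates the swapped
regions), so the neighbor-axiom terms still hold; what fails on the
swapped lesion is the tissue-*order* term (the trace now starts in N) and
in general the ratio term. The verdict flips to false for those reasons,
not because of A1.

## The similarity estimator

Calibrating lesions get target score 1; `train_ols()` solves the normal
equations, `train_robust()` runs bisquare IRLS with tuning constant 4.685,
robust scale `median(|r|)/0.6745` recomputed each sweep, and convergence
when no weight moves by more than 1e-6 (cap 50 sweeps). Residuals are
leverage-adjusted (`r/√(1−h)`) before weighting: with the all-ones target,
a grossly rescaled feature row is a *high-leverage* point that drags the
fit toward itself and keeps its own raw residual moderate — plain IRLS
then never rejects it. The adjustment (which is also what `robustfit`-style
implementations apply) restores the intended behavior: planted ×10 rows
receive weight 0 and are discarded from the retained count m′.

Shrinkage: the spherical estimator is positive-part James–Stein toward the
origin, `a′ = max(0, 1 − (k−2)v/‖a‖²)·a`, requiring k ≥ 3; `v` defaults to
the training residual variance. Its known failure mode is a single extreme
coefficient inflating ‖a‖² so nobody shrinks. The coordinate ("truncated")
variant addresses exactly that, and is implemented as per-coordinate
positive-part truncation `aᵢ′ = max(0, 1 − v/aᵢ²)·aᵢ`: an extreme
coefficient is nearly untouched while coefficients inside the noise level
are zeroed. (A leave-one-out denominator was considered and rejected: it
shrinks the extreme coordinate *hardest* — its factor is computed from the
small norm of the others — which inverts the motivation.) Both variants
contract the norm and are identities at v = 0. Scores are the linear form
clipped to \[0, 1\]; the raw value is reported alongside since clipping
discards information about how far off-manifold a lesion is.

`features_from_image()` fixes the 12-feature layout: t₁, t₂, H:I, V:I,
N:I, H:V, then (averaged over landmarks and bundles) segment count, two
segment length fractions, two slopes, and r_m. Length fractions are taken
relative to r_m rather than to their own total: fractions-of-total sum
identically to 1, which together with the sum-to-one area fractions and a
constant segment count would make the feature matrix structurally
rank-deficient — no calibration set could then satisfy the full-rank
precondition of the normal equations. Missing second segments impute
length fraction 0 and slope 0; an H:V with no viable pixels imputes 0.

## The synthetic-lesion generator

`lesion_spec()` defaults *are* the measured conditions: slopes (−0.21,
−0.06) over segment lengths (172, 267) px, base intensity 200, necrotic
level 230, noise σ = 5, in a 950×950 frame. The viable/hypoxic label
boundary defaults to 376 px, chosen once so the hypoxic ring's area is
0.36 × the viable core's — the measured unsmoothed H:V mean; with an
arbitrary boundary the proposition's ratio term would contradict the
generator's own geometry. Rendering rasterizes the radial profile, adds
seeded Gaussian noise, clips and rounds to the 8-bit grid; the same seed
gives byte-identical output. Ground-truth labels and analytic ring-area
ratios accompany every scene. `make_calibration_set()` renders every
fourth lesion with a single slope so the segment-count feature varies
across the calibration population — otherwise a constant count reintroduces
the collinearity discussed above.

What the generator does *not* emulate: collagen (the main real-world
confound — it mimics necrotic intensity inside lesions), saturated
high-concentration staining, irregular (non-circular) cords, vessel lumina
in the stain channel, and spatially correlated stain noise (noise is
i.i.d. Gaussian). Tests passing on this substrate therefore demonstrate
correct *measurement* of the canonical structure, not robustness to the
full pathology of real sections.

## Numerical conventions and test scales

Coordinates are 0-based, x rightward, y downward, origin top-left;
matrices are indexed \[row, col\] = \[y+1, x+1\]. Intensities live on
0..255 and may be fractional after smoothing. Degenerate inputs error with
typed conditions (`hypoxiafeat_*_error`) rather than returning guesses:
constant images for Otsu, series shorter than 2 points, non-positive C,
bundles with no rays, empty measurement windows, rank-deficient designs,
all-zero robust weights.

Verification runs at deliberately compact sizes: exhaustive-enumeration
oracles cover all segmentations of series up to length 14, all
(trace ≤ 5 states, formula depth ≤ 3) logic cases by witness search,
two-threshold Otsu on 64×64 images, Euler characteristics on 12×12 grids
against flood fill; gradient recovery and the hypoxia proposition run at
the full 950×950 lesion geometry with twenty seeded replicates; shrinkage
dominance uses 2000 replicates at k = 10. The module tests additionally
use a compact 240×240 lesion (slopes −0.4/−0.1 over 40/60 px, lighter
smoothing, C = 30) — the same structure with every length scale, including
the smoothing blur and the per-segment cost, scaled down together.

## Known limitations

* Intensity thresholding over-calls hypoxia on gradient images (the dark
  ring is wider than the true hypoxic band) — visible even on the
  generator's output, where Otsu H:V exceeds the ground-truth ring ratio.
* Gradient slopes recovered under the default smoothing are mildly
  attenuated near the vessel (kink rounding), ~5% on the first segment at
  study scale.
* The proposition's evaluation is trajectory-based; it certifies the
  sampled trajectories, not every path in the image.
* The estimator is linear; it ranks lesions by resemblance to the
  calibration population and has no probabilistic calibration.
* Quad-tree and Euler-characteristic features are retained for exploration
  but excluded from the default feature set on variance grounds.
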