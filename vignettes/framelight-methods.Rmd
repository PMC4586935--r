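---
title: "Methods: two-sided reference-frame evidence from multivoxel patterns"
author: "framelight developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sided reference-frame evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(framelight)
```

## The question and the design space

The package decides whether multivoxel activity patterns encode a movement
target relative to gaze direction (gaze-centered, GC) or relative to the body
midline (body-centered, BC). Three fixation directions (−11°, 0°, +11° of
visual angle) crossed with two lateral targets give six combinations, of
which only the four with the target near the gaze line are used
(`make_configurations()` derives them and refuses degenerate geometries where
a target falls exactly on a gaze line, since its gaze-frame side would be
undefined). The target offsets default to ±5°: the physical layout specifies
the targets 4.5 cm from the central fixation light, and only the *sign* of
the angle enters the logic, so the numeric value is cosmetic but fixed for
reproducibility.

`enumerate_pairs()` derives the six condition pairs and their per-hypothesis
predictions from the configurations rather than hard-coding them; an internal
audit asserts that the six pairs partition all C(4,2) combinations and that
the GC and BC predictions are exact mirrors on the four main pairs.

## Two-sided evidence

Classification accuracy (*a*, leave-one-run-out, binary linear SVM) measures
whether two representations are distinct. Cross-classification (*o*) measures
whether they are common: a classifier trained on pair {A, B} is tested with
one trained configuration replaced by a non-trained one, and the score is
ascribed to the receiving pair {replaced, replacement}. Each of the six
classifiers admits four replacements, and each receiving pair aggregates
exactly four routed scores — an exact combinatorial balance the test suite
asserts. Aggregating a frame's two predicted-common *o* scores with its two
predicted-distinct *a* scores yields `aggregate_gc`, `aggregate_bc` and their
contrast; the conjunction rule instead requires significance on both sides.

### The scoring-mode decision

Whether the cross-classification test scores *only* the replacement pattern
(`xmode = "replacement"`) or the full substituted pair including the retained
configuration (`xmode = "pair"`) is genuinely underdetermined, and the two
choices have different structural consequences, which we derived by
enumeration and verify in the acceptance suite:

- Under pure GC coding, each body-frame receiving pair collects two routes
  through the two independent-pair classifiers. Those classifiers learn the
  gaze-frame axis, and the replacement pattern lies deterministically on the
  *wrong* side, so those routes score 0 (not 0.5). In replacement mode
  `o(body pairs) → 0.25` and `aggregate_bc → 0.375`; in pair mode the
  retained pattern (always correct) pulls the routes back to 0.5 and
  `aggregate_bc → 0.5`.
- Under pure gaze-direction coding, pair mode puts *o* on all four main
  pairs at ≈ 0.625 — reliably above chance — so the frame conjunctions fire,
  destroying the method's own control logic. Replacement mode leaves those
  scores at ≈ 0.375 and the conjunctions stay silent.

No single mode makes both "the opposite frame's aggregate is exactly chance"
and "gaze-direction coding never passes the conjunction" true at once. The
package defaults to `replacement`, because the conjunction control and the
exact complementarity property (the two routes testing one non-trained
pattern through one classifier sum to exactly 1) are the method's load-bearing
guarantees, and because the below-chance *o* on strongly classified pairs
matches the expectation that classification and cross-classification are
negatively correlated. Pair mode remains available and both modes are tested.
Consequence to keep in mind: in replacement mode a *chance-level* aggregate
for the non-dominant frame is ≈ 0.375, not 0.5; contrasts are unaffected.

### Significance and z-scoring

At the single-dataset level, flags come from one-tailed t-tests of per-fold
scores against 0.5 at α = 0.05 (constant folds are resolved
deterministically: constant above chance ⇒ significant). At group level the
group GLM supplies the tests. Z-scoring of t-patterns per voxel defaults to
all 16 patterns (`all_patterns`), the literal reading of the source recipe; a
leakage-free `train_only` scope (moments from training folds only) is
provided and tested, since all-pattern scoping mildly couples train and test
statistics. Cross-modal analyses z-score each modality separately and average
the two transfer directions.

### The classifier

No SVM library is assumed: `linsvm_fit()` is an L1-loss soft-margin linear
SVM solved by dual coordinate descent (liblinear's algorithm) with C = 1, the
bias as an augmented constant feature, a fixed sweep order and a 1e-4
projected-gradient tolerance — deterministic by construction, with a compiled
inner loop and a pure-R reference implementation asserted equal to it. A
decision value of exactly zero counts as half correct.

## The synthetic world

`simulation_spec()` states the world the tests run in: per voxel one i.i.d.
standard-Gaussian tuning prototype per coded level (2 levels for GC or BC —
the target side in that frame; 3 for gaze direction — the fixation position),
spherical unit-variance Gaussian noise per run, and signal scaled by `snr`
(signal SD / noise SD; `snr = 0` is accepted and yields label-independent
data). Defaults mirror the experimental structure: 8 runs per modality, one
pattern per configuration per run. The modality model is `shared`
(identical prototypes), `independent` (fresh prototypes), or `switching`
(visual GC, somaesthetic BC — the anterior-intraparietal signature).
Optional per-run prototype jitter mimics between-run variability; it is off
by default.

Chosen once, not revisited: recovery tests use `snr = 5` and 50 voxels where
the criteria state them; the cohort-level switching test uses `snr = 1` and
40 voxels, a realistic single-region effect size that is nowhere specified;
18 subjects per cohort match the study's sample size.

What the generator does *not* emulate: spatial autocorrelation,
physiological/motion noise, hemodynamic nonlinearity, between-subject
anatomical variability. A green recovery test therefore establishes the
*logic* of the evidence routing, not field-strength realism.

`simulate_schedule()` reproduces the trial economy (16 × 22 trials ⇒ 88 per
configuration; uniform 3–6 s delays; 20 s lead-in / 10 s tail fixation) with
greedy first-order counterbalancing — each next configuration minimizes the
running count of its transition from the previous one, which keeps all 16
transition counts within a small band without exact de-Bruijn sequencing.
`simulate_bold()` drives delay-period boxcars through a double-gamma HRF
(response gamma shape 6, undershoot shape 16, ratio 1/6, sampled at
TR = 1.63 s) so the GLM stage has a noiseless-recovery oracle; the direct
t-pattern path and the BOLD + GLM path agree on pattern structure by test.

## GLM stage

One design per run, 28 columns: 4 planning boxcars (cue → Go), 4 movement
boxcars (Go → return), 3 HRF-convolved spikes (stimulus, saccade cues, run
onset), 12 motion and 5 compartment nuisance columns (AR(1) stand-ins in
simulation, supplied values on real data). Events are binned at TR/16 before
convolution. High-pass filtering regresses out a discrete-cosine basis up to
the 128 s cutoff from data *and* design; the constant/baseline is retained
implicitly (fixation is unmodeled). OLS uses an SVD with rank-aware dof;
contrasts outside the estimable space of a rank-deficient design are errors,
not NaNs. The per-configuration planning-vs-baseline t-values form the
pattern unit.

## Searchlight and group inference

Spheres have a 7 mm (two-voxel) radius, inclusive boundary, distances in
world millimetres via the affine (anisotropic grids supported), truncated at
the mask border; an interior sphere at 3.5 mm voxels has 33 members. Every
in-mask voxel is a center, and membership is symmetric, so the voxel-averaged
map (mean over all spheres *containing* a voxel, not center attribution) is
always defined. Scoring is per-center pure, hence order-independent.

The group GLM is the full crossing (subjects × modalities × pairs × tests)
with subject intercepts plus one regressor per condition cell; the design is
rank-deficient by one, giving the printed 432 − 41 = 391 dof in the full-scale design.
Evidence is chance-centred before fitting so cell means test against chance;
mean-type contrasts add 1/S to the subject columns to stay estimable, and
difference contrasts cancel them. Cluster thresholding is voxelwise p < α
(one-tailed for accuracy maps — below-chance accuracy is not meaningful
evidence; two-tailed for contrasts) with *strictly* greater-than-extent
survival and 26-connectivity by default (6 available); connectivity is a
stated choice, the source is silent. ROI placement finds local maxima
(strictly greater than all in-mask 26-neighbours; equidistant ties broken
lexicographically) of the *independent-pair* evidence map and picks the one
nearest a literature reference coordinate, returning a 7 mm sphere — keeping
ROI selection orthogonal to the frame hypotheses. ROI statistics are
one-tailed vs chance for aggregates and two-tailed paired t-tests for frame,
modality and frame-by-modality interaction effects; the interaction test is
the signature that separates switching regions from shared-code regions.

## Numerical and degenerate-input policy

Zero-variance voxels are flagged and zeroed in z-scoring, not propagated;
zero-residual GLM voxels are flagged; empty planning regressors are flagged,
not silently dropped; delay bounds, overlapping regions, affine mismatches,
unknown configuration labels and missing config keys are hard errors naming
the offender. All randomness flows through explicit integer seeds; fixed
seeds give bit-identical outputs, and every pipeline artefact carries a
config hash in its sidecar.

## Known limitations

- Volumetric only; no surface-based searchlight or statistics.
- No autocorrelation modelling (prewhitening) in the GLM; per-run OLS.
- The NIfTI-1 reader/writer is deliberately minimal (single-file, sform,
  common datatypes); it is validated against round-trips but is not a
  general neuroimaging I/O layer.
- Replacement-mode chance level for the non-dominant aggregate is 0.375 (see
  the scoring-mode analysis); comparisons across studies should use the
  contrast or the conjunction, which are mode-stable.
- The cluster-extent rule is a display threshold, not a calibrated
  familywise correction.
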