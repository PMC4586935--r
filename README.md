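# framelight

Reference-frame evidence combination for fMRI multivoxel pattern analysis.

## The scientific problem

When the brain plans a grasp, in what coordinates does it hold the target's
location — relative to where the eyes are looking (**gaze-centered**, GC) or
relative to the body midline (**body-centered**, BC)? And does the answer
depend on whether the target was seen or felt?

A clean experimental handle on this question crosses three gaze fixation
directions (−11°, 0°, +11°) with two lateral target positions (±~5°), keeping
only the four combinations where the target stays near the gaze line:
`GL-TL`, `GC-TL`, `GC-TR`, `GR-TR` (gaze left/center/right × target
left/right of the body midline). These four conditions define six unordered
pairs. For the four *main* pairs each frame makes an opposite prediction: the
two configurations of `left_wrt_body` (= `GL-TL`, `GC-TL`) share a body-frame
side but lie on opposite sides of gaze, so GC coding predicts their activity
patterns *distinct* while BC coding predicts them *common* — and mirrored for
the `*_wrt_gaze` pairs. The remaining two pairs (`outer_sides`,
`center_sides`) are distinct under both frames and serve to define regions of
interest independently of the frame question.

## The statistic at the core

For each condition pair the package computes two complementary scores from
per-run t-patterns (planning-vs-baseline GLM contrasts), using a binary
linear SVM under leave-one-run-out cross-validation:

- **classification score** *a* — accuracy on the pair itself; evidence the
  two representations are *distinct*;
- **cross-classification score** *o* — accuracy of a classifier trained on a
  *different* pair when one of its trained configurations is replaced by a
  non-trained one; the score is routed to the receiving pair
  {replaced, replacement} and averaged over its four routes; evidence the two
  representations are *common*.

Evidence per frame combines both sides:

```
aggregate_GC = mean( o(left_wrt_gaze), o(right_wrt_gaze),
                     a(left_wrt_body), a(right_wrt_body) )
aggregate_BC = mean( a(left_wrt_gaze), a(right_wrt_gaze),
                     o(left_wrt_body), o(right_wrt_body) )
contrast     = aggregate_GC − aggregate_BC
```

Each aggregate mixes exactly two *a* and two *o* scores, so pure
gaze-direction coding (patterns driven by fixation alone, which inflates *a*
on all four main pairs) cancels in the contrast. The **conjunction** rule
(significant predicted-*o* AND significant predicted-*a*) is immune to it
outright, and a dedicated control test detects it directly: significant *a*
on all four main pairs plus significant *o* on `center_sides` — the only pair
predicted common under gaze-direction coding.

The same machinery runs within modality (visual / somaesthetic), across
modalities (train on one, test on the other, both directions averaged),
inside searchlight spheres (scores averaged back onto every voxel over all
spheres containing it), and through a full-crossing group GLM
(subjects × modalities × pairs × tests; in the full-scale design 432 observations,
42 regressors, 391 residual dof) with cluster-extent thresholding and
local-maximum ROI statistics.

Because no empirical data accompany the design, the package ships a
first-class synthetic generator (`simulate_patterns`, `simulate_volume`,
`simulate_schedule`, `simulate_bold`) with known ground-truth coding schemes
(`gaze_centered`, `body_centered`, `gaze_direction`, `mixed`, `null`, plus
shared / independent / switching modality models), so every stage has a
recoverable target.

## Worked example

```r
library(framelight)

sim <- simulate_patterns(simulation_spec("gaze_centered", snr = 5, seed = 42))
tbl <- evidence_table(sim$visual)   # LORO SVM + replacement-routed transfer
tbl
#>                          pair     a     o n_folds modality_context
#> left_wrt_gaze   left_wrt_gaze 0.500 1.000       8           visual
#> right_wrt_gaze right_wrt_gaze 0.938 1.000       8           visual
#> left_wrt_body   left_wrt_body 1.000 0.188       8           visual
#> right_wrt_body right_wrt_body 1.000 0.188       8           visual
#> outer_sides       outer_sides 1.000 0.344       8           visual
#> center_sides     center_sides 1.000 0.281       8           visual

frame_evidence(tbl)
#> <fl_frame_evidence> GC 1.000  BC 0.453  contrast +0.547 | conj GC=TRUE BC=FALSE | gaze-direction=FALSE
```

Exactly the gaze-centered signature: the gaze pairs *generalize* (o = 1)
while barely classifying, the body pairs *classify* (a = 1) while
generalization is low, the GC aggregate saturates, and only the GC
conjunction fires. A full volumetric run — simulate a cohort, searchlight,
group GLM, clusters, ROIs — is one call:

```r
report <- run_pipeline(pipeline_config("demo.json"))
```

or from the shell via `inst/cli/framelight.R` (subcommands `pairs`,
`simulate`, `decode`, `run-all`; exit codes 0/2/3).

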