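---
title: "Cell-of-origin methylome modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-of-origin methylome modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylCOO)
```

## The model

DNA methylation over a differentiation continuum is treated like sequence
divergence over evolutionary time. The package assumes:

* a set of reference subpopulations sampled along a single (non-branched)
  differentiation path, each with two or more donors;
* a subset of CpGs whose methylation moves monotonically and — for most
  of them — linearly along that path;
* tumors that arise from one position on the path and then acquire
  additional, disease-specific methylation changes.

The analysis proceeds in two halves. The **reference half** defines the
axis: differentiation-dynamic CpGs are selected by a start-versus-end
contrast (mean beta difference strictly greater than 0.20 and
equal-variance Student *t*-test *p* < 0.05 between the most naive and the
most mature subpopulation; intermediate subpopulations do not enter this
contrast), a Manhattan distance matrix over those CpGs is summarized by a
balanced minimum-evolution tree, and the path between the two endpoint
leaves becomes the differentiation axis. Each subpopulation's attachment
point on that path, computed with the three-point formula
raw(x) = (d(s,e) + d(s,x) − d(x,e)) / 2 on tree path distances, gives its
raw stage; rescaling so the mature endpoint equals 100 yields the
differentiation stage d.s. (percent of full differentiation
programming). Per CpG, ordinary least squares of beta on d.s. across all
reference donors yields the linear model M = α + β·d.s.; the tree, axis
and model are then rebuilt exactly once on the linearly behaving dynamic
CpGs.

The **tumor half** uses the axis: each tumor is attached to the reference
tree (balanced minimum evolution again, on the linear dynamic CpGs), its
attachment point on the backbone is its d.s., the linear model evaluated
at that stage and clipped to [0, 1] is its virtual cell-of-origin
methylome, and per-CpG deviations Δ = observed − M beyond ±0.20 (strict)
in at least 75% of patients (inclusive, over patients with a non-missing
value) become class calls: A/B = loss/gain at dynamic CpGs, C/D =
loss/gain at stable CpGs.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `delta_threshold` | 0.20 | beta | minimum start-to-end change for a dynamic CpG (strict >) |
| `p_threshold` | 0.05 | — | *t*-test cut-off for the dynamic contrast |
| `linearity_p` | 0.05 | — | F-test cut-off of the per-CpG regression |
| `delta_cut` | 0.20 | beta | per-patient aberration threshold (strict >) |
| `patient_fraction` | 0.75 | — | fraction of informative patients required (inclusive ≥) |
| `r_threshold` | 0.7 / 0.35 | — | minimum \|r\| for Pearson (genes) / Spearman (miRNAs) |
| promoter window | −2500/+500 | bases | strand-aware window around the TSS |
| miRNA window | 100,000 | bases | upstream reach of pri-miRNA promoter assignment |
| `cv_reps`, `cv_split` | 5000, 0.70 | — | cohort resampling for placement stability |

All thresholds are exposed but default to the method's standard values;
none is re-estimated from data.

## Numerical and design choices

**Linearity test direction.** The default verdict is the overall
regression F-test (equivalent to the slope *t*-test): a significant trend
counts as linear behavior, so *p* < `linearity_p` flags a CpG linear.
This direction cannot reject monotone-but-curved programs — a sigmoidal
CpG with a clear trend passes it. A lack-of-fit alternative
(`linearity_test = "lack_of_fit"`, linear fit versus
subpopulation-means model, linear = lack of fit *not* significant) is
available and is the variant that actually removes curved contaminants in
the refit; we keep the trend test as the default because the calibration
properties asserted by the test suite (nominal size on null CpGs,
near-complete retention of truly linear CpGs) are properties of that
variant, and the lack-of-fit variant sits exactly at its nominal
1 − `linearity_p` retention for true lines.

**Axis geometry.** Subpopulation representatives for tree building are
per-subpopulation mean profiles, which stabilizes the backbone when each
subpopulation has only 2–4 donors. Attachment points use the three-point
formula on tree distances, so the axis is invariant to sample column
order; endpoints are pinned at 0 and 100 by construction. A branchedness
score (fraction of total branch length off the backbone) warns above 0.2
that the continuum may not be path-like.

**One-at-a-time placement.** Tumors are placed singly against the fixed
reference backbone rather than all jointly, so one aberrant sample
cannot distort another's stage. This choice is quantified in this
package: in joint trees, minimum-evolution branch re-estimation under
concentrated high-dimensional noise shrinks the backbone as tumor leaves
accumulate, giving stage estimates a cohort-size-dependent offset of
1–3 d.s. between a full-cohort and a two-thirds-cohort tree on the
default synthetic scenario. Placement beyond the mature endpoint is
possible only for the grid-projection method (`method = "projection"`,
d.s. grid step 0.1), which extrapolates the linear model up to d.s. 120
to avoid silent truncation.

**Cross-validation semantics.** The cohort is repeatedly split 70/30
(the 70% drawn with replacement, duplicates collapsed; the 30% the
untouched remainder) and every group member is re-placed. Under the
default one-at-a-time placement a sample's stage is independent of its
companions, so the cross-validated distribution collapses onto the point
estimate — the stability property (point estimate inside the
interquartile range) holds by construction, and the procedure documents
that cohort membership cannot move an assignment. The `placement =
"joint"` mode places each subgroup jointly and genuinely varies with
composition; because of the size-dependent offset above, its quartiles
measure companionship sensitivity rather than noise, and its interquartile
ranges do not reliably bracket any fixed point estimate on the synthetic
scenario. This is a known limitation of pooled placement, not of the
default path.

**Missing values.** A CpG missing in any reference sample is dropped
from model fitting; for tumors, a missing (probe, sample) value counts
in neither the aberrant nor the informative-patient denominator of that
probe. Placement tolerates up to 20% missing placement CpGs per tumor,
imputing the reference mean for the few missing entries so Manhattan
sums stay comparable.

**Coordinate conventions.** Interval files are BED (0-based half-open);
probe positions are 1-based array-manifest coordinates; overlap tests
convert probes to single-base ranges. Promoter windows of a TSS at t are
[t−2500, t+500] on the plus strand and mirrored on the minus strand
(1-based inclusive). Closest-gene ties break to the smaller TSS
coordinate, then the lexicographically smaller gene id. Promoter-segment
simplification across sources intersects per-source unions, then merges
touching pieces (a union mode exists for permissive merging).

**Determinism.** No stage uses randomness except cross-validation and
the simulator, both seeded; nearest-neighbor-interchange tie-breaking is
delegated to the deterministic `fastme.bal` implementation. Two runs of
`run_pipeline()` with one seed are byte-identical.

## What the synthetic generator emulates — and what it does not

`simulate_reference()` draws stable CpGs from a low/mid/high beta
mixture (45/45/10), linear dynamic CpGs with total change magnitudes
uniform on 0.25–0.70 in either direction (clear effects, as large-scale
differentiation programs show, and comfortably above the 0.20 selection
threshold so that detection is limited by noise, not by boundary
effects), and non-linear contaminants (sigmoidal or single-step programs
of comparable endpoint change) amounting to one fifth of the dynamic
compartment — mirroring the roughly 80/20 linear/non-linear split such
continua exhibit. Donor values add Gaussian beta-scale noise (sd 0.02, a
typical replicate-level array dispersion) and are clipped to [0, 1];
clipped Gaussian noise is used instead of logit-normal noise so planted
effect sizes stay interpretable on the beta scale. Six subpopulations ×
3 donors and 34 tumors match the study-scale design the method targets;
tumor stages default to an even spread over 15–95 (intermediate-to-mature
range). Planted aberrations default to magnitude 0.30 carried by 85% of
tumors — clearly above the 0.20/75% calling thresholds, as near-clonal
disease-defining events are — with class counts 500/50/400/50
(loss-dominated, ~5% of probes). Planted genes repress expression with
slope −8 per beta unit and noise sd 0.4 on a log2-like scale, giving
strong but imperfect correlations.

The generator does **not** emulate array chemistry (type I/II probe
behavior), batch or donor covariance structure, copy-number
contamination, subclonal heterogeneity, or correlated neighboring CpGs.
Passing tests therefore demonstrate correctness of the algorithms under
the model's own assumptions, not robustness to every artifact of real
450K data.

## Problem sizes used by the test suite

The default scenario (20,000 probes, 6×3 reference, 34 tumors) is used
for the end-to-end properties; unit tests run reduced scenarios of
500–3,000 probes and 8–12 tumors, the linearity calibration uses 10,000
null CpGs, cross-validation properties use 200 repetitions (the
full-analysis default is 5,000), and tree optimality is checked
exhaustively up to 6 taxa (105 topologies). These sizes were chosen so
the whole suite exercises every code path at study-like scale while
remaining quick to run.

## Known limitations

* The linear model extrapolates poorly beyond the mature endpoint; the
  projection method caps extrapolation at d.s. 120.
* Stages are estimated, not known: systematic axis warp from non-linear
  contaminants (when the default trend test retains them) can bias
  stages by a few d.s.; the lack-of-fit refit removes most of it.
* Joint placement (and therefore joint-mode cross-validation) carries a
  cohort-size-dependent offset, as discussed above.
* Correlation screening tests every (probe, gene) pair without
  multiple-testing correction by default, following the method's raw-p
  convention; `fdr = TRUE` switches [correlate()] (and the dynamic-CpG
  test) to Benjamini-Hochberg-adjusted thresholds.
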