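---
title: "Scoring endoscopy artefact detectors and segmenters"
author: "endoarteval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring endoscopy artefact detectors and segmenters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoarteval)
```

## The evaluation problem

Endoscopy video frames are routinely corrupted by imaging artefacts —
specular reflections, pixel saturation, under-exposed (contrast) regions,
motion blur, bubbles, floating debris ("artefact") and the endoscopic
instrument itself. Automated detection and pixel-level segmentation of
these seven classes is a prerequisite for any downstream quantitative
analysis, and comparing candidate algorithms fairly requires a fixed,
reproducible scoring pipeline. `endoarteval` implements such a pipeline:
detection scoring with a validity gate, semantic segmentation scoring
with a recall-leaning composite, out-of-sample generalization scoring,
consensus ("super detector" / "super segmentation") ensembling across
submissions, and the nonparametric rank and clinical-applicability
analyses used to compare methods beyond a single leaderboard number.

Two structural features of the domain shape everything downstream.
First, annotations are multi-label: the same spatial location may carry
several class labels, so per-class scoring must never assume exclusive
regions. Second, the small classes (specularity, artefact, bubbles) are
heavily colocalized with larger boxes of other classes, which is exactly
where standard IoU-threshold matching is most brittle.

## Detection scoring

A predicted box matches a reference box of the same class when their
intersection-over-union reaches the match threshold (default 0.25).
Matching is greedy in descending prediction confidence: each prediction
claims the unmatched reference with the highest IoU at or above the
threshold. Greedy confidence-ordered matching is the convention of the
standard object-detection benchmarks; it is deterministic given the
input order (confidence ties break by file order).

Per class, **average precision** (AP) is the area under the
precision-recall curve swept by the confidence ranking, using all-point
(continuous, monotone-envelope) interpolation. We use all-point rather
than 11-point interpolation because it is the modern standard and is
free of the coarse-grid bias of the 11-point variant; every report
header states the interpolation used. AP is undefined for a class with
no reference boxes; such classes are excluded from the macro mean rather
than scored 0, so small fixtures are not distorted.

The leaderboard aggregate is

  score_d = 0.6 mAP + 0.4 IoU,

where mAP is the unweighted mean of per-class AP and IoU is the
unweighted mean over classes of the mean best-match IoU per reference
box, with unmatched references contributing 0. The leaderboard "IoU"
aggregate is not pinned down by its original description; the choice
here (macro over classes, per-reference-box, missed boxes count 0)
penalizes missed artefacts, which matches the declared intent of
weighting retrieval of all artefacts. The pooled (box-weighted)
alternative is also reported (`pooled_iou`); macro is primary.

A submission is **valid** only when 0.7 < IoU/mAP < 1.3 (strict
inequalities), discouraging entrants from trading the two metrics off
against each other via early or late stopping.

Box coordinates are 0-based pixels with half-open extent
`[x1, x2) × [y1, y2)`, so `area = (x2−x1)(y2−y1)`. The original
coordinate convention (inclusive vs half-open) is not documented; we fix
half-open because it makes box arithmetic exact, agrees with mask
rasterization, and avoids the ±1 pixel ambiguity of inclusive corners.

## Segmentation scoring

Per class and frame we compute the Dice coefficient
DSC = 2|R∩S|/(|R|+|S|), the Jaccard index J = |R∩S|/|R∪S| (related by
DSC = 2J/(1+J), asserted to 1e−12 in the test suite), their arithmetic
mean (the "Overlap" column), the F2 score, pixel precision (PPV) and
pixel recall. Averaging is macro-macro: frame means per class, then an
unweighted class mean. The composite score is

  score_s = 0.75·[0.5·(F1 + J)] + 0.25·F2,

computed from the aggregate F1 (≡ DSC), J and F2 — not as a mean of
per-frame composites — because that is the identity the published
per-team components satisfy. Its behaviour is intermediate between F1
and F2, placing moderate extra weight on recall.

**Empty-mask convention.** When a class is absent from both the
reference and the prediction in a frame, all its metrics for that frame
are defined as 1 (perfect agreement on absence); when exactly one side
is empty, overlap metrics are 0 and the 0/0 ratio among PPV/recall is 1.
Absent classes must score positively for an all-background prediction to
earn a nonzero composite score — the known pathology of
pixel-imbalanced mask scoring that makes a null predictor competitive
with weak baselines. Under this convention the all-background
prediction's aggregate score equals, in closed form, the mean
empty-class fraction of the fixture, and the test suite pins that
identity. The convention is recorded in every report.

## Out-of-sample generalization

For each class i, with mAP_d the in-sample and mAP_g the out-of-sample
value, the gated deviation is

  dev_g^i = 0                    if |mAP_d − mAP_g| / mAP_d ≤ 0.1
  dev_g^i = |mAP_d − mAP_g|      otherwise,

and dev_g is the mean over the N = 7 detection classes. The tolerance
boundary is inclusive (a relative deviation of exactly 0.1 is zeroed).
mAP_d = 0 leaves the rule undefined; we extend it as dev = mAP_g (0 if
both are 0) and log the extension. Teams are ranked by

  score_g = 1/3·Rank(dev_g) + 2/3·Rank(mAP_g).

The published rule says mAP_g is ranked "in ascending order", which
contradicts the accompanying statement that the best algorithm has high
mAP_g and low dev_g. We rank mAP_g descending (rank 1 = highest) so
that lower score_g is uniformly better; the literal ascending reading
remains available via `map_ascending = TRUE`, and report metadata notes
the ambiguity rather than guessing silently.

## Consensus ensembling

The "Merged" super detector pools all submissions' boxes per class,
links boxes whose pairwise IoU reaches the threshold (single-linkage,
chosen for determinism; a greedy match-against-first variant would be an
alternative but offers no advantage here), and keeps clusters supported
by more than `min_fraction` of submissions. "Majority" is read as strict
(> 0.5) and is configurable, since ≥ half is an equally defensible
reading. Support counts distinct submissions, so duplicated boxes within
one submission do not inflate a cluster. The representative box is the
cluster's highest-confidence member — which is why a team contributes
little when another method produced the same consensus box with higher
confidence — with ties broken by submission order. Clustering is
class-aware throughout, consistent with per-class leaderboards. The
super segmentation is a per-pixel strict-majority vote per class.

One caveat the test suite makes explicit: when two *true* same-class
boxes overlap at the cluster threshold, single-linkage collapses their
clones into one cluster, so the "clones merge back to the ground truth"
property only holds on fixtures without same-class overlap at the
threshold; the corresponding test enforces that precondition
structurally instead of relying on a lucky seed.

## Rank statistics and clinical applicability

The Friedman test (blocks = artefact classes) uses the tie-corrected
chi-square statistic computed from within-block average ranks; it is
implemented directly — rather than delegating to `stats::friedman.test`
— because the evaluator needs the mean ranks as first-class output and a
defined value (statistic 0, p = 1) on fully tied grids; agreement with
`stats::friedman.test` on tie-free grids is asserted in the tests. The
Nemenyi critical difference is CD = q_α·sqrt(k(k+1)/(6n)) with q_α the
studentized-range quantile over sqrt(2) (`qtukey`-derived, checked
against the published table value 2.343 at k = 3, α = 0.05).
Bonferroni-Dunn compares every method to a designated control at level
α/(k−1).

The Jonckheere-Terpstra trend statistic counts increasing cross-pairs
over ordered groups (ties half). With only seven class-groups the
normal approximation is shaky, so the p-value defaults to a seeded
permutation test (10,000 draws; the approximation remains available).
Permutation p-values are compared against exhaustive relabelling
enumeration on small toys in the tests.

Clinical applicability combines accuracy, consistency and efficiency
rank vectors with weights 0.4 / 0.5 / 0.1; consistency of a method is
the coefficient of variation (sample, n−1 standard deviation — the
variant is not documented upstream, so it is fixed and stated here) of
its per-class scores. Missing efficiency metadata is imputed as the
worst observed rank + 1. The composition of the accuracy, consistency
and efficiency sub-ranks from individual metric columns is
deliberately config-driven: the exact upstream recipe is not public, so
the package reproduces the aggregation given any sub-rank inputs rather
than hard-coding a guess.

## The synthetic fixture generator

Real challenge ground truth for the hidden test sets is not available,
so every evaluator is exercised on seeded synthetic fixtures that
emulate the *statistical* structure of the annotations: per-class box
frequencies (Poisson), normalized box areas (truncated normal; small
means for specularity/artefact/bubbles, large for blur/contrast/
saturation/instrument), and colocalization — small-class boxes are
centred inside a large-class box with probability `overlap_rate`
(default 0.6). Masks are rasterized from boxes as filled rectangles with
an elliptical carving. Default frames are 288×384 px.

Submissions are derived from ground truth by controlled degradation:
corner jitter (`loc_noise_sd`), box dropping, class mislabelling,
spurious boxes, and a monotone IoU-to-confidence map so that
better-localized predictions rank higher — the behaviour every
confidence-swept metric assumes. All generation is bit-reproducible
under the recorded seed.

What the generator does *not* emulate: photorealistic artefact
appearance, annotator disagreement, irregular mask shapes beyond
ellipses, correlated frame content within a video, and the class
imbalance of any particular hospital's data. Green tests therefore
demonstrate correctness of the *scoring arithmetic and its invariants*
on EAD-shaped inputs, not performance claims about real endoscopy data.

## Numerical choices and problem sizes

Degenerate boxes (x2 ≤ x1 or y2 ≤ y1) are rejected at parse time;
confidences outside [0, 1] are errors, not clamps. Ties — in confidence,
consensus representatives and rank vectors — break by input order or
average ranks as noted above, so all pipelines are deterministic.
Mask binarisation treats any pixel value > 0 as foreground, tolerating
both {0, 1} and {0, 255} PNG dialects; a missing class file is an
all-zero mask, logged. Frames present in the ground truth but absent
from a submission are scored as empty predictions, keeping denominators
fixed across teams.

The shipped studies use sizes chosen to make the statistics stable while
keeping the suite quick to run: the matching-oracle property uses 1,000
random instances with up to 4 boxes per side; the localization-noise
study uses 50 frames × 10 seeds × noise levels {0, 2, 8, 32} px, under
which mean mAP and mean IoU decrease strictly monotonically.

## Limitations

The exact leaderboard values of the original challenge depend on its
secret test annotations and are not reproducible here; what the package
reproduces exactly are the score identities linking the published
per-team metric components, plus every structural property of the
scoring machinery on synthetic data. The empty-mask convention, the
leaderboard IoU aggregate, the averaging order and the mAP_g ranking
direction are all choices among defensible readings; each is documented
above, surfaced in report metadata, and isolated behind a single
argument so alternative conventions can be evaluated.
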