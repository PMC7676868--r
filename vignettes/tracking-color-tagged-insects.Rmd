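---
title: "Tracking color-tagged insects on a tracklet graph"
author: "tracktags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking color-tagged insects on a tracklet graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracktags)
```

## The problem

Groups of small social insects -- ants are the motivating case -- are
routinely marked with 1--3 small paint dots so that a human can tell
individuals apart. Automated tracking of such videos is hard for two
reasons. First, the animals aggregate: for long stretches several bodies
touch and form a single dark blob in which nobody, human or machine, can
segment individuals. Second, the tags are tiny and frequently occluded, so
an image classifier can identify an animal only in a fraction of frames.

`tracktags` addresses both problems with a three-stage design:

1. **Segmentation and linking.** Frames are background-subtracted and
   thresholded into *blobs* (connected foreground components that contain
   one *or several* animals -- no attempt is made to split merged
   animals). Blobs in consecutive frames are linked, using dense optical
   flow where the linking is ambiguous, and organized into *tracklets*:
   maximal runs of exclusively linked blobs, which therefore hold a
   constant (unknown) set of animals. Merge and split events become edges
   of a directed acyclic *tracklet graph* recording how animals flow
   between tracklets.
2. **Classification.** A pluggable image classifier labels blobs with an
   ID, "unknown", or "multi"; per-blob labels are aggregated into
   tracklet labels with a confidence score.
3. **Propagation.** Classified tracklets *seed* a greedy constraint
   solver that pushes IDs through the graph -- forward and backward along
   edges, sideways via time exclusivity, and through capacity and
   counting arguments -- assigning identities to tracklets the classifier
   could never read, including multi-animal aggregates.

The package also ships a synthetic arena simulator with full ground
truth, an exhaustive enumeration oracle for the solver, and the
validation statistics used to score tracking runs (assignment rate,
assignment error with exact Clopper--Pearson intervals). Everything is
deterministic given the seeds.

## Segmentation model and choices

The background is the **per-pixel median** over `bgSamples` frames sampled
uniformly in time (default 9; long, aggregation-heavy videos use 25 in our
own runs). The median is robust to transient animals but assumes each
pixel is animal-free in more than half of the sampled frames. A colony
that rests in one spot for most of a *short* clip violates this; for such
clips either supply a known background via `bg =` or sample more frames.
This is an assumption about the data, not a tunable of the method.

Foreground is `max_channel |frame - background| > threshold` (default
0.3 on a [0, 1] intensity scale). The max-over-channels rule covers both
dark bodies and brightly colored tags against a light background.
Components are 8-connected; components smaller than `minArea` (default
16 px, about a quarter of one body) are discarded. Blob orientation is
the principal axis of the mask from second-order central moments, defined
modulo pi; head/tail is resolved only at export time, from motion.

## Linking and optical flow

Where a blob in frame *t - 1* overlaps exactly one blob in frame *t* and
vice versa, the pair is linked directly (the overwhelmingly common case,
and free). Every other case runs dense block-matching optical flow over
the small region spanning the candidate blobs: each pixel takes the
integer displacement minimizing a local SSD over a search window
(`searchPx`, default 8 px; use about twice the fastest per-frame
displacement). The previous blob's pixels are advected by the field and
counted in each (1 px dilated) current blob.

Link **support** is the stronger of advected landings and direct mask
overlap, normalized by the *smallest* of source area, target area, and
one body area (`refArea`, default `4 * minArea`). The body-area
normalization matters: when one animal leaves a five-animal aggregate it
carries only a fifth of the source pixels, yet it is a full animal's
worth of evidence. A link is created when support reaches `supportMin`
(default 0.25 -- a quarter of a body). The asymmetry of the costs drove
this design: a spurious link merely fragments tracklets and makes the
solver more conservative, while a missed link severs an animal's path
through the graph and can make the solver confidently wrong. Occluded
resting animals, whose pixels the flow tends to drag along with the
animals walking over them, are the concrete case the overlap term
rescues.

Tracklet bookkeeping follows four rules applied per frame transition: an
unlinked current blob opens a tracklet; an unlinked previous blob closes
one; an exclusively linked pair extends; and any blob with more than one
link closes all involved previous tracklets, opens new ones, and records
a graph edge per link. Tracklet ids are assigned in order of opening, so
the whole construction is deterministic.

## Classification

The classifier contract is minimal: given the blobs of one frame, return
a probability row over `c(ids, "multi", "unknown")`. Two implementations
are provided.

* `oracleClassifier()` reads the simulation ground truth (optionally
  corrupted at a stated error rate). It is the reference instrument for
  testing the *pipeline*: with zero corruption, any downstream error is
  attributable to tracking or inference, not to classification.
* `trainBlobClassifier()` is a single-hidden-layer softmax network
  (via `nnet`) over engineered crop features: foreground pixels are
  projected onto the blob's principal axis, the head side is identified
  by the darkest pixels (the rendered head), and per-axial-bin tag-color
  means plus shape statistics form the feature vector. On held-out
  synthetic crops it exceeds 99% on visible-tag singles; it is a
  deliberately small model, because the contribution under test is the
  graph machinery around it, and any stronger image model can be plugged
  in through the same contract.

Tracklet labels take the plurality ID among blob labels; ties are left
unlabeled. The confidence is

    conf = mean_score(plurality blobs) * (n_plurality - n_contradictory) / n_classified

clipped to [0, 1], where `n_classified` excludes "unknown" blobs. This
combines the number of identified blobs, their scores, and contradictory
evidence in one monotone quantity. A tracklet whose informative labels
are mostly "multi" is marked multi-animal; with no informative majority
the kind stays "unknown" and no capacity assumption is made -- treating
an aggregated tracklet as single-animal would be an unsound constraint,
so ambiguity is priced as lost precision, never as risk.

## ID propagation

Each node carries an *assigned* set (IDs proven present) and a *possible*
set (IDs not yet excluded); initially nothing is assigned and everything
is possible. Seeds are applied in descending confidence (ties: earlier
start frame, then lower tracklet id), each followed by a fixpoint of:

* **R1 positive-vertical** -- an assigned ID must continue into some
  successor and arrive from some predecessor; with exactly one candidate
  it is assigned there, with several nothing happens, with none the
  state is contradictory.
* **R2 negative-vertical** -- an ID with no possible predecessor
  (successor) is removed from a node's possible set.
* **R3 horizontal** -- an assigned ID is impossible in every
  time-overlapping node.
* **R4 capacity and counting** -- single-animal nodes hold exactly one
  ID; and under *full coverage* (closed arena, every animal detected in
  every frame) an ID possible in only one node covering some frame must
  be there. The counting rule is what lets two seeds resolve an entire
  merge--split motif, and it can fire even before any seed when a single
  blob covers a frame (everyone must be inside). It is enabled by
  default exactly when no tracklet touches an open boundary; disable it
  with `fullCoverage = FALSE` for graphs with detection gaps.
* **R5 boundary exemptions** -- nodes starting at frame 1, ending at the
  last frame, flagged at an open ROI border, or with no incident edge on
  a side are exempt from the vertical rules on that side.

Only unambiguous inferences are ever made. When a seed's fixpoint hits a
contradiction, the lower-confidence seed loses: its entire round is
rolled back (state snapshot) and the seed is recorded in the
`contradicted` table. The outer loop repeats full passes until nothing
changes. Possible sets only shrink and assigned sets only grow (outside
rollbacks), so the number of state mutations is bounded by
`2 x nodes x IDs` and termination is structural, not numerical.

`oracleSolve()` enumerates *every* complete consistent composition of a
small graph (each ID traces a chain through the edges; singles hold one
ID, multis at least two, every node at least one) and intersects them
into the forced set. The solver's contract, enforced in the tests on
hundreds of randomized graphs, is **soundness**: every assignment it
makes lies in the forced set. It is intentionally not complete --
ambiguity is left unassigned.

## Export and validation

`exportTrajectories()` emits one row per (ID, frame) with a flag:
`single_classified` (position from a tracklet the classifier labeled
with this ID), `single_propagated`, `multi_propagated` (position is the
aggregate blob's centroid -- approximate by construction), or
`unassigned` (no position is fabricated; gaps are left to the analyst,
who may interpolate knowing the flags). Orientation is exported only for
single-animal rows; head/tail is resolved by the displacement direction
when the animal moves at least 1 px/frame averaged over +-5 frames,
otherwise the angle is reported modulo pi.

`assignmentRate()` is assigned rows over IDs x frames.
`assignmentError()` scores assignments against ground truth: a
single-animal row is correct within one body length (`matchRadius`,
default 14 px) of the true position; a multi-animal row is correct if
the true position lies inside the assigned blob's mask (1 px dilated).
Both a full census and a seeded uniform subsample of `nPoints`
assignments (the protocol used when humans spot-check long recordings)
are supported, with an exact Clopper--Pearson 95% interval from Beta
quantiles.

## The synthetic arena

`simulateColony()` moves agents by a correlated random walk with heading
persistence, alternating move/rest states, soft-core repulsion (bodies
may touch and overlap but not coincide), and optional attraction that
makes agents steer toward neighbors and rest longer in contact -- which
is what produces the transient aggregates, merged blobs, and occluded
tags that make this tracking problem hard. Agents are rendered as dark
capsules with a darker head disc and 1--3 colored tag discs along the
body axis; drawing order is randomized per frame so lower animals' tags
are realistically hidden. Ground-truth aggregates are connected
components of the body-contact graph (capsule distance below one body
width plus 1.5 px, matching the rasterized touch geometry). Additive
Gaussian pixel noise (default sd 0.02) is seeded per frame so any frame
renders independently -- videos never need to fit in memory.

What the simulator does *not* emulate: illumination drift, shadows,
motion blur, postural variation (bending bodies), tag fading, debris,
and camera artifacts. Passing tests on synthetic data therefore
demonstrate the correctness of the algorithmic chain under its stated
assumptions, not field robustness; on real videos the classifier must be
trained on real crops and the segmentation threshold tuned to the
footage.

The canonical test condition, `smallColonySim()`, is 16 agents carrying
ordered pairs of four tag colors in a closed 256 x 256 px arena with
aggregation on -- a colony size and tagging scheme typical of laboratory
experiments with this marking technique, at a scale (body length 14 px)
that matches low-cost webcam footage.

## Parameters at a glance

| parameter | default | unit | meaning |
|---|---|---|---|
| `threshold` | 0.3 | intensity | background difference cut |
| `minArea` | 16 | px | minimum blob size (~1/4 body) |
| `refArea` | 64 | px | one body, for link support |
| `supportMin` | 0.25 | bodies | evidence needed for a link |
| `searchPx` | 6--8 | px | flow search radius (~2x max speed) |
| `flowStride` | 2 | px | flow sampling stride |
| `bgSamples` | 9--25 | frames | background median sample |
| `matchRadius` | 14 | px | one body, validation criterion |
| `noiseSd` | 0.02 | intensity | render noise |

## Problem sizes and numerical choices

The test suite exercises the full chain on a 4-agent/150-frame colony
and on the 16-agent/2000-frame benchmark condition; solver soundness is
checked against the exhaustive oracle on 200+ random graphs of up to 12
nodes and 4 IDs, sizes at which complete enumeration is itself cheap and
trustworthy. Ties everywhere (seed order, flow shifts, plurality labels)
break deterministically; flow prefers the zero shift on equal cost, so
identical frames yield an exactly zero field. Degenerate blob masks
(under 3 px) get an undefined orientation rather than a noisy one.

## Known limitations

* Propagation's counting rule assumes complete detection in closed
  arenas; videos with dropout frames should disable it
  (`fullCoverage = FALSE`) and will resolve less.
* Multi-animal blobs are never re-segmented; positions inside aggregates
  are blob centroids and should not feed velocity analyses (the flags
  make such rows easy to exclude).
* The ground-truth contact rule and pixel connectivity can disagree for
  bodies resting exactly at the touch threshold; co-membership against
  ground truth is therefore a statistical (95%) rather than exact
  property.
* The solver is greedy and seed-ordered, not a global optimizer: a
  wrong high-confidence seed can suppress a right low-confidence one,
  though rollback confines the damage to the contradicted seed's round.
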