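---
title: "Scoring expert sulcal annotations on endocasts with the SISS index"
author: "endoSISS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring expert sulcal annotations on endocasts with the SISS index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoSISS)
```

## The problem

An endocast — the mould of the braincase — is the only physical proxy for
the brain of an extinct hominin. Shallow grooves on its surface are read as
imprints of cortical sulci, but whether a given groove really corresponds
to a particular sulcus, and whether experts can name it reliably, is
contested. The experimental design this package supports puts numbers on
that question: several raters draw, on a fixed set of five 2D views of an
endocast (anterior, superior, posterior, and the two lateral views), the
sulci they believe they can see, as colour-coded strokes keyed to a shared
nomenclature. Each drawing is then compared against the *reference*
sulcus — the pixel set of the same sulcus extracted automatically from the
subject's brain segmentation and projected into the same view.

Two failure modes must be kept apart: a groove can be *perceived* correctly
but *named* wrongly. The pipeline therefore supports two passes over the
same drawings: a raw analysis with the labels as the raters wrote them, and
a corrected analysis in which a declarative correction table reassigns
misnamed strokes to their true sulci (possibly two, when a stroke covers
both), and discards strokes that match no real sulcus at all. Corrections
are input metadata, not an algorithm: deciding what a stroke "really was"
is expert judgement, and automating it would invent a method.

## The scoring model

For one drawing $A$ and its reference $B$ (binary pixel sets on the same
view frame) the package computes four quantities.

**Dice overlap.**
$\mathrm{Dice} = 2\,|A \cap B| \,/\, (|A| + |B|)$, 1 for identical sets, 0
for disjoint ones. Dice is computed on the *full-width* drawn stroke. It
is blind to near-misses: a drawing that runs 3 px beside its sulcus for
its whole length scores 0.

**Centroid streamline.** Hand-drawn strokes differ in width between
raters, which would contaminate any distance measure. Each drawing is
therefore reduced to a single-pixel-wide ordered streamline: the
independent axis is the axis along which the stroke's bounding box is
longer (ties go to horizontal), and at every occupied integer coordinate of
that axis the transverse coordinate is estimated from the stroke's pixels,
rounded half-away-from-zero, and clipped to the bounding box. As the
estimator we use the per-coordinate conditional mean (a bin-width-1
regressogram). A boosted regression ensemble could be substituted here;
we deliberately use the simplest estimator satisfying the streamline
contract, because it is exact in the two cases that anchor the scale:
on a symmetric bar it returns the central row, and on an already
single-pixel-wide stroke it returns the stroke itself — any smoother that
pools across neighbouring coordinates would break the second property and
with it the exactness of a perfect score. References keep their full pixel
set: their shapes (forks, interruptions) are too complex to reduce to one
streamline.

**MMED.** For each streamline point $a_i$ the Euclidean distance to the
nearest reference pixel is found; the mean minimum Euclidean distance is
$\mathrm{MMED} = \frac{1}{N}\sum_i \min_j d_E(a_i, b_j)$, in pixel units.
It is a *directed* measure (drawing toward reference) of proximity and
shape agreement in the region the rater actually drew.

**Normalization and SISS.** MMED is mapped onto the similarity scale by
$\mathrm{MMEDn} = 1 - \mathrm{MMED}/T$ for $\mathrm{MMED} < T$ and $0$
otherwise, with threshold $T = 100$ px by default: distances that large
only arise for mislabelled strokes with no relation to the reference, so
they are clamped to "no similarity" rather than allowed to dominate.
(Printing the raw threshold value in the saturated branch, as one
formulation of the rule suggests, would break the unit range of the final
index; we therefore floor at zero, which also keeps the function
continuous and monotone.) The combined index is the arithmetic mean

$$\mathrm{SISS} = \tfrac{1}{2}(\mathrm{Dice} + \mathrm{MMEDn}) \in [0, 1],$$

so `siss <= 0.5 + dice/2` always: a score above 0.75 requires genuine
overlap (Dice > 0.5), not just proximity. Scores are kept at full
precision internally and rounded to 2 decimals only in the serialized
reports.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| MMED saturation threshold | 100 | px | beyond it only mislabels occur; exposed in `scorePair()`/`runScore()` |
| colour tolerance | 30 | RGB distance | absorbs anti-aliased stroke edges; palettes are generated ≥ 60 apart so assignment stays unambiguous |
| zone thresholds | 0.5 / 0.4 / 20 % | SISS, rate | green: mean > 0.5 with > 20 % of raters in ≥ 1 view; yellow: best qualifying view in (0.4, 0.5]; red otherwise. Boundaries strict; the paper-style reading of "over" and "between" |
| rate denominator | full cohort (14) | raters | "% of researchers" reads against everyone who took part, not per-view participation; configurable |

Missing table cells are skipped, never zero-filled: a dash in the
reliability table means nobody drew that sulcus in that view, and view
marginals average only the present cells.

## The synthetic cohort generator

The study's drawing set is available only on request, so validation runs
on simulated raters. The generator is *additive-geometric*: it perturbs
the reference's centroid streamline with one interpretable knob per error
mode actually observed in expert drawings, then re-rasterizes at the
rater's stroke width:

* **`displacement_px`** — a rigid shift of exactly this magnitude along
  the normal to the stroke's chord, with random sign. This models the
  systematic transverse misplacement seen for the central/pre-central
  region. A fixed magnitude (rather than a Gaussian draw) makes the knob
  directly interpretable: a cohort at `displacement_px = d` sits `d`
  pixels off its references, so mean SISS responds deterministically —
  1 at `d = 0` (width-1 strokes) down to exactly 0 once `d` exceeds the
  saturation threshold, where every drawing is disjoint and saturated.
* **`smooth_deform_amp` / `smooth_deform_scale`** (px) — a smooth random
  transverse deformation: a natural spline through Gaussian knots of sd
  `amp` spaced `scale` px along the stroke. Shape error without position
  error.
* **`truncation_frac`** — fraction of the stroke removed from a random
  end; drawings rarely cover a sulcus end to end.
* **`rectilinear_bias`** — blend toward the straight chord; at 1 the
  sulcus is drawn as a straight line regardless of its true course, the
  characteristic failure for the superior frontal sulcus.
* **`p_omit`**, **`p_mislabel`** — omission, and label swapping within the
  designated confusable pair of a view (central ↔ pre-central, inferior
  frontal ↔ anterior inferior frontal, superior frontal ↔ intermediate
  frontal, parieto-occipital ↔ occipital). Swaps are logged, and the truth
  log yields the correction file for the corrected-analysis replay. A swap
  whose partner is absent from a view produces the documented
  "no corresponding real sulcus" phenomenon: the drawing is excluded from
  the tables and listed in the unmatched report.

The default layout (`referenceSpecs()`) places 26 gently curved reference
strokes (widths 2–5 px) across the five views of a 600×600 px frame, ten
canonical labels in all, with each confusable pair 40–70 px apart — the
scale at which a mislabel is spatially wrong but not saturated. Stroke
widths of simulated raters cycle over 1–7 px; cohorts default to 14
raters. One cohort seed determines per-rater seeds, so entire fixture
trees and all downstream CSVs are byte-reproducible.

Numerical conventions worth knowing:

* Curves are *function-form*: one pixel per integer coordinate of the
  independent axis, thickened transversely to the stroke width. With all
  knobs at zero and matching odd widths, a simulated drawing equals its
  reference pixel for pixel; even widths cannot round-trip exactly because
  the half-pixel centre of an even-width stroke has no pixel
  representation.
* Rasterized strokes are clipped to the frame; a drawing displaced
  entirely outside it is recorded as omitted.
* Rounding of streamline estimates is half-away-from-zero, not banker's
  rounding.

What the generator does **not** emulate: real endocast anatomy (sutures
and vascular imprints that masquerade as sulci), perspective distortion
across views of one 3D surface, correlated error between views of one
rater, or drawing-tool artefacts beyond anti-aliasing. Passing the
simulation-based checks therefore shows that the *pipeline* measures what
it claims under known noise — not that experts behave like the noise
model.

## Validation choices and problem sizes

The test suite validates the MMED implementation against a brute-force
nested-loop oracle (100 random mask pairs on 50×50 frames, tolerance
1e-9), checks the analytic identities of the indices, and exercises
parameter recovery: over `displacement_px` in {0, 5, 20, 120} with 20
simulated raters each on the width-1 layout, cohort mean SISS is strictly
decreasing with exact endpoints 1 and 0; with `p_mislabel = 0.3` over 14
raters, the corrected analysis beats the raw analysis in every cell that
received a mislabel. These sizes keep the full suite around a minute on
one CPU while leaving the Monte-Carlo orderings far from their decision
boundaries.

## Limitations

* Scoring is strictly 2D and per view; nothing links the five views of a
  rater, and cross-view consistency must be judged downstream.
* All images of a cohort must share one resolution — frames are checked,
  never resampled.
* The directed MMED forgives a drawing that covers only part of a long
  sulcus (that is Dice's job); SISS inherits both behaviours by design.
* Strokes that genuinely overlap in an exported image occlude each other
  pixel-wise, as they do in any flat drawing tool.
* The reliability-zone thresholds are reporting conventions, not
  inferential statistics; no hypothesis testing between raters is
  performed or intended.
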