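---
title: "Methods: assessing multi-rater annotation quality on OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing multi-rater annotation quality on OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotqc)
```

## The problem

Supervised segmentation models for retinal optical coherence tomography
(OCT) depend on pixel-accurate annotations of disease biomarkers such as
intraretinal fluid (IRF), which appears as dark, rounded, minimally
reflective pockets inside the brighter retinal tissue of a B-scan.
Annotations are expensive, so clinics would like to delegate them to less
experienced clinicians — but annotation quality then becomes the question.
`annotqc` implements a complete quality-assessment pipeline for studies in
which several raters, over one or two rounds, each produce a binary mask
per B-scan:

1. a majority-vote consensus over a designated expert panel defines the
   ground truth;
2. every (rater, round) is scored against it with overlap metrics and
   chance-corrected agreement coefficients;
3. image-based analyses — annotation boundary intensities, speckle-noise
   estimation, lateral zone stratification — probe *why* quality varies.

Because clinical studies of this kind rarely deposit their images, the
package ships a synthetic module that generates OCT-like phantoms with
known truth and simulated raters with experience-dependent error, so every
stage can be validated against a known answer.

## Consensus ground truth

`majority_vote()` fuses aligned binary masks pixelwise. A genuine
ambiguity arises with an even panel: with two experts, "majority" is
undefined at a 1-1 tie. Both conventions are implemented:

* `strict_majority` (default): positive votes must *exceed* half the
  panel. For two raters this is the intersection — a ground-truth pixel is
  one that both experts marked, the conservative reading of "most accurate
  representation of ground truth".
* `at_least_half`: votes equal to half suffice; the union for two raters.

`build_ground_truth()` applies the last-round policy: each consensus rater
contributes their highest-numbered round, and a single-round rater
contributes that round wherever a later one is required. Every report
records the rule used; on two-rater panels the difference between rules is
exactly the experts' disagreement area, so surfacing it matters more than
hiding it behind a default.

## Agreement metrics

All metrics derive from pixel confusion counts (TP, TN, FP, FN), pooled
over whatever window is being evaluated:

* IoU $= \mathrm{TP}/(\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$, DSC
  $= 2\mathrm{TP}/(2\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$, TNR, TPR,
  precision — the standard overlap battery. The identity
  $\mathrm{DSC} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ is property-tested.
* Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$ with
  $p_o = (\mathrm{TP}+\mathrm{TN})/N$ and the chance term from both
  raters' marginals. Interpretation bands follow the conventional cut
  points (0.41–0.60 moderate, 0.81–1.00 almost perfect, etc.).
* Gwet's AC1, in **two variants**. The variant used for replication
  (`annotator_marginal`) takes
  $p_e = p_+^2 + p_-^2$ with $p_+ = (\mathrm{TP}+\mathrm{FP})/N$, i.e.
  both category probabilities from the *annotator's* marginal only. This
  matches the formula printed in the study this package emulates, but it
  is not Gwet's published chance term and — unlike $\kappa$ — it is not
  symmetric under swapping the two raters. Whether that formula was
  intended or a typesetting slip cannot be decided from the source, so the
  package computes **both**: `standard` uses Gwet's
  $p_e = 2\pi(1-\pi)$ with $\pi$ the mean of the two raters' positive
  rates. The asymmetry of the first variant is asserted in the test suite
  and documented rather than silently resolved; pairwise matrices orient
  each unordered pair by listing order and mirror the value.

Undefined ratios (0/0) are returned as `NA` — *undefined*, never coerced
to 0 or 1 — and excluded from means with the exclusion count reported.

Two aggregation modes are reported side by side, because "metrics averaged
across all annotations" admits both readings: `pooled` (counts summed over
images per rater-round, then one metric) and `per_region_mean` (metric per
consensus region, then averaged). Pixel pooling is also the default for
pairwise matrices; per-image averaging is a flag.

## Per-region evaluation

`connected_regions()` uses 8-connectivity by default: annotations are
freehand strokes, and 4-connectivity would split thin diagonal necks
(configurable). Each rater component is matched to the consensus region it
overlaps most; unmatched components are counted as false-positive areas.
Per-region confusion counts are taken inside the region's bounding box
dilated by 10 px (configurable), with other consensus regions excluded
from the window — this keeps per-region TNR meaningful without letting
distant background dominate, and prevents a neighbouring region from
being scored as error.

## Boundary intensity analysis

For each region, the inner band is the 1-px shell of region pixels with a
background 8-neighbour (region minus its 3×3 erosion) and the outer band
the 1-px shell of background pixels with a region 8-neighbour (3×3
dilation minus region), clipped at image borders. Since fluid is dark and
tissue bright, an accurate annotation has a large outer−inner mean
intensity difference; oversegmentation drags the inner band into bright
tissue and shrinks the difference while raising the mean intensity of the
annotated area. Both signatures are computed per region and averaged
per-region-then-mean (pooling all annotated pixels instead is a
documented alternative reading).

## Speckle-noise estimation

Speckle is modelled as Poisson count noise: an observed pixel is
$\mathrm{Poisson}(\lambda c)/\lambda$ around its clean value $c$, so local
variance $\approx c/\lambda$. This reading makes the shape parameter
identifiable from the variance-versus-mean slope, which is the estimator's
contract: `estimate_noise_lambda()` tiles the image into 8×8 patches,
computes each patch's sample mean and variance, and returns the
reciprocal of the **median** variance/mean ratio. The median is the key
numerical choice: patches straddling anatomical edges have
structure-dominated variance and would wreck a least-squares slope, but
they are a minority of patches, which a median ignores. Constant images
(no noise signal) and non-positive slopes raise errors rather than
returning a value. Images are grouped as low ($\lambda < 20$), medium
($20 \le \lambda < 40$) and high ($\lambda \ge 40$) noise; the shared
endpoints of the printed groupings are resolved as half-open bins.

Recovery is validated on phantoms: over $\lambda \in \{5,10,20,40,80\}$
(the clinically observed range) the median estimate over 10 phantoms per
level lands within 20% of truth and is rank-monotone. Two caveats are
documented rather than hidden: clipping to $[0,1]$ slightly deflates the
variance of bright low-$\lambda$ pixels (biasing $\hat\lambda$ upward by
a few percent at $\lambda = 5$), and on real OCT the estimator inherits
the usual caveat of any residual-based method — structure that survives
the tiling appears as noise.

## Zone stratification

Three zones extend laterally from the geometric centre column of the
B-scan (the stated origin — no foveal registration is attempted): within
0.5 mm, 0.5–1.5 mm and 1.5–3 mm, using the per-image X scaling
(10.5 µm/px by default, so a 732-px scan spans ±3.84 mm and a thin
outermost strip falls in no zone and is reported as `none`). A region
belongs to its **centroid's** zone; straddling behaviour is therefore
deterministic, and pixel-wise splitting is out of scope. Zone and
noise-group stratifications use each rater's last round only.

## The synthetic module

`generate_phantom()` builds a 428×732 px B-scan at 10.5 × 3.8 µm/px: a
three-band vertical profile (dark vitreous, bright tissue with a ±6%
gradient, dimmer deep layer, cosine ramps between), elliptical fluid
regions (semi-axes drawn from 30–150 µm, so regions are round in physical
space despite anisotropic pixels) placed by rejection sampling inside the
tissue band with overlaps merged, intensity 0.05 against tissue 0.5, a
light Gaussian blur (σ = 0.7 px) for soft edges, then Poisson count noise.
It is a *phantom*, not an OCT simulator: no coherent-imaging physics, no
retinal anatomy, no shadowing artefacts. Consequently, passing tests show
the pipeline is correct and its directional findings are reproducible
under the stated error model — they do not certify behaviour on clinical
images with pathology that mimics fluid.

`simulate_annotator()` perturbs the truth per region: a miss with
probability `miss_rate`, a signed-distance boundary offset of
`boundary_bias_px` (positive = oversegmentation), smooth radial jitter of
SD `jitter_sd_px` (a coarse Gaussian field bilinearly upsampled, so the
boundary wobbles smoothly rather than pixel-wise), and Poisson-many small
spurious regions. Jitter and misses are multiplied by
`zone_decay`$^{\,\mathrm{zone}-1}$, degrading peripheral annotations. The
default panel (two experts, three juniors) encodes the qualitative
findings the package is designed to detect — juniors oversegment (bias
1.5–2.5 px vs 0.2–0.3 px), degrade with eccentricity (`zone_decay`
1.6–1.8 vs ~1), and miss more regions — tuned once to land experts near
IoU 0.9 and juniors near 0.4–0.6. They are presets defining the study
conditions, not estimates of any clinician. Default studies use 10
phantoms whose $\lambda$ values give five low-, three medium- and two
high-noise images, matching the emulated design's noise distribution;
error profiles are deliberately noise-*independent*, so the pipeline's
noise stratification acts as a null check.

Randomness is reproducible by construction: every (image, rater, round)
draws its own sub-seed from the root seed via a deterministic string
hash, so adding a rater never changes anyone else's masks.

## Problem sizes and determinism

Unit tests run on reduced phantoms (≈160×240 px, 2–4 regions); the
directional acceptance checks use the full default design — 20 root
seeds × (10 full-size phantoms, 5 raters, 2 rounds) — and the
speckle-recovery check uses 10 full-size phantoms per $\lambda$ level,
sizes chosen to keep Monte-Carlo error well below the effect sizes being
asserted. Evaluation itself is seed-free and byte-deterministic: repeated
runs on the same study produce identical CSV reports.

## Known limitations

* The phantom's background is piecewise-smooth; real B-scans contain
  layered texture that inflates tile variances, so absolute
  $\hat\lambda$ on clinical images should be read comparatively.
* The two-expert consensus is evaluated against raters who helped build
  it, which inflates expert scores (their TPR is 1 by construction under
  the intersection rule when they annotate a superset of the consensus);
  leave-one-out panels need ≥3 experts and are out of scope.
* Only binary single-biomarker masks are supported; multi-category
  agreement (and coefficients beyond $\kappa$/AC1) is a non-goal.
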