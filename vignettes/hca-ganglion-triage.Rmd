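---
title: "Hierarchical contextual analysis for ganglion-cell triage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical contextual analysis for ganglion-cell triage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ganglia)
```

This vignette is the package's own account of its model and the design
choices behind it: what is computed, why the defaults are what they are,
and what passing the synthetic tests does and does not establish.

## The diagnostic setting

Excluding Hirschsprung's disease means proving a negative: no ganglion
cells anywhere in the submucosal or myenteric plexuses of the sampled
bowel. A single convincing ganglion cell anywhere rules the disease out
at that level, so the operational task is rare-event detection with an
asymmetric cost: a missed cell risks an unnecessary resection. The
pipeline therefore triages rather than diagnoses — it surfaces the best
candidate images in ranked sets for a pathologist, who remains the
decision maker.

## The two-stage detection model

**Stain model.** Both the synthetic renderer and the unmixer share one
fixed two-stain Beer–Lambert model: optical density
$OD = C_h v_h + C_e v_e$ with Ruifrok-style unit vectors for hematoxylin
and eosin (`he_stain_matrix()`). `separate_stains()` inverts this 3×3
system per pixel and clips the two stain concentrations at zero. Because
the mixing is known exactly, unmixing can be validated against ground
truth (reconstruction RMSE < 0.05 OD on noise-free slides), which is the
reason a fixed linear model was chosen over adaptive stain estimation.

**Hierarchical stage.** `segment_layers()` classifies each image *row*
by its median hematoxylin/eosin density against fixed per-layer
signatures, smooths the label sequence with a running median (k = 15)
and expands to a per-pixel map. Medians, not means: cells and vessels
cover a minority of a row and must not drag it toward another layer's
signature. The permissible set is exactly {submucosa, muscularis
propria} and is immutable configuration; `hierarchical_filter()` keeps a
candidate iff its *centroid* lies in a permissible layer. Centroid
lookup (rather than any-overlap) is a single deterministic rule that
matches the encircling convention of the annotations; candidates
straddling a boundary are resolved by centroid alone. The contract for
the segmenter is an accuracy property on synthetic slides (≥ 0.99
pixel agreement at zero noise, ≥ 0.9 at default noise), not a specific
operator — any segmenter meeting it can be swapped in.

**Candidate stage.** Seeds are local maxima (15 px window) of the
Gaussian-blurred (σ = 3 px) hematoxylin channel above 0.6 OD. The blur
acts as a shape filter: a compact nucleolus- or nucleus-scale blob
survives it, while thin Schwann-like streaks and texture noise fall
below threshold. Per seed, four morphology features are measured in the
100 × 100 px patch:

* `nucleus_area` — fraction of pale (low-H, low-E) pixels in the 6–24 px
  ring: the large vesicular nucleus of a mature ganglion cell;
* `nucleolus_prominence` — central hematoxylin excess over the 8–18 px
  surround: the prominent nucleolus;
* `cytoplasm_abundance` — mean eosin in the 12–45 px annulus: abundant
  cytoplasm;
* `stain_ratio` — hematoxylin share of total stain in the 10 px core:
  separates intensely basophilic immature cells from eosinophilic
  background.

The base score is a fixed logistic over a weighted feature sum
(`detection_params()`; intercept −4, weights 3.0 / 1.2 / 2.2 / 1.5), by
construction monotone nondecreasing in the three morphology features.
Non-maximum suppression at 50 px keeps one candidate per soma, with the
stable tie-break (score desc, then y, then x) used everywhere ranks
matter. There are no learned weights anywhere: the published systems in
this space disclose no detector internals and no trained model exists to
reproduce, so the package substitutes a classical, fully deterministic
detector whose quality is asserted only on synthetic data.

**Contextual stage.** `contextual_rescore()` computes, per candidate:
cluster size (single-linkage components of the ≤ 300 px distance graph —
a few soma diameters, so one plexus cluster stays one component),
companion density (fraction of blurred-H ≥ 0.35 pixels in the 50–150 px
annulus, restricted to permissible layers so band borders do not leak
foreign texture in) and vessel proximity (distance-decayed presence of
near-white lumen blobs of 100–4000 px² inside permissible layers, zero
beyond 300 px). The update is

```
contextual = clip(base × (1 + 0.25·min(cluster−1, 3)/3
                            + 0.15·min(companion/0.15, 1)
                            + 0.10·vessel), 0, 1)
```

followed by pruning below a 0.05 floor, iterated to a fixed point (cap
10 iterations). Feedback realized as rescore-and-prune is a deliberate
choice: pruning is monotone, so termination is guaranteed and
idempotence is testable. The companion and vessel detectors are
fixture-calibrated heuristics matched to the synthetic renderings, not
biologically validated operators — a limitation stated openly. An
isolated candidate with no context keeps exactly its base score, and
adding a neighbour can never lower another candidate's score.

## Triage and decision layer

Candidates from all slides of a case compete in one ranking. The top 36
by contextual score are grouped, in rank order, into consecutive triples
— up to 12 sets of 3 — and each set is scored by its best member: a set
is reviewed for *any* ganglion cell, so its evidence is its strongest
image. A partial final set is kept rather than dropped or padded,
because discarding candidates could hide the only ganglion cell of the
case. The case-level AI score is the mean of the 3 highest set scores
(mean of what exists below 3 sets; 0 for none — both degenerate rules
are package conventions, recorded here because the protocol leaves
"when applicable" undefined).

Pathologists score each set 1–5 (1 = certainly no ganglion cells, 5 =
certainly present); scores are immutable once recorded (audit
integrity). Classification follows the printed criteria exactly:

* expert — Positive iff any set scored 5, else Negative;
* non-expert — Positive iff ≥ 2 sets scored 5; otherwise Negative when
  the average AI score is < 0.6 and Doubt when ≥ 0.6 (boundary
  Doubt-inclusive). Doubt requires expert consultation, and
  `resolve_consultations()` refuses to finalize a Doubt case without an
  expert label — the safety property that a high-AI case can never end
  Negative unseen by an expert.

The known failure mode of the non-expert rule — two inaccurate 5s yield
an unconsulted false positive — is implemented as printed, not patched.
A case with no image sets is classified Negative under both rules
(nothing found, nothing to score), flagged in the classification basis.
`consultation_statistics()` reports per-observer consultation counts and
rates and the exactly-k cross-observer distribution, percentages at two
decimals with denominators stated explicitly.

## The synthetic generator

`generate_slide()` renders anatomy as horizontal bands (epithelium at
the top, then mucosa, submucosa, muscularis propria, serosa, background
below) so the layer ground truth is exact and the hierarchical stage is
testable against it; curved biopsy geometry is deliberately out of
scope. Default band fractions 0.08/0.22/0.30/0.30/0.10 give both
permissible bands ample room for full-size cells at the default
768 × 768 px. The geometry scale is tied to `pixel_size_um`: the mature
soma is modelled as 25 µm across, so the default 0.25 µm/px yields the
reference ~100 px soma. No physical calibration is claimed — the
magnification of the reference systems is stated only loosely, so the
pixel size is a modelling choice exposed as a parameter.

Mature cells (soma r = 48 px, pale nucleus r = 20, dark nucleolus r = 5,
eosinophilic cytoplasm) are grouped into clusters (mean size 3) inside
permissible bands, each cluster with a nearby vessel (white lumen,
eosinophilic rim) and six thin Schwann-like streaks; immature cells
(soma r = 16, darker scant intensely stained cytoplasm, no distinct
nucleolus) sit near the clusters; mimics (small dense basophilic blobs)
are placed *only* in epithelium/mucosa/serosa. Gaussian texture noise
(default σ = 0.05 OD) is added to the concentration maps last, so it
affects objects and background alike. Placement is rejection sampling
with a growing search radius; if a cluster becomes too crowded the
spacing falls back (108 → 72 px, still above the 50 px suppression
radius), and bands too thin for a cell raise an explicit error rather
than silently truncating. Every stochastic step runs under one explicit
integer seed via `withr::with_seed`, so a spec fully determines every
byte of the bundle.

Cohorts (`generate_cohort()`) label cases HSCR (zero ganglion cells),
non-HSCR (at least one) or inadequate — a superficial biopsy rendered
with epithelium and mucosa only, hence no permissible layer and
necessarily no ganglia, which the pipeline must classify Negative.

What the generator does **not** emulate: curved or fragmented biopsy
geometry, crypt architecture, staining variability between labs,
scanner artifacts, multi-resolution pyramids, serial-section
persistence. Passing the synthetic benchmark therefore shows the
pipeline's logic is sound under the stated morphology model; it says
nothing about performance on clinical slides, and the detector makes no
such claim.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, x right, y down; polygons are open rings;
  annotation XML prints coordinates at 2 decimals and round-trips
  exactly at that precision.
* Ties in every ranking break by (score desc, y asc, x asc); repeated
  runs are byte-identical.
* The 0.6 Doubt boundary is inclusive exactly as printed.
* All-black images are rejected by the unmixer (log undefined); blank
  images segment to all-background with a warning, not an error; empty
  candidate lists flow through every stage as empty results.
* Patch boxes shrink at image borders instead of discarding the
  candidate.
* The cell-by-cell specificity needs a negative unit the protocol never
  defines; the package uses explicit decoy locations sampled uniformly
  in ganglion-free regions (default 10 per truth cell), a decoy counting
  as correctly rejected iff no detection lies within 50 px.

## Problem sizes used by the tests

Unit tests run on 480 px slides with 3–4 cells; the acceptance benchmark
uses twenty 768 px slides (200 planted cells, ~2000 decoys) and a
10-case cohort — sizes chosen so the whole suite exercises every stage
end to end in a couple of minutes on one CPU. On this benchmark the
suite asserts cell-level sensitivity ≥ 0.90 and specificity ≥ 0.95, and
that every ganglionic case surfaces at least one true ganglion cell in
its presented sets; these thresholds are properties of the synthetic
fixture, deliberately distinct from any clinical performance figure.

One scale caveat: on clinical whole slides the presented patches are a
vanishing fraction of tissue area, but the ratio depends on slide size —
a patch is a fixed physical object size. On 768 px synthetic slides the
36-patch budget is a substantial fraction of the slide, so
`patch_area_fraction()` reports the ratio instead of asserting a
whole-slide bound.

## Known limitations

* The detector and the contextual heuristics are calibrated to the
  generator's morphology model; clinical use would require re-validation
  of every stage, and the layer segmenter in particular assumes banded
  anatomy.
* Meissner vs Auerbach plexus is not distinguished; the permissible set
  treats submucosa and muscularis as one class of admissible locations.
* Context is single-image: serial-section persistence, a real clue for
  immature cells, is out of scope.
* Biopsy adequacy is not determined by the pipeline — an inadequate case
  is simply expected to come out Negative, mirroring how such samples
  behave (no permissible layer, no candidates).
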