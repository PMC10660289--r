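---
title: "Myelin ground truth: detection, vector annotation, adjudication and scoring"
author: "myelinGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin ground truth: detection, vector annotation, adjudication and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinGT)
```

## The measurement model

Myelin in multi-spectral fluorescent z-stacks is defined operationally:
a pixel is *candidate myelin* when the oligodendrocyte membrane channel
and the axon channel are both above threshold there, after pixels that
belong to cell bodies have been removed. Cell bodies are in turn defined
as the overlap of the nucleus channel with the cellular marker (the
oligodendrocyte membrane stain), optionally dilated to cover the soma's
halo. Per z-section:

$$ \mathrm{cand} = \bigl(O \setminus \mathrm{dilate}_r(N \wedge O)\bigr) \wedge A $$

followed by removal of 8-connected components smaller than a
user-chosen area. Candidates are deliberately a *superset* of true
myelin: distinguishing genuine wraps from chance co-localization
("false-positive pixels") is exactly the judgement the human annotator
adds, so the package's job is to hand annotators the smallest honest
superset and then to score their decisions against an adjudicated gold
standard by pixel precision,

$$ \mathrm{precision} = 100 \cdot \frac{TP}{TP + FP}. $$

Every operation is strictly per z-section. Optical sections (typically
1 µm apart) are reviewed with their −1/+1 neighbours visible
(`z_context()`), but masks are never merged across z: myelin wriggles
through sections, and conflating sections would double-count it.

### Assumptions

* The three channels are pixel-aligned and share dimensions and depth;
  stitching and registration are upstream concerns.
* Intensity is non-negative integer data, 8- or 16-bit; channel
  identity is semantic, so RGB pages are rejected rather than silently
  reduced.
* The evaluation unit is the pixel. No shape prior beyond the
  minimum-component-area filter is imposed, because the field's shape
  and size criteria are not quantified anywhere we could cite; the area
  threshold is therefore an explicit user parameter with default 0, not
  a claim about the reference method.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `binarize_method` | – | `"otsu"` | per-section Otsu adapts to section-wise illumination; `"fixed"` is available when thresholds are calibrated externally |
| `fixed_threshold` | intensity | 128 | midpoint of the 8-bit range; meaningful values are data-specific and should be set per channel |
| `cell_body_dilation_px` | px | 0 | somata halos vary with magnification; 0 removes only the literal overlap |
| `min_component_area_px` | px | 0 | strict `< area` removal; 0 keeps everything, larger values encode a minimal myelin fragment size |
| `thickness` (vectors) | px | 1 | odd only, so the disk is centred; even requests error rather than round |
| `simplify_tol` | px | 0 | 0 is lossless (see below); > 0 trades fidelity for fewer vertices |

Binarization uses the convention *foreground iff intensity ≥ t*. The
Otsu threshold maximizes between-class variance over every level of the
dynamic range; ties are broken toward the lower threshold so results
are deterministic, and an all-constant plane (no two classes) yields an
empty mask with a warning instead of an arbitrary split.

## Vector annotations and the mask ↔ vector conversions

A marking is a polyline of 0-based integer pixel coordinates with an
odd thickness and a source label. Rasterization is Bresenham's line
algorithm followed by dilation with the digital Euclidean disk of
radius `(thickness − 1)/2` — binary and pixel-exact, which is why
polygon buffering with anti-aliasing was rejected. Serialization is an
open JSON schema (`.iev.json`); the reference tool's binary project
format is undocumented, and this package deliberately defines a
readable format of the same role instead of reverse-engineering one.
All invariants (unique ids, odd thickness, half-open bounds, `z <
depth`) are re-validated on read.

Converting a binary mask to vectors (`vectorize_mask()`):

1. Zhang–Suen thinning to a 1-px skeleton.
2. Decomposition into maximal branch-free paths, split at junction
   pixels (≥ 3 skeleton neighbours, 8-connectivity). A junction pixel
   terminates every incident path, so the union of paths covers the
   skeleton; pure cycles are cut at their lexicographically smallest
   pixel, and adjacent-junction clusters are traced greedily in
   deterministic order.
3. Simplification. At tolerance 0 only interior points of
   constant-direction runs are dropped. This is provably lossless:
   Bresenham redraws a constant-step run exactly. Classical
   Douglas–Peucker is **not** lossless at tolerance 0 — a vertex can
   lie exactly on its ancestor chord yet off the segment joining the
   finally kept neighbours, after which Bresenham redraws a different
   pixel chain — so Douglas–Peucker is reserved for `simplify_tol > 0`,
   where approximation is requested explicitly.
4. Thickness estimation. With `dt` the Euclidean distance transform of
   the input mask (image border treated as background), each path gets
   the odd integer nearest to the path mean of `2·dt − 1`, ties toward
   the thinner value. The centreline of an ideal band of width `2k + 1`
   sits at `dt = k + 1`, so the estimator is exact on constant-width
   strokes. Near skeleton junctions `dt` reaches √2–2 even on genuinely
   1-px structures; averaging `2·dt − 1` (decision boundaries at
   half-integer mean `dt`) keeps such paths at thickness 1, which the
   naive `2·mean(dt)` rule does not.

Conversion *overwrites*: `replace_with_converted()` returns only the
converted vectors, regardless of what the set held, mirroring how
loading an external candidate image replaces a drawing session.

Together these choices give the round-trip guarantees the tests
enforce: `rasterize(vectorize(M)) = M` exactly for thinning-stable 1-px
masks at tolerance 0, and for uniform-width strokes the result is
sandwiched between the skeleton and the 1-px dilation of `M`.

## Adjudication and scoring

Merging never fuses: a `merged_annotation` holds both sources verbatim,
and edits (delete, trim, draw) apply to one source's set at a time. The
gold standard is purely the rasterization of the adjudicated set; the
experts' sets are logged for provenance but do not leak into the gold
masks.

Scoring restricts to an evaluation domain — by default the candidate
mask when one is available, since annotators are scored on the pixels
they were asked to adjudicate. Precision with `TP + FP = 0` is
*undefined*, raised as a typed error rather than coerced to 0 or 100;
`build_report()` keeps such rows as `NA`, excludes them from averages
and warns. The overall figure is the mean of per-annotator means
(matching how per-expert averages pool into an overall average in the
tables this workflow reproduces); the pooled per-row mean is also
reported, because with unequal image counts per annotator the two
differ and the choice should be visible. Display rounding is half-up to
2 decimals (base R's round-half-to-even would print the mean of 36.23
and 60.54 as 48.38); full precision is retained internally.

## What the synthetic generator emulates — and what it does not

`generate_stack()` draws smoothed random walks (per-step heading change
N(0, `step_sigma`), default 0.25 rad) that drift to a neighbouring
z-section with probability `z_drift_p = 0.05` per step, emulating
fibers that wriggle in x-y-z. True fibers are rasterized into *both*
membrane channels and independently thinned by per-channel pixel
dropout (`granularity_p = 0.15`) — the granular staining an annotator
must bridge. Distractor fibers appear in only one membrane channel;
crossings of opposite-channel distractors are the generator's
irreducible false-positive source, and the generator records them so
tests can verify that every detected candidate is either gold or such a
crossing. Nuclei are filled disks with matching oligodendrocyte signal
underneath (cell bodies); they are placed so that their slightly
dilated disks avoid gold fibers, which keeps "cell-body removal
consumes no true myelin" an exact invariant rather than a statistical
one. Gaussian noise (`noise_sigma = 8` on an 8-bit scale) is added last
and clipped.

Defaults — 256 × 256 px, 3 sections, 12 fibers of thickness 3 px and 80
steps, 6 distractors, 6 nuclei of radius 8 px, intensities 200 over
background 20 — are chosen once as a realistic small field at confocal
scale and are not tuned per test.

The generator does **not** emulate: the microscope's point-spread
function and optical crosstalk, intensity falloff with depth,
continuous 3-D fiber geometry beyond ±1-z drift, or textured
background. Consequently, passing tests demonstrate the *algorithms'*
correctness (set algebra, connectivity, round trips, score recovery) on
data with the right gross structure; they do not certify detection
parameter choices for any particular real stain.

`corrupt_annotation()` simulates an imperfect annotator with planted
rates: vectors are deleted with probability `fn_rate`, and short
spurious strokes are added wholly off-gold (and disjoint from each
other) until the off-gold fraction of annotated pixels reaches
`fp_rate`, so recovered precision is `100·(1 − fp_rate)` up to
whole-stroke granularity. This closes the loop: the scorer recovers a
rate the generator planted, a parameter-recovery test rather than a
self-comparison.

## Numerical and degenerate-input choices

* 8-connectivity everywhere components or skeleton neighbours are
  involved; deterministic tie-breaks (lowest Otsu threshold, first
  maximum in Douglas–Peucker, lexicographic pixel order in path
  tracing).
* Masks are per-section logical matrices; coordinates are 0-based with
  x = column, y = row, z = page, stated once and used everywhere,
  including the JSON schema.
* Empty inputs have defined results: empty mask → empty vector set;
  empty annotation set → all-zero gold; empty precision list → error;
  undefined precision → typed error, excluded from averages.
* All randomness flows through explicit integer seeds; the pipeline
  writes no timestamps into artifacts, so reruns are byte-identical and
  every stage logs md5 digests plus pixel counts for audit.

## Problem sizes in the test suite

The suite exercises detection against a brute-force per-pixel reference
on one hundred 64 × 64 × 3 stacks, serialization identity on one
thousand randomized annotation sets, and rate recovery on a
512 × 512 × 2 scene with more than 10⁴ gold pixels — sizes at which the
brute-force oracles (explicit loops, exhaustive threshold search,
flood fill) remain an independent, readable ground truth.

## Known limitations

* Zhang–Suen thinning can shorten stroke tips by a pixel and produces
  small spurs on noisy blobs; vectorization guarantees are stated for
  thinning-stable masks and uniform-width strokes.
* Thickness is a per-path scalar; strokes of genuinely varying width
  are approximated by their mean width.
* Cross-source fusion of markings is deliberately out of scope:
  adjudication is a human act, and the package only records its result.
* The detector's free parameters default to neutral values (no
  dilation, no area filter) and must be calibrated per dataset; the
  package makes no claim about the reference implementation's internal
  settings.
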