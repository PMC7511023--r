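---
title: "Semi-automated stereological alveolar morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated stereological alveolar morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmorph)
```

## The problem

Quantifying alveolar structure — how large the airspaces are, how much of
the parenchyma is septal tissue — is the primary read-out in research on
bronchopulmonary dysplasia, emphysema and fibrosis. The unbiased way to do
it is stereology: overlay a fixed system of test points and test lines on
randomly sampled 2-D fields and count, per field,

* `Pnon-par` — grid points on non-parenchymal structures (conducting
  airways, vessels, pleura), which are excluded from the reference space;
* `Pref = 64 - Pnon-par` — points on reference parenchyma;
* `Psep` — points on septal tissue;
* `I` — intersections of the air–tissue interface with the test lines.

Manual counting is slow and shows substantial inter-observer variability.
`lungmorph` automates the counting on segmented binary masks while keeping
the two genuinely judgment-laden steps manual: outlining non-parenchymal
tissue and marking alveolar exudates the automatic filter cannot catch.
Both arrive as ROI files instead of interactive selections, which makes
runs reproducible and scriptable.

## The pipeline

Each field is standardized to a 680×680 px, 8-bit grayscale raster at
0.735 µm/px, so a field spans a nominal 500×500 µm (499.8 µm exactly;
the constant is treated as exact). Then, per field:

1. **Threshold.** Tissue is darker than air on H&E, so tissue =
   intensity ≤ t. One threshold serves a whole batch (set on the first
   image, under the assumption of uniform staining and microscope
   settings); `suggest_threshold()` provides an Otsu starting value.
2. **Automatic exudate filter.** Every 8-connected tissue component of
   1–1000 px that does not touch the image border is removed. Exudates in
   contact with septa, or larger than 1000 px, must be selected manually.
3. **Manual selections.** Pixels inside non-parenchyma and manual-exudate
   polygons are blanked to air.
4. **Mask cleaning.** Enclosed air holes of 1–200 px are filled; a
   radius-2 binary majority filter suppresses salt-and-pepper outliers;
   one morphological closing with a 3×3 square element smooths the
   outline.
5. **Edges.** The air–tissue interface is the inner tissue boundary:
   tissue pixels with an air 4-neighbour (mask minus its erosion by the
   3×3 cross). It is one pixel thick by construction and the image border
   is never an edge.
6. **Counting.** A central 567×567 px counting frame holds 8 horizontal
   and 8 vertical test lines of 567 px; the 64 grid points are their
   crossings. `Psep` counts grid points on clean-mask tissue; `I` counts
   maximal contiguous runs of edge∧line pixels (one run = one
   intersection, mirroring particle counting on the AND image).

Per subject, counts are accumulated across fields and converted as ratios
of sums — never as means of per-field ratios:

$$V_{V,sep} = \frac{\sum P_{sep}}{\sum P_{ref}}, \qquad
L_m = 2 d \, \frac{\sum P_{ref} - \sum P_{sep}}{\sum I},$$

with unit test-line length d = 104 µm per point. Two companion read-outs
use the same counts: the mean transsectional wall length
$L_{mw} = 2 d \sum P_{sep} / \sum I$ and the airspace surface density
$S_{V,air} = 2 \sum I / (d \sum P_{ref})$. Their exact printed forms are
not fixed by the validation study (which cites them); the standard
stereological estimators above are adopted, and the identities
$L_m + L_{mw} = 2 d \sum P_{ref}/\sum I$ and
$L_m = 4 (1 - V_{V,sep}) / S_{V,air}$ hold exactly and are tested. With a
total lung volume, densities convert to absolute quantities
($V_{sep} = V_{V,sep} \cdot V_{lung}$, $S_{air} = S_{V,air} \cdot V_{lung}$).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| scale | 0.735 | µm/px | fixed working resolution after resize |
| field size | 680×680 | px | standardized raster |
| frame | 567×567, inset 56 | px | central counting area |
| lines / points | 8+8 / 64 | — | test system (multiply via `density`) |
| d | 104 | µm | unit test-line length per point |
| threshold | per batch | intensity | tissue/air cut, `"otsu-first"` or fixed |
| exudate filter | 1–1000 | px | auto-removed component sizes |
| hole filling | 1–200 | px | enclosed air filled during cleaning |
| closing | 1 × 3×3 box | — | dilate–erode smoothing, `closing_iter` |

Note `d` is nominally 104 µm while the realized geometry gives
141.75 px × 0.735 µm/px = 104.19 µm per point; the nominal value is kept
for read-outs (a −0.2 % effect on `Lm`), and is configurable.

## Design choices where the procedure was open

* **Grid and line placement.** Counts and lengths are fixed by the
  counting convention, offsets are not. Line k (k = 0..7) sits at pixel
  56 + round((k + 0.5)·567/8), centring each line in one of eight equal
  strips. Any fixed placement is stereologically valid for batch
  comparison; this one is frozen for symmetry.
* **Threshold polarity** is tissue = intensity ≤ t (H&E tissue is dark);
  RGB converts to gray by the unweighted channel mean; resizing is
  bilinear and precedes thresholding.
* **Connectivity pairing** is the standard complementary one:
  8-connectivity for tissue components, 4-connectivity for air holes.
* **Edge side.** The inner tissue boundary guarantees a 1-px edge on
  binary input. It shrinks each airspace by one pixel per side, a known
  small negative contribution to `Lm`.
* **Intersection unit.** One maximal run of edge∧line pixels counts once,
  even where a line runs along a straight edge segment.
* **Non-parenchyma handling** is belt and braces: regions are blanked
  before cleaning and edge extraction, and grid points (boundary counts
  as inside) and intersection runs lying wholly inside them are also
  excluded at counting time.
* **Bland–Altman sign.** Relative differences are
  (method − reference)/average, so a method that underestimates shows a
  negative bias. `bland_altman(a, b)` computes (a − b)/mean; pass the
  method under evaluation first.
* **ICC form** is ICC(2,1): two-way random effects, absolute agreement,
  single measurement — the conservative choice where single-vs-average
  measures are not specified.
* **Outlier removal** parameters (radius 2, majority rule, ties keep the
  center, clipped at borders) suppress single-pixel noise without eroding
  septa; exposed in `clean_mask()`.

## The synthetic generators

**Wallpapers** emulate binary validation images: 2040×2040 px, square
tiles, and per tile the same combination of white geometric figures
("airspaces") placed uniformly at random without overlap against the black
"septal" phase. For axis-aligned squares and rectangles the rasterized
area is exactly Σarea and the theory values
$V_{V,sep} = (W^2 - \Sigma A)/W^2$ and $L_m = 4\Sigma A / \Sigma P$ are
exact; intercept counting with axis-aligned lines matches $4A/P$ exactly
in expectation for these figures. Circles are supported but carry a
systematic π/4 discrepancy between axis-aligned intercept counting of a
disc and the 4A/P formula — a plausible contributor to reported `Lm`
underestimation on such images — so the default validation set uses
squares and rectangles only.

`run_validation_experiment()` regenerates the validation study at its
original size: 11 images spanning VVsep ≈ 0.30–0.90 (`Lm` ≈ 46–209 µm, a
realistic alveolar range), 20 random, possibly overlapping 680×680 fields
per image, counted with the binary-input pipeline variant (the image is
already a mask, so exudate filtering and cleaning are skipped), and
per-image computed-vs-theory agreement summarized by identity regression
and Bland–Altman bias.

One measured property of this design is worth knowing: the counting
estimator is exactly unbiased over uniform field offsets, but a *single*
wallpaper realization with one large figure per tile retains a few percent
of design variance — a quadratic test grid sampling a quadratic tile
repetition weights image regions unevenly, and with coarse figures the
realized air fraction of the well-sampled region deviates from the global
one. This is the sampling-error mechanism one expects for such images,
visible here because ground truth is exact. Fine-grained compositions
(several ~90 px figures per tile) converge to theory well within 2 %
(VVsep) and 5 % (Lm) under dense sampling, and the convergence test uses
such a composition.

**Histology phantoms** emulate an H&E field for segmentation tests: an
airspace partition from ~45 seeded cells, its ridges dilated to ~7 px
septal walls, 2 vessel-like discs (r 25–50 px, area always above the
1000-px filter bound) and 5 exudate-like discs (100–900 px) planted with a
guaranteed 2-px gap from other structures, phase intensities 90 (tissue)
and 220 (air) with Gaussian noise (sd 12). Truth masks are pairwise
disjoint. Vessels are drawn at tissue intensity, as they stain: the
midpoint threshold on a noiseless phantom recovers septa ∪ vessels ∪
exudates pixel-exactly, and the automatic filter must then remove exactly
the planted exudates.

What phantoms do *not* emulate: staining gradients, out-of-focus blur,
touching exudates, irregular (non-disc) exudate shapes, and septa of
varying thickness. Passing the recovery tests therefore shows the filter
logic is right, not that real slides segment perfectly — on real data the
threshold choice and the manual selections remain the accuracy-critical
steps.

## Numerical and degenerate-input conventions

* A constant image has no tissue/air separation: `suggest_threshold()`
  returns 0 with a warning.
* ΣPref = 0 (all fields fully non-parenchymal) and ΣI = 0 with air
  points present raise structured `undefined read-out` errors rather than
  returning infinities; ΣI = 0 with no air returns `Lm = 0`.
* Mask stages (`raw → exudate_filtered → clean`) are enforced, so steps
  cannot be reordered silently.
* ROI vertices are clipped to the field on load; a polygon needs ≥ 3
  vertices; exudate/non-parenchyma overlap resolves to non-parenchyma.
* Wallpaper figure placement retries are bounded; infeasible packings
  fail loudly rather than overlapping figures.
* All generators and the batch runner are deterministic given their
  seeds; batch CSVs are byte-identical across reruns.

## Problem sizes used in the tests

The suite validates the full experiment at its original size
(11 × 20 fields, ~15 s). The closed-form oracle for `Lm` uses a single
square airspace counted with a 4×-densified system; line-count
quantization bounds the per-realization error at roughly
(line spacing)/(square side), so sides of 420–520 px keep every
realization within the 5 % tolerance while the estimator is exact in the
mean. Convergence and recovery properties run at 300 fields and 20
phantom seeds respectively.

## Known limitations

* No learned segmentation and no automatic vessel/airway detection —
  non-parenchyma and large or connected exudates are manual by design.
* No alveolar number estimation (disector methods) and no whole-slide
  ingestion; fields arrive as PNGs, sampled upstream or via
  `sample_fields()`.
* The 0–1000 px exudate bound and the 1–200 px hole bound are pixel
  counts at the fixed 0.735 µm/px scale; images acquired at other optical
  resolutions are resampled to this scale first, which is what makes the
  bounds comparable across batches.
* ICC confidence intervals and mixed-model extensions are out of scope.
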