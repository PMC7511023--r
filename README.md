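# lungmorph

Semi-automated stereological alveolar morphometry in R.

Researchers studying diseases that diffusely alter lung structure —
bronchopulmonary dysplasia, emphysema, fibrosis — quantify alveolar
architecture by stereology: a fixed test system of points and lines is
overlaid on randomly sampled fields of H&E-stained parenchyma and one
counts points on septal tissue and intersections of the air–tissue
interface with the test lines. Manual counting is slow and
observer-dependent. `lungmorph` automates the counting on segmented binary
masks while keeping the two judgment-laden steps manual as ROI files:
outlining non-parenchymal tissue (airways, vessels, pleura) and marking
alveolar exudates the automatic size filter cannot catch.

## What it computes

Fields are standardized to 680×680 px at 0.735 µm/px (a nominal 500×500 µm
field). A batch-wide threshold produces a tissue/air mask; unconnected dark
particles of 1–1000 px that avoid the image border are removed as exudates;
manual selections are blanked; the mask is cleaned (1–200 px holes filled,
majority filtering, one 3×3 closing) and its inner boundary taken as the
edge image. A central 567×567 px counting frame carries 8 horizontal and
8 vertical test lines (unit length d = 104 µm per point) whose 64 crossings
are the test points. Per subject, counts accumulate across fields as ratios
of sums:

    VVsep = ΣPsep / ΣPref                      septal volume density
    Lm    = 2·d·(ΣPref − ΣPsep) / ΣI   [µm]    mean linear intercept
    Lmw   = 2·d·ΣPsep / ΣI             [µm]    mean transsectional wall length
    SVair = 2·ΣI / (d·ΣPref)           [1/µm]  airspace surface density

with optional conversion to absolute volume and surface when a total lung
volume is known.

The package also ships the validation tooling: generators for binary
"wallpaper" images of geometric figures with exact area/perimeter ground
truth and for histology-like phantoms with known septa/vessel/exudate
masks, a random field sampler, and the agreement statistics used for
method comparison (regression against identity, Bland–Altman on relative
differences, ICC(2,1) for absolute agreement, Welch's t-test).

## Worked example

Count one field (here a generated histology-like phantom written to PNG;
real usage points at a folder of sampled lung fields):

```r
library(lungmorph)

ph <- make_histology_phantom(seed = 1)
write_synthetic(ph, "pup7_field01.png")

img <- load_field("pup7_field01.png")
t   <- suggest_threshold(img)         # 149 on this phantom
fc  <- count_field(img, roi_set(), t = t)
fc
#> <field_counts> pup7_field01.png: Pref 64, Psep 9, I 211 (t = 149)

subject_summary(list(fc), subject_id = "pup7")
#> <subject_summary> pup7 (1 fields)
#>   sums: Pnonpar 0, Pref 64, Psep 9, I 211
#>   VVsep 0.1406 | Lm 54.2 um | Lmw 8.9 um | SVair 0.06340 /um
```

Reading: 9 of 64 grid points fell on septal tissue (VVsep 0.14 — 14 % of
the parenchyma is septum) and the test lines crossed the air–tissue
interface 211 times, giving a mean airspace chord of 54 µm — a small,
densely septated airspace pattern. Batch processing works on folders
(`field.png` + optional `field.rois.json`) and writes per-field and
per-subject CSVs, a log of every exclusion, and QC overlay PNGs:

```r
rep <- run_batch(batch_config("fields/", "out/", threshold = "otsu-first", qc = TRUE))
rep$subjects
```

A thin CLI wraps the same functions
(`Rscript inst/cli/lungmorph.R count --input fields/ --output out/`, plus
`validate`, `phantom` and `report` verbs).

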