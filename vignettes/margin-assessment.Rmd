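---
title: "Ex vivo 3D ultrasound margin assessment against histopathology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ex vivo 3D ultrasound margin assessment against histopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonomargin)
```

## The problem

After surgical removal of a tongue squamous cell carcinoma, the
pathologist reports the resection margin — the closest distance from
tumor to the cut surface of the specimen. Margins under 5 mm are
"close" and may trigger adjuvant therapy, but the histopathological
verdict arrives days after the operation. Intra-operative 3D ultrasound
of the freshly resected specimen promises the same measurement within
minutes; the question is how well its distances agree with
histopathology. This package implements the comparison pipeline as
reusable, tested components: slide-to-ultrasound slice correspondence,
a reproducible partition of the resection surface, six distance
measurements per specimen and modality, and Spearman / Bland-Altman
agreement statistics — exercised end to end on a digital specimen
phantom with analytic ground truth, since the underlying clinical data
are not public.

## Data model and geometry conventions

The ultrasound side is a `label_volume`: a voxel grid with labels
0 (background / saline), 1 (specimen tissue), 2 (tumor), 3 (fiducial
channel), physical spacing in mm, and axis roles x = in-plane lateral,
y = in-plane depth, z = elevation along the motorized sweep, which is
also the anterior-to-posterior sectioning axis. The reconstructed
elevation spacing is 0.5 mm. The histology side is a `slide_stack`: one
2D label mask per 4 mm section, anterior first, with per-slide
mucosal-edge landmarks and an explicit orientation tag mapping image
axes to cranial/caudal (sutures and ink orient the physical specimen;
masks cannot encode that, so it travels as metadata). All distances are
computed in physical millimetres at pixel/voxel centers
(`world = origin + (index - 1) * spacing`); nothing is ever reported in
pixels.

## The measurement procedure

On every tumor-bearing slice a chord is drawn between the two mucosal
edge points. From its midpoint, two rays at ±45° (measured in mm space,
so anisotropic pixels cannot distort the angle) split the non-mucosal
boundary into three resection-surface regions — cranial, deep, caudal;
the boundary on the mucosal side of the chord is excluded. Four
quantities are measured per slice:

* **TT** — tumor thickness, the extent of the tumor projected on the
  chord-normal axis. The source study defines it only as "maximum
  thickness"; the chord-normal extent is adopted because it is
  rotation-consistent and well-defined for exophytic tumors (logged as
  an assumption).
* **M1/M2/M3** — the cranial, deep and caudal margins: the minimum
  Euclidean distance from any tumor pixel to the resection-surface
  pixels *of that region* (one value per non-empty region; an
  alternative convention — assign the single global closest point to
  its region — would leave regions without a value).

Distances use an exact anisotropic Euclidean distance transform
(separable lower-envelope algorithm in C++), so every margin equals the
brute-force minimum over all tumor x surface pixel pairs to machine
precision; the test suite asserts that equality literally.

Per specimen, anterior and posterior margins are measured along the
sectioning axis: on histology, tumor-free slides to the end cap x 4 mm
(the pathologist's counting rule); on ultrasound, the z-distance from
the tumor annotation to the end of the specimen annotation. An earlier
design used the full 3D distance to the end-cap surface, but on a
convex specimen that distance takes a diagonal shortcut across the
tapering nose and systematically undercuts the counting rule by
several millimetres even with identical geometry; the axial distance
is the construct both modalities share. The 4 mm quantization of the
counting rule remains, exactly as in clinical practice.

## Slice correspondence

Measurements are only comparable if made at the same location. The
matcher reproduces the study's two-step scheme. First, the annotated
specimen length L is divided by the number of slices M
(`nominal_positions()`). Second, each slide is refined within ±4 mm
(one slice — the sectioning uncertainty) using the fiducials: up to
three 1.7 mm (16-gauge) cannulas inserted roughly along the long axis
appear as channels in ultrasound and holes in histology. Per plane,
connected-component centroids give pairwise distances, sorted
descending so the profile is invariant to fiducial labeling; because
the cannulas are independently tilted, these distances vary linearly
with z and localize the plane.

Histology distances are first rescaled by a global factor (fixation
shrinkage otherwise dominates the residual). Matching then minimizes
the total profile residual subject to strictly increasing slice
indices, solved exactly by dynamic programming with an equal-spacing
penalty between consecutive matches (sections are equally cut). Three
numerical refinements proved necessary and are worth knowing about:

1. *Window centers.* L/M under-estimates the section spacing whenever
   the last section is only partially filled; windows are centered on
   spacing L/(M − 0.5) anchored at the anterior extent, and the spacing
   is re-estimated from the residual-matched slides (median of
   consecutive differences).
2. *Scale estimation.* The ratio of mean profiles is biased when
   fiducial visibility is asymmetric along z, and a wrong scale trades
   off against a coherent shift of all matches. The scale is therefore
   estimated by least squares at the geometrically anchored positions,
   which pins the offset.
3. *Unequal component counts.* Sorted tuples of different lengths
   compare different fiducial pairs; such planes are compared by
   nearest-subset matching with a penalty per missing component, and
   clipped components (much smaller than the largest in the plane) are
   rejected because their centroids are biased.

The study's final manual visual check is replaced by the reported
residual: nothing is silently thresholded, and slides without usable
fiducials are placed on the line fitted through the confident matches
(the automated analogue of a human extrapolating), or at the nominal
position when no fiducials exist at all. The greedy-with-backtracking
formulation suggested during design is replaced by the dynamic program:
the same decidable rule, globally optimal.

## Agreement statistics

Pairs are formed by an inner join on (specimen, slide, measure); a
slide where only one modality shows tumor (superficial tumors may be
invisible on ultrasound) becomes a counted discordant detection, never
a silent drop. Normality (Shapiro-Wilk, alpha = 0.05, both modalities)
is assessed once on the pooled pairs and selects Pearson or Spearman
for *all* strata, mirroring the single gate of the source analysis.
Spearman uses average ranks; p-values come from the two-sided
t-approximation, with an exact permutation enumeration available for
n ≤ 10. Bland-Altman agreement is the mean of the differences —
fixed direction US − histology, stated in every output header — with
95% limits d̄ ± 1.96·SD (normal-theory multiplier, not t-based).
`sensitivity_exclude()` recomputes the full report without named
specimens, reproducing the study's re-analysis after excluding its
stretched-and-pinned outlier patient. The pooled analysis treats
multiple slices of one patient as independent, exactly as the source
does; the clustering caveat is inherited knowingly.

## The phantom: what it emulates, what it does not

`phantom_config()` describes a continuous scene from which everything
else is derived analytically:

* a superellipsoid specimen (default half-axes 11 x 9 x 19 mm,
  exponent 2.5 — convex-ish, 38 mm long axis; the study reports no
  size statistics, so this is an assumption in the plausible 30-50 mm
  range), long axis along z;
* a mucosal sector of the boundary (default the upper 45°-135° band),
  whose intersection with each slice plane yields the two mucosal-edge
  landmarks analytically — the phantom must not require a human
  observer;
* an axis-aligned ellipsoidal tumor strictly inside the specimen;
* 0-3 straight cylindrical fiducials of diameter 1.7 mm with
  independent random tilts (≤10° by default). Parallel fiducials would
  make the distance profile constant and matching uninformative, so
  tilts are bounded away from zero; axes are re-drawn until they stay
  separated by more than one diameter over the whole length, because
  rigid cannulas cannot cross (and crossing channels merge into a
  single connected component, which produced degenerate profiles in
  early versions).

The histopathology transform applies, in order: uniform linear
shrinkage 1 − s (default s = 0.2, inside the 11.3-35% range reported
for fixation and paraffin embedding), an optional volume-preserving
stretch (z x F, in-plane x F^(-1/2); F = 1.3 emulates the pinned-out
outlier specimen — a pure z-stretch would leave the in-plane
measurements untouched and could not produce outliers), and an
optional smooth low-frequency in-plane warp (default amplitude 0: the
source quantifies only bulk shrinkage, so deformation is an
exploratory knob; keeping it in-plane means 4 mm sections remain planar
pre-images of planes). Sectioning cuts the transformed specimen into
4 mm blocks from the anterior end; each slide rasterizes the central
plane of its block — a 4 µm microtome slide samples one plane — except
the final, partially filled block, whose slide samples the center of
the remaining tissue.

Ground truth is computed on the continuous geometry to sub-voxel
accuracy: closed forms where available (support widths for TT,
point-to-ellipse distance by vectorized bisection on the KKT
parameter), dense boundary sampling (arc steps ~0.02 mm) where the
deformation makes curves non-elliptical. US voxels default to
0.2 x 0.2 x 0.5 mm (the in-plane spacing is not specified by the
source and must accompany any real dataset); histology masks to
0.1 mm.

What the phantom does *not* emulate: B-mode speckle or any acoustic
texture, the hypoechoic peritumoral inflammation halo (phantoms are
label-level — segmentation is assumed), split-and-reassembled slides,
and observer variability in the annotations themselves. A green test
therefore establishes the correctness of the geometry, matching and
statistics pipeline downstream of segmentation, not the difficulty of
segmenting real ultrasound.

## Numerical choices and degenerate inputs

* Distance transforms carry per-axis spacings and are exact; tests
  compare against brute force at tolerance 1e-12 (floating-point
  association is matched by construction).
* Rasterization accuracy: measured-vs-analytic error per slice
  measurement is bounded in tests by one in-plane pixel diagonal plus
  half the elevation spacing (the latter absorbs the quantization of
  the measurement plane along z).
* A single-pixel tumor yields TT = 0 with a thin-tumor warning;
  a region with no surface pixels yields an absent (NA) margin;
  a specimen with no tumor anywhere raises an error, matching the
  study's excluded patient.
* `estimate_shrinkage()` is the through-origin slope of histology on
  US over the per-slice measures only; end margins are excluded
  because their 4 mm quantization gives them leverage without scale
  information, and a free intercept would trade the resolution-offset
  against the slope.
* Margin classification: clear iff margin ≥ 5 mm, involved iff
  margin ≤ 0 (an added completeness category; only "close" is defined
  by the clinical convention), close otherwise; thresholds are
  configurable.
* Matching ties break toward the expected section position; with no
  usable fiducials the matcher reduces to nearest-to-nominal.

## Known limitations

* The ±1-slice matching guarantee is statistical, not absolute: the
  test suite asserts ≥95% of slides within ±1 slice across seeds at
  s = 0.2, and occasional ±2 matches occur where the fiducial pair
  geometry is nearly degenerate in a window.
* The equal-spacing prior assumes careful sectioning (the study used a
  cut-up device); heavily uneven manual sectioning would call for a
  weaker prior.
* End margins inherit the 4 mm step of the counting rule; their
  agreement is intrinsically coarser than the per-slice measures, as
  the source itself observes.
* Orientation for specimens cut obliquely to the anterior-posterior
  axis must be supplied via the stack's orientation tag; the package
  does not infer it.
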