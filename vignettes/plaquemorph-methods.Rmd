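---
title: "Segmentation and morphometry of OMSB-stained artery sections: methods and design"
author: "plaquemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plaquemorph methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemorph)
```

## The segmentation model

An OMSB-stained artery cross-section encodes tissue identity in color:
orcein stains elastic material purple, methyl blue stains collagen blue,
martius yellow stains erythrocytes yellow, crystal scarlet stains muscle,
fibrin and (with nuclear staining omitted) nuclei red to pink, and the
lumen and areas whose lipid dissolved during processing are unstained
white. The pipeline turns that code into compartment masks in five steps.

**1. Per-pixel color classification.** Classification happens in HSV
space because the stain classes are separated by hue while brightness
varies with staining intensity and illumination. The rule order matters:
`WHITE` is decided first (value ≥ 0.85 and saturation ≤ 0.15), because at
low saturation hue is numerically meaningless and a bright, faintly tinted
pixel must not acquire a spurious hue label. Chromatic pixels then fall
into hue sectors — yellow 40–70°, blue 190–260°, purple 260–320°, red/pink
320–40° wrapping through zero — provided they pass chroma gates
(saturation and value ≥ 0.15); everything else is `OTHER`. Shared sector
boundaries are resolved by the documented class order, so the result is
always a partition. No numeric thresholds for the original analysis were
ever published; these sectors are conventional hue ranges for the named
colors, every one of them exposed in the configuration file, and they
should be tuned to a lab's staining and camera before use on real slides.

The purple class is deliberately impure: orcein-positive material includes
cell nuclei, fibrin and foam cells besides elastic fibers. The color model
does not try to separate them — that separation is geometric and happens
in lamina detection.

**2. Lamina detection.** Elastic laminae are the only orcein-positive
structures that form large thin closed rings. Each 8-connected component
of the purple mask is morphologically closed with a disc (default radius
3 px) to bridge breaks — broken elastic laminae are common in
atherosclerotic media — and accepted as a lamina when the closed
component encloses a filled interior of at least `minEnclosedArea`
(default 500 px) and its mean thickness, computed as ring area divided by
the mean of the inner and outer boundary perimeters, is at most
`maxThickness` (default 15 px). Nuclei and foam cells are compact blobs
that enclose nothing; a filled scar or dense fibrin sheet that does
enclose area fails the thickness test. The original method also used
"texture" to recognise laminae; no descriptor was published, so this
implementation is purely geometric and says so. A convex-hull closure
fallback was considered and rejected: it would fabricate interior for
strongly concave vessels.

Accepted rings are ordered by enclosed area ascending, with deterministic
tie-breaking (smaller component pixel count, then topmost, then leftmost
centroid). The innermost interior must nest inside the outermost;
multi-vessel images are out of scope and rejected.

**3. Vessel partition.** The media is the area between the innermost and
outermost elastic lamina: the filled interior of the outermost ring
(ring included) minus the *strict* interior of the innermost ring. The
internal vessel area — plaque plus lumen — is the strict interior of the
innermost lamina. Whether the inner lamina's own pixels belong to media
or internal was left open by the source method; this package assigns them
to the media, on the reading that a boundary that "outlines" a region is
not part of it. The choice is a one-ring-thickness effect (a fraction of
a percent of either compartment at typical resolution) and is applied
consistently in the synthetic generator, so recovery comparisons are
convention-free.

**4. Lumen vs lipid.** Both are white; erythrocytes disambiguate. The
candidate regions are 8-connected components of (white ∪ yellow) pixels
inside the internal area. A component containing white pixels and at
least `minRbcPixels` erythrocyte pixels is lumen, erythrocyte pixels
included; white components without that many erythrocytes are lipid. A
component of erythrocyte pixels *only* — red blood cells entrapped in the
plaque matrix after intraplaque hemorrhage — is neither: the lumen rule
keys on membership in a white region, not on erythrocytes alone, which is
exactly what the entrapped-erythrocyte fixture of the test suite checks.
`minRbcPixels` defaults to 10 px at 0.5 µm/px; because it stands for "at
least about one erythrocyte", it scales with the inverse square of the
calibration (`defaultMinRbcPixels()`). Sections that graze the vessel can
legitimately contain no erythrocytes; the lumen then comes back empty
with a warning rather than an error.

**5. Plaque and collagen.** Plaque area is obtained by subtraction —
internal pixel count minus lumen pixel count — and is therefore a count,
not a mask. Collagen inside the plaque is the blue mask clipped to
internal ∖ lumen. Lipid is only ever assigned inside the internal area,
so slide background (also white) can never be counted as lipid.

Connectivity is the standard complementary pair: 8-connectivity for
foreground components, 4-connectivity for background when filling ring
interiors. Using the same connectivity for both creates topological
paradoxes (a diagonal ring would both enclose and leak); the pair is
verified in the tests against a breadth-first-search oracle.

## Morphometry

Absolute areas are pixel counts × calibration² (µm²); derived parameters
follow the standard formulas (total vessel area = media + lumen + plaque;
lumen and plaque relative to total; collagen and lipid relative to
plaque). Relative media area is computed as well, since per-section
reports conventionally print it. All arithmetic is double precision;
two-decimal rendering is presentation-only (display conventions in
published per-section legends mix truncation and rounding at the second
decimal, so reproduction checks use a 0.02-percentage-point tolerance
rather than guessing the intent). Ratios with a zero denominator are
explicitly `NA`: a plaque-free section must not masquerade as a section
with collagen-free plaque.

## Group statistics

The Mann–Whitney *U* statistic is computed from midranks, so ties
contribute half units. The two-sided p-value is exact when the combined
sample size is ≤ 12 and the data are tie-free — the null distribution of
*U* is enumerated by the box-partition recurrence and checked in the
tests against brute-force enumeration of all rank assignments — and
otherwise uses the normal approximation with tie-corrected variance and
continuity correction, which matches `wilcox.test(exact = FALSE,
correct = TRUE)` to machine precision (the reference implementation is a
cross-check in the tests, never the implementation). The original
analysis did not state whether its test was exact, nor its tie policy;
the branch rule above is this package's documented choice. Box summaries
use Tukey's scheme with quartiles by linear interpolation of order
statistics (R's default type 7 — no convention was stated in the source
analysis, so the most common one is used and documented), whiskers at the
most extreme observations within 1.5 × IQR of the quartiles, and
everything beyond listed as outliers. The ten compared parameters (six
absolute areas, four ratios) are each tested marginally at α = 0.05 with
no multiple-testing correction, mirroring common practice in this
literature; a Holm adjustment is available behind a flag.

## What the synthetic generator emulates — and what it does not

`generateSection()` renders an idealised cross-section: concentric
annular laminae (optionally broken by an angular gap), pink media and
plaque matrix, an eccentric circular lumen seeded with yellow erythrocyte
disks, blue collagen blobs and white lipid vacuoles in the plaque, white
background, and optional per-channel additive Gaussian noise clipped to
[0, 255] (the simplest stand-in for stain and illumination variability).
Ground truth is recorded before noise from the exact geometry, so truth
masks satisfy the segmentation algebra by construction. The default
geometry (outer lamina radius ~150 px, media ≈ one third of the vessel,
plaque ≈ half, collagen and lipid each ~10% of plaque at 0.5 µm/px) was
chosen once as a realistic advanced-lesion profile and is not tuned per
test.

The generator deliberately does *not* emulate: elastic fiber texture and
fine fibers in plaque, fibrous caps, pseudochondroplasia, fibrin age
classes, anti-aliased or chromatically aberrated edges, uneven
illumination, or staining gradients. Passing recovery tests on these
renders therefore demonstrates that the mask algebra, geometry handling
and thresholds are implemented correctly — not that the default color
thresholds will segment any particular lab's real slides, which have
continuous color distributions and require threshold calibration against
manual tracings (the published workflow validated its automatic
segmentation against free-hand tracing on 60 sections, with relative
differences within ±5% for media, lumen and plaque and < 7% for lipids;
`autoManualAgreement()` computes exactly those percentages).

Cohorts (`generateCohort()`) draw per-section geometry from documented
distributions and apply group effects analytically — e.g. a +20% plaque
effect moves the inner lamina outward at fixed lumen and media area, so
the true plaque area scales by the requested factor in expectation. All
randomness flows from one seed through per-section seeds drawn up front,
so single sections can be regenerated independently of cohort size.

## Numerical choices and degenerate inputs

* Rasterization: pixel centers, half-open image bounds, row-major origin
  top-left. Analytic-vs-rasterized area comparisons in the tests use a 2%
  tolerance; rotation by 90° permutes the pixel grid exactly, so areas
  are required to agree within 1%.
* A blank or vessel-free image raises a typed condition
  (`plaquemorph_no_vessel`) carrying diagnostics (component count,
  largest enclosed area) rather than a bare string.
* A single detected lamina cannot delimit media; callers may opt into a
  zero-width fallback (media = ring pixels only), used when degenerate
  sections should still yield internal-area statistics.
* Batch processing records per-section failures as rows instead of
  aborting, and result rows plus failure rows always equal the number of
  inputs; the fully resolved configuration is echoed next to the outputs.

## Problem sizes used in validation

The test suite and the acceptance script use 400 × 400 px sections
(segmentation takes well under a second each), 20 clean plus 20 noisy
sections for recovery checks, exhaustive *U*-test enumeration up to
combined size 10, 1,000 null simulations at n = 150/150 for the type-I
rate, cohorts of 150 + 150 for the power check and 500 + 500 for the
effect-size law-of-large-numbers check. These sizes were chosen so the
statistical assertions have comfortable margins at their stated bounds.

## Known limitations

* Color thresholds are hue-sector conventions, not a reproduction of the
  original (unpublished) threshold values; real-slide use requires
  calibration.
* One vessel per image; no serial-section registration; no whole-slide
  pyramidal formats (single-plane TIFF/PNG only).
* "Texture" in lamina recognition is approximated geometrically.
* No stain deconvolution or illumination correction; strongly uneven
  illumination will erode the WHITE/chromatic separation before it erodes
  the geometry.
* No detection of fibrous caps, buried caps, pseudochondroplasia or
  fibrin age classes; these remain qualitative readings.
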