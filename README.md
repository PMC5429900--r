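# plaquemorph

Automated segmentation and morphometry of atherosclerotic plaques in
polychrome-stained artery cross-sections.

## The problem

Combined orcein + martius scarlet blue (OMSB) staining gives murine artery
sections a color code that separates the tissue compartments relevant to
atherosclerosis: elastic laminae and fibers purple, collagen blue,
erythrocytes yellow, muscle/fibrin/nuclei red to pink, and unstained lumen
and dissolved-lipid areas white. That color separation is good enough to
segment a section automatically, which is what this package does for
researchers quantifying plaque burden in vessels such as the murine
brachiocephalic artery:

1. **Color model** — every pixel is classified in HSV space into one of six
   stain classes (`ELASTIC_PURPLE`, `COLLAGEN_BLUE`, `ERYTHROCYTE_YELLOW`,
   `RED_PINK`, `WHITE`, `OTHER`); all thresholds are named and
   user-overridable.
2. **Lamina detection** — elastic laminae are recognised in the purple mask
   as thin closed rings (after morphological closing, which bridges broken
   laminae); nuclei, fibrin and foam cells share the orcein color but
   enclose nothing and are rejected.
3. **Vessel partition** — media = area between the innermost and outermost
   elastic lamina; the inner lamina outlines the internal area (plaque +
   lumen); white regions with erythrocytes are lumen, white regions without
   are lipid; plaque = internal − lumen; collagen is masked inside the
   plaque by blue thresholding.
4. **Morphometry** — pixel counts × calibration² give areas in µm², plus the
   standard relative parameters:
   total vessel area *T* = media + lumen + plaque;
   relative lumen = lumen/*T* × 100%; relative plaque = plaque/*T* × 100%;
   relative collagen = collagen/plaque × 100%;
   relative lipid = lipid/plaque × 100%.
5. **Group statistics** — per-parameter two-group comparison with a
   Mann–Whitney *U* test (exact by enumeration for small tie-free samples,
   tie- and continuity-corrected normal approximation otherwise) and Tukey
   box-and-whisker summaries.
6. **Synthetic sections** — a generator renders OMSB-like cross-sections
   with exact per-compartment ground truth, so the whole pipeline is
   testable without slide material.

## Worked example

```r
library(plaquemorph)

# a synthetic section with known ground truth
tr  <- generateSection(sectionSpec(seed = 1))
seg <- segmentSection(tr$image)
computeMorphometry(seg, micronsPerPixel = 0.5, sectionId = "s1")
```

```
MorphometryRecord 's1' (unspecified)
  media        6351.0 um2 (34.11%)
  lumen        2826.0 um2 (15.18%)
  plaque       9444.0 um2 (50.72%)
  collagen    1099.00 um2 (11.64% of plaque)
  lipid        837.50 um2 (8.87% of plaque)
  total vessel  18621.0 um2
```

The vessel media covers 34% of this section, the plaque 51%, and collagen
and lipid occupy 12% and 9% of the plaque. For this noise-free render the
recovered areas equal the generator's ground truth
(`tr$truth@areasPx`) exactly.

Real micrographs go through the same calls
(`readSectionImage("section.png")` in place of the generator), batches
through `runBatch()` with a YAML configuration (see
`inst/extdata/default-config.yaml`), and two groups of sections are
compared with `compareSegments()`:

```r
coh <- generateCohort(150, c(plaque = 1.2), seed = 11)
cmp <- compareSegments(cohortRecords(coh))
cmp[cmp$parameter == "plaque_area_um2", c("u_statistic", "p_value", "significant")]
#   u_statistic      p_value significant
# 3        2482 1.802191e-31        TRUE
```

A thin command-line wrapper with `segment`, `batch`, `simulate` and
`compare` subcommands is at `inst/scripts/plaquemorph-cli.R`.

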