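# chromoquant

Quantitative analysis of pericentromeric heterochromatin (PCH) in
fluorescence microscopy and sequencing data. In mouse nuclei, PCH from
several chromosomes clusters into DAPI-dense **chromocenters**; whether a
chromatin mark (H3K27me3, H3K9me3, EZH2, BEND3, ...) accumulates there is
a recurring question in early-development and stem-cell epigenetics. This
package provides the four measurements that answer it, plus synthetic-data
generators with known ground truth so the whole pipeline is testable
without any external data.

## What it computes

**1. Chromocenter enrichment score (the core statistic).** Intensity
profiles of DAPI and a marker are sampled along a line across a
chromocenter midline (bilinear interpolation, sub-pixel spacing). The
chromocenter is delineated on the DAPI profile as the maximal contiguous
run of samples strictly above the profile mean that contains the global
DAPI maximum — the "bell above the average of the plot". Enrichment is the
sample Pearson correlation coefficient over that segment,

    PCC = cov(DAPI, marker) / (sd(DAPI) sd(marker)),  restricted to the segment,

which is 1 when the marker mirrors DAPI at the focus, ≈0 when the marker
is diffuse, and negative when the marker avoids the focus.

**2. Nuclear intensity levels.** Per-channel totals over a nucleus mask
after subtracting a local background (median over a 3-px annulus outside
the mask), normalised to DAPI; percent change between treatment groups and
two-sided Mann–Whitney tests (exact for small tie-free groups). A variant
quantifies a marker over a sub-nuclear region delineated on another
channel (e.g. the inactive X on EZH2).

**3. RNA-FISH focus counts.** Difference-of-Gaussians spot detection per
nucleus with a robust (median + k·MAD) threshold and minimum-separation
merge, tabulated into the categorical bins 0 / 1–2 / 3–4 / 5+ per
stage × lineage.

**4. Alignment-free satellite assays.** Directly on FASTQ files, with no
mapping: the percentage of reads containing one of eight major-satellite
motifs (a reverse-complement-closed set, exact substring match), and
percent bisulfite conversion at motif cytosines via C-wildcarded matching
— an inverse proxy of satellite DNA methylation.

## Worked example

```r
library(chromoquant)

# a synthetic nucleus whose marker colocalises with the chromocenters
syn  <- generate_nucleus_image(marker_mode = "colocalized", seed = 1)
ctr  <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
prof <- extract_profile(syn$image, ctr, half_length = 2.5)
seg  <- delineate_chromocenter(prof)
seg
#> <chromocenter_segment> samples 33..69 (peak 49), threshold 12298.724, 0 other run(s)
pcc_enrichment(prof, seg, "marker")[, c("pcc", "n_samples")]
#>         pcc n_samples
#> 1 0.9926505        37
```

The profile spans ±2.5 µm around the chromocenter centre; samples 33–69
(≈1.8 µm) rise above the profile-mean DAPI threshold, and over that
segment the marker tracks DAPI with PCC ≈ 0.993 — a fully enriched
chromocenter. A `"cloudy"` nucleus (marker in and around the focus) scores
≈0.35 and a `"diffuse"` one ≈0 under the same procedure.

An end-to-end run from the shipped demo configuration:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "chromoquant")
res <- run_pipeline(cfg, "demo_out")
res$tables$pcc_summary[, c("marker_mode", "n", "median")]
#>   marker_mode  n      median
#> 1      cloudy 12 0.375051416
#> 2 colocalized 12 0.993503608
#> 3     diffuse 12 0.004721015
```

which writes per-chromocenter PCC tables, FISH focus proportions,
satellite/bisulfite assay results, group comparisons and a provenance file
into `demo_out/`; re-running the same config reproduces every numeric
table byte for byte.

## Package layout

- `R/` — implementation: synthetic generators (`generate_*`), profile
  analysis (`extract_profile`, `delineate_chromocenter`,
  `pcc_enrichment`, `summarize_pcc`), intensity quantification
  (`measure_nucleus`, `measure_region`, `mann_whitney`), FISH counting
  (`detect_foci`, `count_fish_foci`, `bin_and_tabulate`), satellite
  assays (`count_satellite_reads`, `bisulfite_conversion`), and the
  config-driven `run_pipeline`.
- `vignettes/chromocenter-quantification.Rmd` — the methods account:
  model, assumptions, parameter choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests, each checked
  against independent brute-force oracles or planted ground truth.
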