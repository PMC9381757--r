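---
title: "Quantifying marker enrichment at chromocenters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marker enrichment at chromocenters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoquant)
```

## The measurement problem

In mouse interphase nuclei, pericentromeric heterochromatin (PCH) from
several chromosomes clusters into chromocenters — AT-rich, DAPI-dense foci.
Whether a chromatin mark such as H3K27me3 or H3K9me3 accumulates at these
foci is a question about the *spatial coincidence* of two fluorescence
channels, and the practical readout in embryos is simple: draw a line
across a chromocenter midline on a single optical section, record the DAPI
and marker intensity profiles along it, and ask how similar they are.

`chromoquant` implements this readout and the three companion
quantifications usually reported alongside it (whole-nucleus intensity
levels, RNA-FISH transcription-focus counts, and alignment-free satellite
read assays on FASTQ files), together with synthetic-data generators that
give every stage a known ground truth.

## The chromocenter enrichment score

Three steps, each a separate function so intermediate objects can be
inspected:

1. **Profile extraction** — `extract_profile()` samples the requested
   channels along a line through a chromocenter centre by bilinear
   interpolation at a fixed sub-pixel spacing of half the smaller in-plane
   pixel pitch. Half a pixel is fine enough that the profile shape is
   stable under sub-pixel shifts of the line, while inventing no resolution
   that the image does not carry. All channels share one sampling grid and
   positions are centred on the chromocenter (0 µm at the centre).
2. **Delineation** — a chromocenter appears on the DAPI profile as a
   bell-shaped curve rising above the average fluorescence of the plot.
   `delineate_chromocenter()` therefore thresholds at the arithmetic mean
   of the DAPI values *over the extracted profile* (not the nucleus or the
   image — the plot is the object the rule refers to) and returns the
   maximal contiguous run of samples strictly above that mean containing
   the global DAPI maximum. Strict comparison means a perfectly flat
   profile contains no chromocenter, which is reported as a distinct
   "not found" outcome rather than an error. Other above-mean runs (a
   second chromocenter clipped by the line) are ignored and counted.
3. **Scoring** — `pcc_enrichment()` computes the sample Pearson correlation
   between DAPI and marker restricted to the delineated segment. A marker
   that mirrors DAPI over the chromocenter scores near 1; a marker that
   avoids the focus scores near or below 0. Pearson correlation is
   invariant under positive affine transforms of either channel, so the
   score is insensitive to staining gain and offset. If either channel has
   zero variance over the segment the score is undefined and flagged —
   never silently set to 0.

```{r pcc-example}
syn <- generate_nucleus_image(marker_mode = "colocalized", seed = 1)
ctr <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
prof <- extract_profile(syn$image, ctr, half_length = 2.5)
seg <- delineate_chromocenter(prof)
pcc_enrichment(prof, seg, "marker")[, c("pcc", "n_samples")]
```

`summarize_pcc()` aggregates records by stage/lineage/marker into the
n-median-quartile summaries behind violin plots, excluding (and counting)
undefined records.

Design points worth knowing:

* Profiles are taken on a single z-plane — the plane of the DAPI maximum
  at the line centre when not specified — matching measurements made on a
  single section of a representative nucleus. The line direction defaults
  to the image x-axis and is freely orientable; for the isotropic foci the
  package simulates, direction does not matter, and for real data the
  midline is an analyst's choice.
* No smoothing or background subtraction is applied before correlation:
  the score is defined on the raw profile.
* One segment per profile: each plotted profile crosses one highlighted
  chromocenter, so runs not containing the global maximum are deliberately
  not scored.

## What the synthetic nuclei emulate

`generate_nucleus_image()` builds a circular (or spherical) nucleus with
Gaussian chromocenter foci (sd = radius/2, so the above-mean bell of a
typical profile spans roughly the nominal radius) placed by rejection
sampling — non-overlapping, fully inside the nucleus. The marker channel
has three modes mirroring the biological patterns:

* **colocalized** — marker foci share DAPI centres and widths; inside the
  nucleus the marker is an exact positive affine transform of DAPI, so the
  noiseless enrichment score is exactly 1. This is the fully enriched
  pattern of late cleavage stages.
* **cloudy** — the marker accumulates *in and around* the focus: a weak
  colocalised component (weight 0.5) plus a Gaussian shell centred at
  0.45 × the focus radius with sd 0.2 µm. The cross-profile is bimodal
  with a local minimum at the DAPI peak, yet the overall correlation over
  the above-mean segment stays mildly positive (median ≈ 0.35 at default
  noise). Both properties matter: a pure shell at the focus boundary
  reproduces the bimodal profile but drives the correlation strongly
  negative, which does not match the mildly positive scores that
  early-stage "cloud around the focus" patterns actually produce — hence
  the mixed model.
* **diffuse** — spatially uniform marker over the nucleus; the score is
  pure noise around 0. This is the post-implantation / primed pattern.

Noise is additive Gaussian (default sd 600 on a 16-bit scale, i.e. ~3 % of
the focus amplitude) with an optional Poisson shot-noise component
(`poisson_gain`); the defaults were chosen once so that the three modes
produce median scores near 0.99 / 0.35 / 0, the regime the in-vivo data
span. Defaults for nucleus radius (5 µm), focus radii (0.8–1.2 µm) and
focus count (4) are configurable and not claimed to be biological
distributions — stage-specific chromocenter statistics are simply not
identifiable from published section images.

What the simulations deliberately do **not** model: optical point-spread
functions, chromatic shift, anisotropic or textured chromatin,
photobleaching, and spatially varying background. Passing tests on this
synthetic data therefore demonstrate correctness of the *estimators*
(delineation, correlation, totals, detection) under controlled conditions,
not robustness to every artefact of real microscopy.

```{r ordering}
pccs <- sapply(c("colocalized", "cloudy", "diffuse"), function(mode) {
  median(sapply(1:20, function(i) {
    syn <- generate_nucleus_image(marker_mode = mode, seed = 100 + i)
    ctr <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
    prof <- extract_profile(syn$image, ctr, half_length = 2.5)
    pcc_enrichment(prof, delineate_chromocenter(prof), "marker")$pcc
  }))
})
round(pccs, 2)
```

## Nuclear intensity quantification

`measure_nucleus()` totals each channel over a nucleus mask after
subtracting a per-channel local background, and normalises marker totals
to the DAPI total. Choices:

* **Background** = median intensity over a 3-pixel annulus just outside
  the mask. The annulus keeps the estimate local to each nucleus; the
  median makes it robust to bright signal from neighbouring structures.
* Negative post-subtraction pixels are clamped to 0 (totals are totals of
  non-negative signal) and the clamping is flagged. Under noise this
  clamping adds the same small positive offset to every nucleus, which
  slightly compresses ratios between groups; planted fold-changes are
  recovered exactly in the noiseless regime and within a few percent at
  moderate noise.
* **Percent change** between groups is computed on group means of the
  DAPI-normalised levels (`percent_change()`), the form a single
  "x % reduction" summary takes.

`measure_region()` restricts the same measurement to a sub-nuclear region
delineated on another channel — the motivating case being the inactive X
territory delineated on EZH2. The region is the largest connected
component of defining-channel pixels above mean + k·sd of the nuclear
values (default k = 2; no published rule exists, so k is a documented,
configurable choice).

`mann_whitney()` compares two groups with the rank-sum test: the exact
null distribution when `n_a * n_b <= 64` with no ties, the
normal approximation with tie and continuity corrections otherwise, the
method used being recorded in the output. The exact branch is validated
in the test suite against exhaustive enumeration of all group assignments
for every size with `n_a + n_b <= 8`.

## RNA-FISH focus counting

The published readout is categorical — the proportion of cells with 0,
1–2, 3–4 or 5+ transcription foci — and was obtained by eye. The package
substitutes an explicit, parameterised detector (`detect_foci()`): a
difference-of-Gaussians band-pass at the spot scale (default sd 0.2 µm,
background scale 4×), local maxima inside the nucleus mask above a robust
threshold (median + k·MAD of the filtered in-mask intensities, default
k = 6), and a minimum-separation merge (default 0.5 µm) keeping the
brighter of nearby candidates. Robust statistics are essential here: the
spots being detected would otherwise inflate their own detection
threshold. In z-stacks, detection runs per plane and candidates within one
z-step merge, since diffraction-limited foci span few 0.5 µm sections.
All parameters travel with the result.

At the generator's default signal-to-noise (amplitude 20× the noise sd),
planted counts are recovered exactly for >90 % of nuclei (100 % in the
shipped tests) and pure-noise nuclei yield zero detections in ≥95 % of
fixtures. `bin_and_tabulate()` then applies the total binning map
0 → "0", 1–2 → "1-2", 3–4 → "3-4", ≥5 → "5+" and emits all four
categories per group with fractions summing to 1.

## Alignment-free satellite assays

Mapping short reads to tandem repeats is biased by multi-mapping and
reference representation, so satellite abundance is assayed directly on
the FASTQ: a read counts as a satellite read if any of eight major
satellite selection motifs occurs as an exact, case-insensitive substring.
The motif set contains both strands (it is closed under reverse
complement, verified at load), each read counts at most once, and the
result is a percentage of all reads. Exact matching is deliberate — the
whole point of the assay is to avoid fuzzy decisions; allowing mismatches
would define a different assay.

For whole-genome bisulfite data, `bisulfite_conversion()` matches reads
against C-wildcarded motif variants (each motif C may read C or T, all
other bases exact) and tallies every motif C position of every occurrence:
T = converted (unmethylated), C = protected (methylated). Percent
conversion is an inverse proxy of satellite DNA methylation. Two
conventions are documented rather than asserted: reads are matched as
given (no reverse-complementing — both strands' motifs are in the set),
and G-position wildcarding for complementary-strand bisulfite protocols is
not applied. One motif contains no cytosine; it contributes matches but no
assayed sites. Both assays stream the file in chunks, so memory use is
constant in the number of reads.

The paired generator `generate_fastq()` plants a Bernoulli fraction of
motif-bearing reads (background reads are rejection-sampled motif-free, so
planted counts are recoverable exactly) and, in bisulfite mode, applies
per-cytosine chemistry with known methylation rate and conversion
efficiency, giving an expected conversion of
`(1 - methylation_rate) * conversion_efficiency` at every assayed site.

```{r satellite}
fq <- tempfile(fileext = ".fastq")
g <- generate_fastq(fq, n_reads = 1000, satellite_fraction = 0.1, seed = 42)
count_satellite_reads(fq)
```

## Orchestration and reproducibility

`run_pipeline()` drives everything from a YAML config validated against
`default_pipeline_config()` (unknown keys are rejected; missing keys take
defaults). Each run writes TSV tables plus `provenance.yaml` carrying the
merged config, its MD5 hash and the package version. All randomness
derives from the single config seed, and numeric tables are written with
fixed formatting, so re-running an identical config reproduces every table
byte for byte — the only timestamp lives in the provenance file. A demo
config ships in `inst/extdata/demo_config.yaml`.

Problem sizes in the shipped tests and acceptance script — 100 nuclei per
marker mode, 200 FISH nuclei, 10,000-read FASTQ files, 20 nuclei per
treatment group — were chosen as the smallest sizes at which medians,
recovery rates and binomial estimates are stable to well within the
tolerances being checked.

## Known limitations

* Chromocenter delineation is profile-based, as in the motivating
  measurements; the package does not segment chromocenters volumetrically,
  and does not compute Manders or Costes colocalization.
* Nucleus masks are inputs (synthetic truth or external segmentation);
  the package does not segment nuclei from raw DAPI.
* The FISH detector's notion of a "focus" (band-pass scale, prominence,
  separation) is an explicit parameterisation of a judgement the original
  visual counts left implicit; on real data those parameters need tuning
  against a hand-annotated subset.
* The bisulfite assay reports a single conversion percentage over motif
  cytosines; it does not call per-context (CpG/CHH/CHG) methylation.
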