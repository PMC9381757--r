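Package: chromoquant
Title: Quantification of Marker Enrichment at Chromocenters, RNA-FISH Foci
    and Satellite Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the enrichment of chromatin marks (such as
    H3K27me3 and H3K9me3) at DAPI-dense pericentromeric chromocenters in
    fluorescence microscopy images of early mouse embryos and stem cells.
    Extracts sub-pixel intensity line profiles across a chromocenter
    midline, delineates the chromocenter as the above-mean bell of the DAPI
    profile, and scores enrichment as the Pearson correlation between DAPI
    and marker intensities over the delineated segment.  Also provides
    whole-nucleus intensity quantification with local background
    subtraction and DAPI normalisation, Mann-Whitney group comparisons,
    RNA-FISH transcription-focus detection with the 0 / 1-2 / 3-4 / 5+
    categorical tabulation, and alignment-free assays that count major
    satellite repeat reads and estimate bisulfite conversion directly from
    FASTQ files.  A synthetic-data module generates images and reads with
    known ground truth so every stage of the pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    EBImage,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
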