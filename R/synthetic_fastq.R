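## Synthetic FASTQ with a planted fraction of satellite-motif reads and,
## optionally, bisulfite chemistry with known per-cytosine methylation and
## conversion rates.

#' Generate a synthetic FASTQ file with planted satellite reads
#'
#' Writes `n_reads` reads of length `read_length`.  Each read is satellite-
#' bearing with probability `satellite_fraction`: one of the eight motifs,
#' chosen uniformly, is embedded verbatim at a uniformly chosen offset in an
#' otherwise random background.  Background (non-satellite) reads are
#' rejection-sampled to be motif-free, so the planted satellite count is
#' recovered exactly by any exact-substring counter on noise-free output.
#'
#' With `bisulfite = TRUE`, every cytosine of every read (background and
#' motif alike) is independently methylated with probability
#' `methylation_rate` (and then protected), or else converted C to T with
#' probability `conversion_efficiency` - so the expected conversion at any
#' C site is `(1 - methylation_rate) * conversion_efficiency`.  Conversion
#' is applied after motif embedding, emulating bisulfite treatment of
#' satellite DNA.
#'
#' Quality strings are constant `"I"` (Phred 40); the downstream assays
#' ignore qualities.  Output is deterministic under `seed`.
#'
#' @param path output path (`.fastq`, or `.fastq.gz` / `.fq.gz` for gzip).
#' @param n_reads number of reads.
#' @param read_length read length in bp; must be at least the longest motif
#'   (24 bp) so a motif can be embedded intact.
#' @param satellite_fraction probability a read carries a motif.
#' @param background_composition base frequencies (A, C, G, T) of background
#'   sequence.
#' @param bisulfite apply bisulfite chemistry.
#' @param methylation_rate per-cytosine probability of being methylated.
#' @param conversion_efficiency per-unmethylated-cytosine probability of
#'   C to T conversion.
#' @param motifs motif set (default [satellite_motifs()]).
#' @param seed RNG seed.
#' @return (invisibly) a list of class `synthetic_fastq`: `path`, `truth`
#'   (per-read data frame: `read_id`, `is_satellite`, `motif_index`,
#'   `offset`, and under bisulfite `n_C`, `n_methylated`, `n_converted`),
#'   `n_satellite_planted` and the generation parameters.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' g <- generate_fastq(fq, n_reads = 100, satellite_fraction = 0.1, seed = 1)
#' g$n_satellite_planted
#' @export
generate_fastq <- function(path, n_reads = 10000L, read_length = 50L,
                           satellite_fraction = 0.1,
                           background_composition = c(A = 0.25, C = 0.25,
                                                      G = 0.25, T = 0.25),
                           bisulfite = FALSE, methylation_rate = 0,
                           conversion_efficiency = 1,
                           motifs = satellite_motifs(), seed = NULL) {
  .assert(n_reads >= 1L, "n_reads must be positive")
  max_w <- max(nchar(motifs))
  .assert(read_length >= max_w,
          sprintf("read_length must be >= %d bp so a motif can be embedded intact",
                  max_w))
  for (p in c(satellite_fraction, methylation_rate, conversion_efficiency)) {
    .assert(p >= 0 && p <= 1, "rates must lie in [0, 1]")
  }
  .assert(length(background_composition) == 4L &&
            all(background_composition >= 0) &&
            sum(background_composition) > 0,
          "background_composition must give 4 non-negative frequencies")
  bases <- c("A", "C", "G", "T")
  comp <- background_composition / sum(background_composition)

  out <- .with_seed(seed, {
    is_sat <- runif(n_reads) < satellite_fraction
    ## base matrix: reads x positions
    mat <- matrix(sample(bases, n_reads * read_length, replace = TRUE,
                         prob = comp),
                  nrow = n_reads)
    motif_idx <- rep(NA_integer_, n_reads)
    offset <- rep(NA_integer_, n_reads)
    sat <- which(is_sat)
    if (length(sat)) {
      motif_idx[sat] <- sample.int(length(motifs), length(sat), replace = TRUE)
      for (i in sat) {
        m <- motifs[[motif_idx[i]]]
        w <- nchar(m)
        off <- sample.int(read_length - w + 1L, 1L)
        offset[i] <- off
        mat[i, off:(off + w - 1L)] <- strsplit(m, "")[[1L]]
      }
    }
    ## background reads must not contain a motif by chance
    paste_rows <- function(m) do.call(paste0, asplit(m, 2L))
    contains_motif <- function(s) {
      hit <- rep(FALSE, length(s))
      for (m in motifs) hit <- hit | grepl(m, s, fixed = TRUE)
      hit
    }
    bgi <- which(!is_sat)
    if (length(bgi)) {
      repeat {
        bad <- bgi[contains_motif(paste_rows(mat[bgi, , drop = FALSE]))]
        if (!length(bad)) break
        mat[bad, ] <- sample(bases, length(bad) * read_length, replace = TRUE,
                             prob = comp)
      }
    }
    truth <- data.frame(read_id = sprintf("read_%d", seq_len(n_reads)),
                        is_satellite = is_sat, motif_index = motif_idx,
                        offset = offset, stringsAsFactors = FALSE)
    if (bisulfite) {
      isC <- mat == "C"
      meth <- isC & matrix(runif(length(mat)) < methylation_rate, nrow(mat))
      conv <- isC & !meth &
        matrix(runif(length(mat)) < conversion_efficiency, nrow(mat))
      mat[conv] <- "T"
      truth$n_C <- rowSums(isC)
      truth$n_methylated <- rowSums(meth)
      truth$n_converted <- rowSums(conv)
    }
    seqs <- paste_rows(mat)
    qual <- strrep("I", read_length)
    recs <- rbind(paste0("@", truth$read_id), seqs, "+", qual)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    writeLines(as.vector(recs), con)
    close(con)
    list(truth = truth, n_satellite_planted = sum(is_sat))
  })
  out$path <- path
  out$params <- list(n_reads = n_reads, read_length = read_length,
                     satellite_fraction = satellite_fraction,
                     bisulfite = bisulfite,
                     methylation_rate = methylation_rate,
                     conversion_efficiency = conversion_efficiency,
                     seed = seed)
  class(out) <- "synthetic_fastq"
  invisible(out)
}
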