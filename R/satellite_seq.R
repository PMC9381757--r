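## Alignment-free satellite assays: count reads carrying a major satellite
## motif as a percentage of all reads in a FASTQ file, and estimate percent
## bisulfite conversion at the cytosines of those motifs.  Both operations
## stream the file in chunks (constant memory in the number of reads).

.SATELLITE_MOTIFS <- c(
  "GACGACTTGAAAAATGACGAAATC",
  "CATATTCCAGGTCCTTCAGTGTGC",
  "GAAAAAGGTGGAAAATTTAGA",
  "AGAAAACTGAAAATCATGGAAAAT",
  "GATTTCGTCATTTTTCAAGTCGTC",
  "GCACACTGAAGGACCTGGAATATG",
  "TCTAAATTTTCCACCTTTTTC",
  "ATTTTCCATGATTTTCAGTTTTCT"
)

#' The eight major satellite selection motifs
#'
#' The mouse major satellite sequences used to select satellite-containing
#' reads directly from FASTQ files.  The set is closed under reverse
#' complement - motifs 1/5, 2/6, 3/7 and 4/8 are reverse-complement pairs,
#' so both strands of the repeat are matched - and this pairing is verified
#' on every call.
#'
#' @return character vector of 8 uppercase DNA motifs.
#' @examples
#' satellite_motifs()
#' @export
satellite_motifs <- function() {
  m <- .SATELLITE_MOTIFS
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(m)))
  .assert(identical(rc[1:4], m[5:8]) && identical(rc[5:8], m[1:4]),
          "satellite motif set is not reverse-complement closed")
  m
}

## Apply `fun(seqs, offset)` to successive chunks of read sequences from a
## FASTQ file (plain or gzip).  Validates the 4-line record structure and
## fails with the 1-based record number on malformation.
.fastq_apply <- function(path, fun, chunk_size = 20000L) {
  .assert(file.exists(path), sprintf("no such FASTQ file: '%s'", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  n_reads <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L) {
      stop(sprintf("malformed FASTQ: truncated record %d in '%s'",
                   n_reads + length(lines) %/% 4L + 1L, path), call. = FALSE)
    }
    nrec <- length(lines) %/% 4L
    heads <- lines[seq.int(1L, by = 4L, length.out = nrec)]
    plus <- lines[seq.int(3L, by = 4L, length.out = nrec)]
    bad <- which(substr(heads, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
    if (length(bad)) {
      stop(sprintf("malformed FASTQ record %d in '%s'",
                   n_reads + bad[1L], path), call. = FALSE)
    }
    seqs <- toupper(lines[seq.int(2L, by = 4L, length.out = nrec)])
    fun(seqs, n_reads)
    n_reads <- n_reads + nrec
  }
  n_reads
}

#' Count satellite-containing reads in a FASTQ file
#'
#' A read counts as a satellite read if any of the eight motifs occurs as an
#' exact, case-insensitive substring of its sequence; each read is counted
#' at most once however many motifs it contains.  The result is reported as
#' a percentage of all reads in the file.  No alignment or mapping is
#' involved, which keeps the assay free of mapping biases against highly
#' repetitive sequence.
#'
#' @param fastq_path path to a FASTQ or FASTQ.gz file.
#' @param motifs motif set (default [satellite_motifs()]).
#' @param chunk_size reads per streamed chunk.
#' @return object of class `satellite_assay`: `n_reads_total`,
#'   `n_satellite_reads`, `percent_satellite` (NA with `empty = TRUE` for an
#'   empty file).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' generate_fastq(fq, n_reads = 200, satellite_fraction = 0.2, seed = 1)
#' count_satellite_reads(fq)
#' @export
count_satellite_reads <- function(fastq_path, motifs = satellite_motifs(),
                                  chunk_size = 20000L) {
  n_sat <- 0L
  n_total <- .fastq_apply(fastq_path, function(seqs, offset) {
    hit <- rep(FALSE, length(seqs))
    for (m in motifs) hit <- hit | grepl(m, seqs, fixed = TRUE)
    n_sat <<- n_sat + sum(hit)
  }, chunk_size = chunk_size)
  structure(list(file = fastq_path, mode = "satellite",
                 n_reads_total = n_total, n_satellite_reads = n_sat,
                 percent_satellite = if (n_total > 0) 100 * n_sat / n_total
                 else NA_real_,
                 empty = n_total == 0L),
            class = "satellite_assay")
}

## Bisulfite matching: every C of a motif may read C or T; all other
## positions must match exactly.  Compiled once per motif set.
.bisulfite_patterns <- function(motifs) {
  lapply(motifs, function(m) {
    chars <- strsplit(m, "")[[1L]]
    c_pos <- which(chars == "C")
    pat <- chars
    pat[c_pos] <- "[CT]"
    ## zero-width lookahead so overlapping occurrences are all found
    list(motif = m, c_pos = c_pos,
         regex = paste0("(?=", paste(pat, collapse = ""), ")"),
         width = length(chars))
  })
}

#' Estimate bisulfite conversion at satellite motif cytosines
#'
#' Matches reads against C-wildcarded variants of the satellite motifs
#' (each motif cytosine may read C or T, all other bases exact; overlapping
#' occurrences of different motifs are all tallied).  Every motif C
#' position of every occurrence contributes one assayed site: T means the
#' cytosine was bisulfite-converted (unmethylated), C means it was
#' protected (methylated).  Percent conversion over all assayed sites is an
#' inverse proxy of satellite DNA methylation.
#'
#' Reads are taken as given (no reverse-complementing): because the motif
#' set contains both strands, reads from either strand are matched via
#' their own motif.  G-position wildcarding for complementary-strand
#' bisulfite protocols is deliberately not applied.
#'
#' @inheritParams count_satellite_reads
#' @return object of class `satellite_assay` with `n_reads_total`,
#'   `n_reads_matched`, `n_occurrences`, `n_C_sites_assayed`, `n_converted`,
#'   `percent_conversion` (NA when no site was assayed).
#' @export
bisulfite_conversion <- function(fastq_path, motifs = satellite_motifs(),
                                 chunk_size = 20000L) {
  pats <- .bisulfite_patterns(motifs)
  n_occ <- 0L
  n_sites <- 0L
  n_conv <- 0L
  matched <- 0L
  n_total <- .fastq_apply(fastq_path, function(seqs, offset) {
    read_hit <- rep(FALSE, length(seqs))
    for (p in pats) {
      hits <- gregexpr(p$regex, seqs, perl = TRUE)
      for (i in seq_along(seqs)) {
        starts <- hits[[i]]
        if (starts[1L] == -1L) next
        read_hit[i] <- TRUE
        for (s in as.integer(starts)) {
          n_occ <<- n_occ + 1L
          ## a motif without cytosines contributes matches but no sites
          if (length(p$c_pos)) {
            sites <- s + p$c_pos - 1L
            obs <- substring(seqs[i], sites, sites)
            n_sites <<- n_sites + length(sites)
            n_conv <<- n_conv + sum(obs == "T")
          }
        }
      }
    }
    matched <<- matched + sum(read_hit)
  }, chunk_size = chunk_size)
  structure(list(file = fastq_path, mode = "bisulfite",
                 n_reads_total = n_total, n_reads_matched = matched,
                 n_occurrences = n_occ, n_C_sites_assayed = n_sites,
                 n_converted = n_conv,
                 percent_conversion = if (n_sites > 0) 100 * n_conv / n_sites
                 else NA_real_,
                 empty = n_total == 0L),
            class = "satellite_assay")
}

#' @export
print.satellite_assay <- function(x, ...) {
  if (x$mode == "satellite") {
    cat(sprintf("<satellite_assay> %s: %d/%d reads satellite (%s%%)\n",
                basename(x$file), x$n_satellite_reads, x$n_reads_total,
                if (is.na(x$percent_satellite)) "NA" else
                  sprintf("%.3f", x$percent_satellite)))
  } else {
    cat(sprintf(
      "<satellite_assay> %s: %d sites over %d occurrences, %s%% converted\n",
      basename(x$file), x$n_C_sites_assayed, x$n_occurrences,
      if (is.na(x$percent_conversion)) "NA" else
        sprintf("%.3f", x$percent_conversion)))
  }
  invisible(x)
}

#' @rdname print.satellite_assay
#' @param x a `satellite_assay`.
#' @param ... unused.
#' @export
as.data.frame.satellite_assay <- function(x, ...) {
  as.data.frame(x[setdiff(names(x), c("mode"))], stringsAsFactors = FALSE)
}
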