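test_that("the motif set is exactly the eight satellite tags, revcomp-closed", {
  m <- satellite_motifs()
  expect_length(m, 8)
  expect_true(all(grepl("^[ACGT]+$", m)))
  rc <- vapply(strsplit(m, ""), function(ch) {
    paste(rev(chartr("ACGT", "TGCA", ch)), collapse = "")
  }, character(1))
  expect_setequal(rc, m)
  expect_equal(rc[1:4], m[5:8])   # documented pairing 1/5, 2/6, 3/7, 4/8
})

write_fastq <- function(seqs, path) {
  recs <- rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                strrep("I", nchar(seqs)))
  writeLines(as.vector(recs), path)
  path
}

test_that("reads without motifs give percent_satellite 0", {
  fq <- write_fastq(rep(strrep("A", 40), 20), withr::local_tempfile())
  res <- count_satellite_reads(fq)
  expect_equal(res$n_reads_total, 20)
  expect_equal(res$n_satellite_reads, 0)
  expect_equal(res$percent_satellite, 0)
})

test_that("a read containing two different motifs is counted once", {
  m <- satellite_motifs()
  two <- paste0(m[1], "AAAA", m[2])
  fq <- write_fastq(c(two, strrep("G", nchar(two))), withr::local_tempfile())
  res <- count_satellite_reads(fq)
  expect_equal(res$n_reads_total, 2)
  expect_equal(res$n_satellite_reads, 1)
  expect_equal(res$percent_satellite, 50)
})

test_that("matching is case-insensitive and works through gzip", {
  m <- satellite_motifs()
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(fq, "wt")
  writeLines(c("@r1", tolower(paste0("acgt", m[3], "acgt")), "+",
               strrep("I", nchar(m[3]) + 8)), con)
  close(con)
  res <- count_satellite_reads(fq)
  expect_equal(res$n_satellite_reads, 1)
})

test_that("an empty FASTQ is flagged, a malformed one fails with its record number", {
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  res <- count_satellite_reads(empty)
  expect_true(res$empty)
  expect_true(is.na(res$percent_satellite))

  bad <- withr::local_tempfile()
  writeLines(c("@r1", "ACGT", "+", "IIII", "no-at-sign", "ACGT", "+", "IIII"),
             bad)
  expect_error(count_satellite_reads(bad), "record 2")
  trunc <- withr::local_tempfile()
  writeLines(c("@r1", "ACGT", "+"), trunc)
  expect_error(count_satellite_reads(trunc), "truncated")
})

test_that("generated background reads are motif-free and satellite reads embed one motif", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  g <- generate_fastq(fq, n_reads = 400, satellite_fraction = 0, seed = 2)
  expect_equal(g$n_satellite_planted, 0)
  seqs <- oracle_read_fastq(fq)
  expect_false(any(oracle_contains_motif(seqs, satellite_motifs())))

  g1 <- generate_fastq(fq, n_reads = 100, satellite_fraction = 1, seed = 3)
  expect_equal(g1$n_satellite_planted, 100)
  seqs <- oracle_read_fastq(fq)
  expect_true(all(oracle_contains_motif(seqs, satellite_motifs())))
  ## the planted motif sits verbatim at the recorded offset
  m <- satellite_motifs()
  for (i in c(1, 50, 100)) {
    tr <- g1$truth[i, ]
    w <- nchar(m[tr$motif_index])
    expect_equal(substring(seqs[i], tr$offset, tr$offset + w - 1),
                 m[tr$motif_index])
  }
})

test_that("FASTQ generation is deterministic and rejects too-short reads", {
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(fq1, n_reads = 50, seed = 7)
  generate_fastq(fq2, n_reads = 50, seed = 7)
  expect_identical(readLines(fq1), readLines(fq2))
  expect_error(generate_fastq(fq1, n_reads = 10, read_length = 20),
               ">= 24")
})

test_that("the counter agrees exactly with the quadratic scanner and the planted truth", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  g <- generate_fastq(fq, n_reads = 3000, satellite_fraction = 0.1, seed = 11)
  res <- count_satellite_reads(fq)
  expect_equal(res$n_reads_total, 3000)
  expect_equal(res$n_satellite_reads, g$n_satellite_planted)
  seqs <- oracle_read_fastq(fq)
  expect_equal(res$n_satellite_reads,
               sum(oracle_contains_motif(seqs, satellite_motifs())))
})

test_that("reverse-complementing every read leaves the satellite count unchanged", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  g <- generate_fastq(fq, n_reads = 500, satellite_fraction = 0.3, seed = 13)
  res <- count_satellite_reads(fq)
  seqs <- oracle_read_fastq(fq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  fq_rc <- write_fastq(rc, withr::local_tempfile(fileext = ".fastq"))
  res_rc <- count_satellite_reads(fq_rc)
  expect_equal(res_rc$n_satellite_reads, res$n_satellite_reads)
})

test_that("an unaltered motif occurrence assays as 0% converted, a fully converted one as 100%", {
  m1 <- satellite_motifs()[1]            # GACGACTTGAAAAATGACGAAATC
  full <- chartr("C", "T", m1)
  fq <- write_fastq(c(paste0("AAAA", m1, "AAAA"),
                      paste0("AAAA", full, "AAAA")),
                    withr::local_tempfile())
  res <- bisulfite_conversion(fq)
  n_c <- lengths(regmatches(m1, gregexpr("C", m1)))
  expect_equal(res$n_C_sites_assayed, 2 * n_c)
  expect_equal(res$n_converted, n_c)     # only the converted copy reads T
})

test_that("motifs without cytosines contribute matches but no assayed sites", {
  m3 <- satellite_motifs()[3]            # GAAAAAGGTGGAAAATTTAGA, no C
  fq <- write_fastq(paste0("AA", m3, "AA"), withr::local_tempfile())
  res <- bisulfite_conversion(fq)
  expect_equal(res$n_reads_matched, 1)
  expect_equal(res$n_occurrences, 1)
  expect_equal(res$n_C_sites_assayed, 0)
  expect_true(is.na(res$percent_conversion))
})

test_that("bisulfite site tallies equal the wildcard-matcher oracle exactly", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  generate_fastq(fq, n_reads = 2000, satellite_fraction = 0.2,
                 bisulfite = TRUE, methylation_rate = 0.5,
                 conversion_efficiency = 0.9, seed = 17)
  res <- bisulfite_conversion(fq)
  seqs <- oracle_read_fastq(fq)
  want <- oracle_bisulfite_tally(seqs, satellite_motifs())
  expect_equal(res$n_occurrences, want$n_occurrences)
  expect_equal(res$n_C_sites_assayed, want$n_sites)
  expect_equal(res$n_converted, want$n_converted)
  expect_equal(res$n_reads_matched, want$n_reads_matched)
})

test_that("forced-limit bisulfite chemistry converts every motif cytosine", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  g <- generate_fastq(fq, n_reads = 300, satellite_fraction = 0.5,
                      bisulfite = TRUE, methylation_rate = 0,
                      conversion_efficiency = 1, seed = 19)
  expect_equal(sum(g$truth$n_converted), sum(g$truth$n_C))
  res <- bisulfite_conversion(fq)
  expect_gt(res$n_C_sites_assayed, 0)
  expect_equal(res$percent_conversion, 100)

  ## fully methylated: no conversion anywhere
  g2 <- generate_fastq(fq, n_reads = 300, satellite_fraction = 0.5,
                       bisulfite = TRUE, methylation_rate = 1,
                       conversion_efficiency = 1, seed = 20)
  expect_equal(sum(g2$truth$n_converted), 0)
  res2 <- bisulfite_conversion(fq)
  expect_equal(res2$percent_conversion, 0)
})

test_that("planted rates are recovered within binomial error over seeds", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  frac_hat <- conv_hat <- numeric(10)
  for (s in 1:10) {
    g <- generate_fastq(fq, n_reads = 800, satellite_fraction = 0.1,
                        bisulfite = TRUE, methylation_rate = 0.8,
                        conversion_efficiency = 1, seed = 400 + s)
    conv <- bisulfite_conversion(fq)
    conv_hat[s] <- conv$percent_conversion / 100
    frac_hat[s] <- g$n_satellite_planted / 800
  }
  ## 3 binomial SEs around the planted values
  expect_lt(abs(mean(frac_hat) - 0.1),
            3 * sqrt(0.1 * 0.9 / (800 * 10)))
  expect_lt(abs(mean(conv_hat) - 0.2), 0.02)
})
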