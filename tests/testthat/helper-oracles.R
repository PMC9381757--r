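# Independent brute-force oracles used to validate the package
# implementations. These deliberately share no code with the package:
# explicit sums, position-by-position scans and exhaustive enumeration.

# Textbook Pearson correlation from explicit sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# Above-mean run containing the global maximum, by stepping outward from
# the peak one sample at a time.
oracle_segment <- function(dapi) {
  thr <- sum(dapi) / length(dapi)
  peak <- which.max(dapi)
  if (!(dapi[peak] > thr)) return(NULL)
  lo <- peak
  while (lo > 1 && dapi[lo - 1] > thr) lo <- lo - 1
  hi <- peak
  while (hi < length(dapi) && dapi[hi + 1] > thr) hi <- hi + 1
  list(start = lo, end = hi, peak = peak, threshold = thr)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups, with the same two-sided rule R uses
# (double the smaller tail, capped at 1).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  n <- length(b)
  u_of <- function(xa, xb) sum(outer(xa, xb, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  if (u_obs > m * n / 2) {
    min(2 * mean(us >= u_obs), 1)
  } else {
    min(2 * mean(us <= u_obs), 1)
  }
}

# Read a whole (plain) FASTQ into a character vector of sequences.
oracle_read_fastq <- function(path) {
  lines <- readLines(path)
  toupper(lines[seq(2, length(lines), by = 4)])
}

# Quadratic exact-substring scan: does each read contain any motif?
# Vectorised over reads but scanning every offset of every motif.
oracle_contains_motif <- function(seqs, motifs) {
  hit <- rep(FALSE, length(seqs))
  width <- unique(nchar(seqs))
  stopifnot(length(width) == 1)
  for (m in motifs) {
    w <- nchar(m)
    for (off in seq_len(width - w + 1)) {
      hit <- hit | (substring(seqs, off, off + w - 1) == m)
    }
  }
  hit
}

# Position-by-position C-wildcard matcher: tallies occurrences, assayed C
# sites and conversions for every motif at every offset of every read.
oracle_bisulfite_tally <- function(seqs, motifs) {
  width <- unique(nchar(seqs))
  stopifnot(length(width) == 1)
  n_occ <- 0L
  n_sites <- 0L
  n_conv <- 0L
  matched <- rep(FALSE, length(seqs))
  for (m in motifs) {
    chars <- strsplit(m, "")[[1]]
    w <- length(chars)
    c_pos <- which(chars == "C")
    for (off in seq_len(width - w + 1)) {
      ok <- rep(TRUE, length(seqs))
      for (p in seq_len(w)) {
        obs <- substring(seqs, off + p - 1, off + p - 1)
        ok <- ok & if (chars[p] == "C") (obs == "C" | obs == "T") else
          (obs == chars[p])
      }
      if (!any(ok)) next
      matched <- matched | ok
      n_occ <- n_occ + sum(ok)
      for (p in c_pos) {
        obs <- substring(seqs[ok], off + p - 1, off + p - 1)
        n_sites <- n_sites + length(obs)
        n_conv <- n_conv + sum(obs == "T")
      }
    }
  }
  list(n_occurrences = n_occ, n_sites = n_sites, n_converted = n_conv,
       n_reads_matched = sum(matched))
}

# Exhaustive local-maximum scan of a matrix by explicit loops.
oracle_local_maxima <- function(mat, threshold) {
  out <- NULL
  for (i in 2:(nrow(mat) - 1)) {
    for (j in 2:(ncol(mat) - 1)) {
      v <- mat[i, j]
      if (v <= threshold) next
      nb <- mat[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v >= max(nb)) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Evaluate the generative nucleus-image formulas at arbitrary physical
# coordinates (um), from the ground truth alone.
oracle_nucleus_value <- function(truth, params, pts, channel,
                                 bit_depth = 16,
                                 dapi_baseline_frac = 0.15,
                                 marker_baseline_frac = 0.08,
                                 outside_frac = 0.02) {
  maxval <- 2^bit_depth - 1
  ctr <- truth$nucleus_center_um
  inside <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) <=
    truth$nucleus_radius_um
  dapi_base <- dapi_baseline_frac * maxval
  out_base <- outside_frac * maxval
  m_base <- marker_baseline_frac * maxval
  a_dapi <- (params$dapi_focus_contrast - 1) * dapi_base
  a_marker <- params$marker_amplitude_frac * maxval
  gsum <- rep(0, nrow(pts))
  csum <- rep(0, nrow(pts))
  for (i in seq_len(nrow(truth$foci))) {
    f <- truth$foci[i, ]
    d <- sqrt((pts[, 1] - f$x_um)^2 + (pts[, 2] - f$y_um)^2)
    g <- exp(-d^2 / (2 * f$sigma_um^2))
    gsum <- gsum + g
    rs <- params$cloudy_ring_radius_frac * f$radius_um
    ss <- params$cloudy_ring_width / 2
    csum <- csum + params$cloudy_infocus_weight * g +
      exp(-(d - rs)^2 / (2 * ss^2))
  }
  if (channel == "DAPI") {
    out_base + (dapi_base - out_base) * inside + a_dapi * gsum * inside
  } else if (params$marker_mode == "colocalized") {
    out_base + (m_base - out_base) * inside + a_marker * gsum * inside
  } else if (params$marker_mode == "cloudy") {
    out_base + (m_base - out_base) * inside + a_marker * csum * inside
  } else {
    stop("oracle supports DAPI, colocalized and cloudy channels")
  }
}

# Simulated nuclei -> one PCC per nucleus through the first planted focus.
simulate_mode_pccs <- function(mode, n, seed0, noise_sd = 600, ...) {
  vapply(seq_len(n), function(i) {
    syn <- generate_nucleus_image(marker_mode = mode, noise_sd = noise_sd,
                                  seed = seed0 + i, ...)
    ctr <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
    prof <- extract_profile(syn$image, ctr, half_length = 2.5)
    seg <- delineate_chromocenter(prof)
    if (!seg$found) return(NA_real_)
    rec <- pcc_enrichment(prof, seg, "marker")
    if (rec$undefined) NA_real_ else rec$pcc
  }, numeric(1))
}
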