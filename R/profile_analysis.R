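## Core statistic: DAPI/marker intensity line profiles across a chromocenter
## midline, delineation of the chromocenter as the above-mean DAPI bell, and
## the Pearson correlation between the two channels over that segment.

.STAGES <- c("2-cell", "4-cell", "8-cell", "16-cell", "E3.25", "E3.5",
             "E3.75", "E4.0", "E4.25", "E4.5", "E5.0", "E5.5", "E6.5",
             "ESC", "EpiSC", "EpiLC", "TSC", "none")
.LINEAGES <- c("EPI", "PrE", "TE", "ICM", "ExE", "VE", "none")

.check_vocab <- function(value, vocab, what) {
  if (!is.na(value) && !value %in% vocab) {
    warning(sprintf("%s '%s' is outside the standard vocabulary (%s)",
                    what, value, paste(vocab, collapse = ", ")),
            call. = FALSE)
  }
  value
}

## Bilinear interpolation of a 2-D matrix at continuous pixel coordinates
## (pixel centres at integer coordinates); samples are clamped to the border.
.bilinear <- function(mat, px, py) {
  nx <- nrow(mat); ny <- ncol(mat)
  px <- pmin(pmax(px, 1), nx)
  py <- pmin(pmax(py, 1), ny)
  x0 <- pmin(floor(px), nx - 1L); x1 <- x0 + 1L
  y0 <- pmin(floor(py), ny - 1L); y1 <- y0 + 1L
  fx <- px - x0; fy <- py - y0
  mat[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    mat[cbind(x1, y0)] * fx * (1 - fy) +
    mat[cbind(x0, y1)] * (1 - fx) * fy +
    mat[cbind(x1, y1)] * fx * fy
}

#' Extract a multi-channel intensity profile along a line
#'
#' Samples the requested channels along the line through `center` with
#' direction `direction`, from `-half_length` to `+half_length` micrometres,
#' by bilinear interpolation at a fixed sub-pixel spacing of half the
#' smaller in-plane pixel pitch.  All channels share the same sampling grid
#' and positions are centred so that `center` sits at 0 um - the intended
#' use is a line across a chromocenter midline, with the chromocenter
#' centre at the origin.
#'
#' For 3-D stacks the profile is taken on a single z-plane: `plane` if
#' given, otherwise the plane on which DAPI (the first requested channel)
#' is maximal at `center`, matching measurements made on a single optical
#' section.
#'
#' Parts of the line falling outside the image are dropped and the profile
#' is flagged (`truncated = TRUE`); a profile must retain at least 5
#' samples.
#'
#' @param image an [image_stack].
#' @param center line centre in micrometres (x, y); any z component is
#'   ignored in favour of `plane`.
#' @param direction in-plane direction vector (need not be normalised);
#'   default the image x-axis.
#' @param half_length half the profile length, micrometres.
#' @param channels channel names to sample (default: all).
#' @param plane z-plane index for 3-D stacks.
#' @return an object of class `line_profile`: list with `positions_um`,
#'   `intensity` (samples x channels matrix), `center_um`, `direction`,
#'   `endpoints_um`, `plane`, `truncated`.
#' @examples
#' syn <- generate_nucleus_image(n_chromocenters = 1, noise_sd = 0, seed = 1)
#' ctr <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
#' prof <- extract_profile(syn$image, ctr, half_length = 2)
#' plot(prof$positions_um, prof$intensity[, "DAPI"], type = "l")
#' @export
extract_profile <- function(image, center, direction = c(1, 0),
                            half_length = 2.5, channels = NULL,
                            plane = NULL) {
  .assert(inherits(image, "image_stack"), "image must be an image_stack")
  .assert(half_length > 0, "half_length must be positive")
  channels <- channels %||% channel_names(image)
  for (ch in channels) get_channel(image, ch)  # validates names
  nd <- .stack_ndim(image)
  vox <- image$voxel_size
  dims <- .stack_dim(image)
  .assert(length(center) >= 2L, "center must give in-plane coordinates")
  center <- as.numeric(center[1:2])
  direction <- as.numeric(direction[1:2])
  nrm <- sqrt(sum(direction^2))
  .assert(nrm > 0, "direction must be a non-zero vector")
  direction <- direction / nrm

  planes <- lapply(channels, function(ch) {
    arr <- get_channel(image, ch)
    if (nd == 2L) return(arr)
    if (is.null(plane)) {
      px <- pmin(pmax(round(center / vox[1:2] + 0.5), 1L), dims[1:2])
      plane <<- which.max(arr[px[1L], px[2L], ])
    }
    .assert(plane >= 1L && plane <= dims[3L], "plane index out of range")
    arr[, , plane]
  })
  names(planes) <- channels

  step <- min(vox[1:2]) / 2
  positions <- seq(-half_length, half_length, by = step)
  pts_x <- center[1L] + positions * direction[1L]
  pts_y <- center[2L] + positions * direction[2L]
  ## continuous pixel coordinates: centre of pixel i at (i - 0.5) * vox
  px <- pts_x / vox[1L] + 0.5
  py <- pts_y / vox[2L] + 0.5
  keep <- px >= 0.5 & px <= dims[1L] + 0.5 & py >= 0.5 & py <= dims[2L] + 0.5
  truncated <- !all(keep)
  positions <- positions[keep]; px <- px[keep]; py <- py[keep]
  .assert(length(positions) >= 5L,
          "profile has fewer than 5 samples inside the image")

  intensity <- vapply(channels, function(ch) .bilinear(planes[[ch]], px, py),
                      numeric(length(positions)))
  intensity <- matrix(intensity, ncol = length(channels),
                      dimnames = list(NULL, channels))
  structure(
    list(positions_um = positions, intensity = intensity,
         center_um = center, direction = direction,
         endpoints_um = rbind(c(pts_x[keep][1L], pts_y[keep][1L]),
                              c(pts_x[keep][length(px)], pts_y[keep][length(py)])),
         plane = if (nd == 3L) plane else NA_integer_,
         truncated = truncated),
    class = "line_profile"
  )
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.2f um, channels: %s%s\n",
              length(x$positions_um), diff(range(x$positions_um)),
              paste(colnames(x$intensity), collapse = ", "),
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Delineate a chromocenter on the DAPI profile
#'
#' The chromocenter appears on a line profile as a bell-shaped DAPI curve
#' with values higher than the average fluorescence of the plot.  The
#' threshold is therefore the arithmetic mean of the DAPI values over the
#' whole profile, and the segment is the maximal contiguous run of samples
#' strictly above that mean which contains the global DAPI maximum.  Other
#' above-mean runs (e.g. a second chromocenter clipped by the line) are
#' ignored but counted in `n_secondary_runs`.
#'
#' A flat profile has no sample strictly above its mean and yields a
#' "no chromocenter" result (`found = FALSE`), which is a valid outcome,
#' not an error.
#'
#' @param profile a [line_profile].
#' @param dapi_channel name of the DAPI channel in the profile.
#' @return an object of class `chromocenter_segment`: list with `found`,
#'   `start_index`, `end_index`, `peak_index` (1-based, inclusive),
#'   `threshold` and `n_secondary_runs`.
#' @examples
#' prof <- structure(list(
#'   positions_um = seq(-2, 2, 0.5),
#'   intensity = cbind(DAPI = c(1, 1, 1, 5, 9, 5, 1, 1, 1))),
#'   class = "line_profile")
#' delineate_chromocenter(prof)
#' @export
delineate_chromocenter <- function(profile, dapi_channel = "DAPI") {
  .assert(inherits(profile, "line_profile"), "profile must be a line_profile")
  .assert(dapi_channel %in% colnames(profile$intensity),
          sprintf("profile has no channel '%s'", dapi_channel))
  dapi <- profile$intensity[, dapi_channel]
  thr <- mean(dapi)
  above <- dapi > thr
  if (!any(above)) {
    return(structure(list(found = FALSE, start_index = NA_integer_,
                          end_index = NA_integer_, peak_index = NA_integer_,
                          threshold = thr, n_secondary_runs = 0L),
                     class = "chromocenter_segment"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peak <- which.max(dapi)
  main <- runs[starts[runs] <= peak & ends[runs] >= peak]
  ## the global maximum is necessarily above the mean, so `main` exists
  structure(list(found = TRUE,
                 start_index = starts[main], end_index = ends[main],
                 peak_index = peak, threshold = thr,
                 n_secondary_runs = length(runs) - 1L),
            class = "chromocenter_segment")
}

#' @export
print.chromocenter_segment <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<chromocenter_segment> none found (threshold %.3f)\n",
                x$threshold))
  } else {
    cat(sprintf(
      "<chromocenter_segment> samples %d..%d (peak %d), threshold %.3f, %d other run(s)\n",
      x$start_index, x$end_index, x$peak_index, x$threshold,
      x$n_secondary_runs))
  }
  invisible(x)
}

#' Pearson correlation between DAPI and a marker over a chromocenter
#'
#' Computes the sample Pearson correlation coefficient (PCC) between the
#' DAPI and marker intensity values of a line profile restricted to the
#' delineated chromocenter segment.  The closer the marker profile is to
#' the DAPI profile over the chromocenter, the closer the PCC is to 1; a
#' marker that avoids the DAPI-dense focus gives a PCC near or below 0.
#'
#' If either channel has zero variance over the segment the PCC is
#' undefined; the record is returned with `pcc = NA` and `undefined = TRUE`
#' so that summaries can exclude and count it - it is never silently 0.
#'
#' @param profile a [line_profile].
#' @param segment a [chromocenter_segment] for that profile (`found` must
#'   be `TRUE` and the segment at least 3 samples long).
#' @param marker_channel marker channel name.
#' @param dapi_channel DAPI channel name.
#' @param metadata named list with any of `chromocenter_id`, `nucleus_id`,
#'   `embryo_id`, `stage`, `lineage`.
#' @return a one-row data frame (a PCC record) with columns `pcc`, `marker`,
#'   `n_samples`, `undefined`, `chromocenter_id`, `nucleus_id`, `embryo_id`,
#'   `stage`, `lineage`.
#' @export
pcc_enrichment <- function(profile, segment, marker_channel,
                           dapi_channel = "DAPI", metadata = list()) {
  .assert(inherits(profile, "line_profile"), "profile must be a line_profile")
  .assert(inherits(segment, "chromocenter_segment"),
          "segment must be a chromocenter_segment")
  .assert(isTRUE(segment$found), "segment has no chromocenter")
  .assert(marker_channel %in% colnames(profile$intensity),
          sprintf("profile has no channel '%s'", marker_channel))
  idx <- segment$start_index:segment$end_index
  .assert(length(idx) >= 3L, "segment must span at least 3 samples")
  dapi <- profile$intensity[idx, dapi_channel]
  marker <- profile$intensity[idx, marker_channel]
  undefined <- sd(dapi) == 0 || sd(marker) == 0
  pcc <- if (undefined) NA_real_ else cor(dapi, marker)
  stage <- .check_vocab(metadata$stage %||% NA_character_, .STAGES, "stage")
  lineage <- .check_vocab(metadata$lineage %||% NA_character_, .LINEAGES,
                          "lineage")
  data.frame(
    pcc = pcc, marker = marker_channel, n_samples = length(idx),
    undefined = undefined,
    chromocenter_id = as.character(metadata$chromocenter_id %||% NA_character_),
    nucleus_id = as.character(metadata$nucleus_id %||% NA_character_),
    embryo_id = as.character(metadata$embryo_id %||% NA_character_),
    stage = as.character(stage), lineage = as.character(lineage),
    stringsAsFactors = FALSE
  )
}

#' Summarise PCC records by group
#'
#' Groups PCC records (rows as returned by [pcc_enrichment()]) by the given
#' metadata columns and reports, per group, the number of chromocenters and
#' the distribution of the PCC (median, quartiles, min, max) - the numbers
#' behind a violin plot of PCC by stage or lineage.  Records with an
#' undefined PCC are excluded and counted.
#'
#' @param records data frame of PCC records.
#' @param group_by character vector of grouping columns (subset of
#'   `stage`, `lineage`, `marker`, ...).
#' @return list with `summary` (one row per group: n, median, q1, q3, min,
#'   max), `long` (one row per retained chromocenter, ready for violin
#'   plotting) and `n_undefined`.
#' @export
summarize_pcc <- function(records, group_by = c("stage", "lineage", "marker")) {
  .assert(is.data.frame(records) && nrow(records) >= 1L,
          "records must be a non-empty data frame")
  .assert(all(group_by %in% names(records)),
          "group_by columns missing from records")
  bad <- if ("undefined" %in% names(records)) records$undefined else
    is.na(records$pcc)
  n_undefined <- sum(bad)
  keep <- records[!bad, , drop = FALSE]
  .assert(nrow(keep) >= 1L, "no records with a defined PCC")
  key <- interaction(keep[group_by], drop = TRUE, sep = "|")
  summ <- do.call(rbind, lapply(levels(key), function(lv) {
    rows <- keep[key == lv, , drop = FALSE]
    q <- quantile(rows$pcc, c(0.25, 0.5, 0.75), names = FALSE)
    cbind(rows[1L, group_by, drop = FALSE],
          data.frame(n = nrow(rows), median = q[2L], q1 = q[1L], q3 = q[3L],
                     min = min(rows$pcc), max = max(rows$pcc)))
  }))
  rownames(summ) <- NULL
  long <- keep[c(group_by, "pcc",
                 intersect(c("chromocenter_id", "nucleus_id", "embryo_id"),
                           names(keep)))]
  rownames(long) <- NULL
  list(summary = summ, long = long, n_undefined = n_undefined)
}
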