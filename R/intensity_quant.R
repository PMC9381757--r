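## Whole-nucleus intensity quantification with local background subtraction
## and DAPI normalisation, region (inactive-X style) quantification, and
## Mann-Whitney group comparison with percent change.

## Background per channel: median intensity over a thin annulus just outside
## the nucleus mask (local, robust to stray signal elsewhere in the field).
.annulus_background <- function(arr, mask, annulus_width) {
  ann <- .dilate_mask(mask, annulus_width) & !mask
  if (!any(ann)) {
    warning("nucleus mask leaves no room for a background annulus; using 0",
            call. = FALSE)
    return(list(value = 0, n = 0L))
  }
  list(value = median(arr[ann]), n = sum(ann))
}

#' Measure background-subtracted total intensities in a nucleus
#'
#' For each channel, estimates the local background as the median intensity
#' over an annulus of `annulus_width` pixels just outside the nucleus mask,
#' subtracts it pixel-wise (negative values clamped to 0), and sums over the
#' mask - the whole nuclear area of a 2-D section or the whole nuclear
#' volume of a 3-D stack.  Marker totals are normalised to the DAPI total,
#' making levels comparable across nuclei of different size and staining
#' efficiency.
#'
#' @param image an [image_stack].
#' @param nucleus_mask logical array, same shape as the image.
#' @param channels channels to measure (default: all).
#' @param dapi_channel name of the DAPI channel (must be measured).
#' @param annulus_width background annulus width in pixels.
#' @param nucleus_id,group identifiers carried into the result.
#' @return object of class `nucleus_measurement`: list with `nucleus_id`,
#'   `group`, `total` (named, background-subtracted), `background` (named),
#'   `normalized` (marker totals / DAPI total), `clamped` (any negative
#'   pixels clamped per channel), `valid` (DAPI total > 0).
#' @examples
#' q <- generate_quant_image(seed = 1)
#' m <- measure_nucleus(q$image, q$mask)
#' m$normalized
#' @export
measure_nucleus <- function(image, nucleus_mask, channels = NULL,
                            dapi_channel = "DAPI", annulus_width = 3L,
                            nucleus_id = NA_character_,
                            group = NA_character_) {
  .assert(inherits(image, "image_stack"), "image must be an image_stack")
  .assert(is.logical(nucleus_mask) &&
            identical(dim(nucleus_mask), .stack_dim(image)),
          "nucleus_mask must be a logical array matching the image shape")
  .assert(any(nucleus_mask), "nucleus mask is empty")
  channels <- channels %||% channel_names(image)
  .assert(dapi_channel %in% channels, "DAPI channel must be measured")
  total <- background <- numeric(0)
  clamped <- logical(0)
  for (ch in channels) {
    arr <- get_channel(image, ch)
    bg <- .annulus_background(arr, nucleus_mask, annulus_width)
    v <- arr[nucleus_mask] - bg$value
    clamped[ch] <- any(v < 0)
    total[ch] <- sum(pmax(v, 0))
    background[ch] <- bg$value
  }
  valid <- total[dapi_channel] > 0
  if (!valid) {
    warning("DAPI total is 0 after background subtraction; measurement flagged invalid",
            call. = FALSE)
  }
  markers <- setdiff(channels, dapi_channel)
  normalized <- if (valid) total[markers] / total[dapi_channel] else
    setNames(rep(NA_real_, length(markers)), markers)
  structure(list(nucleus_id = nucleus_id, group = group, total = total,
                 background = background, normalized = normalized,
                 dapi_total = unname(total[dapi_channel]),
                 clamped = clamped, valid = valid),
            class = "nucleus_measurement")
}

#' @export
print.nucleus_measurement <- function(x, ...) {
  cat(sprintf("<nucleus_measurement> %s%s\n",
              if (is.na(x$nucleus_id)) "(unnamed)" else x$nucleus_id,
              if (x$valid) "" else " [INVALID: DAPI total 0]"))
  for (ch in names(x$total)) {
    cat(sprintf("  %-12s total %.4g (bg %.4g)%s\n", ch, x$total[ch],
                x$background[ch],
                if (ch %in% names(x$normalized))
                  sprintf(", DAPI-normalised %.4g", x$normalized[ch]) else ""))
  }
  invisible(x)
}

#' @rdname measure_nucleus
#' @param x a `nucleus_measurement`.
#' @param ... unused.
#' @export
as.data.frame.nucleus_measurement <- function(x, ...) {
  row <- data.frame(nucleus_id = x$nucleus_id, group = x$group,
                    dapi_total = x$dapi_total, valid = x$valid,
                    stringsAsFactors = FALSE)
  for (ch in names(x$total)) row[[paste0("total_", ch)]] <- unname(x$total[ch])
  for (ch in names(x$normalized)) {
    row[[paste0("norm_", ch)]] <- unname(x$normalized[ch])
  }
  row
}

#' Measure a marker over a region delineated by another channel
#'
#' Delineates a sub-nuclear region (e.g. the inactive X territory) as the
#' largest connected component of defining-channel pixels exceeding
#' `mean + k * sd` (statistics over the nucleus mask), then totals and
#' DAPI-normalises the target channel over that region exactly as
#' [measure_nucleus()] does over the whole nucleus.
#'
#' @param image an [image_stack].
#' @param defining_channel channel whose bright patch defines the region.
#' @param nucleus_mask logical array delimiting the nucleus.
#' @param target_channel channel to quantify over the region.
#' @param k threshold in standard deviations above the nuclear mean.
#' @param dapi_channel DAPI channel for normalisation.
#' @param annulus_width background annulus width (pixels), as in
#'   [measure_nucleus()].
#' @param nucleus_id,group,region_id identifiers carried into the result.
#' @return object of class `region_measurement`: `found`, `region_mask`,
#'   `n_pixels`, `total` (target), `background`, `dapi_total`, `normalized`.
#'   When no pixel exceeds the threshold, `found = FALSE` (a "no region"
#'   result, not an error).
#' @export
measure_region <- function(image, defining_channel, nucleus_mask,
                           target_channel, k = 2, dapi_channel = "DAPI",
                           annulus_width = 3L, nucleus_id = NA_character_,
                           group = NA_character_, region_id = "Xi") {
  .assert(inherits(image, "image_stack"), "image must be an image_stack")
  .assert(any(nucleus_mask), "nucleus mask is empty")
  def <- get_channel(image, defining_channel)
  vals <- def[nucleus_mask]
  thr <- mean(vals) + k * sd(vals)
  cand <- def > thr & nucleus_mask
  if (!any(cand)) {
    return(structure(list(found = FALSE, region_id = region_id,
                          nucleus_id = nucleus_id, group = group,
                          threshold = thr),
                     class = "region_measurement"))
  }
  labels <- .label_components(cand)
  sizes <- tabulate(labels[labels > 0L])
  region <- labels == which.max(sizes)
  tgt <- get_channel(image, target_channel)
  bg <- .annulus_background(tgt, nucleus_mask, annulus_width)
  total <- sum(pmax(tgt[region] - bg$value, 0))
  dap <- get_channel(image, dapi_channel)
  bg_d <- .annulus_background(dap, nucleus_mask, annulus_width)
  dapi_total <- sum(pmax(dap[region] - bg_d$value, 0))
  structure(list(found = TRUE, region_id = region_id,
                 nucleus_id = nucleus_id, group = group, threshold = thr,
                 region_mask = region, n_pixels = sum(region),
                 total = total, background = bg$value,
                 dapi_total = dapi_total,
                 normalized = if (dapi_total > 0) total / dapi_total else
                   NA_real_),
            class = "region_measurement")
}

#' @export
print.region_measurement <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<region_measurement> %s: no region above threshold %.4g\n",
                x$region_id, x$threshold))
  } else {
    cat(sprintf(
      "<region_measurement> %s: %d px, target total %.4g, DAPI-normalised %.4g\n",
      x$region_id, x$n_pixels, x$total, x$normalized))
  }
  invisible(x)
}

#' Percent change between two groups of measurements
#'
#' `100 * (mean(b) - mean(a)) / mean(a)`: the single summary number behind
#' statements such as "a 76% reduction of fluorescence intensity" (which
#' corresponds to a value of -76).
#'
#' @param values_a,values_b numeric vectors (reference group first).
#' @return percent change, negative for a reduction.
#' @export
percent_change <- function(values_a, values_b) {
  .assert(length(values_a) >= 1L && length(values_b) >= 1L,
          "both groups need at least one value")
  ma <- mean(values_a)
  .assert(ma != 0, "reference group mean is 0; percent change undefined")
  100 * (mean(values_b) - ma) / ma
}

#' Two-sided Mann-Whitney comparison of two groups
#'
#' Rank-sum comparison of two independent groups, as used for per-nucleus
#' intensity levels between treatment conditions.  The exact null
#' distribution is used when `n_a * n_b <= 64` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.  The method actually used is recorded in the result.
#'
#' When all values are identical across both groups the comparison is
#' degenerate: `p = 1` with `degenerate = TRUE`.
#'
#' @param values_a,values_b numeric vectors (group sizes >= 1).
#' @param group_a,group_b group labels.
#' @return one-row data frame with `group_a`, `group_b`, `n_a`, `n_b`,
#'   `U_statistic` (number of (a, b) pairs with a > b, i.e. the U of the
#'   first group), `p_value` (two-sided), `percent_change`
#'   (`100 * (mean_b - mean_a) / mean_a`), `method`, `degenerate`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(values_a, values_b, group_a = "A", group_b = "B") {
  n_a <- length(values_a); n_b <- length(values_b)
  .assert(n_a >= 1L && n_b >= 1L, "both groups need at least one value")
  pc <- if (mean(values_a) != 0) percent_change(values_a, values_b) else
    NA_real_
  if (length(unique(c(values_a, values_b))) == 1L) {
    return(data.frame(group_a = group_a, group_b = group_b,
                      n_a = n_a, n_b = n_b,
                      U_statistic = n_a * n_b / 2, p_value = 1,
                      percent_change = pc, method = "degenerate",
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- (n_a * n_b <= 64L) && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  data.frame(group_a = group_a, group_b = group_b, n_a = n_a, n_b = n_b,
             U_statistic = unname(wt$statistic), p_value = wt$p.value,
             percent_change = pc,
             method = if (exact) "exact" else "normal_approximation",
             degenerate = FALSE, stringsAsFactors = FALSE)
}
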