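## RNA-FISH transcription-focus detection per nucleus and the categorical
## 0 / 1-2 / 3-4 / 5+ tabulation by stage and lineage.

.FOCI_CATEGORIES <- c("0", "1-2", "3-4", "5+")

#' Map focus counts to the standard categories
#'
#' The categorical binning used for per-cell RNA-FISH focus counts:
#' 0 -> `"0"`, 1 or 2 -> `"1-2"`, 3 or 4 -> `"3-4"`, 5 or more -> `"5+"`.
#' The map is total over non-negative integers and order-preserving.
#'
#' @param n integer vector of focus counts.
#' @return factor with levels `"0"`, `"1-2"`, `"3-4"`, `"5+"`.
#' @examples
#' bin_foci_category(c(0, 1, 2, 3, 4, 5, 12))
#' @export
bin_foci_category <- function(n) {
  .assert(all(n >= 0 & n == floor(n)), "counts must be non-negative integers")
  lab <- ifelse(n == 0, "0",
                ifelse(n <= 2, "1-2",
                       ifelse(n <= 4, "3-4", "5+")))
  factor(lab, levels = .FOCI_CATEGORIES)
}

## Strict-enough local maxima of a matrix: a pixel >= all 8 neighbours.
## Plateau ties are resolved later by the minimum-separation merge.
.local_maxima_2d <- function(mat) {
  nx <- nrow(mat); ny <- ncol(mat)
  if (nx < 3L || ny < 3L) return(matrix(integer(0), 0L, 2L))
  core <- mat[2:(nx - 1L), 2:(ny - 1L)]
  ok <- array(TRUE, dim(core))
  for (dx in -1:1) {
    for (dy in -1:1) {
      if (dx == 0L && dy == 0L) next
      nb <- mat[(2:(nx - 1L)) + dx, (2:(ny - 1L)) + dy]
      ok <- ok & (core >= nb)
    }
  }
  idx <- which(ok, arr.ind = TRUE)
  idx + 1L  # back to full-image indices
}

#' Detect RNA-FISH foci in a nucleus
#'
#' Band-pass spot detection: the FISH channel is filtered with a difference
#' of Gaussians (spot scale `spot_sigma_um` minus background scale
#' `bg_sigma_factor` times larger), candidate foci are local maxima of the
#' filtered image inside the nucleus mask whose amplitude exceeds the
#' background level by `k` background standard deviations, and candidates
#' closer than `min_separation_um` are merged keeping the brighter one.
#' The background centre and spread of the filtered image are estimated
#' robustly (median and MAD over the mask) so that the planted or real
#' spots themselves do not inflate the threshold.
#' For a z-stack, detection runs per plane and maxima within one z-step of
#' a brighter candidate are merged, since diffraction-limited FISH foci
#' span few 0.5 um sections.  All parameters are returned with the result.
#'
#' If at least 1% of in-mask pixels sit at the bit-depth maximum the
#' channel is flagged as saturated (`attr(, "saturated")`).
#'
#' @param image an [image_stack].
#' @param fish_channel FISH channel name.
#' @param nucleus_mask logical array (one nucleus).
#' @param k detection threshold in robust-sd (MAD) units above the in-mask
#'   background median of the filtered image.
#' @param min_separation_um minimum separation between retained foci.
#' @param spot_sigma_um expected spot sd in micrometres.
#' @param bg_sigma_factor background Gaussian scale relative to the spot
#'   scale.
#' @return numeric matrix of focus coordinates in micrometres (columns
#'   `x_um`, `y_um` and `z_um` for stacks), with attributes `n`,
#'   `saturated` and `params`.
#' @examples
#' fix <- generate_fish_image(n_foci_per_nucleus = 3, seed = 1)
#' foci <- detect_foci(fix$image, "FISH", fix$label_mask == 1)
#' attr(foci, "n")
#' @export
detect_foci <- function(image, fish_channel = "FISH", nucleus_mask,
                        k = 6, min_separation_um = 0.5,
                        spot_sigma_um = 0.2, bg_sigma_factor = 4) {
  .assert(inherits(image, "image_stack"), "image must be an image_stack")
  arr <- get_channel(image, fish_channel)
  .assert(is.logical(nucleus_mask) && identical(dim(nucleus_mask), dim(arr)),
          "nucleus_mask must be a logical array matching the image shape")
  .assert(any(nucleus_mask), "nucleus mask is empty")
  vox <- image$voxel_size
  nd <- .stack_ndim(image)
  maxval <- 2^image$bit_depth - 1
  saturated <- mean(arr[nucleus_mask] >= maxval) >= 0.01
  if (saturated) {
    warning("FISH channel is saturated over >= 1% of the nucleus", call. = FALSE)
  }

  s_small <- spot_sigma_um / vox[1L]
  s_big <- bg_sigma_factor * s_small
  dog_plane <- function(m) {
    as.array(EBImage::gblur(m, sigma = s_small)) -
      as.array(EBImage::gblur(m, sigma = s_big))
  }

  dog_threshold <- function(vals) median(vals) + k * mad(vals)

  if (nd == 2L) {
    dog <- dog_plane(arr)
    thr <- dog_threshold(dog[nucleus_mask])
    pk <- .local_maxima_2d(dog)
    keep <- nucleus_mask[pk] & dog[pk] > thr
    pk <- pk[keep, , drop = FALSE]
    cand <- data.frame(x_um = (pk[, 1L] - 0.5) * vox[1L],
                       y_um = (pk[, 2L] - 0.5) * vox[2L],
                       value = dog[pk])
  } else {
    cand <- do.call(rbind, lapply(seq_len(dim(arr)[3L]), function(z) {
      dg <- dog_plane(arr[, , z])
      msk <- nucleus_mask[, , z]
      if (!any(msk)) return(NULL)
      thr <- dog_threshold(dg[msk])
      pk <- .local_maxima_2d(dg)
      keep <- msk[pk] & dg[pk] > thr
      pk <- pk[keep, , drop = FALSE]
      if (!nrow(pk)) return(NULL)
      data.frame(x_um = (pk[, 1L] - 0.5) * vox[1L],
                 y_um = (pk[, 2L] - 0.5) * vox[2L],
                 z_um = (z - 0.5) * vox[3L], value = dg[pk])
    }))
    if (is.null(cand)) cand <- data.frame(x_um = numeric(0), y_um = numeric(0),
                                          z_um = numeric(0), value = numeric(0))
  }

  ## greedy merge: brightest first, drop candidates within min separation
  ## in-plane (and within one z-step for stacks) of a retained focus
  cand <- cand[order(-cand$value), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      dxy <- sqrt((cand$x_um[i] - cand$x_um[j])^2 +
                    (cand$y_um[i] - cand$y_um[j])^2)
      dz <- if (nd == 3L) abs(cand$z_um[i] - cand$z_um[j]) else 0
      if (dxy < min_separation_um && dz <= vox[length(vox)] + 1e-9) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  cols <- if (nd == 3L) c("x_um", "y_um", "z_um") else c("x_um", "y_um")
  out <- as.matrix(cand[kept, cols, drop = FALSE])
  rownames(out) <- NULL
  structure(out, n = nrow(out), saturated = saturated,
            params = list(k = k, min_separation_um = min_separation_um,
                          spot_sigma_um = spot_sigma_um,
                          bg_sigma_factor = bg_sigma_factor))
}

#' Count FISH foci for every nucleus of a labelled mask
#'
#' Runs [detect_foci()] per labelled nucleus and assembles the per-nucleus
#' records with the standard count category.
#'
#' @param image an [image_stack].
#' @param label_mask integer array; 0 = background, k = nucleus k.
#' @param fish_channel FISH channel name.
#' @param metadata optional data frame with columns `nucleus_id` and any of
#'   `stage`, `lineage`, matched to labels by position.
#' @param ... passed to [detect_foci()].
#' @return data frame with one row per nucleus: `nucleus_id`, `stage`,
#'   `lineage`, `n_foci`, `category`, `saturated`; focus coordinate
#'   matrices in `attr(, "foci_coordinates")`.
#' @export
count_fish_foci <- function(image, label_mask, fish_channel = "FISH",
                            metadata = NULL, ...) {
  ids <- sort(setdiff(unique(as.integer(label_mask)), 0L))
  .assert(length(ids) >= 1L, "label mask contains no nuclei")
  coords <- list()
  rows <- lapply(seq_along(ids), function(i) {
    lab <- ids[i]
    fc <- detect_foci(image, fish_channel, label_mask == lab, ...)
    coords[[i]] <<- fc
    md <- if (!is.null(metadata) && i <= nrow(metadata)) metadata[i, ] else
      list()
    data.frame(
      nucleus_id = as.character(md$nucleus_id %||% lab),
      stage = as.character(md$stage %||% NA_character_),
      lineage = as.character(md$lineage %||% NA_character_),
      n_foci = attr(fc, "n"),
      saturated = attr(fc, "saturated"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$category <- bin_foci_category(out$n_foci)
  attr(out, "foci_coordinates") <- coords
  out
}

#' Tabulate focus-count categories by group
#'
#' Converts per-nucleus focus records into the per-group proportions of
#' cells with 0, 1-2, 3-4 and 5+ foci.  All four categories are always
#' emitted (empty ones with fraction 0) and fractions within a group sum
#' to 1.
#'
#' @param records data frame with at least `n_foci` and the grouping
#'   columns (as returned by [count_fish_foci()]).
#' @param group_by grouping columns; defaults to `stage` and `lineage`
#'   where present.
#' @return data frame: grouping columns, `category`, `n`, `fraction`,
#'   `n_nuclei`.
#' @examples
#' rec <- data.frame(n_foci = c(0, 0, 1, 5), stage = "E3.5", lineage = "EPI")
#' bin_and_tabulate(rec)
#' @export
bin_and_tabulate <- function(records, group_by = NULL) {
  .assert(is.data.frame(records) && nrow(records) >= 1L,
          "records must be a non-empty data frame")
  .assert("n_foci" %in% names(records), "records must have a n_foci column")
  group_by <- group_by %||% intersect(c("stage", "lineage"), names(records))
  cat <- bin_foci_category(records$n_foci)
  key <- if (length(group_by)) {
    interaction(records[group_by], drop = TRUE, sep = "|")
  } else {
    factor(rep("all", nrow(records)))
  }
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    sel <- key == lv
    counts <- table(cat[sel])
    base <- if (length(group_by)) {
      records[which(sel)[1L], group_by, drop = FALSE]
    } else {
      data.frame(group = "all")
    }
    cbind(base[rep(1L, length(.FOCI_CATEGORIES)), , drop = FALSE],
          data.frame(category = .FOCI_CATEGORIES,
                     n = as.integer(counts[.FOCI_CATEGORIES]),
                     fraction = as.numeric(counts[.FOCI_CATEGORIES]) / sum(sel),
                     n_nuclei = sum(sel)))
  }))
  rownames(out) <- NULL
  out
}
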