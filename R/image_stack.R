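#' Multi-channel image stack
#'
#' Container for a registered multi-channel fluorescence image: a named list
#' of 2-D matrices (single optical section) or 3-D arrays (z-stack), all of
#' identical shape, together with the voxel size in micrometres per axis and
#' the acquisition bit depth (8 or 16).  Intensities are stored as doubles in
#' raw camera units (`0 .. 2^bit_depth - 1`); they are only quantised when
#' written to TIFF.
#'
#' Axis convention: arrays are indexed `[x, y]` or `[x, y, z]` and
#' `voxel_size` follows the same order, so `voxel_size = c(0.1, 0.1, 0.5)`
#' means 0.1 um in-plane pixels with a 0.5 um z-step.  Physical coordinates
#' are in micrometres with the centre of pixel `i` at `(i - 0.5) * voxel`.
#'
#' @param channels named list of numeric arrays of identical dimension.
#' @param voxel_size numeric vector, micrometres per axis (length = number of
#'   array dimensions).
#' @param bit_depth integer, 8 or 16.
#' @return an object of class `image_stack`.
#' @examples
#' img <- image_stack(list(DAPI = matrix(100, 8, 8)), voxel_size = c(0.1, 0.1))
#' channel_names(img)
#' @export
image_stack <- function(channels, voxel_size, bit_depth = 16L) {
  .assert(is.list(channels) && length(channels) >= 1L &&
            !is.null(names(channels)) && all(nzchar(names(channels))),
          "channels must be a non-empty named list of arrays")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch) || is.array(ch)) ch else as.matrix(ch)
  })
  dims <- dim(channels[[1L]])
  for (ch in channels) {
    .assert(identical(dim(ch), dims), "all channels must share one shape")
  }
  .assert(length(voxel_size) == length(dims) && all(voxel_size > 0),
          "voxel_size must give a positive size per image axis")
  .assert(bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  for (ch in channels) {
    .assert(all(is.finite(ch)) && min(ch) >= 0 && max(ch) <= maxval,
            sprintf("intensities must lie in [0, %d]", as.integer(maxval)))
  }
  structure(
    list(channels = channels, voxel_size = as.numeric(voxel_size),
         bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  dims <- dim(x$channels[[1L]])
  cat(sprintf("<image_stack> %s px, voxel %s um, %d-bit\n",
              paste(dims, collapse = " x "),
              paste(format(x$voxel_size), collapse = " x "),
              x$bit_depth))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
channel_names <- function(x) names(x$channels)

#' @rdname image_stack
#' @param name channel name.
#' @export
get_channel <- function(x, name) {
  .assert(name %in% names(x$channels),
          sprintf("unknown channel '%s' (have: %s)", name,
                  paste(names(x$channels), collapse = ", ")))
  x$channels[[name]]
}

.stack_dim <- function(x) dim(x$channels[[1L]])
.stack_ndim <- function(x) length(.stack_dim(x))

#' Write / read an image stack as TIFF files
#'
#' Each channel is written to `<prefix>_<channel>.tif` (one page per z-plane
#' for 3-D stacks) and the geometry (channel names, voxel size, bit depth)
#' to a `<prefix>_stack.yaml` sidecar, so that `read_image_stack(prefix)`
#' restores the object.  Intensities are scaled by `2^bit_depth - 1` into
#' the `[0, 1]` range the TIFF writer expects and are therefore quantised
#' to within one integer grey level on disk.
#'
#' @param x an `image_stack`.
#' @param prefix path prefix for the output files.
#' @return `write_image_stack` returns the sidecar path invisibly;
#'   `read_image_stack` returns an `image_stack`.
#' @export
write_image_stack <- function(x, prefix) {
  .assert(inherits(x, "image_stack"), "x must be an image_stack")
  maxval <- 2^x$bit_depth - 1
  files <- character(0)
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]] / maxval
    pages <- if (length(dim(ch)) == 3L) {
      lapply(seq_len(dim(ch)[3L]), function(k) t(ch[, , k]))
    } else {
      list(t(ch))
    }
    f <- paste0(prefix, "_", nm, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = x$bit_depth)
    files <- c(files, basename(f))
  }
  side <- paste0(prefix, "_stack.yaml")
  yaml::write_yaml(list(channels = as.list(setNames(files, names(x$channels))),
                        voxel_size = x$voxel_size, bit_depth = x$bit_depth),
                   side)
  invisible(side)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(prefix) {
  side <- paste0(prefix, "_stack.yaml")
  .assert(file.exists(side), sprintf("no stack sidecar at '%s'", side))
  meta <- yaml::read_yaml(side)
  maxval <- 2^meta$bit_depth - 1
  dirn <- dirname(side)
  channels <- lapply(meta$channels, function(f) {
    pages <- tiff::readTIFF(file.path(dirn, f), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    planes <- lapply(pages, function(p) t(p) * maxval)
    if (length(planes) == 1L) planes[[1L]] else {
      arr <- array(0, c(dim(planes[[1L]]), length(planes)))
      for (k in seq_along(planes)) arr[, , k] <- planes[[k]]
      arr
    }
  })
  image_stack(channels, voxel_size = as.numeric(meta$voxel_size),
              bit_depth = meta$bit_depth)
}
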