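`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## Run `expr` under a fixed seed if one is given, without disturbing the
## caller's RNG state; seeds derived from a root seed stay below 2^31.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

## Pixel-centre coordinates (micrometres) along each image axis.
.axes_um <- function(shape, voxel_size) {
  lapply(seq_along(shape), function(k) (seq_len(shape[k]) - 0.5) * voxel_size[k])
}

## Squared Euclidean distance (um^2) from `center` at every voxel, built by
## outer sums so it works for 2-D and 3-D anisotropic grids alike.
.dist2_grid <- function(axes, center) {
  out <- (axes[[1L]] - center[1L])^2
  for (k in seq_along(axes)[-1L]) {
    out <- outer(out, (axes[[k]] - center[k])^2, "+")
  }
  out
}

## Binary dilation by a Chebyshev ball of radius `iterations` pixels,
## implemented as repeated axis-wise shifts (works for any dimensionality).
.dilate_mask <- function(mask, iterations = 1L) {
  .assert(is.logical(mask) && !is.null(dim(mask)), "mask must be a logical array")
  dims <- dim(mask)
  nd <- length(dims)
  out <- mask
  for (it in seq_len(iterations)) {
    ## sequential axis-wise dilation composes to the 3^nd box element
    for (ax in seq_len(nd)) {
      n <- dims[ax]
      if (n < 2L) next
      idx_lo <- lapply(dims, seq_len)
      idx_hi <- idx_lo
      idx_lo[[ax]] <- c(1L, seq_len(n - 1L))   # shift +1 along ax
      idx_hi[[ax]] <- c(seq_len(n - 1L) + 1L, n) # shift -1 along ax
      out <- out | do.call(`[`, c(list(out), idx_lo)) |
        do.call(`[`, c(list(out), idx_hi))
    }
  }
  out
}

## Connected-component labelling (orthogonal connectivity: 4 in 2-D, 6 in
## 3-D) by breadth-first search over linear indices.
.label_components <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  strides <- cumprod(c(1L, dims[-nd]))
  labels <- integer(length(mask))
  coord <- function(i, ax) ((i - 1L) %/% strides[ax]) %% dims[ax] + 1L
  comp <- 0L
  for (s in which(mask)) {
    if (labels[s] > 0L) next
    comp <- comp + 1L
    frontier <- s
    labels[s] <- comp
    while (length(frontier)) {
      nxt <- integer(0)
      for (ax in seq_len(nd)) {
        cc <- coord(frontier, ax)
        lo <- frontier[cc > 1L] - strides[ax]
        hi <- frontier[cc < dims[ax]] + strides[ax]
        nb <- c(lo, hi)
        nb <- nb[mask[nb] & labels[nb] == 0L]
        if (length(nb)) {
          labels[nb] <- comp
          nxt <- c(nxt, nb)
        }
      }
      frontier <- unique(nxt)
    }
  }
  array(labels, dims)
}

## Deterministic TSV writer: fixed significant digits so that re-running a
## pipeline with the same config yields byte-identical tables.
.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = NA))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
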