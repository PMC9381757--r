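## Synthetic microscopy: nuclei with DAPI-dense chromocenters and a marker
## channel in one of three enrichment modes, FISH images with planted
## transcription foci, and simple quantification fixtures.  Every generator
## returns the ground truth alongside the image and is byte-deterministic
## under a seed.

## Gaussian chromocenter: sd = radius / 2, so the above-mean DAPI bell of a
## typical line profile spans roughly the nominal radius.
.FOCUS_SIGMA_PER_RADIUS <- 0.5

## Shell and in-focus weights of the "cloudy" marker mode (see vignette):
## the shell sits at `cloudy_ring_radius_frac * radius` from the focus
## centre with sd `cloudy_ring_width / 2`, on top of a weak colocalised
## component, reproducing the bimodal cross-profile with an overall
## mildly positive DAPI correlation.
.CLOUDY_DEFAULT_WEIGHT <- 0.5
.CLOUDY_DEFAULT_RING_FRAC <- 0.45

.add_noise <- function(values, noise_sd, poisson_gain, maxval) {
  if (poisson_gain > 0) {
    values <- rpois(length(values), pmax(values, 0) / poisson_gain) * poisson_gain
  }
  if (noise_sd > 0) {
    values <- values + rnorm(length(values), 0, noise_sd)
  }
  pmin(pmax(values, 0), maxval)
}

## Rejection-sample `n` non-overlapping focus centres with radii `radii`
## inside a ball of radius `R` around `center` (all in micrometres).
.sample_foci_centers <- function(n, radii, center, R, min_gap = 0,
                                 max_attempts = 1000L) {
  nd <- length(center)
  centers <- matrix(NA_real_, n, nd)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      room <- R - radii[i]
      .assert(room > 0, "chromocenter radius exceeds the nucleus radius")
      cand <- center + runif(nd, -room, room)
      if (sum((cand - center)^2) > room^2) next
      if (i > 1L) {
        d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                             matrix(cand, i - 1L, nd, byrow = TRUE))^2))
        if (any(d < radii[seq_len(i - 1L)] + radii[i] + min_gap)) next
      }
      centers[i, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(paste0("could not place %d non-overlapping chromocenters ",
                          "of radius %.2f-%.2f um in a nucleus of radius ",
                          "%.2f um after %d attempts"),
                   n, min(radii), max(radii), R, max_attempts), call. = FALSE)
    }
  }
  centers
}

#' Generate a synthetic nucleus with chromocenters and a marker channel
#'
#' Builds a two-channel (DAPI + marker) image of a single nucleus containing
#' DAPI-dense chromocenter foci, with the marker channel in one of three
#' enrichment modes mirroring the patterns seen across early development:
#'
#' * `"colocalized"` - marker foci share the DAPI focus centres and widths,
#'   so inside the nucleus the marker is a positive affine transform of DAPI
#'   (the fully enriched, 16-cell-like pattern; noiseless PCC = 1);
#' * `"cloudy"` - marker accumulates in and around each focus as a weak
#'   in-focus component plus a Gaussian shell, giving a bimodal cross-profile
#'   with a local minimum at the DAPI peak (the 2-cell-like pattern);
#' * `"diffuse"` - marker is spatially uniform over the nucleus (the
#'   post-implantation / primed pattern; PCC centred on 0).
#'
#' Chromocenters are isotropic Gaussians of sd `radius / 2`, placed by
#' rejection sampling so that they do not overlap and lie fully inside the
#' nucleus.  Intensities are expressed as fractions of the dynamic range
#' `2^bit_depth - 1`.  Noise is additive Gaussian with an optional Poisson
#' (shot-noise) component controlled by `poisson_gain`.
#'
#' @param image_shape integer vector of pixels per axis (2-D or 3-D).
#' @param voxel_size micrometres per axis; defaults to 0.1 um in plane and,
#'   for 3-D shapes, a 0.5 um z-step.
#' @param bit_depth 8 or 16.
#' @param nucleus_radius nucleus radius in micrometres.
#' @param n_chromocenters number of chromocenter foci.
#' @param chromocenter_radius_range min/max focus radius (um).
#' @param dapi_focus_contrast ratio of chromocenter DAPI peak to the
#'   nucleoplasm baseline (> 1).
#' @param marker_mode `"colocalized"`, `"cloudy"` or `"diffuse"`.
#' @param cloudy_ring_width full width (um) of the cloudy-mode shell
#'   (shell sd = width / 2).
#' @param cloudy_ring_radius_frac shell centre as a fraction of the focus
#'   radius.
#' @param cloudy_infocus_weight weight of the colocalised component in the
#'   cloudy mode, relative to the shell peak.
#' @param marker_name channel name for the marker (e.g. `"H3K27me3"`).
#' @param noise_sd additive Gaussian noise sd in intensity units.
#' @param poisson_gain camera gain for the optional Poisson component
#'   (0 disables it).
#' @param dapi_baseline_frac,marker_baseline_frac,outside_frac baselines of
#'   the DAPI / marker channels inside the nucleus and of all channels
#'   outside it, as fractions of the dynamic range.
#' @param marker_amplitude_frac marker focus amplitude as a fraction of the
#'   dynamic range.
#' @param diffuse_level_frac uniform marker elevation (above baseline) in the
#'   diffuse mode, as a fraction of the dynamic range.
#' @param seed RNG seed; identical arguments + seed give identical output.
#' @param max_attempts rejection-sampling budget for focus placement.
#' @return a list of class `synthetic_nucleus` with elements `image` (an
#'   [image_stack] with channels `DAPI` and `marker_name`), `truth` (focus
#'   centres/radii in um, nucleus centre/radius, logical nucleus mask) and
#'   `params`.
#' @examples
#' syn <- generate_nucleus_image(n_chromocenters = 2, seed = 1)
#' syn$truth$foci
#' @export
generate_nucleus_image <- function(image_shape = c(128L, 128L),
                                   voxel_size = NULL,
                                   bit_depth = 16L,
                                   nucleus_radius = 5,
                                   n_chromocenters = 4L,
                                   chromocenter_radius_range = c(0.8, 1.2),
                                   dapi_focus_contrast = 3,
                                   marker_mode = c("colocalized", "cloudy", "diffuse"),
                                   cloudy_ring_width = 0.4,
                                   cloudy_ring_radius_frac = .CLOUDY_DEFAULT_RING_FRAC,
                                   cloudy_infocus_weight = .CLOUDY_DEFAULT_WEIGHT,
                                   marker_name = "marker",
                                   noise_sd = 600,
                                   poisson_gain = 0,
                                   dapi_baseline_frac = 0.15,
                                   marker_baseline_frac = 0.08,
                                   outside_frac = 0.02,
                                   marker_amplitude_frac = 0.25,
                                   diffuse_level_frac = 0.1,
                                   seed = NULL,
                                   max_attempts = 1000L) {
  marker_mode <- match.arg(marker_mode)
  nd <- length(image_shape)
  .assert(nd %in% c(2L, 3L), "image_shape must be 2-D or 3-D")
  if (is.null(voxel_size)) {
    voxel_size <- if (nd == 2L) c(0.1, 0.1) else c(0.1, 0.1, 0.5)
  }
  .assert(length(voxel_size) == nd, "voxel_size must match image_shape")
  .assert(dapi_focus_contrast > 1, "dapi_focus_contrast must exceed 1")
  .assert(n_chromocenters >= 0L, "n_chromocenters must be non-negative")
  .assert(length(chromocenter_radius_range) == 2L &&
            chromocenter_radius_range[1L] <= chromocenter_radius_range[2L],
          "chromocenter_radius_range must be an increasing interval")
  field <- image_shape * voxel_size
  center <- field / 2
  .assert(nucleus_radius <= min(field) / 2,
          "nucleus does not fit inside the image")

  maxval <- 2^bit_depth - 1
  out <- .with_seed(seed, {
    axes <- .axes_um(image_shape, voxel_size)
    d2_nuc <- .dist2_grid(axes, center)
    inside <- d2_nuc <= nucleus_radius^2

    radii <- if (n_chromocenters > 0L) {
      runif(n_chromocenters, chromocenter_radius_range[1L],
            chromocenter_radius_range[2L])
    } else numeric(0)
    centers <- if (n_chromocenters > 0L) {
      .sample_foci_centers(n_chromocenters, radii, center, nucleus_radius,
                           max_attempts = max_attempts)
    } else matrix(numeric(0), 0L, nd)

    dapi_base <- dapi_baseline_frac * maxval
    out_base <- outside_frac * maxval
    m_base <- marker_baseline_frac * maxval
    a_dapi <- (dapi_focus_contrast - 1) * dapi_base
    a_marker <- marker_amplitude_frac * maxval

    gsum <- array(0, image_shape)   # colocalised focus profile
    csum <- array(0, image_shape)   # cloudy-mode profile
    for (i in seq_len(n_chromocenters)) {
      d2 <- .dist2_grid(axes, centers[i, ])
      sig <- .FOCUS_SIGMA_PER_RADIUS * radii[i]
      g <- exp(-d2 / (2 * sig^2))
      gsum <- gsum + g
      if (marker_mode == "cloudy") {
        rs <- cloudy_ring_radius_frac * radii[i]
        ss <- cloudy_ring_width / 2
        csum <- csum + cloudy_infocus_weight * g +
          exp(-(sqrt(d2) - rs)^2 / (2 * ss^2))
      }
    }

    dapi <- out_base + (dapi_base - out_base) * inside + a_dapi * gsum * inside
    marker <- switch(
      marker_mode,
      colocalized = out_base + (m_base - out_base) * inside +
        a_marker * gsum * inside,
      cloudy = out_base + (m_base - out_base) * inside +
        a_marker * csum * inside,
      diffuse = out_base + (m_base - out_base + diffuse_level_frac * maxval) *
        inside
    )
    dapi <- array(.add_noise(dapi, noise_sd, poisson_gain, maxval), image_shape)
    marker <- array(.add_noise(marker, noise_sd, poisson_gain, maxval),
                    image_shape)

    foci <- as.data.frame(centers)
    names(foci) <- paste0(c("x", "y", "z")[seq_len(nd)], "_um")
    foci <- cbind(focus_id = seq_len(n_chromocenters), foci,
                  radius_um = radii,
                  sigma_um = .FOCUS_SIGMA_PER_RADIUS * radii)
    channels <- setNames(list(dapi, marker), c("DAPI", marker_name))
    list(image = image_stack(channels, voxel_size, bit_depth),
         truth = list(foci = foci, nucleus_center_um = center,
                      nucleus_radius_um = nucleus_radius, mask = inside))
  })
  out$params <- list(marker_mode = marker_mode, noise_sd = noise_sd,
                     dapi_focus_contrast = dapi_focus_contrast,
                     cloudy_ring_width = cloudy_ring_width,
                     cloudy_ring_radius_frac = cloudy_ring_radius_frac,
                     cloudy_infocus_weight = cloudy_infocus_weight,
                     marker_amplitude_frac = marker_amplitude_frac,
                     seed = seed)
  class(out) <- "synthetic_nucleus"
  out
}

#' Generate a synthetic RNA-FISH image with planted transcription foci
#'
#' Lays `length(n_foci_per_nucleus)` circular nuclei on a rectangular grid of
#' square tiles and plants the requested number of Gaussian FISH spots in
#' each, at least `min_separation` apart and away from the nuclear rim.  The
#' truth table records every spot coordinate, so detection can be scored
#' exactly.
#'
#' If `focus_amplitude < 5 * noise_sd` the spots sit near the noise floor and
#' a warning is issued (the image is still produced, with
#' `attr(, "low_snr") = TRUE` on the truth table).
#'
#' @param n_foci_per_nucleus integer vector; ground-truth focus count per
#'   nucleus.
#' @param focus_amplitude spot peak amplitude (intensity units).
#' @param focus_sigma spot Gaussian sd (um).
#' @param noise_sd additive Gaussian noise sd.
#' @param nucleus_radius nucleus radius (um).
#' @param tile_px side of the square per-nucleus tile (pixels).
#' @param voxel_size in-plane pixel size (um), length 2.
#' @param bit_depth 8 or 16.
#' @param dapi_level_frac,fish_baseline_frac,outside_frac levels as fractions
#'   of the dynamic range.
#' @param min_separation minimum distance between planted spots (um).
#' @param seed RNG seed.
#' @return a list of class `synthetic_fish` with `image` (channels `DAPI`,
#'   `FISH`), `label_mask` (integer array, 0 = background, k = nucleus k) and
#'   `truth` (data frame: nucleus_id, focus_id, x_um, y_um).
#' @export
generate_fish_image <- function(n_foci_per_nucleus = c(0L, 1L, 2L, 3L, 5L),
                                focus_amplitude = 12000,
                                focus_sigma = 0.2,
                                noise_sd = 600,
                                nucleus_radius = 2.5,
                                tile_px = 64L,
                                voxel_size = c(0.1, 0.1),
                                bit_depth = 16L,
                                dapi_level_frac = 0.15,
                                fish_baseline_frac = 0.05,
                                outside_frac = 0.02,
                                min_separation = 1,
                                seed = NULL) {
  counts <- as.integer(n_foci_per_nucleus)
  .assert(all(counts >= 0L), "focus counts must be non-negative")
  n_nuc <- length(counts)
  .assert(n_nuc >= 1L, "need at least one nucleus")
  tile_um <- tile_px * voxel_size
  .assert(nucleus_radius < min(tile_um) / 2, "nucleus does not fit its tile")
  low_snr <- focus_amplitude < 5 * noise_sd
  if (low_snr) {
    warning("focus_amplitude is below 5 x noise_sd; planted foci may not be detectable",
            call. = FALSE)
  }
  ncol_t <- ceiling(sqrt(n_nuc))
  nrow_t <- ceiling(n_nuc / ncol_t)
  shape <- c(ncol_t * tile_px, nrow_t * tile_px)
  maxval <- 2^bit_depth - 1

  out <- .with_seed(seed, {
    axes <- .axes_um(shape, voxel_size)
    dapi <- array(outside_frac * maxval, shape)
    fish <- array(outside_frac * maxval, shape)
    labels <- array(0L, shape)
    rows <- list()
    margin <- 3 * focus_sigma
    for (k in seq_len(n_nuc)) {
      tx <- (k - 1L) %% ncol_t
      ty <- (k - 1L) %/% ncol_t
      cen <- c((tx + 0.5) * tile_um[1L], (ty + 0.5) * tile_um[2L])
      d2 <- .dist2_grid(axes, cen)
      inside <- d2 <= nucleus_radius^2
      labels[inside] <- k
      dapi[inside] <- dapi_level_frac * maxval
      fish[inside] <- fish_baseline_frac * maxval
      if (counts[k] > 0L) {
        pts <- .sample_foci_centers(counts[k],
                                    rep(min_separation / 2, counts[k]),
                                    cen, nucleus_radius - margin +
                                      min_separation / 2)
        for (i in seq_len(counts[k])) {
          df2 <- .dist2_grid(axes, pts[i, ])
          fish <- fish + focus_amplitude * exp(-df2 / (2 * focus_sigma^2))
          rows[[length(rows) + 1L]] <- data.frame(
            nucleus_id = k, focus_id = i, x_um = pts[i, 1L], y_um = pts[i, 2L])
        }
      }
    }
    dapi <- array(.add_noise(dapi, noise_sd, 0, maxval), shape)
    fish <- array(.add_noise(fish, noise_sd, 0, maxval), shape)
    truth <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(nucleus_id = integer(0), focus_id = integer(0),
                 x_um = numeric(0), y_um = numeric(0))
    }
    attr(truth, "n_foci") <- counts
    attr(truth, "low_snr") <- low_snr
    list(image = image_stack(list(DAPI = dapi, FISH = fish), voxel_size,
                             bit_depth),
         label_mask = labels, truth = truth)
  })
  out$params <- list(focus_amplitude = focus_amplitude,
                     focus_sigma = focus_sigma, noise_sd = noise_sd,
                     min_separation = min_separation, seed = seed)
  class(out) <- "synthetic_fish"
  out
}

#' Generate a quantification fixture nucleus
#'
#' Single-nucleus image for testing whole-nucleus and region quantification:
#' the marker channel is `background + amplitude * sum of Gaussian blobs`
#' inside the nucleus, with the nucleoplasm level equal to the outside
#' background, so that after local background subtraction the integrated
#' marker signal is exactly proportional to `marker_amplitude`.  With
#' `xi = TRUE` two additional channels emulate the inactive-X measurement:
#' a defining channel (`EZH2`) carrying one bright patch, and a target
#' channel (`XiTarget`) whose signal over that patch scales with
#' `xi_target_amplitude`.
#'
#' @param marker_amplitude peak amplitude of the marker blobs.
#' @param n_blobs number of marker blobs.
#' @param blob_sigma blob Gaussian sd (um).
#' @param nucleus_radius nucleus radius (um).
#' @param image_shape,voxel_size,bit_depth image geometry.
#' @param background_frac,dapi_level_frac levels as fractions of the range.
#' @param noise_sd additive Gaussian noise sd.
#' @param xi add the inactive-X channels.
#' @param xi_patch_radius radius (um) of the Xi patch.
#' @param xi_defining_level intensity of the patch in the defining channel.
#' @param xi_target_amplitude peak amplitude of the target signal over the
#'   patch.
#' @param seed RNG seed.
#' @return list of class `synthetic_quant` with `image`, `mask` (logical
#'   nucleus mask) and `truth` (blob / patch geometry).
#' @export
generate_quant_image <- function(marker_amplitude = 12000,
                                 n_blobs = 3L,
                                 blob_sigma = 0.5,
                                 nucleus_radius = 4,
                                 image_shape = c(96L, 96L),
                                 voxel_size = c(0.1, 0.1),
                                 bit_depth = 16L,
                                 background_frac = 0.02,
                                 dapi_level_frac = 0.15,
                                 noise_sd = 0,
                                 xi = FALSE,
                                 xi_patch_radius = 0.8,
                                 xi_defining_level = 20000,
                                 xi_target_amplitude = 10000,
                                 seed = NULL) {
  nd <- length(image_shape)
  .assert(nd == 2L, "quantification fixtures are single-plane 2-D images")
  maxval <- 2^bit_depth - 1
  field <- image_shape * voxel_size
  center <- field / 2
  .assert(nucleus_radius <= min(field) / 2, "nucleus does not fit the image")

  out <- .with_seed(seed, {
    axes <- .axes_um(image_shape, voxel_size)
    inside <- .dist2_grid(axes, center) <= nucleus_radius^2
    bg <- background_frac * maxval
    dapi <- bg + (dapi_level_frac * maxval - bg) * inside
    blob_room <- nucleus_radius - 3 * blob_sigma
    pts <- .sample_foci_centers(n_blobs, rep(blob_sigma, n_blobs), center,
                                blob_room + blob_sigma)
    gsum <- array(0, image_shape)
    for (i in seq_len(n_blobs)) {
      gsum <- gsum + exp(-.dist2_grid(axes, pts[i, ]) / (2 * blob_sigma^2))
    }
    marker <- bg + marker_amplitude * gsum * inside
    channels <- list(DAPI = dapi, marker = marker)
    truth <- list(blob_centers_um = pts, blob_sigma_um = blob_sigma,
                  nucleus_center_um = center,
                  nucleus_radius_um = nucleus_radius)
    if (xi) {
      ## patch offset from the nucleus centre, fully inside
      patch_cen <- center + c(nucleus_radius / 2, 0)
      pin <- .dist2_grid(axes, patch_cen) <= xi_patch_radius^2
      channels$EZH2 <- bg + (xi_defining_level - bg) * (pin & inside)
      channels$XiTarget <- bg + xi_target_amplitude * (pin & inside)
      truth$xi_center_um <- patch_cen
      truth$xi_radius_um <- xi_patch_radius
      truth$xi_mask <- pin & inside
    }
    channels <- lapply(channels, function(ch) {
      array(.add_noise(ch, noise_sd, 0, maxval), image_shape)
    })
    list(image = image_stack(channels, voxel_size, bit_depth),
         mask = inside, truth = truth)
  })
  out$params <- list(marker_amplitude = marker_amplitude, noise_sd = noise_sd,
                     xi = xi, xi_target_amplitude = xi_target_amplitude,
                     seed = seed)
  class(out) <- "synthetic_quant"
  out
}
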