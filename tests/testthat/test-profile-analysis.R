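make_profile <- function(intensity, step = 0.05) {
  n <- nrow(intensity)
  structure(list(
    positions_um = (seq_len(n) - (n + 1) / 2) * step,
    intensity = intensity,
    center_um = c(0, 0), direction = c(1, 0),
    endpoints_um = rbind(c(0, 0), c(1, 0)),
    plane = NA_integer_, truncated = FALSE
  ), class = "line_profile")
}

test_that("extract_profile samples a constant image as a constant profile", {
  img <- image_stack(list(DAPI = matrix(123.4, 40, 40)), c(0.1, 0.1))
  prof <- extract_profile(img, center = c(2, 2), half_length = 1)
  expect_lt(max(abs(prof$intensity[, "DAPI"] - 123.4)), 1e-9)
  expect_equal(diff(prof$positions_um), rep(0.05, length(prof$positions_um) - 1))
  expect_equal(prof$positions_um[which.min(abs(prof$positions_um))], 0)
})

test_that("extract_profile validates inputs and reports truncation", {
  img <- image_stack(list(DAPI = matrix(10, 40, 40)), c(0.1, 0.1))
  expect_error(extract_profile(img, c(2, 2), channels = "nope"),
               "unknown channel")
  expect_error(extract_profile(img, c(2, 2), half_length = 0), "positive")
  expect_error(extract_profile(img, c(2, 2), direction = c(0, 0)),
               "non-zero")
  near_edge <- extract_profile(img, c(0.3, 2), half_length = 1)
  expect_true(near_edge$truncated)
  expect_true(all(near_edge$positions_um >= -0.31))
})

test_that("profiles through a noiseless colocalized focus peak at 0 and match the generator formula", {
  syn <- generate_nucleus_image(marker_mode = "colocalized", noise_sd = 0,
                                n_chromocenters = 1L,
                                chromocenter_radius_range = c(1.0, 1.2),
                                seed = 8)
  ctr <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
  prof <- extract_profile(syn$image, ctr, half_length = 2)
  for (ch in c("DAPI", "marker")) {
    v <- prof$intensity[, ch]
    expect_lt(abs(prof$positions_um[which.max(v)]), 0.051)
    ## compare with the generative formula well inside the nucleus, where
    ## bilinear sampling does not straddle the nuclear-rim intensity step
    core <- abs(prof$positions_um) <= 0.9
    pts <- cbind(ctr[1] + prof$positions_um[core], ctr[2])
    want <- oracle_nucleus_value(syn$truth, syn$params, pts, ch)
    expect_lt(max(abs(v[core] - want)), 0.02 * diff(range(want)))
  }
})

test_that("profile direction is honoured", {
  syn <- generate_nucleus_image(marker_mode = "colocalized", noise_sd = 0,
                                n_chromocenters = 1L, seed = 8)
  ctr <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
  ## short profiles stay within the focus for any direction
  horiz <- extract_profile(syn$image, ctr, direction = c(1, 0),
                           half_length = 0.7)
  diag <- extract_profile(syn$image, ctr, direction = c(1, 1),
                          half_length = 0.7)
  ## an isotropic Gaussian looks the same along any midline direction
  expect_equal(diag$intensity[, "DAPI"], horiz$intensity[, "DAPI"],
               tolerance = 0.02)
})

test_that("delineation applies the above-mean rule exactly", {
  prof <- make_profile(cbind(DAPI = c(1, 1, 1, 5, 9, 5, 1, 1, 1)))
  seg <- delineate_chromocenter(prof)
  expect_true(seg$found)
  expect_equal(seg$threshold, 25 / 9)
  expect_equal(seg$start_index, 4)
  expect_equal(seg$end_index, 6)
  expect_equal(seg$peak_index, 5)
  expect_equal(seg$n_secondary_runs, 0)
})

test_that("flat profiles yield a no-chromocenter result, not an error", {
  seg <- delineate_chromocenter(make_profile(cbind(DAPI = rep(7, 9))))
  expect_false(seg$found)
  expect_true(is.na(seg$peak_index))
  expect_equal(seg$threshold, 7)
})

test_that("secondary above-mean runs are ignored but counted", {
  dapi <- c(1, 6, 1, 1, 5, 9, 5, 1, 6, 1)
  seg <- delineate_chromocenter(make_profile(cbind(DAPI = dapi)))
  expect_equal(seg$start_index, 5)
  expect_equal(seg$end_index, 7)
  expect_equal(seg$peak_index, 6)
  expect_equal(seg$n_secondary_runs, 2)
})

test_that("delineation matches the independent threshold-scan oracle on random bells", {
  withr::local_seed(42)
  for (i in 1:300) {
    n <- sample(15:80, 1)
    base <- runif(1, 1, 50)
    amp <- runif(1, 5, 200)
    ctr <- runif(1, 0.25, 0.75) * n
    sig <- runif(1, 1, n / 6)
    dapi <- base + amp * exp(-((seq_len(n) - ctr)^2) / (2 * sig^2)) +
      rnorm(n, 0, amp / 20)
    seg <- delineate_chromocenter(make_profile(cbind(DAPI = dapi)))
    want <- oracle_segment(dapi)
    if (is.null(want)) {
      expect_false(seg$found)
    } else {
      expect_equal(seg$start_index, want$start)
      expect_equal(seg$end_index, want$end)
      expect_equal(seg$peak_index, want$peak)
      expect_equal(seg$threshold, want$threshold)
    }
  }
})

test_that("segment half-width matches the mean-crossing radius of the Gaussian", {
  ## hand-built single Gaussian focus with fully controlled geometry
  base <- 2000; amp <- 18000; sigma <- 0.5
  vox <- c(0.1, 0.1)
  ax <- (seq_len(80) - 0.5) * vox[1]
  ctr <- c(4.02, 4.02)   # off pixel centres on purpose
  d2 <- outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+")
  img <- image_stack(list(DAPI = base + amp * exp(-d2 / (2 * sigma^2))), vox)
  prof <- extract_profile(img, ctr, half_length = 2)
  seg <- delineate_chromocenter(prof)
  dapi <- prof$intensity[, "DAPI"]
  ## crossing radius of the generative Gaussian at the profile-mean level
  lvl <- seg$threshold - base
  x_star <- sigma * sqrt(2 * log(amp / lvl))
  half_width <- (prof$positions_um[seg$end_index] -
                   prof$positions_um[seg$start_index]) / 2
  expect_lt(abs(half_width - x_star), 0.051)  # within one sample spacing
})

test_that("pcc_enrichment is exact on affine cases and matches the textbook formula", {
  dapi <- c(2, 4, 8, 4, 2)
  seg_all <- list(found = TRUE, start_index = 1L, end_index = 5L,
                  peak_index = 3L, threshold = 0, n_secondary_runs = 0L)
  class(seg_all) <- "chromocenter_segment"

  up <- make_profile(cbind(DAPI = dapi, marker = 2 * dapi + 10))
  expect_equal(pcc_enrichment(up, seg_all, "marker")$pcc, 1)

  down <- make_profile(cbind(DAPI = dapi, marker = -dapi))
  expect_equal(pcc_enrichment(down, seg_all, "marker")$pcc, -1)

  tent <- make_profile(cbind(DAPI = dapi, marker = c(1, 2, 3, 2, 1)))
  expect_equal(pcc_enrichment(tent, seg_all, "marker")$pcc,
               oracle_pearson(dapi, c(1, 2, 3, 2, 1)), tolerance = 1e-12)
})

test_that("zero-variance segments give an undefined PCC, never silently 0", {
  seg <- list(found = TRUE, start_index = 1L, end_index = 4L,
              peak_index = 2L, threshold = 0, n_secondary_runs = 0L)
  class(seg) <- "chromocenter_segment"
  flat <- make_profile(cbind(DAPI = c(5, 5, 5, 5), marker = c(1, 2, 3, 4)))
  rec <- pcc_enrichment(flat, seg, "marker")
  expect_true(rec$undefined)
  expect_true(is.na(rec$pcc))
})

test_that("PCC is invariant under positive affine transforms of either channel", {
  withr::local_seed(7)
  seg <- list(found = TRUE, start_index = 1L, end_index = 20L,
              peak_index = 10L, threshold = 0, n_secondary_runs = 0L)
  class(seg) <- "chromocenter_segment"
  for (i in 1:50) {
    d <- rnorm(20, 100, 20)
    m <- rnorm(20, 50, 10)
    base <- pcc_enrichment(make_profile(cbind(DAPI = d, marker = m)),
                           seg, "marker")$pcc
    a <- runif(2, 0.1, 10)
    b <- runif(2, -5, 5)
    tr <- pcc_enrichment(
      make_profile(cbind(DAPI = a[1] * d + b[1], marker = a[2] * m + b[2])),
      seg, "marker")$pcc
    expect_equal(tr, base, tolerance = 1e-9)
    expect_true(base >= -1 && base <= 1)
  }
})

test_that("metadata outside the standard vocabulary is flagged", {
  prof <- make_profile(cbind(DAPI = c(2, 4, 8, 9, 8, 4, 2),
                             marker = c(1, 2, 3, 4, 3, 2, 1)))
  seg <- delineate_chromocenter(prof)
  expect_warning(
    pcc_enrichment(prof, seg, "marker", metadata = list(stage = "99-cell")),
    "vocabulary"
  )
  rec <- pcc_enrichment(prof, seg, "marker",
                        metadata = list(stage = "2-cell", lineage = "EPI",
                                        nucleus_id = "n1"))
  expect_equal(rec$stage, "2-cell")
  expect_equal(rec$nucleus_id, "n1")
})

test_that("summarize_pcc groups, excludes undefined records and counts them", {
  rec <- data.frame(
    pcc = c(0.2, 0.4, 0.9, NA, 0.5),
    marker = "H3K27me3",
    undefined = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stage = c("2-cell", "2-cell", "2-cell", "2-cell", "16-cell"),
    lineage = "none",
    chromocenter_id = paste0("cc", 1:5),
    stringsAsFactors = FALSE
  )
  out <- summarize_pcc(rec)
  expect_equal(out$n_undefined, 1)
  two <- out$summary[out$summary$stage == "2-cell", ]
  expect_equal(two$n, 3)
  expect_equal(two$median, 0.4)
  expect_equal(two$min, 0.2)
  expect_equal(two$max, 0.9)
  sixteen <- out$summary[out$summary$stage == "16-cell", ]
  expect_equal(sixteen$n, 1)
  expect_equal(sixteen$median, 0.5)
  expect_equal(nrow(out$long), 4)
})

test_that("marker-mode medians are ordered colocalized > cloudy > diffuse over seeds", {
  n <- 25
  co <- median(simulate_mode_pccs("colocalized", n, 4000), na.rm = TRUE)
  cl <- median(simulate_mode_pccs("cloudy", n, 4100), na.rm = TRUE)
  di <- median(simulate_mode_pccs("diffuse", n, 4200), na.rm = TRUE)
  expect_gt(co, cl)
  expect_gt(cl, di)
})

test_that("noiseless colocalized recovery gives PCC = 1 to 1e-9", {
  for (s in 1:5) {
    syn <- generate_nucleus_image(marker_mode = "colocalized", noise_sd = 0,
                                  seed = 600 + s)
    ctr <- unlist(syn$truth$foci[1, c("x_um", "y_um")])
    prof <- extract_profile(syn$image, ctr, half_length = 2.5)
    seg <- delineate_chromocenter(prof)
    rec <- pcc_enrichment(prof, seg, "marker")
    expect_equal(rec$pcc, 1, tolerance = 1e-9)
  }
})
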