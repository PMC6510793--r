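test_that("a pure-noise frame yields no detection", {
  set.seed(1)
  img <- two_channel_image(
    matrix(as.integer(pmax(0, round(rnorm(150^2, 0.05, 0.01) * 4095))), 150),
    matrix(as.integer(pmax(0, round(rnorm(150^2, 0.05, 0.01) * 4095))), 150))
  expect_null(detect_bead(img))
})

test_that("objects under 100 pixels are filtered out", {
  red <- matrix(round(0.05 * 4095L), 150, 150)
  speck <- disk_mask(c(150L, 150L), c(75, 75), 3.9)   # ~48 px
  expect_lt(sum(speck), 100)
  red[speck] <- 3500L
  img <- two_channel_image(matrix(as.integer(red), 150),
                           matrix(round(0.05 * 4095L), 150, 150))
  expect_null(detect_bead(img))
  # the same object above 100 px is kept
  red2 <- matrix(round(0.05 * 4095L), 150, 150)
  blob <- disk_mask(c(150L, 150L), c(75, 75), 7)       # ~150 px
  expect_gt(sum(blob), 100)
  red2[blob] <- 3500L
  img2 <- two_channel_image(matrix(as.integer(red2), 150),
                            matrix(round(0.05 * 4095L), 150, 150))
  expect_length(detect_bead(img2), 1)
})

test_that("detected mask recovers the truth disk", {
  fr <- quick_render("CLASS1_RED_HOMOG", diameter_um = 150,
                     shape = c(220L, 220L), seed = 21)
  segs <- detect_bead(fr$image)
  expect_length(segs, 1)
  seg <- segs[[1]]
  truth <- fr$truth_masks[[1]]
  expect_equal(seg$area_px, sum(truth), tolerance = 0.1)
  truth_centroid <- colMeans(which(truth, arr.ind = TRUE))
  expect_lt(max(abs(seg$centroid - truth_centroid)), 3)
})

test_that("detection is robust to halved fluorescence intensity", {
  for (id in c("CLASS1_RED_HOMOG", "CLASS2_GREEN_HOMOG",
               "CLASS6_RED_NARROW_HALO")) {
    fr <- quick_render(id, diameter_um = 130, seed = 31)
    half <- two_channel_image(
      matrix(as.integer(fr$image$red %/% 2L), nrow(fr$image$red)),
      matrix(as.integer(fr$image$green %/% 2L), nrow(fr$image$green)))
    expect_length(detect_bead(half), length(detect_bead(fr$image)))
  }
})

test_that("green-only beads are detected through the channel union", {
  fr <- quick_render("CLASS2_GREEN_HOMOG", seed = 41)
  expect_length(detect_bead(fr$image), 1)
})

test_that("mask partitions hold on every class", {
  for (id in setdiff(bead_class_ids(), "UNLABELED")) {
    seg <- quick_seg(quick_render(id, seed = 51))
    expect_partition(seg)
  }
})

test_that("smoothing does not inflate the mask area", {
  for (d in c(100, 180)) {
    fr <- quick_render("CLASS3_DUAL_HOMOG", diameter_um = d, seed = 61)
    seg <- quick_seg(fr)
    ratio <- seg$area_px / sum(fr$truth_masks[[1]])
    expect_gte(ratio, 0.8)
    expect_lte(ratio, 1.1)
  }
})

test_that("bright stratum of a narrow-halo bead concentrates in the shell", {
  fr <- quick_render("CLASS6_RED_NARROW_HALO", diameter_um = 150,
                     shape = c(220L, 220L), seed = 71)
  seg <- quick_seg(fr)
  r_eq <- sqrt(seg$area_px / pi)
  center <- seg$centroid
  outer <- seg$bead_mask &
    !disk_mask(dim(seg$bead_mask), center, 0.75 * r_eq)
  expect_gte(sum(seg$bright_mask & outer) / sum(seg$bright_mask), 0.8)
})

test_that("a uniform bead forms a single bright stratum (empty dim mask)", {
  fr <- quick_render("CLASS1_RED_HOMOG", seed = 81, noise_sigma = 0,
                     label_jitter_sd = 0)
  seg <- quick_seg(fr)
  expect_false(any(seg$dim_mask))
  expect_identical(seg$bright_mask, seg$bead_mask)
})

test_that("segment_bright requires a nonempty mask", {
  img <- matrix(0.5, 50, 50)
  expect_error(segment_bright(img, matrix(FALSE, 50, 50)), "empty")
})

test_that("outer ring geometry matches the analytic annulus", {
  mask <- disk_mask(c(140L, 140L), c(70, 70), 50)
  rc <- outer_ring(mask, 0.2)
  expect_equal(sum(rc$outer_ring_mask) / sum(mask), 1 - 0.8^2,
               tolerance = 0.05)
  whole <- outer_ring(mask, 1)
  expect_identical(whole$outer_ring_mask, mask)
  expect_false(any(whole$core_mask))
  none <- outer_ring(mask, 0)
  expect_false(any(none$outer_ring_mask))
  expect_identical(none$core_mask, mask)
  expect_error(outer_ring(mask, 1.2), "\\[0, 1\\]")
})
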