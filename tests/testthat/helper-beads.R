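# shared fixtures: small frames keep the suite fast; geometry and metrics
# are scale-free in the bead radius, so nothing scientific depends on size

quick_render <- function(class_id, diameter_um = 120, seed = 1,
                         shape = c(200L, 200L), ...) {
  render_bead(default_class_spec(class_id), diameter_um = diameter_um,
              image_shape = shape, seed = seed, ...)
}

quick_seg <- function(frame, ...) {
  segs <- detect_bead(frame$image, ...)
  expect_false(is.null(segs))
  segs[[1]]
}

quick_metrics <- function(class_id, diameter_um = 120, seed = 1, ...) {
  fr <- quick_render(class_id, diameter_um, seed, ...)
  extract_metrics(fr$image, quick_seg(fr))
}

# independent sort-based percentile oracle (linear interpolation between
# order statistics at rank 1 + (n-1) q/100)
oracle_percentile <- function(v, q) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# ideal disk mask for analytic-geometry checks
disk_mask <- function(shape, center, radius) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  sqrt(rr^2 + cc^2) <= radius
}

# flat two-channel image at constant normalized intensities
flat_image <- function(red_level, green_level, shape = c(120L, 120L)) {
  two_channel_image(
    matrix(as.integer(round(red_level * 4095)), shape[1], shape[2]),
    matrix(as.integer(round(green_level * 4095)), shape[1], shape[2]))
}

expect_partition <- function(seg) {
  expect_identical(seg$bright_mask | seg$dim_mask, seg$bead_mask)
  expect_false(any(seg$bright_mask & seg$dim_mask))
  expect_identical(seg$outer_ring_mask | seg$core_mask, seg$bead_mask)
  expect_false(any(seg$outer_ring_mask & seg$core_mask))
  expect_true(all(seg$bead_mask[seg$bright_mask]))
  expect_true(all(seg$bead_mask[seg$outer_ring_mask]))
}
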