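#' @title Local-mean (first-order statistic) box filter
#' @description Mean of each pixel's square neighbourhood, computed with
#'   integral images; windows are truncated (and renormalized) at the frame
#'   border rather than wrapped. With `weights`, a weighted local mean is
#'   returned (used for bead-masked means); pixels with zero local weight
#'   get `NA`.
#' @param x Numeric matrix.
#' @param window Odd window width in pixels.
#' @param weights Optional non-negative weight matrix (e.g. a mask).
#' @return Matrix of local means, same shape as `x`.
#' @keywords internal
box_mean <- function(x, window, weights = NULL) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1) / 2
  if (is.null(weights)) {
    num <- box_sum(x, h)
    den <- box_sum(matrix(1, nrow(x), ncol(x)), h)
  } else {
    num <- box_sum(x * weights, h)
    den <- box_sum(weights, h)
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# sliding-window sum via 2-D cumulative sums (integral image)
box_sum <- function(x, h) {
  n <- nrow(x); m <- ncol(x)
  s <- apply(apply(x, 2, cumsum), 1, cumsum)   # transposed integral image
  s <- t(s)
  pad <- matrix(0, n + 1, m + 1)
  pad[-1, -1] <- s
  r1 <- pmax(seq_len(n) - h, 1); r2 <- pmin(seq_len(n) + h, n)
  c1 <- pmax(seq_len(m) - h, 1); c2 <- pmin(seq_len(m) + h, m)
  pad[r2 + 1, c2 + 1, drop = FALSE] -
    pad[r1, c2 + 1, drop = FALSE] -
    pad[r2 + 1, c1, drop = FALSE] +
    pad[r1, c1, drop = FALSE]
}

#' Default segmentation parameters
#'
#' @param window Local-mean window width (px) for bead detection.
#' @param offset Additive offset above the local mean for a pixel to count
#'   as foreground during detection.
#' @param min_object_px Connected components smaller than this many pixels
#'   are discarded as background noise.
#' @param smooth_radius Disc radius (px) of the structuring element used by
#'   the reconstruction dilation, opening and erosion.
#' @param final_dilate_radius Disc radius of the last smoothing dilation.
#' @param bright_window Window width for the bright/dim stratification.
#' @param bright_factor Multiplicative sensitivity of the bright threshold:
#'   a pixel is "bright" when it exceeds `bright_factor` times the
#'   bead-masked local mean (larger factor = lower sensitivity).
#' @param ring_fraction Fraction of the equivalent radius assigned to the
#'   bead's outer ring.
#' @return Named list of parameters.
#' @export
segmentation_params <- function(window = 51L, offset = 0.02,
                                min_object_px = 100L, smooth_radius = 3L,
                                final_dilate_radius = 1L,
                                bright_window = 51L, bright_factor = 1.3,
                                ring_fraction = 0.25) {
  list(window = as.integer(window), offset = offset,
       min_object_px = as.integer(min_object_px),
       smooth_radius = as.integer(smooth_radius),
       final_dilate_radius = as.integer(final_dilate_radius),
       bright_window = as.integer(bright_window),
       bright_factor = bright_factor,
       ring_fraction = ring_fraction)
}

disc <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

#' Detect and segment beads in a frame
#'
#' The detection pipeline, in fixed order: (1) each channel is binarized by
#' a local first-order-statistic (local-mean) threshold and the channels are
#' combined by union, so a bead labeled in either color is found;
#' (2) connected components smaller than `min_object_px` (default 100
#' pixels) are removed as background noise; (3) the mask is dilated and
#' hole-filled to reconstruct the bead structure (a homogeneous or halo
#' bead thresholds as a ring whose interior must be recovered); (4) the
#' mask is opened, eroded and lightly dilated to smooth the bead shape.
#' Each surviving connected component becomes one [`bead segmentation`
#' object][segment_bead_component], carrying the whole-bead, bright/dim
#' and outer-ring/core masks.
#'
#' @param image A [two_channel_image()].
#' @param params [segmentation_params()].
#' @return `NULL` when no bead is present, otherwise a list of
#'   segmentation objects, one per detected component.
#' @export
detect_bead <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "two_channel_image"))
  red <- normalize_intensity(image$red)
  green <- normalize_intensity(image$green)

  fg <- (red > box_mean(red, params$window) + params$offset) |
        (green > box_mean(green, params$window) + params$offset)
  fg <- drop_small_components(fg, params$min_object_px)
  if (!any(fg)) return(NULL)

  k <- disc(params$smooth_radius)
  mask <- EBImage::dilate(fg * 1, k)
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::opening(mask, k)
  mask <- EBImage::erode(mask, k)
  mask <- EBImage::dilate(mask, disc(params$final_dilate_radius))
  mask <- drop_small_components(as.matrix(mask) > 0, params$min_object_px)
  if (!any(mask)) return(NULL)

  labels <- as.matrix(EBImage::bwlabel(mask * 1))
  lapply(seq_len(max(labels)), function(i) {
    segment_bead_component(red, green, labels == i, params)
  })
}

drop_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  labels <- as.matrix(EBImage::bwlabel(mask * 1))
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_px)
  matrix(labels %in% keep, nrow(mask))
}

#' Build the full segmentation of one detected component
#'
#' Combines the whole-bead mask with its bright/dim stratification
#' ([segment_bright()]) and outer-ring/core partition ([outer_ring()]),
#' plus the centroid and pixel area.
#'
#' @param red,green Normalized channel matrices.
#' @param bead_mask Logical matrix of the component.
#' @param params [segmentation_params()].
#' @return Object of class `bead_segmentation`.
#' @export
segment_bead_component <- function(red, green, bead_mask,
                                   params = segmentation_params()) {
  bd <- segment_bright(pmax(red, green), bead_mask,
                       window = params$bright_window,
                       factor = params$bright_factor)
  rc <- outer_ring(bead_mask, params$ring_fraction)
  idx <- which(bead_mask, arr.ind = TRUE)
  structure(
    list(bead_mask = bead_mask,
         bright_mask = bd$bright_mask, dim_mask = bd$dim_mask,
         outer_ring_mask = rc$outer_ring_mask, core_mask = rc$core_mask,
         ring_fraction = params$ring_fraction,
         area_px = nrow(idx),
         centroid = colMeans(idx)),
    class = "bead_segmentation"
  )
}

#' @export
print.bead_segmentation <- function(x, ...) {
  cat(sprintf(
    "<bead_segmentation> area %d px, centroid (%.1f, %.1f), bright %d px, ring %d px\n",
    x$area_px, x$centroid[1], x$centroid[2], sum(x$bright_mask),
    sum(x$outer_ring_mask)))
  invisible(x)
}

#' Split a bead into bright and dim strata
#'
#' A local first-order-statistic threshold with decreased sensitivity
#' toward the bright foreground: a pixel is bright when its normalized
#' intensity exceeds `factor` times the local mean computed over bead
#' pixels only. The dim stratum is the set difference `bead_mask \\
#' bright_mask`. A bead with no internal brightness contrast (e.g. a
#' noise-free homogeneous bead) produces an empty bright mask, which by
#' convention is re-classed as entirely bright (one brightness stratum).
#'
#' @param intensity Normalized intensity matrix used for stratification.
#' @param bead_mask Logical whole-bead mask; must be nonempty.
#' @param window Local-mean window (px).
#' @param factor Multiplicative threshold above the masked local mean.
#' @return List with logical `bright_mask` and `dim_mask`.
#' @export
segment_bright <- function(intensity, bead_mask, window = 51L, factor = 1.3) {
  if (!any(bead_mask)) stop("bead_mask is empty")
  local_mean <- box_mean(intensity, window, weights = bead_mask * 1)
  bright <- bead_mask & !is.na(local_mean) & (intensity > factor * local_mean)
  if (!any(bright)) bright <- bead_mask      # uniform bead: one stratum
  list(bright_mask = bright, dim_mask = bead_mask & !bright)
}

#' Partition a bead into outer ring and core
#'
#' The outer ring is the bead mask minus the mask eroded by
#' `ring_fraction` times the equivalent radius (the radius of the disk
#' with the same pixel area); the core is the eroded remainder. Ring and
#' core partition the bead exactly.
#'
#' @param bead_mask Logical whole-bead mask.
#' @param ring_fraction Fraction of the equivalent radius in `[0, 1]`.
#' @return List with logical `outer_ring_mask` and `core_mask`.
#' @export
outer_ring <- function(bead_mask, ring_fraction = 0.25) {
  if (ring_fraction < 0 || ring_fraction > 1) {
    stop("ring_fraction must lie in [0, 1]")
  }
  if (!any(bead_mask)) stop("bead_mask is empty")
  r_eq <- sqrt(sum(bead_mask) / pi)
  depth <- round(ring_fraction * r_eq)
  if (ring_fraction >= 1 || depth >= r_eq) {
    core <- bead_mask & FALSE
  } else if (depth < 1) {
    core <- bead_mask
  } else {
    core <- as.matrix(EBImage::erode(bead_mask * 1, disc(depth))) > 0
    core <- core & bead_mask
  }
  list(outer_ring_mask = bead_mask & !core, core_mask = core)
}
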