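#' Normalize 12-bit intensities to [0, 1]
#'
#' Converts the 12-bit pixel value range 0 (black) - 4095 (white) to
#' 0 (black) - 1 (white) by dividing by 4095.
#'
#' @param raw Integer vector or matrix with values in `[0, 4095]`.
#' @return Numeric object of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(raw) {
  if (anyNA(raw) || min(raw) < 0 || max(raw) > BIT12_MAX) {
    stop("raw intensities must lie in [0, 4095]")
  }
  raw / BIT12_MAX
}

#' Percentile of normalized intensity under a mask
#'
#' The q-th percentile of the normalized pixel values under the mask,
#' using the linear-interpolation convention between order statistics
#' (R's quantile type 7): for n sorted values the q-th percentile sits at
#' rank `1 + (n - 1) q / 100`, interpolating linearly between the
#' neighbouring order statistics. `q = 100` equals the maximum.
#'
#' @param intensity Normalized intensity matrix.
#' @param mask Logical mask; must be nonempty.
#' @param q Percentile in `[0, 100]`.
#' @return Scalar normalized intensity.
#' @export
percentile_intensity <- function(intensity, mask, q) {
  if (!any(mask)) stop("mask is empty")
  if (q < 0 || q > 100) stop("q must lie in [0, 100]")
  quantile(intensity[mask], q / 100, names = FALSE, type = 7)
}

#' Alpha homogeneity score
#'
#' `alpha = (M - p90) / M`, where `M` is the maximum and `p90` the 90th
#' percentile of normalized intensity in a region. Small alpha indicates a
#' homogeneous fluorescence distribution; large alpha indicates a wide gap
#' between the brightest pixels and the bulk — the signature of a halo or
#' of isolated bright spots. For a fully dark region (`M = 0`) alpha is
#' defined as 0 (maximally homogeneous darkness).
#'
#' @param M Maximum normalized intensity of the region.
#' @param p90 90th-percentile normalized intensity of the region;
#'   must satisfy `0 <= p90 <= M`.
#' @return Score in `[0, 1]`.
#' @export
alpha_score <- function(M, p90) {
  if (p90 < 0 || M < p90) stop("require 0 <= p90 <= M")
  if (M == 0) return(0)
  (M - p90) / M
}

#' Extract the full metric panel of a segmented bead
#'
#' Computes the normalized percentile, maximum, mean and alpha homogeneity
#' metrics of both channels over the whole-bead, outer-ring, core, bright
#' and dim regions — the named metrics driving the selection criteria plus
#' a panel of additional descriptive metrics (more than 20 in total).
#' Naming convention: suffix `e` = entire bead, `o` = outer ring,
#' `r`/`g` = red/green channel; `M` = maximum, `pNN` = NNth percentile.
#' `p90_dim_r` is the 90th percentile of the dim (non-bright) stratum in
#' the red channel; when the dim stratum is empty (uniform bead) it falls
#' back to the whole-bead value `p90_er`.
#'
#' @param image A [two_channel_image()].
#' @param segmentation A `bead_segmentation` from [detect_bead()].
#' @return Object of class `bead_metrics`: a named list of scalar metrics.
#' @export
extract_metrics <- function(image, segmentation) {
  stopifnot(inherits(image, "two_channel_image"),
            inherits(segmentation, "bead_segmentation"))
  if (!any(segmentation$bead_mask)) stop("segmentation has an empty bead mask")
  red <- normalize_intensity(image$red)
  green <- normalize_intensity(image$green)
  bead <- segmentation$bead_mask
  ring <- segmentation$outer_ring_mask
  core <- segmentation$core_mask
  dim_m <- segmentation$dim_mask

  reg <- function(ch, mask) {
    v <- ch[mask]
    list(M = max(v), p90 = percentile_intensity(ch, mask, 90),
         mean = mean(v), median = median(v),
         p75 = percentile_intensity(ch, mask, 75))
  }
  er <- reg(red, bead); eg <- reg(green, bead)
  or_ <- reg(red, ring); og <- reg(green, ring)

  m <- list(
    p90_er = er$p90, p90_eg = eg$p90,
    p95_er = percentile_intensity(red, bead, 95),
    p99_er = percentile_intensity(red, bead, 99),
    M_er = er$M, M_eg = eg$M,
    p90_or = or_$p90, p90_og = og$p90,
    M_or = or_$M, M_og = og$M,
    p90_dim_r = if (any(dim_m)) percentile_intensity(red, dim_m, 90) else er$p90,
    alpha_er = alpha_score(er$M, er$p90),
    alpha_eg = alpha_score(eg$M, eg$p90),
    alpha_or = alpha_score(or_$M, or_$p90),
    alpha_og = alpha_score(og$M, og$p90),
    mean_er = er$mean, mean_eg = eg$mean,
    bead_area_px = segmentation$area_px,
    # additional descriptive panel
    median_er = er$median, median_eg = eg$median,
    p75_er = er$p75, p75_eg = eg$p75,
    p95_eg = percentile_intensity(green, bead, 95),
    p99_eg = percentile_intensity(green, bead, 99),
    mean_or = or_$mean, mean_og = og$mean,
    p90_dim_g = if (any(dim_m)) percentile_intensity(green, dim_m, 90) else eg$p90,
    bright_area_frac = sum(segmentation$bright_mask) / segmentation$area_px
  )
  # core may be empty at ring_fraction 1; fall back to the whole bead
  core_mask <- if (any(core)) core else bead
  m$mean_core_r <- mean(red[core_mask])
  m$mean_core_g <- mean(green[core_mask])
  m$ring_core_ratio_r <- (m$mean_or + 1e-9) / (m$mean_core_r + 1e-9)
  m$ring_core_ratio_g <- (m$mean_og + 1e-9) / (m$mean_core_g + 1e-9)
  structure(m, class = "bead_metrics")
}

#' @export
print.bead_metrics <- function(x, ...) {
  cat(sprintf(
    "<bead_metrics> %d metrics | p90_er %.3f p90_eg %.3f alpha_er %.3f alpha_or %.3f area %d px\n",
    length(unclass(x)), x$p90_er, x$p90_eg, x$alpha_er, x$alpha_or,
    x$bead_area_px))
  invisible(x)
}

#' Convert bead metrics to a one-row data frame
#'
#' Stable column order (the order of [extract_metrics()] fields), suitable
#' for row-binding into the metrics table written by [write_report()].
#'
#' @param metrics A `bead_metrics` object.
#' @return One-row `data.frame`.
#' @export
metrics_as_row <- function(metrics) {
  stopifnot(inherits(metrics, "bead_metrics"))
  as.data.frame(unclass(metrics))
}
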