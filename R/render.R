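#' Construct a two-channel image
#'
#' Pairs same-shape red and green 12-bit integer intensity grids. Values
#' must lie in `[0, 4095]`, the range of the simulated camera.
#'
#' @param red,green Integer matrices of identical dimension with values in
#'   `[0, 4095]`.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return An object of class `two_channel_image`.
#' @export
two_channel_image <- function(red, green, pixel_size_um = 1) {
  red <- as_channel(red)
  green <- as_channel(green)
  if (!identical(dim(red), dim(green))) {
    stop("red and green channels must have identical dimensions")
  }
  stopifnot(pixel_size_um > 0)
  structure(list(red = red, green = green, pixel_size_um = pixel_size_um),
            class = "two_channel_image")
}

as_channel <- function(x) {
  if (!is.matrix(x)) stop("channel must be a matrix")
  if (anyNA(x)) stop("channel contains missing values")
  if (min(x) < 0 || max(x) > BIT12_MAX) {
    stop("channel values outside the 12-bit range [0, 4095]")
  }
  storage.mode(x) <- "integer"
  x
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px, %.2g um/px\n",
              nrow(x$red), ncol(x$red), x$pixel_size_um))
  invisible(x)
}

quantize12 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  matrix(as.integer(round(x * BIT12_MAX)), nrow = nrow(x))
}

# Radial label profile over a disk: homogeneous fill when penetration >= 1,
# otherwise a uniform bright shell occupying the outermost `penetration`
# fraction of the radius with `core_leak` inside it.
label_profile <- function(r_frac, peak, penetration, core_leak) {
  if (peak <= 0) return(rep(0, length(r_frac)))
  if (penetration >= 1) return(rep(peak, length(r_frac)))
  ifelse(r_frac >= 1 - penetration, peak, core_leak)
}

#' Render a single bead into a two-channel frame
#'
#' Draws one porous bead as a disk whose fluorescence follows the class
#' specification: frame background everywhere, plus the class's radial
#' label profile inside the disk (peak intensity within the labeled shell,
#' `core_leak` inside it), optional angular (partial-halo) modulation and
#' bright corona spots, additive Gaussian camera noise, and quantization
#' to the 12-bit range.
#'
#' @param spec A [bead_class_spec()].
#' @param diameter_um Bead diameter in micrometres; must map to at least
#'   20 pixels across and fit inside the field of view.
#' @param pixel_size_um Pixel size in micrometres (default 1).
#' @param image_shape Integer vector `c(rows, cols)` of the frame
#'   (default 350 x 350, the width of the imaging zone at 1 um/px).
#' @param noise_sigma Gaussian noise standard deviation on the normalized
#'   intensity scale (default 0.01).
#' @param background_level Normalized background intensity of the frame
#'   (default 0.05).
#' @param label_jitter_sd Bead-to-bead labeling variability: each bead's
#'   whole label signal (peaks, core leak, spots) is scaled by a lognormal
#'   factor with this log-scale standard deviation (default 0.1),
#'   mimicking variable dye conjugation / protein adsorption. Set to 0 for
#'   noise-free geometric renders.
#' @param center Optional bead center `c(row, col)`; defaults to the frame
#'   center.
#' @param seed Optional integer seed for reproducible noise/spot placement;
#'   when `NULL` the current RNG stream is used.
#' @return A `labeled_frame`: list with the rendered `image`
#'   (a [two_channel_image()]), `truth_masks` (list of logical disk masks)
#'   and `truth_classes` (character vector of class ids).
#' @export
render_bead <- function(spec, diameter_um, pixel_size_um = 1,
                        image_shape = c(350L, 350L),
                        noise_sigma = 0.01, background_level = 0.05,
                        label_jitter_sd = 0.1, center = NULL, seed = NULL) {
  stopifnot(inherits(spec, "bead_class_spec"))
  if (diameter_um <= 0) stop("diameter must be positive")
  d_px <- diameter_um / pixel_size_um
  if (d_px < 20) stop("bead must span at least 20 pixels across")
  if (d_px > min(image_shape)) stop("bead larger than the field of view")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  frame <- blank_frame(image_shape, background_level, noise_sigma)
  frame <- add_bead(frame, spec, d_px, center, label_jitter_sd)
  finish_frame(frame, pixel_size_um = pixel_size_um)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Internal accumulator for a frame under construction: noise-free signal
# fields plus the bead bookkeeping; noise is added once at finish time.
blank_frame <- function(image_shape, background_level, noise_sigma) {
  shape <- as.integer(image_shape)
  stopifnot(length(shape) == 2, all(shape > 0))
  list(shape = shape,
       red = matrix(background_level, shape[1], shape[2]),
       green = matrix(background_level, shape[1], shape[2]),
       noise_sigma = noise_sigma,
       masks = list())
}

add_bead <- function(frame, spec, d_px, center = NULL, label_jitter_sd = 0) {
  shape <- frame$shape
  radius <- d_px / 2
  if (is.null(center)) center <- (shape + 1) / 2
  if (center[1] - radius < 1 || center[1] + radius > shape[1] ||
      center[2] - radius < 1 || center[2] + radius > shape[2]) {
    stop("bead does not fit inside the field of view")
  }
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  dist <- sqrt(rr^2 + cc^2)
  disk <- dist <= radius
  r_frac <- dist[disk] / radius

  # bead-to-bead labeling variability scales the whole label signal
  jitter <- if (label_jitter_sd > 0) exp(rnorm(1, 0, label_jitter_sd)) else 1

  for (ch in c("red", "green")) {
    peak <- if (ch == "red") spec$red_peak else spec$green_peak
    sig <- jitter * label_profile(r_frac, peak, spec$halo_penetration,
                                  spec$core_leak)
    if (peak > 0 && spec$modulation > 0 && spec$halo_penetration < 1) {
      # partial halo: attenuate the shell on one (random) side
      theta <- atan2(rr[disk], cc[disk])
      phase <- runif(1, 0, 2 * pi)
      fac <- 1 - spec$modulation * (1 + cos(theta - phase)) / 2
      shell <- r_frac >= 1 - spec$halo_penetration
      sig[shell] <- sig[shell] * fac[shell]
    }
    frame[[ch]][disk] <- frame[[ch]][disk] + sig
    if (peak > 0 && spec$spot_count > 0) {
      frame[[ch]] <- add_spots(frame[[ch]], center, radius, spec, jitter)
    }
  }
  frame$masks <- c(frame$masks, list(disk))
  frame$classes <- c(frame$classes, spec$class_id)
  frame
}

# Bright adsorption spots on the corona (radius 0.9 R), drawn as small
# disks whose intensity replaces weaker signal underneath.
add_spots <- function(channel, center, radius, spec, jitter = 1) {
  shape <- dim(channel)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  spot_r <- max(2, 0.07 * radius)
  angles <- runif(spec$spot_count, 0, 2 * pi)
  for (a in angles) {
    sr <- center[1] + 0.9 * radius * sin(a) - center[1]
    sc <- center[2] + 0.9 * radius * cos(a) - center[2]
    spot <- sqrt((rr - sr)^2 + (cc - sc)^2) <= spot_r
    channel[spot] <- pmax(channel[spot], jitter * spec$spot_level)
  }
  channel
}

finish_frame <- function(frame, classes = frame$classes, pixel_size_um = 1) {
  n <- length(frame$red)
  red <- frame$red
  green <- frame$green
  if (frame$noise_sigma > 0) {
    red <- red + rnorm(n, sd = frame$noise_sigma)
    green <- green + rnorm(n, sd = frame$noise_sigma)
  }
  img <- two_channel_image(quantize12(red), quantize12(green), pixel_size_um)
  structure(list(image = img,
                 truth_masks = frame$masks,
                 truth_classes = classes),
            class = "labeled_frame")
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat(sprintf("<labeled_frame> %d bead(s): %s\n",
              length(x$truth_classes),
              paste(x$truth_classes, collapse = ", ")))
  invisible(x)
}
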