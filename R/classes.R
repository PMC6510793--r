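#' Bead class identifiers
#'
#' The seven labeled bead classes used throughout, plus the unlabeled
#' background-only class. Classes 1-3 carry homogeneous fluorescence
#' (red, green, dual); classes 4-6 carry red halo patterns of decreasing
#' width (broad, medium, narrow), mimicking adsorption of labeled proteins
#' of increasing molecular weight that cannot penetrate the porous bead
#' core; class 7 is the green broad-halo analogue.
#'
#' @return Character vector of the valid `class_id` values.
#' @export
bead_class_ids <- function() {
  c("CLASS1_RED_HOMOG", "CLASS2_GREEN_HOMOG", "CLASS3_DUAL_HOMOG",
    "CLASS4_RED_BROAD_HALO", "CLASS5_RED_MEDIUM_HALO",
    "CLASS6_RED_NARROW_HALO", "CLASS7_GREEN_BROAD_HALO", "UNLABELED")
}

#' Construct a bead class specification
#'
#' A `bead_class_spec` describes how a bead of a given class fluoresces:
#' peak label intensity per channel, how deep the label penetrates from the
#' bead surface (`halo_penetration`, as a fraction of the radius; 1 means
#' the label fills the bead homogeneously), residual signal in the core
#' (`core_leak`), the number of bright adsorption spots scattered on the
#' corona (`spot_count`), and an angular modulation depth producing a
#' partial (one-sided) halo.
#'
#' @param class_id One of [bead_class_ids()].
#' @param red_peak,green_peak Peak normalized label intensity per channel,
#'   in `[0, 1]`, on top of the frame background.
#' @param halo_penetration Fraction of the bead radius reached by the label,
#'   in `[0, 1]`; `1` renders a homogeneous bead.
#' @param core_leak Normalized intensity of residual label inside the core.
#' @param spot_count Non-negative integer count of bright corona spots.
#' @param spot_level Normalized intensity of the spots.
#' @param modulation Angular modulation depth of the shell in `[0, 1)`;
#'   `0` is a uniform halo, larger values give a partial halo.
#' @return An object of class `bead_class_spec`.
#' @export
bead_class_spec <- function(class_id,
                            red_peak = 0,
                            green_peak = 0,
                            halo_penetration = 1,
                            core_leak = 0,
                            spot_count = 0L,
                            spot_level = 0.95,
                            modulation = 0) {
  class_id <- match.arg(class_id, bead_class_ids())
  stopifnot(
    red_peak >= 0, red_peak <= 1,
    green_peak >= 0, green_peak <= 1,
    halo_penetration >= 0, halo_penetration <= 1,
    core_leak >= 0, core_leak <= 1,
    spot_count >= 0,
    modulation >= 0, modulation < 1
  )
  if (class_id == "UNLABELED" && (red_peak > 0 || green_peak > 0)) {
    stop("UNLABELED beads must not carry label signal above background")
  }
  structure(
    list(class_id = class_id, red_peak = red_peak, green_peak = green_peak,
         halo_penetration = halo_penetration, core_leak = core_leak,
         spot_count = as.integer(spot_count), spot_level = spot_level,
         modulation = modulation),
    class = "bead_class_spec"
  )
}

#' Default specifications for the seven bead classes
#'
#' Returns the built-in `bead_class_spec` for a class id. The defaults
#' encode the qualitative ordering of the halo widths (smaller adsorbed
#' proteins diffuse deeper, giving broader halos): broad halos penetrate
#' 0.55 of the radius, medium 0.30, narrow 0.04. The medium-halo class 5
#' carries core leak, a partial (angularly modulated) halo and a few
#' bright corona spots; the narrow-halo class 6 is a thin bright shell
#' over a near-dark core. Unlabeled beads add no signal in either channel.
#'
#' @param class_id One of [bead_class_ids()].
#' @return A `bead_class_spec`.
#' @export
default_class_spec <- function(class_id) {
  class_id <- match.arg(class_id, bead_class_ids())
  switch(class_id,
    CLASS1_RED_HOMOG =
      bead_class_spec(class_id, red_peak = 0.8, halo_penetration = 1),
    CLASS2_GREEN_HOMOG =
      bead_class_spec(class_id, green_peak = 0.8, halo_penetration = 1),
    CLASS3_DUAL_HOMOG =
      bead_class_spec(class_id, red_peak = 0.8, green_peak = 0.7,
                      halo_penetration = 1),
    CLASS4_RED_BROAD_HALO =
      bead_class_spec(class_id, red_peak = 0.7, halo_penetration = 0.55,
                      core_leak = 0.02),
    CLASS5_RED_MEDIUM_HALO =
      bead_class_spec(class_id, red_peak = 0.45, halo_penetration = 0.30,
                      core_leak = 0.15, spot_count = 4L, spot_level = 0.95,
                      modulation = 0.4),
    CLASS6_RED_NARROW_HALO =
      bead_class_spec(class_id, red_peak = 0.9, halo_penetration = 0.04,
                      core_leak = 0.02),
    CLASS7_GREEN_BROAD_HALO =
      bead_class_spec(class_id, green_peak = 0.7, halo_penetration = 0.55,
                      core_leak = 0.02),
    UNLABELED =
      bead_class_spec(class_id)
  )
}

#' @export
print.bead_class_spec <- function(x, ...) {
  cat(sprintf(
    "<bead_class_spec> %s  red %.2f  green %.2f  penetration %.2f  leak %.2f  spots %d\n",
    x$class_id, x$red_peak, x$green_peak, x$halo_penetration,
    x$core_leak, x$spot_count))
  invisible(x)
}
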