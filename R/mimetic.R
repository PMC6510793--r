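#' Specify a library mimetic
#'
#' A library mimetic is a constructed mixture of pre-labeled bead classes
#' standing in for a real screened library: a composition of (class, count)
#' pairs fed one bead at a time (or, with probability `co_entry_prob`, two
#' beads sharing a frame) through the imaging zone.
#'
#' @param composition Named integer vector `c(CLASS1_RED_HOMOG = 18, ...)`
#'   or a list of `list(spec = bead_class_spec, count = n)` entries.
#' @param diameter_range_um Bead diameter range in micrometres
#'   (default `c(100, 300)`, the polydispersity of commercial resin).
#' @param pixel_size_um Pixel size in micrometres.
#' @param image_shape Frame shape in pixels.
#' @param noise_sigma Gaussian camera noise (normalized scale).
#' @param background_level Normalized frame background.
#' @param label_jitter_sd Bead-to-bead labeling variability (lognormal
#'   log-scale sd; see [render_bead()]).
#' @param co_entry_prob Probability that a frame holds two beads (beads
#'   co-entering the imaging zone by aggregation or proximity).
#' @param seed Integer seed; identical specs with identical seeds generate
#'   bit-identical frame streams.
#' @return An object of class `mimetic_spec`.
#' @export
mimetic_spec <- function(composition,
                         diameter_range_um = c(100, 300),
                         pixel_size_um = 1,
                         image_shape = c(350L, 350L),
                         noise_sigma = 0.01,
                         background_level = 0.05,
                         label_jitter_sd = 0.1,
                         co_entry_prob = 0,
                         seed = 1L) {
  composition <- normalize_composition(composition)
  if (length(composition) == 0 || sum(vapply(composition, `[[`, 0L, "count")) == 0) {
    stop("composition must contain at least one bead")
  }
  stopifnot(
    length(diameter_range_um) == 2,
    diameter_range_um[1] > 0,
    diameter_range_um[1] <= diameter_range_um[2],
    co_entry_prob >= 0, co_entry_prob <= 1,
    noise_sigma >= 0, background_level >= 0, background_level <= 1
  )
  if (diameter_range_um[2] / pixel_size_um > min(image_shape)) {
    stop("diameter range exceeds the field of view")
  }
  structure(
    list(composition = composition,
         diameter_range_um = diameter_range_um,
         pixel_size_um = pixel_size_um,
         image_shape = as.integer(image_shape),
         noise_sigma = noise_sigma,
         background_level = background_level,
         label_jitter_sd = label_jitter_sd,
         co_entry_prob = co_entry_prob,
         seed = as.integer(seed)),
    class = "mimetic_spec"
  )
}

normalize_composition <- function(composition) {
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- lapply(seq_along(composition), function(i) {
      list(spec = default_class_spec(names(composition)[i]),
           count = as.integer(composition[i]))
    })
  }
  lapply(composition, function(entry) {
    stopifnot(inherits(entry$spec, "bead_class_spec"), entry$count >= 0)
    entry
  })
}

#' Generate the frame stream of a library mimetic
#'
#' Renders one frame per arrival event, feeding the mimetic's beads in
#' randomized order. With probability `co_entry_prob` a frame contains two
#' beads placed side by side (shrunk if needed to share the field of view),
#' reproducing the co-entry error mode of the physical device. The stream
#' is fully determined by the spec's seed.
#'
#' @param spec A [mimetic_spec()].
#' @return List of `labeled_frame` objects.
#' @export
generate_mimetic <- function(spec) {
  stopifnot(inherits(spec, "mimetic_spec"))
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(spec$seed)

  specs <- unlist(lapply(spec$composition, function(entry) {
    rep(list(entry$spec), entry$count)
  }), recursive = FALSE)
  order <- sample(length(specs))
  specs <- specs[order]
  diam <- runif(length(specs), spec$diameter_range_um[1], spec$diameter_range_um[2])

  frames <- list()
  i <- 1L
  while (i <= length(specs)) {
    two <- i < length(specs) && runif(1) < spec$co_entry_prob
    idx <- if (two) c(i, i + 1L) else i
    frames[[length(frames) + 1L]] <- render_arrival(spec, specs[idx], diam[idx])
    i <- i + length(idx)
  }
  frames
}

render_arrival <- function(spec, bead_specs, diameters_um) {
  shape <- spec$image_shape
  frame <- blank_frame(shape, spec$background_level, spec$noise_sigma)
  d_px <- diameters_um / spec$pixel_size_um
  if (any(d_px < 20)) stop("diameter range maps to beads under 20 pixels across")
  if (length(bead_specs) == 1) {
    center <- jittered_center(shape, d_px)
    frame <- add_bead(frame, bead_specs[[1]], d_px, center, spec$label_jitter_sd)
  } else {
    # two beads share the frame: shrink if the pair cannot fit side by side
    fit <- shape[2] - 10
    if (sum(d_px) > fit) d_px <- d_px * fit / sum(d_px)
    mid <- (shape + 1) / 2
    c1 <- c(mid[1], mid[2] - d_px[2] / 2 - 1)
    c2 <- c(mid[1], mid[2] + d_px[1] / 2 + 1)
    frame <- add_bead(frame, bead_specs[[1]], d_px[1], c1, spec$label_jitter_sd)
    frame <- add_bead(frame, bead_specs[[2]], d_px[2], c2, spec$label_jitter_sd)
  }
  finish_frame(frame, pixel_size_um = spec$pixel_size_um)
}

# random in-frame placement leaving the full disk inside the field of view
jittered_center <- function(shape, d_px) {
  slack <- pmax((shape - d_px) / 2 - 2, 0)
  (shape + 1) / 2 + runif(2, -1, 1) * pmin(slack, 15)
}

#' Read a mimetic specification from a YAML or JSON config file
#'
#' The config mirrors the arguments of [mimetic_spec()]; `composition` is
#' a mapping of class ids to counts. Class parameter overrides may be given
#' under `class_overrides` as mappings of class id to [bead_class_spec()]
#' fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [mimetic_spec()].
#' @export
read_mimetic_config <- function(path) {
  cfg <- read_config_file(path)
  stopifnot(!is.null(cfg$composition))
  comp <- unlist(cfg$composition)
  overrides <- cfg$class_overrides
  composition <- lapply(seq_along(comp), function(i) {
    id <- names(comp)[i]
    args <- unclass(default_class_spec(id))
    if (!is.null(overrides[[id]])) args <- modifyList(args, overrides[[id]])
    spec <- do.call(bead_class_spec, args)
    list(spec = spec, count = as.integer(comp[i]))
  })
  args <- cfg[setdiff(names(cfg), c("composition", "class_overrides"))]
  do.call(mimetic_spec, c(list(composition = composition), args))
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
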