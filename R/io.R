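#' Write a two-channel frame as a 2-page 16-bit grayscale TIFF
#'
#' Page 1 carries the red channel, page 2 the green channel; the 12-bit
#' data are stored in the low bits of the 16-bit samples, as microscopy
#' cameras do. The round trip through [read_frame()] is bit-exact.
#'
#' @param image A [two_channel_image()] or a `labeled_frame` (its image is
#'   written; truth goes to a JSON sidecar when `truth_sidecar = TRUE`).
#' @param path Output `.tif` path.
#' @param truth_sidecar Write `<path>.truth.json` with the per-frame class
#'   list and run-length-encoded truth masks (labeled frames only).
#' @return `path`, invisibly.
#' @export
write_frame <- function(image, path, truth_sidecar = FALSE) {
  frame <- NULL
  if (inherits(image, "labeled_frame")) {
    frame <- image
    image <- image$image
  }
  stopifnot(inherits(image, "two_channel_image"))
  tiff::writeTIFF(list(image$red / 65535, image$green / 65535), path,
                  bits.per.sample = 16L)
  if (truth_sidecar) {
    if (is.null(frame)) stop("truth sidecar requires a labeled_frame")
    truth <- list(
      classes = frame$truth_classes,
      shape = dim(image$red),
      masks = lapply(frame$truth_masks, function(m) {
        r <- rle(as.vector(m))
        list(lengths = r$lengths, values = as.integer(r$values))
      })
    )
    jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a two-channel frame from the 2-page TIFF dialect
#'
#' Expects exactly two 16-bit grayscale pages (page 1 red, page 2 green)
#' whose values stay within the 12-bit range `[0, 4095]`.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size_um Pixel size to attach (micrometres).
#' @return A [two_channel_image()].
#' @export
read_frame <- function(path, pixel_size_um = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 2) {
    stop("expected a 2-page TIFF (page 1 red, page 2 green), found ",
         length(pages), " page(s)")
  }
  for (p in pages) {
    if (max(p) > BIT12_MAX) {
      stop("pixel values exceed the 12-bit range [0, 4095]")
    }
  }
  two_channel_image(pages[[1]], pages[[2]], pixel_size_um)
}

#' Read the truth sidecar of a frame
#'
#' @param path Path of the TIFF the sidecar belongs to (reads
#'   `<path>.truth.json`).
#' @return List with `classes` and logical `masks`.
#' @export
read_truth_sidecar <- function(path) {
  truth <- jsonlite::read_json(paste0(path, ".truth.json"),
                               simplifyVector = TRUE)
  shape <- as.integer(truth$shape)
  masks <- lapply(seq_along(truth$classes), function(i) {
    m <- truth$masks[i, ]
    matrix(inverse.rle(list(lengths = m$lengths[[1]],
                            values = as.logical(m$values[[1]]))),
           nrow = shape[1])
  })
  list(classes = truth$classes, masks = masks)
}

# stable, dependency-free config fingerprint (polynomial rolling hash over
# the deparsed object; provenance marker, not cryptographic)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a sort run to disk
#'
#' Emits `report.json` (counts, yield, accuracy, config hash, seed),
#' `outcomes.csv` (per-frame routing) and, when a metrics table is given,
#' `metrics.csv` — stable schemas, so reruns with the same config and seed
#' are byte-identical.
#'
#' @param report A `sort_report` from [run_sort()].
#' @param dir Output directory (created if missing).
#' @param metrics Optional data frame of per-bead metrics
#'   (see [metrics_as_row()]).
#' @param config Optional configuration object embedded as a hash.
#' @param seed Seed recorded for provenance.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, metrics = NULL, config = NULL,
                         seed = NA_integer_) {
  stopifnot(inherits(report, "sort_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(report = file.path(dir, "report.json"),
             outcomes = file.path(dir, "outcomes.csv"))
  counts <- list(
    positives_fed = report$positives_fed,
    true_positives = report$true_positives,
    false_positives = report$false_positives,
    false_negatives = report$false_negatives,
    true_negatives = report$true_negatives,
    total_collected = report$total_collected
  )
  jsonlite::write_json(
    list(criteria = report$criteria_name, mode = report$mode,
         counts = counts, yield = report$yield, accuracy = report$accuracy,
         config_hash = config_hash(config), seed = seed),
    files[["report"]], auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(report$outcomes, files[["outcomes"]], row.names = FALSE)
  if (!is.null(metrics)) {
    files <- c(files, metrics = file.path(dir, "metrics.csv"))
    write.csv(metrics, files[["metrics"]], row.names = FALSE)
  }
  invisible(files)
}
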