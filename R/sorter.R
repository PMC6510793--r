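#' Valve configurations of the screening loop
#'
#' The four canonical valve states of the sorting flowchart. Each state
#' fixes the loading, imaging, positive-outlet and negative-outlet valves:
#' \describe{
#'   \item{load}{loading closed, imaging open, negative open, positive
#'     closed — beads flow through the imaging zone while frames are
#'     monitored.}
#'   \item{trap}{imaging, loading and positive closed — a detected bead is
#'     retained in the imaging zone for metric extraction.}
#'   \item{route_negative}{loading open, positive closed (negative open) —
#'     the bead is expelled through the negative outlet.}
#'   \item{route_positive}{negative closed, positive and loading open — the
#'     bead travels to the collection receptacle.}
#' }
#'
#' @param stage One of `"load"`, `"trap"`, `"route_negative"`,
#'   `"route_positive"`.
#' @return Named character vector with entries `loading`, `imaging`,
#'   `positive_outlet`, `negative_outlet`, each `"open"` or `"closed"`.
#' @export
valve_state <- function(stage = c("load", "trap", "route_negative",
                                  "route_positive")) {
  stage <- match.arg(stage)
  switch(stage,
    load = c(loading = "closed", imaging = "open",
             positive_outlet = "closed", negative_outlet = "open"),
    trap = c(loading = "closed", imaging = "closed",
             positive_outlet = "closed", negative_outlet = "open"),
    route_negative = c(loading = "open", imaging = "open",
                       positive_outlet = "closed", negative_outlet = "open"),
    route_positive = c(loading = "open", imaging = "open",
                       positive_outlet = "open", negative_outlet = "closed")
  )
}

# 96-well sequence A1..A12, B1..B12, ..., H1..H12
well_sequence <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
}

#' Well assignment for single-bead collection mode
#'
#' In single-bead mode every positive bead pauses the run and is deposited
#' in the next well of a 96-well plate (A1 ... H12). Past 96 positives the
#' sequence wraps back to A1 with a warning.
#'
#' @param positive_index 1-based index of the positive bead.
#' @return Well label such as `"A1"`.
#' @export
well_for_positive <- function(positive_index) {
  stopifnot(positive_index >= 1)
  wells <- well_sequence()
  if (positive_index > length(wells)) {
    warning("more than 96 positives in single-bead mode: well sequence wraps")
  }
  wells[(positive_index - 1L) %% length(wells) + 1L]
}

#' Simulate the screening loop over a frame stream
#'
#' Replays the sorting flowchart on a sequence of labeled frames. For each
#' frame the loop runs bead detection; an undetected frame lets its
#' content flow to the negative outlet (valves remain in the load state).
#' A detected frame is trapped, every detected component is metric-extracted
#' and classified against the criteria, and the frame is routed positive if
#' any component is positive — co-entering beads are routed jointly, so a
#' mixed pair necessarily produces one false routing. Per-bead ground truth
#' is scored individually against the `positive_class`.
#'
#' Yield is true positives / positives fed; accuracy is true positives /
#' total beads collected at the positive outlet. With no positives fed the
#' yield is undefined and reported as `NA`; with nothing collected the
#' accuracy is vacuously 1.
#'
#' @param frames List of `labeled_frame` objects (from
#'   [generate_mimetic()], [render_bead()] or [read_frame()] plus truth).
#' @param criteria A [selection_criteria()].
#' @param positive_class Class id counted as ground-truth positive.
#' @param mode `"bulk"` (common flask) or `"single"` (one well per
#'   positive, with a pause event per bead).
#' @param params [segmentation_params()].
#' @return Object of class `sort_report` with counts
#'   (`positives_fed`, `true_positives`, `false_positives`,
#'   `false_negatives`, `true_negatives`, `total_collected`), `yield`,
#'   `accuracy`, `mode`, and a per-frame `outcomes` data frame (frame id,
#'   truth classes, decision, routing, valve trace, well, pause flag).
#' @export
run_sort <- function(frames, criteria, positive_class,
                     mode = c("bulk", "single"),
                     params = segmentation_params()) {
  mode <- match.arg(mode)
  stopifnot(length(frames) > 0, inherits(criteria, "selection_criteria"))
  positive_class <- match.arg(positive_class, bead_class_ids())

  outcomes <- vector("list", length(frames))
  tp <- fp <- fn <- tn <- 0L
  n_pos_routed <- 0L

  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    stopifnot(inherits(fr, "labeled_frame"))
    segs <- detect_bead(fr$image, params)
    truth_pos <- fr$truth_classes == positive_class

    if (is.null(segs)) {
      # nothing detected: contents flow through the open negative outlet
      decision <- "absent"
      routed <- "negative"
      trace <- "load"
    } else {
      decisions <- vapply(segs, function(s) {
        classify_bead(extract_metrics(fr$image, s), criteria)
      }, character(1))
      decision <- if (any(decisions == "positive")) "positive" else "negative"
      routed <- decision
      trace <- paste("load", "trap",
                     if (decision == "positive") "route_positive"
                     else "route_negative")
    }

    if (routed == "positive") {
      tp <- tp + sum(truth_pos)
      fp <- fp + sum(!truth_pos)
      n_pos_routed <- n_pos_routed + 1L
      well <- if (mode == "single") well_for_positive(n_pos_routed) else NA_character_
      pause <- mode == "single"
    } else {
      fn <- fn + sum(truth_pos)
      tn <- tn + sum(!truth_pos)
      well <- NA_character_
      pause <- FALSE
    }

    outcomes[[i]] <- data.frame(
      frame = i,
      truth_classes = paste(fr$truth_classes, collapse = "+"),
      n_beads = length(fr$truth_classes),
      n_detected = if (is.null(segs)) 0L else length(segs),
      decision = decision,
      routed_to = routed,
      valve_trace = trace,
      well = well,
      pause = pause,
      stringsAsFactors = FALSE
    )
  }

  outcomes <- do.call(rbind, outcomes)
  positives_fed <- tp + fn
  total_collected <- tp + fp
  report <- structure(
    list(positives_fed = positives_fed,
         true_positives = tp, false_positives = fp,
         false_negatives = fn, true_negatives = tn,
         total_collected = total_collected,
         yield = if (positives_fed == 0) NA_real_ else tp / positives_fed,
         accuracy = if (total_collected == 0) 1 else tp / total_collected,
         mode = mode,
         criteria_name = criteria$name,
         outcomes = outcomes),
    class = "sort_report"
  )
  report
}

#' @export
print.sort_report <- function(x, ...) {
  cat(sprintf(
    "<sort_report> %s (%s mode)\n  fed %d positives | TP %d FP %d FN %d TN %d\n  yield %s, accuracy %.3f\n",
    x$criteria_name, x$mode, x$positives_fed, x$true_positives,
    x$false_positives, x$false_negatives, x$true_negatives,
    ifelse(is.na(x$yield), "NA", sprintf("%.3f", x$yield)), x$accuracy))
  invisible(x)
}
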