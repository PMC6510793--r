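#' Construct selection criteria
#'
#' A conjunction of strict inequalities over bead metrics. Each clause has
#' an expression — a single metric name (e.g. `"p90_er"`) or a difference
#' of two metrics (e.g. `"alpha_er - alpha_eg"`) — a comparator (`">"` or
#' `"<"`) and a numeric threshold. A bead is positive only if every clause
#' holds; inequalities are strict, so a metric exactly on the threshold
#' fails its clause.
#'
#' @param clauses A data frame with columns `expr`, `op`, `thr`, or a list
#'   of `list(expr=, op=, thr=)` clauses.
#' @param name Label of the criteria set.
#' @return Object of class `selection_criteria`.
#' @export
selection_criteria <- function(clauses, name = "custom") {
  if (is.data.frame(clauses)) {
    clauses <- lapply(seq_len(nrow(clauses)), function(i) {
      list(expr = clauses$expr[i], op = clauses$op[i], thr = clauses$thr[i])
    })
  }
  if (length(clauses) == 0) stop("criteria need at least one clause")
  clauses <- lapply(clauses, function(cl) {
    stopifnot(is.character(cl$expr), cl$op %in% c("<", ">"), is.numeric(cl$thr))
    if (!grepl("^[A-Za-z0-9_]+( *- *[A-Za-z0-9_]+)?$", cl$expr)) {
      stop("clause expression must be a metric or a difference of two metrics: ",
           cl$expr)
    }
    list(expr = cl$expr, op = cl$op, thr = as.numeric(cl$thr))
  })
  structure(list(clauses = clauses, name = name), class = "selection_criteria")
}

#' @export
print.selection_criteria <- function(x, ...) {
  cat(sprintf("<selection_criteria> %s\n", x$name))
  for (cl in x$clauses) cat(sprintf("  %s %s %g\n", cl$expr, cl$op, cl$thr))
  invisible(x)
}

criteria_fields <- function(criteria) {
  unique(unlist(lapply(criteria$clauses, function(cl) {
    strsplit(gsub(" ", "", cl$expr), "-", fixed = TRUE)[[1]]
  })))
}

#' Classify a bead against selection criteria
#'
#' Positive iff every clause of the conjunction holds (strict
#' inequalities). A clause referencing a metric absent from `metrics` is
#' an error.
#'
#' @param metrics A `bead_metrics` object (or named list of metrics).
#' @param criteria A [selection_criteria()].
#' @return `"positive"` or `"negative"`.
#' @export
classify_bead <- function(metrics, criteria) {
  stopifnot(inherits(criteria, "selection_criteria"))
  vals <- unclass(metrics)
  missing <- setdiff(criteria_fields(criteria), names(vals))
  if (length(missing)) {
    stop("criteria reference unknown metrics: ", paste(missing, collapse = ", "))
  }
  for (cl in criteria$clauses) {
    parts <- strsplit(gsub(" ", "", cl$expr), "-", fixed = TRUE)[[1]]
    value <- vals[[parts[1]]]
    if (length(parts) == 2) value <- value - vals[[parts[2]]]
    ok <- if (cl$op == ">") value > cl$thr else value < cl$thr
    if (!isTRUE(ok)) return("negative")
  }
  "positive"
}

#' Built-in criteria presets
#'
#' The decision hyperplanes of the validation screens and the library
#' screen, verbatim:
#' \describe{
#'   \item{TEST1_CLASS1}{homogeneous red: `p90_er > 0.5`, `p90_eg < 0.2`}
#'   \item{TEST2_CLASS2}{homogeneous green: `p90_eg > 0.5`, `p90_er < 0.2`}
#'   \item{TEST3_CLASS3}{dual color: `p90_er > 0.5`, `p90_eg > 0.4`}
#'   \item{TEST4_CLASS6}{narrow halo: `alpha_er > 0.15`,
#'     `alpha_er - alpha_eg > 0`, `p90_eg < 0.1`}
#'   \item{TEST5_CLASS5}{medium halo (outer ring): `alpha_or > 0.15`,
#'     `alpha_or - alpha_og > 0`, `p90_eg < 0.1`}
#'   \item{LIBRARY_IGG}{competitive IgG screen: `alpha_or - alpha_og > 0`,
#'     `alpha_or > 0.25`, `p90_eg < 0.1`, `p95_er > 0.08`}
#' }
#'
#' @param name Preset name.
#' @return A [selection_criteria()].
#' @export
criteria_preset <- function(name) {
  presets <- list(
    TEST1_CLASS1 = list(
      list(expr = "p90_er", op = ">", thr = 0.5),
      list(expr = "p90_eg", op = "<", thr = 0.2)),
    TEST2_CLASS2 = list(
      list(expr = "p90_eg", op = ">", thr = 0.5),
      list(expr = "p90_er", op = "<", thr = 0.2)),
    TEST3_CLASS3 = list(
      list(expr = "p90_er", op = ">", thr = 0.5),
      list(expr = "p90_eg", op = ">", thr = 0.4)),
    TEST4_CLASS6 = list(
      list(expr = "alpha_er", op = ">", thr = 0.15),
      list(expr = "alpha_er - alpha_eg", op = ">", thr = 0),
      list(expr = "p90_eg", op = "<", thr = 0.1)),
    TEST5_CLASS5 = list(
      list(expr = "alpha_or", op = ">", thr = 0.15),
      list(expr = "alpha_or - alpha_og", op = ">", thr = 0),
      list(expr = "p90_eg", op = "<", thr = 0.1)),
    LIBRARY_IGG = list(
      list(expr = "alpha_or - alpha_og", op = ">", thr = 0),
      list(expr = "alpha_or", op = ">", thr = 0.25),
      list(expr = "p90_eg", op = "<", thr = 0.1),
      list(expr = "p95_er", op = ">", thr = 0.08))
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  selection_criteria(presets[[name]], name = name)
}

#' Read selection criteria from a YAML or JSON file
#'
#' Schema: a top-level `name` (optional) and a `clauses` list of
#' `{expr: "alpha_or - alpha_og", op: ">", thr: 0.0}` entries, so operators
#' can define new decision hyperplanes without code changes.
#'
#' @param path Path to the criteria file.
#' @return A [selection_criteria()].
#' @export
read_criteria <- function(path) {
  cfg <- read_config_file(path)
  clauses <- if (!is.null(cfg$clauses)) cfg$clauses else cfg
  selection_criteria(clauses,
                     name = if (!is.null(cfg$name)) cfg$name else "custom")
}

#' Write selection criteria to a YAML file
#'
#' @param criteria A [selection_criteria()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(criteria, path) {
  stopifnot(inherits(criteria, "selection_criteria"))
  yaml::write_yaml(list(name = criteria$name, clauses = criteria$clauses), path)
  invisible(path)
}
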