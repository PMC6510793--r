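#' Unsupervised two-class discrimination by K-means
#'
#' Runs K-means with k = 2 (multiple seeded restarts, best within-cluster
#' sum of squares kept) on a two-column feature matrix — canonically the
#' normalized 99th-percentile red intensity and the 90th-percentile red
#' intensity of the non-bright (dim) bead segment, the pair that best
#' separates the medium- and narrow-halo classes. Features are standardized
#' (z-scored) before clustering. When ground-truth labels are supplied, the
#' clustering accuracy (correctly classified beads / total beads) is scored
#' under the better of the two cluster-label permutations, so it is always
#' at least 0.5.
#'
#' @param points Numeric matrix or data frame with two feature columns, one
#'   row per bead.
#' @param truth_labels Optional vector of true class labels (two classes).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param nstart Number of random restarts (default 10).
#' @param iter_max Maximum K-means iterations (default 300).
#' @return Object of class `clustering_result`: `assignments` (cluster id
#'   per bead, relabeled to best match truth when given), `centers` (2 x 2
#'   matrix on the original feature scale), `accuracy` (or `NA` without
#'   truth), and `sizes`.
#' @export
kmeans_discriminate <- function(points, truth_labels = NULL, seed = 1L,
                                nstart = 10L, iter_max = 300L) {
  x <- as.matrix(points)
  stopifnot(ncol(x) >= 2, nrow(x) >= 2)
  if (!is.null(truth_labels)) {
    stopifnot(length(truth_labels) == nrow(x))
    if (length(unique(truth_labels)) != 2) {
      stop("truth_labels must contain exactly two classes")
    }
    if (any(table(truth_labels) < 2)) stop("need at least 2 points per class")
  }

  sds <- apply(x, 2, sd)
  z <- sweep(x, 2, colMeans(x), "-")
  nz <- sds > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sds[nz], "/")

  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  if (nrow(unique(z)) < 2) {
    # degenerate: all points identical; a single cluster, accuracy equals
    # the majority-class fraction
    warning("all points identical: no separation is possible")
    assignments <- rep(1L, nrow(x))
    centers <- rbind(colMeans(x), colMeans(x))
    acc <- if (is.null(truth_labels)) NA_real_ else
      max(table(truth_labels)) / length(truth_labels)
    return(structure(list(assignments = assignments, centers = centers,
                          accuracy = acc, sizes = c(nrow(x), 0L)),
                     class = "clustering_result"))
  }

  fit <- kmeans(z, centers = 2, nstart = nstart, iter.max = iter_max)
  assignments <- fit$cluster
  acc <- NA_real_
  if (!is.null(truth_labels)) {
    truth <- as.integer(factor(truth_labels))
    hits <- sum(assignments == truth)
    if (hits < nrow(x) - hits) {          # better under the swapped labels
      assignments <- 3L - assignments
      hits <- nrow(x) - hits
    }
    acc <- hits / nrow(x)
  }
  # centers reported on the original feature scale
  centers <- t(vapply(1:2, function(k) {
    colMeans(x[assignments == k, , drop = FALSE])
  }, numeric(ncol(x))))
  structure(list(assignments = assignments, centers = centers,
                 accuracy = acc, sizes = as.integer(table(factor(assignments, 1:2)))),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> sizes %s, accuracy %s\n",
              paste(x$sizes, collapse = "/"),
              ifelse(is.na(x$accuracy), "NA", sprintf("%.3f", x$accuracy))))
  invisible(x)
}

#' Rank metrics by between-class separation
#'
#' Orders the columns of a metric table by the absolute standardized
#' between-class mean difference `|mean_A - mean_B| / pooled SD`, the
#' screening statistic used to pick the discriminative metric pair before
#' clustering. Constant (zero-variance, zero-difference) columns get a
#' score of 0 and hence rank last, but are not dropped; a metric separating
#' the classes with no within-class variance scores `Inf` and ranks first.
#'
#' @param metric_table Data frame or matrix of metrics, one row per bead.
#' @param truth_labels Vector of true class labels (exactly two classes).
#' @return Data frame with columns `metric` and `score`, ordered by
#'   decreasing score.
#' @export
rank_metrics <- function(metric_table, truth_labels) {
  x <- as.data.frame(metric_table)
  if (ncol(x) < 2) stop("need at least two metrics to rank")
  classes <- unique(truth_labels)
  if (length(classes) != 2) stop("truth_labels must contain exactly two classes")
  a <- truth_labels == classes[1]
  score <- vapply(x, function(col) {
    col <- as.numeric(col)
    sp <- sqrt((sum(a) * var_or0(col[a]) + sum(!a) * var_or0(col[!a])) /
                 length(col))
    d <- abs(mean(col[a]) - mean(col[!a]))
    if (d == 0) 0 else if (sp == 0) Inf else d / sp
  }, numeric(1))
  out <- data.frame(metric = names(score), score = unname(score))
  out[order(-out$score), , drop = FALSE]
}

var_or0 <- function(v) if (length(v) < 2) 0 else var(v)
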