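#' Default matching radius from the gold standard
#'
#' Half the median nearest-neighbour distance among the truth centers, which
#' adapts the correspondence tolerance to the flower scale in the image
#' without a hand-set constant.
#'
#' @param truth_centers n x 2 matrix of (row, col) truth centers, n >= 2.
#' @return radius in pixels.
#' @export
default_match_radius <- function(truth_centers) {
  truth_centers <- .as_centers(truth_centers)
  if (nrow(truth_centers) < 2L)
    abort_ic("need at least 2 truth points to derive a matching radius; pass `radius` explicitly",
             "inflocount_error_invalid_input")
  dm <- as.matrix(stats::dist(truth_centers))
  diag(dm) <- Inf
  stats::median(apply(dm, 1L, min)) / 2
}

#' @keywords internal
.as_centers <- function(x) {
  if (inherits(x, "ground_truth")) x <- x$centers
  if (inherits(x, "detection_result")) x <- x$centers
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    abort_ic("centers must be a two-column (row, col) matrix",
             "inflocount_error_invalid_input")
  colnames(x) <- c("row", "col")
  x
}

#' Match detected centers to gold-standard centers
#'
#' Greedy nearest-pair matching in increasing distance order: a detection may
#' match at most one truth point within `radius`, and each truth point is
#' matched at most once. Further detections falling within the radius of an
#' already-matched truth point are redundant detections and count as false
#' positives (a flower detected more than once). Unmatched truth points are
#' false negatives.
#'
#' @param detections n x 2 matrix of (row, col) detected centers (or a
#'   `detection_result`).
#' @param truth m x 2 matrix of truth centers (or a `ground_truth`).
#' @param radius matching radius in pixels (> 0); by default derived from the
#'   truth by [default_match_radius()].
#' @return object of class `match_result`: `TP`, `FP`, `FN`, and `pairs`
#'   (matrix of matched `(detection, truth)` indices).
#' @export
match_detections <- function(detections, truth, radius = NULL) {
  det <- .as_centers(detections)
  tru <- .as_centers(truth)
  if (is.null(radius)) radius <- default_match_radius(tru)
  if (!is.numeric(radius) || radius <= 0)
    abort_ic("`radius` must be > 0", "inflocount_error_invalid_input")

  n_det <- nrow(det); n_tru <- nrow(tru)
  pairs <- matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("detection", "truth")))
  if (n_det > 0L && n_tru > 0L) {
    dd <- outer(det[, 1], tru[, 1], "-")^2 + outer(det[, 2], tru[, 2], "-")^2
    cand <- which(dd <= radius^2, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dd[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      det_used <- logical(n_det); tru_used <- logical(n_tru)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!det_used[i] && !tru_used[j]) {
          det_used[i] <- TRUE; tru_used[j] <- TRUE; keep[k] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
      colnames(pairs) <- c("detection", "truth")
    }
  }
  TP <- nrow(pairs)
  structure(list(TP = TP, FP = n_det - TP, FN = n_tru - TP, pairs = pairs,
                 radius = radius),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: TP = %d, FP = %d, FN = %d (radius %.2f px)\n",
              x$TP, x$FP, x$FN, x$radius))
  invisible(x)
}

#' Recall and precision of a matching
#'
#' `RC = TP / (TP + FN)` (fraction of actual flowers found) and
#' `PC = TP / (TP + FP)` (fraction of detections that are actual flowers).
#' A zero denominator leaves the metric missing (`NA`) with a warning,
#' never 0.
#'
#' @param match a `match_result`.
#' @return object of class `metrics_report` with `recall`, `precision`,
#'   `TP`, `FP`, `FN`.
#' @export
compute_metrics <- function(match) {
  stopifnot(inherits(match, "match_result"))
  rc <- if (match$TP + match$FN > 0) match$TP / (match$TP + match$FN) else {
    warning("recall undefined: no truth points (TP + FN = 0)")
    NA_real_
  }
  pc <- if (match$TP + match$FP > 0) match$TP / (match$TP + match$FP) else {
    warning("precision undefined: no detections (TP + FP = 0)")
    NA_real_
  }
  structure(list(recall = rc, precision = pc,
                 TP = match$TP, FP = match$FP, FN = match$FN),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  if (!is.null(x$mean_recall)) {
    cat(sprintf("metrics_report (aggregate over %d images): mean recall %s, mean precision %s\n",
                x$n_images,
                ifelse(is.na(x$mean_recall), "NA", sprintf("%.4f", x$mean_recall)),
                ifelse(is.na(x$mean_precision), "NA", sprintf("%.4f", x$mean_precision))))
  } else {
    cat(sprintf("metrics_report: recall %s, precision %s (TP %d, FP %d, FN %d)\n",
                ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall)),
                ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
                x$TP, x$FP, x$FN))
  }
  invisible(x)
}

#' Average per-image metrics over an image set
#'
#' Unweighted per-image means (not pooled counts), matching how per-variety
#' averages are reported over the images of each variety; missing per-image
#' metrics are skipped. An all-missing metric stays missing.
#'
#' @param reports non-empty list of `metrics_report` objects.
#' @return `metrics_report` with `mean_recall`, `mean_precision`, `n_images`
#'   and the number of contributing images per metric.
#' @export
aggregate_metrics <- function(reports) {
  if (!length(reports))
    abort_ic("`reports` must be non-empty", "inflocount_error_invalid_input")
  stopifnot(all(vapply(reports, inherits, logical(1), "metrics_report")))
  rc <- vapply(reports, function(r) r$recall, numeric(1))
  pc <- vapply(reports, function(r) r$precision, numeric(1))
  structure(list(
    mean_recall = if (all(is.na(rc))) NA_real_ else mean(rc, na.rm = TRUE),
    mean_precision = if (all(is.na(pc))) NA_real_ else mean(pc, na.rm = TRUE),
    n_images = length(reports),
    n_recall = sum(!is.na(rc)),
    n_precision = sum(!is.na(pc))
  ), class = "metrics_report")
}

#' Score one detection result against ground truth
#'
#' Convenience wrapper: maps detections back to original-image coordinates,
#' matches them to the truth centers and computes recall/precision.
#'
#' @param result a `detection_result`.
#' @param truth a `ground_truth` (or centers matrix).
#' @param radius matching radius; default from [default_match_radius()].
#' @return a `metrics_report`.
#' @export
score_detection <- function(result, truth, radius = NULL) {
  det <- centers_original(result)
  compute_metrics(match_detections(det, truth, radius))
}
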