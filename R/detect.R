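#' Scale an image down to a target size
#'
#' Images above the target are resized by the area-based linear factor
#' `sqrt(target_px / current_px)` (bilinear interpolation), preserving aspect
#' ratio; smaller images pass through untouched. Never upscales.
#'
#' @param image `H x W x 3` array, values in `[0, 255]`.
#' @param target_megapixels size bound in megapixels (default 2).
#' @return list with `image` (possibly resized) and `scale_factor`, the
#'   linear ratio of analyzed-image pixels per original-image pixel (1 when
#'   untouched).
#' @export
downscale_image <- function(image, target_megapixels = 2) {
  validate_rgb(image)
  if (!is.numeric(target_megapixels) || target_megapixels <= 0)
    abort_ic("`target_megapixels` must be > 0", "inflocount_error_invalid_input")
  d <- dim(image)
  target_px <- target_megapixels * 1e6
  if (d[1] * d[2] <= target_px)
    return(list(image = image, scale_factor = 1))
  s <- sqrt(target_px / (d[1] * d[2]))
  new_h <- max(1L, round(d[1] * s))
  new_w <- max(1L, round(new_h * d[2] / d[1]))
  while (new_h > 1L && as.numeric(new_h) * new_w > target_px) {
    new_h <- new_h - 1L
    new_w <- max(1L, round(new_h * d[2] / d[1]))
  }
  img <- EBImage::Image(aperm(image / 255, c(2L, 1L, 3L)), colormode = "Color")
  res <- EBImage::resize(img, w = new_w, h = new_h, filter = "bilinear")
  out <- aperm(EBImage::imageData(res), c(2L, 1L, 3L)) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  list(image = round(out), scale_factor = new_h / d[1])
}

#' Segment the inflorescence from the dark background
#'
#' Photographs follow the acquisition protocol of placing dark cardboard
#' behind the inflorescence, so background pixels are both dark and
#' achromatic. A pixel is classified background when its L* falls below a
#' threshold (automatic bimodal/Otsu threshold by default, floored at
#' L* = 10) AND its chroma is below `chroma_ceiling`; everything else is
#' foreground. Foreground specks below `speck_fraction` of the image area are
#' removed. The dual criterion is invariant to moderate exposure changes.
#'
#' @param image `H x W x 3` array, values in `[0, 255]`.
#' @param config a [pipeline_config()].
#' @return `H x W` logical matrix, `TRUE` on the inflorescence, with
#'   attribute `coverage_fraction`. Raises a `segmentation-failed` error when
#'   no foreground survives (the photo must be re-acquired).
#' @export
segment_roi <- function(image, config = pipeline_config()) {
  lab <- rgb_to_lab(image)
  .segment_roi_lab(lab, config)
}

#' @keywords internal
.segment_roi_lab <- function(lab, config) {
  L <- lab$L
  chroma <- sqrt(lab$a^2 + lab$b^2)
  thr <- config$lightness_threshold
  if (identical(thr, "auto")) thr <- max(.triangle_threshold(L), 10)
  fg <- !(L < thr & chroma < config$chroma_ceiling)
  n_px <- length(L)
  if (!any(fg))
    abort_ic(paste("segmentation failed: every pixel classified as background;",
                   "re-acquire the photo with the inflorescence in frame",
                   "against the dark backing"),
             "inflocount_error_segmentation")
  min_size <- config$speck_fraction * n_px
  labs <- cc_label(fg, config$connectivity)
  sizes <- tabulate(labs[labs > 0L])
  drop <- which(sizes < min_size)
  if (length(drop)) fg[labs %in% drop] <- FALSE
  if (!any(fg))
    abort_ic(paste("segmentation failed: only specks found;",
                   "re-acquire the photo closer to the inflorescence"),
             "inflocount_error_segmentation")
  if (all(fg))
    abort_ic(paste("segmentation failed: no background detected;",
                   "re-acquire the photo against the dark backing"),
             "inflocount_error_segmentation")
  attr(fg, "coverage_fraction") <- sum(fg) / n_px
  attr(fg, "lightness_threshold") <- thr
  fg
}

# Triangle threshold on a 256-bin histogram of L* in [0, 100]. Suited to the
# acquisition protocol's histogram shape: a dominant compact dark-background
# peak and a long-tailed bright inflorescence class (for which Otsu's
# between-class criterion lands mid-foreground and clips dim rim pixels).
# The threshold is the histogram point farthest from the chord joining the
# background peak to the last occupied bin.
#' @keywords internal
.triangle_threshold <- function(L) {
  nbin <- 256L
  h <- tabulate(pmin(pmax(floor(L / 100 * nbin) + 1L, 1L), nbin), nbins = nbin)
  peak <- which.max(h)
  last <- max(which(h > 0L))
  if (last <= peak) return(100 * peak / nbin)
  bx <- seq.int(peak, last)
  # distance from (bin, count) to the chord, up to a common positive factor
  d <- (h[peak] - h[last]) * bx + (last - peak) * h[bx]
  thr_bin <- bx[which.max(d)]
  100 * thr_bin / nbin
}

#' Find regional-maximum candidate regions in the lightness map
#'
#' A candidate is a connected plateau of equal L* inside the ROI whose
#' ROI-neighbours (under the configured connectivity) all have strictly lower
#' values -- the signature of a specular highlight on a quasi-spherical
#' flower. Plateaus touching the ROI boundary are eligible; a plateau
#' covering the whole ROI is degenerate and discarded, as are plateaus
#' smaller than `min_candidate_area`. With `h_maxima > 0`, peaks of
#' prominence below that depth are first suppressed by grayscale
#' reconstruction.
#'
#' @param lightness `H x W` numeric matrix (L*).
#' @param roi `H x W` logical matrix.
#' @param config a [pipeline_config()].
#' @return object of class `candidate_set`: list with `features` (data frame
#'   of `label`, `area`, `centroid_row`, `centroid_col`, `major_axis`,
#'   `minor_axis`, `elongation`) and `labels` (integer matrix of plateau
#'   labels, 0 outside candidates).
#' @export
find_regional_maxima <- function(lightness, roi, config = pipeline_config()) {
  if (!is.matrix(lightness) || !is.numeric(lightness))
    abort_ic("`lightness` must be a numeric matrix", "inflocount_error_invalid_input")
  if (!is.matrix(roi) || !is.logical(roi) || !identical(dim(roi), dim(lightness)))
    abort_ic("`roi` must be a logical matrix with the dimensions of `lightness`",
             "inflocount_error_invalid_input")
  v <- lightness
  if (config$h_maxima > 0)
    v <- reconstruct_dilate(v - config$h_maxima, v, config$connectivity)
  labs <- regional_maxima_labels(v, roi, config$connectivity)
  feats <- .region_features(labs)
  n_roi <- sum(roi)
  keep <- feats$area < n_roi & feats$area >= config$min_candidate_area
  feats <- feats[keep, , drop = FALSE]
  rownames(feats) <- NULL
  structure(list(features = feats, labels = labs), class = "candidate_set")
}

# Area, centroid and equal-second-moment ellipse descriptors per label.
# Axis lengths follow the standard moment-ellipse convention
# (major = 4*sqrt(lambda_1) for eigenvalues of the coordinate covariance).
# Degenerate regions: area <= 3 px is pinned to elongation 1; larger
# collinear regions are re-evaluated with half-pixel quadrature (adding the
# 1/12 variance of a unit pixel to the diagonal).
#' @keywords internal
.region_features <- function(labs) {
  idx <- which(labs > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      elongation = numeric()))
  H <- nrow(labs)
  lab <- labs[idx]
  r <- as.numeric((idx - 1L) %% H + 1L)
  cc <- as.numeric((idx - 1L) %/% H + 1L)
  area <- as.integer(tabulate(lab))
  labels <- which(area > 0L)
  area <- area[labels]
  g <- factor(lab, levels = labels)
  sr <- rowsum(r, g); sc <- rowsum(cc, g)
  rbar <- as.numeric(sr) / area
  cbar <- as.numeric(sc) / area
  mrr <- as.numeric(rowsum(r * r, g)) / area - rbar^2
  mcc <- as.numeric(rowsum(cc * cc, g)) / area - cbar^2
  mrc <- as.numeric(rowsum(r * cc, g)) / area - rbar * cbar
  ax <- .moment_axes(mrr, mcc, mrc)
  elong <- ifelse(ax$minor > 0, ax$major / ax$minor, Inf)
  degen <- area > 3L & !(ax$minor > 1e-8)
  if (any(degen)) {
    ax2 <- .moment_axes(mrr[degen] + 1 / 12, mcc[degen] + 1 / 12, mrc[degen])
    elong[degen] <- ax2$major / ax2$minor
    ax$major[degen] <- ax2$major
    ax$minor[degen] <- ax2$minor
  }
  elong[area <= 3L] <- 1
  data.frame(label = labels, area = area,
             centroid_row = rbar, centroid_col = cbar,
             major_axis = ax$major, minor_axis = ax$minor,
             elongation = elong)
}

#' @keywords internal
.moment_axes <- function(mrr, mcc, mrc) {
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- pmax((mrr + mcc + common) / 2, 0)
  l2 <- pmax((mrr + mcc - common) / 2, 0)
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

#' Pixel coordinates of one candidate region
#'
#' @param candidates a `candidate_set`.
#' @param i row index into `candidates$features`.
#' @return two-column integer matrix of (row, col) pixel coordinates.
#' @export
candidate_pixels <- function(candidates, i) {
  lab <- candidates$features$label[i]
  which(candidates$labels == lab, arr.ind = TRUE)
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d regions\n", nrow(x$features)))
  if (nrow(x$features)) print(utils::head(x$features, 10L))
  invisible(x)
}

#' Remove candidates larger than expected
#'
#' Robust single-pass upper fence on region area: candidates with
#' `area > median + k * MAD` (raw median absolute deviation) are removed.
#' The fence is estimated once from the input population; with `MAD = 0`
#' (homogeneous areas) it degenerates to `median + k`, so an all-equal
#' population is never pruned. Only an upper cut is applied, because the
#' defect this filter targets is merged highlights over several flowers,
#' which are larger than expected.
#'
#' @param candidates a `candidate_set`.
#' @param config a [pipeline_config()]; uses `size_filter_k`.
#' @return the `candidate_set` with offending rows dropped (order preserved).
#' @export
filter_by_size <- function(candidates, config = pipeline_config()) {
  feats <- candidates$features
  if (nrow(feats) == 0L) return(candidates)
  med <- stats::median(feats$area)
  m <- stats::mad(feats$area, constant = 1)
  fence <- if (m == 0) med + config$size_filter_k else
    med + config$size_filter_k * m
  candidates$features <- feats[feats$area <= fence, , drop = FALSE]
  rownames(candidates$features) <- NULL
  candidates
}

#' Remove elongated candidates
#'
#' The area of maximum light reflection on a quasi-spherical flower is
#' quasi-circular, so candidates whose moment-ellipse elongation
#' (major/minor axis ratio) exceeds `elongation_threshold` are removed.
#' Degenerate regions of up to 3 pixels are pinned to elongation 1 and
#' always retained.
#'
#' @param candidates a `candidate_set`.
#' @param config a [pipeline_config()]; uses `elongation_threshold`.
#' @return the `candidate_set` with elongated rows dropped (order preserved).
#' @export
filter_by_shape <- function(candidates, config = pipeline_config()) {
  feats <- candidates$features
  if (nrow(feats) == 0L) return(candidates)
  candidates$features <-
    feats[feats$elongation <= config$elongation_threshold, , drop = FALSE]
  rownames(candidates$features) <- NULL
  candidates
}

#' Count flowers in an inflorescence photograph
#'
#' Full three-stage pipeline: the image is scaled down to the target
#' resolution, the inflorescence is segmented from the dark background,
#' candidate flowers are detected as regional maxima of CIE L* inside the
#' ROI, and the size and shape filters are applied in sequence. Surviving
#' candidate centroids are the counted flowers. Deterministic for a fixed
#' image and configuration.
#'
#' @param image `H x W x 3` array, values in `[0, 255]`.
#' @param config a [pipeline_config()].
#' @return object of class `detection_result`: `centers` (n x 2 matrix of
#'   (row, col) centroids in analyzed-image coordinates, 1-based), `count`,
#'   stage counts `n_raw_candidates`, `n_after_size_filter`,
#'   `n_after_shape_filter`, `scale_factor` (analyzed px per original px),
#'   `analyzed_dim`, `original_dim` and the `config` snapshot.
#' @export
count_flowers <- function(image, config = pipeline_config()) {
  validate_rgb(image)
  d0 <- dim(image)[1:2]
  ds <- downscale_image(image, config$target_megapixels)
  lab <- rgb_to_lab(ds$image)
  roi <- .segment_roi_lab(lab, config)
  cand <- find_regional_maxima(lab$L, roi, config)
  n_raw <- nrow(cand$features)
  cand_sz <- filter_by_size(cand, config)
  n_size <- nrow(cand_sz$features)
  cand_sh <- filter_by_shape(cand_sz, config)
  feats <- cand_sh$features
  centers <- cbind(row = feats$centroid_row, col = feats$centroid_col)
  structure(list(
    centers = centers,
    count = nrow(feats),
    n_raw_candidates = n_raw,
    n_after_size_filter = n_size,
    n_after_shape_filter = nrow(feats),
    scale_factor = ds$scale_factor,
    analyzed_dim = dim(ds$image)[1:2],
    original_dim = d0,
    roi_coverage = attr(roi, "coverage_fraction"),
    config = config
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d flowers (candidates %d -> size filter %d -> shape filter %d)\n",
              x$count, x$n_raw_candidates, x$n_after_size_filter,
              x$n_after_shape_filter))
  cat(sprintf("  analyzed at %d x %d px (scale factor %.4f of original %d x %d)\n",
              x$analyzed_dim[1], x$analyzed_dim[2], x$scale_factor,
              x$original_dim[1], x$original_dim[2]))
  invisible(x)
}

#' Map detected centers back to original-image coordinates
#'
#' @param result a `detection_result`.
#' @return n x 2 matrix of (row, col) centers at the original resolution.
#' @export
centers_original <- function(result) {
  s <- result$scale_factor
  out <- (result$centers - 0.5) / s + 0.5
  colnames(out) <- c("row", "col")
  out
}

#' Overlay detected flowers on the original photograph
#'
#' Draws a cross at every detected center, mapped back to original-image
#' coordinates through the scale factor. Pixels outside the crosses are
#' untouched.
#'
#' @param image the original `H x W x 3` image the detection was run on.
#' @param result a `detection_result` for that image.
#' @param arm cross half-length in pixels (default scales with image size).
#' @param color length-3 RGB of the cross (default red, as in the result
#'   display).
#' @return annotated copy of `image`.
#' @export
annotate_image <- function(image, result, arm = NULL, color = c(255, 0, 0)) {
  validate_rgb(image)
  d <- dim(image)
  if (is.null(arm)) arm <- max(4L, round(0.005 * max(d[1:2])))
  ctr <- round(centers_original(result))
  if (nrow(ctr)) {
    if (any(ctr[, 1] < 1 | ctr[, 1] > d[1] | ctr[, 2] < 1 | ctr[, 2] > d[2]))
      abort_ic("detected center out of image bounds after rescaling",
               "inflocount_error_invalid_input")
  }
  out <- image
  for (i in seq_len(nrow(ctr))) {
    r <- ctr[i, 1]; cc <- ctr[i, 2]
    rows <- max(1L, r - arm):min(d[1], r + arm)
    cols <- max(1L, cc - arm):min(d[2], cc + arm)
    for (ch in 1:3) {
      out[rows, cc, ch] <- color[ch]
      out[r, cols, ch] <- color[ch]
    }
  }
  out
}
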