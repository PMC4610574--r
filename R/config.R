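#' Detection pipeline configuration
#'
#' Collects the tunable parameters of the flower-counting pipeline. Defaults
#' are the shipped operating point; all are overridable per call or through a
#' flat key-value config file (see [read_pipeline_config()]).
#'
#' @param target_megapixels images larger than this are scaled down before
#'   analysis to bound the computational load; 2 Mpx by default.
#' @param connectivity pixel adjacency for plateaus and components, 4 or 8.
#' @param lightness_threshold `"auto"` for a bimodal-histogram (Otsu)
#'   threshold on L*, or a fixed numeric L* value in `[0, 100]`. In automatic
#'   mode the threshold is floored at L* = 10 so an all-dark frame fails
#'   segmentation instead of splitting sensor noise.
#' @param chroma_ceiling background pixels must also have chroma
#'   `sqrt(a*^2 + b*^2)` below this ceiling; the dark cardboard backing is
#'   both dark and achromatic, so the dual criterion tolerates exposure
#'   changes.
#' @param speck_fraction foreground components smaller than this fraction of
#'   the image area are removed as specks during ROI cleanup.
#' @param size_filter_k multiplier of the raw median absolute deviation in
#'   the robust upper size fence `median + k * MAD`; with `MAD = 0` the fence
#'   degenerates to `median + k`.
#' @param elongation_threshold candidates whose moment-ellipse elongation
#'   (major/minor axis) exceeds this are discarded as non-circular.
#' @param min_candidate_area regional-maximum plateaus smaller than this many
#'   pixels are discarded; 1 disables the cut, >= 2 can help with noisy
#'   sensors.
#' @param h_maxima optional suppression of shallow peaks: maxima with
#'   prominence below this L* depth are merged into their surroundings via
#'   grayscale reconstruction before candidate detection. 0 (default)
#'   disables the transform.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_megapixels = 2,
                            connectivity = 8L,
                            lightness_threshold = "auto",
                            chroma_ceiling = 15,
                            speck_fraction = 1e-4,
                            size_filter_k = 3,
                            elongation_threshold = 2,
                            min_candidate_area = 1L,
                            h_maxima = 0) {
  if (!is.numeric(target_megapixels) || target_megapixels <= 0)
    abort_ic("`target_megapixels` must be > 0", "inflocount_error_invalid_input")
  if (!connectivity %in% c(4L, 8L))
    abort_ic("`connectivity` must be 4 or 8", "inflocount_error_invalid_input")
  if (is.character(lightness_threshold)) {
    if (!identical(lightness_threshold, "auto"))
      abort_ic("`lightness_threshold` must be \"auto\" or a numeric L* value",
               "inflocount_error_invalid_input")
  } else if (!is.numeric(lightness_threshold) ||
             lightness_threshold < 0 || lightness_threshold > 100) {
    abort_ic("fixed `lightness_threshold` must lie in [0, 100]",
             "inflocount_error_invalid_input")
  }
  if (!is.numeric(size_filter_k) || size_filter_k <= 0)
    abort_ic("`size_filter_k` must be > 0", "inflocount_error_invalid_input")
  if (!is.numeric(elongation_threshold) || elongation_threshold < 1)
    abort_ic("`elongation_threshold` must be >= 1", "inflocount_error_invalid_input")
  if (!is.numeric(min_candidate_area) || min_candidate_area < 1)
    abort_ic("`min_candidate_area` must be >= 1", "inflocount_error_invalid_input")
  if (!is.numeric(h_maxima) || h_maxima < 0)
    abort_ic("`h_maxima` must be >= 0", "inflocount_error_invalid_input")
  structure(list(
    target_megapixels = as.numeric(target_megapixels),
    connectivity = as.integer(connectivity),
    lightness_threshold = lightness_threshold,
    chroma_ceiling = as.numeric(chroma_ceiling),
    speck_fraction = as.numeric(speck_fraction),
    size_filter_k = as.numeric(size_filter_k),
    elongation_threshold = as.numeric(elongation_threshold),
    min_candidate_area = as.integer(min_candidate_area),
    h_maxima = as.numeric(h_maxima)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Flower-detection pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Lines of the form `key = value`; `#` starts a comment; keys are the
#' arguments of [pipeline_config()]. Unknown keys raise an error.
#'
#' @param path file path.
#' @return object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    abort_ic(sprintf("config file not found: %s", path),
             "inflocount_error_invalid_input")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      abort_ic(sprintf("malformed config line: %s", ln),
               "inflocount_error_invalid_input")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(pipeline_config)))
      abort_ic(sprintf("unknown config key: %s", key),
               "inflocount_error_invalid_input")
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (is.na(num)) val else num
  }
  do.call(pipeline_config, args)
}
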