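# Run code under a fixed seed without disturbing the caller's RNG state.
#' @keywords internal
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of a synthetic inflorescence scene
#'
#' Describes a rendered stand-in for a field photograph: a near-black
#' low-chroma background (dark cardboard), dozens of bright quasi-spherical
#' flower buttons each carrying one specular highlight, an illumination
#' gradient, sensor noise, and optional elongated distractor streaks (stem
#' glints) that specifically exercise the shape filter. Defaults are the
#' package's frozen desk-scale operating point (see the methods vignette).
#'
#' @param image_size `(H, W)` in pixels.
#' @param n_flowers number of flowers to place (>= 0).
#' @param flower_radius_range `(min, max)` flower radius in pixels.
#' @param min_center_separation minimum pairwise distance between
#'   non-clustered flower centers, and between cluster anchors.
#' @param crowding fraction in `[0, 1]` of flowers placed in contact with a
#'   host flower (overlapping discs), emulating compact cultivars; clustered
#'   members are exempt from the separation constraint.
#' @param background_lightness background L* (dark cardboard, default 3).
#' @param highlight_gain multiplier on the specular highlight amplitude.
#' @param illumination_gradient maximum relative intensity change across the
#'   frame (multiplicative ramp along a random direction).
#' @param noise_sigma per-channel Gaussian noise standard deviation in 8-bit
#'   digital numbers.
#' @param distractor_count elongated bright streaks per image (aspect >= 3).
#' @param seed RNG seed; identical params give bit-identical scenes.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_size = c(600L, 800L),
                         n_flowers = 50L,
                         flower_radius_range = c(8, 14),
                         min_center_separation = 34,
                         crowding = 0,
                         background_lightness = 3,
                         highlight_gain = 1,
                         illumination_gradient = 0.25,
                         noise_sigma = 1.5,
                         distractor_count = 3L,
                         seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 1))
    abort_ic("`image_size` must be (H, W) with positive entries",
             "inflocount_error_invalid_input")
  if (n_flowers < 0)
    abort_ic("`n_flowers` must be >= 0", "inflocount_error_invalid_input")
  if (length(flower_radius_range) != 2L ||
      flower_radius_range[1] > flower_radius_range[2] ||
      flower_radius_range[1] <= 0)
    abort_ic("`flower_radius_range` must be positive (min, max) with min <= max",
             "inflocount_error_invalid_input")
  if (crowding < 0 || crowding > 1)
    abort_ic("`crowding` must lie in [0, 1]", "inflocount_error_invalid_input")
  if (noise_sigma < 0)
    abort_ic("`noise_sigma` must be >= 0", "inflocount_error_invalid_input")
  if (distractor_count < 0)
    abort_ic("`distractor_count` must be >= 0", "inflocount_error_invalid_input")
  structure(list(
    image_size = as.integer(image_size),
    n_flowers = as.integer(n_flowers),
    flower_radius_range = as.numeric(flower_radius_range),
    min_center_separation = as.numeric(min_center_separation),
    crowding = as.numeric(crowding),
    background_lightness = as.numeric(background_lightness),
    highlight_gain = as.numeric(highlight_gain),
    illumination_gradient = as.numeric(illumination_gradient),
    noise_sigma = as.numeric(noise_sigma),
    distractor_count = as.integer(distractor_count),
    seed = as.integer(seed)
  ), class = "scene_params")
}

# Fixed scene illumination: unit light direction (row, col, z) and the
# greenish-white flower albedo in sRGB. The specular spot sits at the
# projection of the light direction onto the sphere, i.e. at the diffuse
# maximum, so each flower carries exactly one dominant peak.
.SCENE_LIGHT <- c(-0.25, 0.33, sqrt(1 - 0.25^2 - 0.33^2))
.SCENE_ALBEDO <- c(0.80, 0.86, 0.68)
.SCENE_AMBIENT <- 0.35
.SCENE_SPEC_AMPLITUDE <- 180
.SCENE_SPEC_SIGMA <- 2.2
.SCENE_STREAK_AMPLITUDE <- 330

#' Render a synthetic inflorescence scene with ground truth
#'
#' Each flower is a shaded (Lambertian) sphere with one specular highlight
#' offset towards the light; the highlight core saturates, as real specular
#' reflections do, giving one compact bright plateau per flower. Distractor
#' streaks are anisotropic Gaussian ridges. An illumination gradient,
#' per-channel Gaussian noise and 8-bit quantization are applied last.
#'
#' @param params a [scene_params()].
#' @return list with `image` (`H x W x 3`, 0-255) and `truth`, an object of
#'   class `ground_truth`: `centers` (n x 2 matrix of (row, col), 1-based),
#'   `flower_mask` (`H x W` logical union of flower discs) and `params_used`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  .with_seed(params$seed, .render_scene(params))
}

#' @keywords internal
.render_scene <- function(params) {
  H <- params$image_size[1]; W <- params$image_size[2]
  n <- params$n_flowers
  rr <- params$flower_radius_range

  radii <- if (n > 0) runif(n, rr[1], rr[2]) else numeric()
  margin <- rr[2] + 2
  if (n > 0 && (H - 2 * margin < 1 || W - 2 * margin < 1))
    abort_ic("placement failed: image too small for the flower radius range",
             "inflocount_error_placement")

  n_cluster <- round(params$crowding * n)
  n_main <- n - n_cluster
  centers <- matrix(NA_real_, n, 2L)
  # main flowers: rejection sampling under the separation constraint
  for (i in seq_len(n_main)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      if (i == 1L) { ok <- TRUE } else {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        dmin <- sqrt(min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2))
        ok <- dmin >= params$min_center_separation
      }
      if (ok) { centers[i, ] <- cand; break }
    }
    if (!ok)
      abort_ic(paste("placement failed: could not satisfy",
                     "min_center_separation for the requested flower count"),
               "inflocount_error_placement")
  }
  # clustered flowers: in contact with a random host, exempt from separation
  for (i in seq_len(n_cluster)) {
    j <- n_main + i
    ok <- FALSE
    for (try in seq_len(200L)) {
      host <- sample.int(max(n_main, 1L), 1L)
      if (n_main == 0L)
        abort_ic("placement failed: crowding > 0 requires at least one non-clustered flower",
                 "inflocount_error_placement")
      theta <- runif(1, 0, 2 * pi)
      d <- 0.8 * (radii[host] + radii[j])
      cand <- centers[host, ] + d * c(cos(theta), sin(theta))
      if (cand[1] >= margin && cand[1] <= H - margin &&
          cand[2] >= margin && cand[2] <= W - margin) {
        centers[j, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok)
      abort_ic("placement failed: could not keep clustered flowers inside the frame",
               "inflocount_error_placement")
  }

  # background: dark, nearly achromatic cardboard
  bg <- grDevices::convertColor(
    matrix(c(params$background_lightness, -1, 2), 1L), from = "Lab", to = "sRGB")
  bg <- pmin(pmax(bg, 0), 1) * 255
  canvas <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) canvas[, , ch] <- bg[ch]
  flower_mask <- matrix(FALSE, H, W)

  lt <- .SCENE_LIGHT
  draw_order <- if (n > 0) sample.int(n) else integer()
  for (i in draw_order) {
    r <- radii[i]; cy <- centers[i, 1]; cx <- centers[i, 2]
    rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
    cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
    dr <- outer(rows - cy, rep(1, length(cols)))
    dc <- outer(rep(1, length(rows)), cols - cx)
    d2 <- dr^2 + dc^2
    inside <- d2 <= r^2
    if (!any(inside)) next
    nz <- sqrt(pmax(r^2 - d2, 0)) / r
    diffuse <- pmax((dr / r) * lt[1] + (dc / r) * lt[2] + nz * lt[3], 0)
    shade <- .SCENE_AMBIENT + (1 - .SCENE_AMBIENT) * diffuse
    hy <- r * lt[1]; hx <- r * lt[2]
    spec <- params$highlight_gain * .SCENE_SPEC_AMPLITUDE *
      exp(-((dr - hy)^2 + (dc - hx)^2) / (2 * .SCENE_SPEC_SIGMA^2))
    for (ch in 1:3) {
      val <- 255 * .SCENE_ALBEDO[ch] * shade + spec
      plane <- canvas[rows, cols, ch]
      plane[inside] <- val[inside]
      canvas[rows, cols, ch] <- plane
    }
    fm <- flower_mask[rows, cols]
    fm[inside] <- TRUE
    flower_mask[rows, cols] <- fm
  }

  # elongated distractor streaks (stem glints), max-combined onto the canvas
  for (k in seq_len(params$distractor_count)) {
    y0 <- runif(1, 10, H - 10); x0 <- runif(1, 10, W - 10)
    theta <- runif(1, 0, pi)
    sl <- runif(1, 5, 9)
    sp <- sl / runif(1, 3, 4.5)
    ext <- ceiling(3 * sl)
    rows <- max(1L, floor(y0 - ext)):min(H, ceiling(y0 + ext))
    cols <- max(1L, floor(x0 - ext)):min(W, ceiling(x0 + ext))
    dr <- outer(rows - y0, rep(1, length(cols)))
    dc <- outer(rep(1, length(rows)), cols - x0)
    u <- dc * cos(theta) + dr * sin(theta)
    v <- -dc * sin(theta) + dr * cos(theta)
    ridge <- .SCENE_STREAK_AMPLITUDE * exp(-u^2 / (2 * sl^2) - v^2 / (2 * sp^2))
    glint <- c(0.92, 1, 0.88)
    for (ch in 1:3) {
      plane <- canvas[rows, cols, ch]
      canvas[rows, cols, ch] <- pmax(plane, bg[ch] + glint[ch] * ridge)
    }
  }

  # illumination gradient: multiplicative ramp along a random direction
  if (params$illumination_gradient > 0) {
    phi <- runif(1, 0, 2 * pi)
    gr <- cos(phi); gc <- sin(phi)
    tmat <- outer((seq_len(H) - 1) / max(H - 1, 1) * gr, rep(1, W)) +
      outer(rep(1, H), (seq_len(W) - 1) / max(W - 1, 1) * gc)
    tmat <- (tmat - min(tmat)) / max(max(tmat) - min(tmat), 1e-12)
    gain <- 1 + params$illumination_gradient * (tmat - 0.5)
    for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] * gain
  }

  if (params$noise_sigma > 0)
    canvas <- canvas + array(rnorm(length(canvas), 0, params$noise_sigma),
                             dim = dim(canvas))
  canvas[canvas < 0] <- 0; canvas[canvas > 255] <- 255
  image <- round(canvas)

  colnames(centers) <- c("row", "col")
  truth <- structure(list(
    centers = centers,
    flower_mask = flower_mask,
    params_used = params
  ), class = "ground_truth")
  list(image = image, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d flower centers, mask covering %.1f%% of %d x %d px\n",
              nrow(x$centers), 100 * mean(x$flower_mask),
              nrow(x$flower_mask), ncol(x$flower_mask)))
  invisible(x)
}

#' Generate a seeded benchmark set of synthetic scenes
#'
#' Per-image seeds are derived deterministically from the master seed, and
#' per-image flower counts are drawn uniformly from `count_range`, standing
#' in for a field image set with varying inflorescence sizes.
#'
#' @param n_images number of scenes (>= 1).
#' @param params a [scene_params()] template; its `seed` and `n_flowers` are
#'   overridden per image.
#' @param seed master seed.
#' @param count_range inclusive integer range for per-image flower counts.
#' @return list of `n_images` elements, each a list with `image` and `truth`.
#' @export
generate_benchmark_set <- function(n_images, params = scene_params(),
                                   seed = 1L, count_range = c(40L, 60L)) {
  if (n_images < 1)
    abort_ic("`n_images` must be >= 1", "inflocount_error_invalid_input")
  vals <- seq.int(count_range[1], count_range[2])
  counts <- .with_seed(seed,
    vals[sample.int(length(vals), n_images, replace = TRUE)])
  lapply(seq_len(n_images), function(i) {
    p <- params
    p$seed <- as.integer((seed * 48271 + i * 104729) %% 2147483647)
    p$n_flowers <- counts[i]
    generate_scene(p)
  })
}

#' Write a scene to disk as PNG plus a ground-truth sidecar CSV
#'
#' The sidecar uses the evaluation module's annotation format: columns
#' `row,col`, 0-based, header required.
#'
#' @param scene list with `image` and `truth` as from [generate_scene()].
#' @param png_path destination PNG.
#' @param csv_path destination CSV (default: PNG path with `.csv`).
#' @return invisibly, the two paths.
#' @export
write_scene <- function(scene, png_path,
                        csv_path = sub("\\.png$", ".csv", png_path)) {
  write_rgb(scene$image, png_path)
  write_centers_csv(scene$truth$centers, csv_path)
  invisible(c(png_path, csv_path))
}
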