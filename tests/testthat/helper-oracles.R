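# Independent oracles and shared fixtures for the test suite.

# Brute-force regional-maxima oracle: enumerates every equal-value plateau by
# breadth-first search and inspects all its ROI neighbours. Independent of the
# package's compiled path. Returns a canonical representation: a sorted list
# of sorted linear-index vectors, one per regional-maximum plateau.
oracle_regional_maxima <- function(v, roi, connectivity = 8) {
  H <- nrow(v); W <- ncol(v)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  }
  visited <- matrix(FALSE, H, W)
  out <- list()
  n_roi <- sum(roi)
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!roi[r0, c0] || visited[r0, c0]) next
    val <- v[r0, c0]
    queue <- list(c(r0, c0))
    visited[r0, c0] <- TRUE
    plateau <- integer()
    is_max <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      plateau <- c(plateau, as.integer((p[2] - 1) * H + p[1]))
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr < 1 || rr > H || cc < 1 || cc > W || !roi[rr, cc]) next
        w <- v[rr, cc]
        if (w > val) is_max <- FALSE
        if (w == val && !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
    if (is_max && length(plateau) < n_roi) out <- c(out, list(sort(plateau)))
  }
  out[order(vapply(out, min, numeric(1)))]
}

# Canonical plateau sets from a candidate_set, comparable with the oracle.
candidate_pixel_sets <- function(cs) {
  labs <- cs$labels
  keep <- cs$features$label
  idx <- which(labs > 0L)
  idx <- idx[labs[idx] %in% keep]
  sets <- split(idx, labs[idx])
  sets <- lapply(sets, sort)
  names(sets) <- NULL
  sets[order(vapply(sets, min, numeric(1)))]
}

# Maximum bipartite matching (augmenting paths) between detections and truth
# points within `radius` -- the optimal-matching oracle for the greedy scheme.
oracle_max_matching_tp <- function(det, tru, radius) {
  n <- nrow(det); m <- nrow(tru)
  if (n == 0 || m == 0) return(0L)
  d2 <- outer(det[, 1], tru[, 1], "-")^2 + outer(det[, 2], tru[, 2], "-")^2
  adj <- d2 <= radius^2
  match_t <- rep(0L, m)
  try_augment <- function(i, seen) {
    for (j in which(adj[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_t[j] == 0L || Recall(match_t[j], seen)) {
        match_t[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_len(n)) if (try_augment(i, rep(FALSE, m))) tp <- tp + 1L
  tp
}

# Desk-scale scene template used where full-size scenes would be wasteful.
small_scene_params <- function(seed = 1L, n_flowers = 12L,
                               distractor_count = 1L, ...) {
  scene_params(image_size = c(220L, 300L), n_flowers = n_flowers,
               flower_radius_range = c(7, 11), min_center_separation = 28,
               distractor_count = distractor_count, seed = seed, ...)
}

# Random integer lightness maps with many plateaus, plus a random ROI.
random_map_and_roi <- function(seed, size = 30L, levels = 8L) {
  set.seed(seed)
  v <- matrix(sample.int(levels, size * size, replace = TRUE), size, size)
  roi <- if (seed %% 3 == 0) {
    matrix(TRUE, size, size)
  } else {
    m <- matrix(runif(size * size) < 0.85, size, size)
    if (!any(m)) m[1, 1] <- TRUE
    m
  }
  list(v = v, roi = roi)
}

# Strictly increasing piecewise-linear remap of [0, 100].
random_monotone_remap <- function(seed, knots = 8L) {
  set.seed(seed)
  x <- c(0, sort(runif(knots, 0, 100)), 100)
  y <- cumsum(c(0, runif(knots + 1L, 0.2, 2)))
  y <- y / max(y) * 100
  function(v) {
    out <- stats::approx(x, y, xout = as.vector(v), rule = 2)$y
    matrix(out, nrow(v), ncol(v))
  }
}
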