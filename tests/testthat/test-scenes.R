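test_that("identical parameters give bit-identical scenes", {
  p <- small_scene_params(seed = 4)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth$centers, s2$truth$centers)
  expect_identical(s1$truth$flower_mask, s2$truth$flower_mask)
})

test_that("an empty scene is background plus noise with no truth centers", {
  sc <- generate_scene(small_scene_params(seed = 1, n_flowers = 0L,
                                          distractor_count = 0L))
  expect_equal(nrow(sc$truth$centers), 0L)
  expect_false(any(sc$truth$flower_mask))
  expect_lt(mean(sc$image), 25)  # dark cardboard
})

test_that("default placement honours the separation constraint", {
  sc <- generate_scene(scene_params(n_flowers = 50L, seed = 1L))
  ctr <- sc$truth$centers
  expect_equal(nrow(ctr), 50L)
  dm <- as.matrix(dist(ctr)); diag(dm) <- Inf
  expect_gte(min(dm), scene_params()$min_center_separation)
  expect_true(all(ctr[, 1] >= 1 & ctr[, 1] <= 600 &
                  ctr[, 2] >= 1 & ctr[, 2] <= 800))
})

test_that("every truth center and highlight lies inside the flower mask", {
  sc <- generate_scene(small_scene_params(seed = 6, noise_sigma = 0,
                                          distractor_count = 0L))
  ctr <- round(sc$truth$centers)
  expect_true(all(sc$truth$flower_mask[ctr]))
  # with a clean render, detected highlight plateaus sit inside flower pixels
  res <- count_flowers(sc$image)
  det <- round(res$centers)
  expect_true(all(sc$truth$flower_mask[det]))
})

test_that("infeasible packing raises a placement error naming the constraint", {
  err <- tryCatch(
    generate_scene(scene_params(image_size = c(120L, 120L), n_flowers = 60L,
                                seed = 1L)),
    error = identity)
  expect_s3_class(err, "inflocount_error_placement")
  expect_match(conditionMessage(err), "min_center_separation|radius")
})

test_that("crowded flowers are rendered in contact with their hosts", {
  sc <- generate_scene(small_scene_params(seed = 12, n_flowers = 10L,
                                          crowding = 0.4))
  ctr <- sc$truth$centers
  dm <- as.matrix(dist(ctr)); diag(dm) <- Inf
  # clustered members violate the separation constraint by design
  expect_lt(min(dm), small_scene_params()$min_center_separation)
  expect_equal(nrow(ctr), 10L)
})

test_that("benchmark sets are reproducible, seed-sensitive and composable", {
  p <- small_scene_params()
  s7a <- generate_benchmark_set(4, p, seed = 7, count_range = c(8L, 12L))
  s7b <- generate_benchmark_set(4, p, seed = 7, count_range = c(8L, 12L))
  s8 <- generate_benchmark_set(4, p, seed = 8, count_range = c(8L, 12L))
  expect_identical(s7a, s7b)
  sum7 <- vapply(s7a, function(s) sum(s$image), numeric(1))
  sum8 <- vapply(s8, function(s) sum(s$image), numeric(1))
  expect_false(identical(sum7, sum8))
  expect_gt(length(unique(sum7)), 1)  # distinct images within a set

  # a one-image set equals generate_scene at the derived seed and count
  one <- generate_benchmark_set(1, p, seed = 7, count_range = c(9L, 9L))
  p1 <- p
  p1$seed <- as.integer((7 * 48271 + 104729) %% 2147483647)
  p1$n_flowers <- 9L
  expect_identical(one[[1]]$image, generate_scene(p1)$image)
})

test_that("recall degrades monotonically with crowding and with noise", {
  levels_rc <- function(field, values) {
    vapply(values, function(val) {
      rc <- vapply(1:20, function(s) {
        args <- list(seed = s, n_flowers = 14L, distractor_count = 1L)
        args[[field]] <- val
        sc <- generate_scene(do.call(small_scene_params, args))
        score_detection(count_flowers(sc$image), sc$truth)$recall
      }, numeric(1))
      mean(rc)
    }, numeric(1))
  }
  rc_crowd <- levels_rc("crowding", c(0, 0.3, 0.6))
  expect_lte(rc_crowd[2], rc_crowd[1] + 0.005)
  expect_lte(rc_crowd[3], rc_crowd[2] + 0.005)
  rc_noise <- levels_rc("noise_sigma", c(1.5, 4, 8))
  expect_lte(rc_noise[2], rc_noise[1] + 0.005)
  expect_lte(rc_noise[3], rc_noise[2] + 0.005)
})

test_that("scene sidecar round-trips through the annotation format", {
  sc <- generate_scene(small_scene_params(seed = 3, n_flowers = 8L))
  png <- tempfile(fileext = ".png")
  write_scene(sc, png)
  on.exit(unlink(c(png, sub("\\.png$", ".csv", png))))
  expect_equal(read_rgb(png), sc$image, ignore_attr = TRUE)
  ctr <- read_centers_csv(sub("\\.png$", ".csv", png))
  expect_equal(ctr, sc$truth$centers, ignore_attr = TRUE)
})
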