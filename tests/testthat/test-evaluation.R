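test_that("matching handles the canonical cases", {
  # one detection exactly on one truth point
  m <- match_detections(matrix(c(10, 10), 1), matrix(c(10, 10), 1), radius = 3)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))

  # two detections within radius of one truth point: the redundant one is FP
  det <- rbind(c(10, 10.5), c(10, 9.5))
  m <- match_detections(det, matrix(c(10, 10), 1), radius = 3)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 1L, 0L))

  # three truths, no detections: all missed
  m <- match_detections(matrix(numeric(), 0, 2),
                        rbind(c(1, 1), c(5, 5), c(9, 9)), radius = 2)
  expect_equal(c(m$TP, m$FP, m$FN), c(0L, 0L, 3L))

  # a detection outside the radius of every truth is FP, the truth FN
  m <- match_detections(matrix(c(0, 0), 1), matrix(c(50, 50), 1), radius = 5)
  expect_equal(c(m$TP, m$FP, m$FN), c(0L, 1L, 1L))
})

test_that("greedy matching prefers the nearest pair", {
  det <- rbind(c(0, 0), c(0, 3))
  tru <- rbind(c(0, 1))
  m <- match_detections(det, tru, radius = 5)
  expect_equal(m$TP, 1L)
  expect_equal(unname(m$pairs[1, ]), c(1L, 1L))  # closer detection wins
})

test_that("recall and precision follow the contingency definitions", {
  fake <- function(TP, FP, FN) structure(
    list(TP = TP, FP = FP, FN = FN,
         pairs = matrix(integer(), 0, 2), radius = 1),
    class = "match_result")
  r <- compute_metrics(fake(84, 6, 16))
  expect_equal(r$recall, 0.84, tolerance = 1e-12)
  expect_equal(r$precision, 84 / 90, tolerance = 1e-12)

  w <- capture_warnings(r0 <- compute_metrics(fake(0, 0, 0)))
  expect_length(w, 2L)
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(r0$recall) && is.na(r0$precision))

  r1 <- compute_metrics(fake(7, 0, 0))
  expect_equal(c(r1$recall, r1$precision), c(1, 1))
})

test_that("aggregation is an unweighted per-image mean that skips missing", {
  rep_rc <- function(rc, pc) structure(
    list(recall = rc, precision = pc, TP = 0L, FP = 0L, FN = 0L),
    class = "metrics_report")
  agg <- aggregate_metrics(list(rep_rc(0.8, 0.9), rep_rc(0.9, 1.0)))
  expect_equal(agg$mean_recall, 0.85)
  expect_equal(agg$mean_precision, 0.95)

  single <- aggregate_metrics(list(rep_rc(0.7, 0.6)))
  expect_equal(single$mean_recall, 0.7)
  expect_equal(single$mean_precision, 0.6)

  agg2 <- aggregate_metrics(list(rep_rc(0.8, NA), rep_rc(NA, 0.5), rep_rc(0.9, NA)))
  expect_equal(agg2$mean_recall, 0.85)
  expect_equal(agg2$mean_precision, 0.5)
  expect_equal(agg2$n_recall, 2L)

  all_na <- aggregate_metrics(list(rep_rc(NA, NA)))
  expect_true(is.na(all_na$mean_recall) && is.na(all_na$mean_precision))
  expect_error(aggregate_metrics(list()), class = "inflocount_error_invalid_input")
})

test_that("accounting is conserved on fuzzed instances", {
  set.seed(99)
  for (i in 1:150) {
    n_det <- sample(0:25, 1); n_tru <- sample(0:25, 1)
    det <- matrix(runif(2 * n_det, 0, 40), ncol = 2)
    tru <- matrix(runif(2 * n_tru, 0, 40), ncol = 2)
    m <- match_detections(det, tru, radius = runif(1, 0.5, 8))
    expect_identical(m$TP + m$FN, n_tru)
    expect_identical(m$TP + m$FP, n_det)
    expect_equal(anyDuplicated(m$pairs[, 2]), 0L)
    expect_equal(anyDuplicated(m$pairs[, 1]), 0L)
  }
})

test_that("permuting detections never changes TP/FP/FN", {
  set.seed(17)
  for (i in 1:25) {
    det <- matrix(runif(30, 0, 20), ncol = 2)
    tru <- matrix(runif(24, 0, 20), ncol = 2)
    m0 <- match_detections(det, tru, radius = 3)
    perm <- sample(nrow(det))
    m1 <- match_detections(det[perm, ], tru, radius = 3)
    expect_identical(c(m0$TP, m0$FP, m0$FN), c(m1$TP, m1$FP, m1$FN))
  }
})

test_that("greedy equals optimal bipartite matching for well-separated truths", {
  set.seed(41)
  for (i in 1:50) {
    radius <- runif(1, 1, 3)
    # truths separated by more than 2 * radius: each detection can reach at
    # most one truth, so greedy is exactly optimal
    tru <- matrix(numeric(), 0, 2)
    while (nrow(tru) < 8) {
      cand <- matrix(runif(2, 0, 60), 1)
      if (!nrow(tru) ||
          min(sqrt((tru[, 1] - cand[1])^2 + (tru[, 2] - cand[2])^2)) >
            2 * radius + 0.1)
        tru <- rbind(tru, cand)
    }
    det <- tru[sample(8, 6), ] + matrix(runif(12, -radius / 2, radius / 2), 6)
    det <- rbind(det, matrix(runif(6, 0, 60), 3))
    m <- match_detections(det, tru, radius = radius)
    expect_identical(m$TP, oracle_max_matching_tp(det, tru, radius))
  }
})

test_that("the default radius is half the median nearest-neighbour spacing", {
  # 3 x 3 grid with 10 px pitch: every nearest neighbour is 10 away
  tru <- as.matrix(expand.grid(row = c(10, 20, 30), col = c(10, 20, 30)))
  expect_equal(default_match_radius(tru), 5)
  expect_error(default_match_radius(matrix(c(1, 1), 1)),
               class = "inflocount_error_invalid_input")
})
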