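test_that("identical point sets match perfectly", {
  pts <- data.frame(x = c(1, 5, 9), y = c(2, 4, 8))
  m <- match_points(pts, pts, max_match_distance = 2)
  expect_equal(m$n_tp, 3)
  expect_equal(m$n_fp, 0)
  expect_equal(m$n_fn, 0)
  expect_true(all(m$pairs$distance == 0))
})

test_that("missing detections count as false negatives", {
  ann <- data.frame(x = 1:5, y = 1:5)
  m <- match_points(data.frame(x = numeric(0), y = numeric(0)), ann, 2)
  expect_equal(m$n_fn, 5)
  expect_equal(m$n_tp, 0)
  expect_equal(m$n_fp, 0)
})

test_that("optimal matching beats greedy on a crafted geometry", {
  # greedy pairs d1 with a2 (distance 1) and strands d2; the optimal
  # assignment pairs d1-a1 (2.0) and d2-a2 (1.5), two TPs
  det <- data.frame(x = c(0, 4), y = c(0, 0))
  ann <- data.frame(x = c(-2, 1, 10), y = c(0, 0, 10))
  det$x <- c(0, 2.5)
  m <- match_points(det, ann, max_match_distance = 2)
  o <- oracle_match(det, ann, 2)
  expect_equal(m$n_tp, o$n)
  expect_equal(sum(m$pairs$distance), o$dist)
  expect_equal(m$n_tp, 2)
})

test_that("matching equals exhaustive assignment enumeration", {
  set.seed(37)
  for (i in 1:12) {
    nd <- sample(0:6, 1); na <- sample(0:6, 1)
    det <- data.frame(x = runif(nd, 0, 10), y = runif(nd, 0, 10))
    ann <- data.frame(x = runif(na, 0, 10), y = runif(na, 0, 10))
    gate <- runif(1, 1, 6)
    m <- match_points(det, ann, gate)
    o <- oracle_match(det, ann, gate)
    expect_equal(m$n_tp, o$n)
    expect_equal(sum(m$pairs$distance), o$dist, tolerance = 1e-9)
    # invariants: one-to-one within the gate
    expect_equal(anyDuplicated(m$pairs$detection), 0)
    expect_equal(anyDuplicated(m$pairs$annotation), 0)
    expect_true(all(m$pairs$distance <= gate))
    expect_equal(m$n_fp, nd - m$n_tp)
    expect_equal(m$n_fn, na - m$n_tp)
  }
})

test_that("swapping detections and annotations swaps precision and recall", {
  set.seed(43)
  det <- data.frame(x = runif(5, 0, 20), y = runif(5, 0, 20))
  ann <- data.frame(x = runif(8, 0, 20), y = runif(8, 0, 20))
  r1 <- compute_report(list(match_points(det, ann, 5)))
  r2 <- compute_report(list(match_points(ann, det, 5)))
  expect_equal(r1$precision, r2$recall)
  expect_equal(r1$recall, r2$precision)
  expect_equal(r1$f1, r2$f1)
})

test_that("a far-away detection adds exactly one false positive", {
  ann <- data.frame(x = c(2, 8), y = c(2, 8))
  det <- ann
  r0 <- compute_report(list(match_points(det, ann, 3)))
  det2 <- rbind(det, data.frame(x = 100, y = 100))
  r1 <- compute_report(list(match_points(det2, ann, 3)))
  expect_equal(r1$fp, r0$fp + 1)
  expect_lt(r1$precision, r0$precision)
  expect_equal(r1$recall, r0$recall)
})

test_that("report metrics follow the pooled TP/FP/FN identities", {
  fake <- function(tp, fp, fn) structure(
    list(pairs = data.frame(detection = seq_len(tp),
                            annotation = seq_len(tp),
                            distance = rep(0, tp)),
         n_tp = tp, n_fp = fp, n_fn = fn, max_match_distance = 5),
    class = "match_result")
  r <- compute_report(list(fake(9, 1, 3)))
  expect_equal(r$precision, 0.9)
  expect_equal(r$recall, 0.75)
  expect_equal(r$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))
  # MAE is averaged over images in trees
  r2 <- compute_report(list(fake(3, 0, 2), fake(4, 0, 0)),
                       counts = data.frame(predicted = c(3, 4),
                                           true = c(5, 4)))
  expect_equal(r2$mae, 1.0)
  # degenerate denominators define the metrics as 0
  r3 <- compute_report(list(fake(0, 0, 0)))
  expect_equal(c(r3$precision, r3$recall, r3$f1), c(0, 0, 0))
  expect_error(compute_report(list()), "empty")
  # identities re-derived from the pooled tallies for random reports
  set.seed(51)
  for (i in 1:8) {
    ms <- lapply(1:3, function(j)
      fake(sample(0:9, 1), sample(0:5, 1), sample(0:5, 1)))
    r <- compute_report(ms)
    TP <- sum(sapply(ms, `[[`, "n_tp")); FP <- sum(sapply(ms, `[[`, "n_fp"))
    FN <- sum(sapply(ms, `[[`, "n_fn"))
    expect_equal(r$precision, if (TP + FP > 0) TP / (TP + FP) else 0)
    expect_equal(r$recall, if (TP + FN > 0) TP / (TP + FN) else 0)
    expect_equal(r$f1, if (r$precision + r$recall > 0)
      2 * r$precision * r$recall / (r$precision + r$recall) else 0)
  }
})
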