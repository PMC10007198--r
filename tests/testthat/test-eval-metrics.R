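test_that("metrics evaluate the printed sorting-count examples exactly", {
  cc <- confusion_counts(480, 480, 20, 20)
  expect_equal(precision(cc), 0.96)
  expect_equal(recall(cc), 0.96)
  expect_equal(accuracy(cc), 0.96)

  cc <- confusion_counts(436, 456, 44, 64)
  expect_equal(round(precision(cc), 4), 0.9083)
  expect_equal(recall(cc), 0.8720)
  expect_equal(accuracy(cc), 0.8920)

  cc <- confusion_counts(1, 0, 0, 0)
  expect_equal(precision(cc), 1)
  expect_equal(recall(cc), 1)
  expect_equal(accuracy(cc), 1)
  expect_equal(f1_score(cc), 1)
})

test_that("zero denominators are errors, not silent zeros", {
  expect_error(precision(confusion_counts(0, 5, 0, 2)), "zero denominator")
  expect_error(recall(confusion_counts(0, 5, 3, 0)), "zero denominator")
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "zero denominator")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("metric identities hold", {
  set.seed(5)
  for (i in 1:25) {
    v <- sample(0:200, 4, replace = TRUE) + c(1, 1, 0, 0)
    cc <- confusion_counts(v[1], v[2], v[3], v[4])
    n <- v[1] + v[2] + v[3] + v[4]
    expect_equal(accuracy(cc) * n, v[1] + v[2])
    p <- precision(cc); r <- recall(cc)
    expect_equal(f1_score(cc), 2 / (1 / p + 1 / r))
  }
})

make_dets <- function(boxes, scores) {
  if (length(boxes) == 0L)
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      score = numeric(0)))
  data.frame(x_min = sapply(boxes, `[`, 1), y_min = sapply(boxes, `[`, 2),
             x_max = sapply(boxes, `[`, 3), y_max = sapply(boxes, `[`, 4),
             score = scores)
}

truth_df <- function(boxes, fluor) {
  data.frame(x_min = sapply(boxes, `[`, 1), y_min = sapply(boxes, `[`, 2),
             x_max = sapply(boxes, `[`, 3), y_max = sapply(boxes, `[`, 4),
             fluorescent = fluor)
}

grid_boxes <- function(n) lapply(seq_len(n), function(i)
  bbox(20 * i, 10, 20 * i + 10, 20))

test_that("match_detections implements the greedy per-kernel contract", {
  tb <- grid_boxes(4)
  truths <- truth_df(tb, c(TRUE, TRUE, TRUE, FALSE))
  # perfect detections on the fluorescent truths
  cc <- match_detections(make_dets(tb[1:3], c(0.9, 0.8, 0.7)), truths)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(3, 1, 0, 0))
  # no detections: all fluorescent truths are misses, non-fluor is a TN
  cc <- match_detections(make_dets(list(), numeric(0)), truths)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(0, 1, 0, 3))
  # two detections on one truth: greedy gives 1 TP + 1 FP
  cc <- match_detections(make_dets(tb[c(1, 1)], c(0.9, 0.8)),
                         truth_df(tb[1], TRUE))
  expect_equal(c(cc$tp, cc$fp), c(1, 1))
  # a detection sitting on a non-fluorescent truth is a false alarm
  cc <- match_detections(make_dets(tb[4], 0.9), truths)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(0, 0, 1, 3))
})

test_that("match_detections is truth-permutation invariant and tie-stable", {
  tb <- grid_boxes(5)
  truths <- truth_df(tb, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  dets <- make_dets(tb[c(2, 4, 1)], c(0.5, 0.5, 0.5))  # tied scores
  cc1 <- match_detections(dets, truths)
  set.seed(3)
  for (i in 1:5) {
    perm <- sample(nrow(truths))
    cc2 <- match_detections(dets, truths[perm, ])
    expect_equal(c(cc2$tp, cc2$tn, cc2$fp, cc2$fn),
                 c(cc1$tp, cc1$tn, cc1$fp, cc1$fn))
  }
  # ties broken by input order: both tied dets overlap truth 1 equally
  off <- bbox(2, 10, 12, 20)
  t1 <- truth_df(list(bbox(0, 10, 10, 20)), TRUE)
  d <- make_dets(list(off, off), c(0.5, 0.5))
  cc <- match_detections(d, t1, iou_thresh = 0.5)
  expect_equal(attr(cc, "matches"), c(1L, NA_integer_))
})

test_that("pr curve and AP reproduce the hand-enumerated cases", {
  tb <- grid_boxes(3)
  truths <- truth_df(tb, rep(TRUE, 3))
  # perfect detector: all truths found before any FP
  dets <- make_dets(c(tb, tb[1]), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(average_precision(pr_curve(dets, truths)), 1)
  # 1 truth, FP at 0.9 then TP at 0.8: envelope precision at recall 1 is 1/2
  t1 <- truth_df(tb[1], TRUE)
  dets <- make_dets(list(bbox(100, 100, 110, 110), tb[[1]]), c(0.9, 0.8))
  expect_equal(average_precision(pr_curve(dets, t1)), 0.5)
  # detector emitting only FPs
  dets <- make_dets(list(bbox(100, 100, 110, 110)), 0.9)
  expect_equal(average_precision(pr_curve(dets, t1)), 0)
  expect_error(pr_curve(dets, truth_df(tb[1], FALSE)), "no fluorescent")
  # recall is non-decreasing along the sweep
  set.seed(9)
  dets <- make_dets(c(tb, tb), runif(6))
  cv <- pr_curve(dets, truths)
  expect_true(all(diff(cv$recall) >= 0))
})

test_that("AP equals the brute-force threshold-enumeration oracle", {
  set.seed(21)
  tb <- grid_boxes(8)
  for (case in 1:30) {
    n_truth <- sample(1:4, 1)
    truths <- truth_df(tb[seq_len(n_truth)], rep(TRUE, n_truth))
    n_det <- sample(1:8, 1)
    which_box <- sample(seq_len(8), n_det, replace = TRUE)
    dets <- make_dets(tb[which_box], round(runif(n_det), 2))
    cv <- pr_curve(dets, truths)
    # recover per-detection TP flags independently: greedy in score order
    ord <- order(-dets$score, seq_len(n_det))
    taken <- rep(FALSE, n_truth)
    is_tp <- logical(n_det)
    for (r in seq_along(ord)) {
      j <- which_box[ord[r]]
      if (j <= n_truth && !taken[j]) { taken[j] <- TRUE; is_tp[r] <- TRUE }
    }
    expect_equal(average_precision(cv),
                 brute_force_ap(dets$score[ord], is_tp, n_truth),
                 tolerance = 1e-12)
  }
})
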