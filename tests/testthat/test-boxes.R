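# Box geometry (IoU/CIoU) and detection metrics (P/R, AP, mAP).

test_that("ciou matches hand-evaluated cases", {
  # identical boxes: perfect-match limit
  id <- ciou(c(0, 0, 2, 2), c(0, 0, 2, 2))
  expect_identical(id$iou, 1)
  expect_identical(id$v, 0)
  expect_identical(id$alpha, 0)
  expect_identical(id$ciou, 1)
  expect_identical(id$l_ciou, 0)

  # offset unit-overlap squares: iou 1/7, rho2 2, c2 18, v 0
  b <- ciou(c(0, 0, 2, 2), c(1, 1, 3, 3))
  expect_equal(b$iou, 1 / 7, tolerance = 1e-12)
  expect_equal(b$rho2, 2, tolerance = 1e-12)
  expect_equal(b$c2, 18, tolerance = 1e-12)
  expect_identical(b$v, 0)
  expect_equal(b$ciou, 1 / 7 - 1 / 9, tolerance = 1e-12)
  expect_equal(b$l_ciou, 1 - 1 / 7 + 1 / 9, tolerance = 1e-12)

  # gt aspect 2:1 vs pred 1:1, independent of placement
  v_expect <- 4 / pi^2 * (atan(2) - atan(1))^2
  for (shift in list(c(0, 0), c(10, -5))) {
    g <- c(0, 0, 4, 2) + rep(shift, 2)
    p <- c(1, 1, 3, 3)
    expect_equal(ciou(p, g)$v, v_expect, tolerance = 1e-12)
  }
  expect_error(ciou(c(0, 0, 0, 2), c(0, 0, 1, 1)),
               class = "perclos_input_error")
})

test_that("ciou terms respect swap symmetry and stay within bounds", {
  # iou, rho2 and c2 are symmetric by construction; v distinguishes the
  # gt and pred roles in the formula, but the arctan difference is squared,
  # so the numeric value is also swap-symmetric -- asserted here so the
  # implementation keeps the argument roles straight without breaking it
  set.seed(13)
  for (k in 1:30) {
    a <- sort(stats::runif(2, 0, 10)); b <- sort(stats::runif(2, 0, 10))
    c_ <- sort(stats::runif(2, 0, 10)); d <- sort(stats::runif(2, 0, 10))
    p <- c(a[1], b[1], a[2], b[2]); g <- c(c_[1], d[1], c_[2], d[2])
    x <- ciou(p, g); y <- ciou(g, p)
    expect_equal(x$iou, y$iou, tolerance = 1e-12)
    expect_equal(x$rho2, y$rho2, tolerance = 1e-12)
    expect_equal(x$c2, y$c2, tolerance = 1e-12)
    expect_equal(x$v, y$v, tolerance = 1e-12)
    # bounds on valid boxes
    expect_true(x$iou >= 0 && x$iou <= 1)
    expect_true(x$v >= 0)
    expect_true(x$ciou > -1 && x$ciou <= 1)
    expect_true(x$l_ciou >= 0 && x$l_ciou < 3)
  }
})

test_that("l_ciou shrinks to 0 as pred approaches gt along a homotopy", {
  g <- c(2, 3, 7, 11)
  p0 <- c(0, 0, 4, 5)
  prev <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    p <- (1 - t) * p0 + t * g
    l <- ciou(p, g)$l_ciou
    expect_true(l <= prev + 1e-12)
    prev <- l
  }
  expect_equal(prev, 0, tolerance = 1e-12)
})

test_that("greedy matching follows confidence order and the IoU threshold", {
  gts <- data.frame(x_min = c(0, 10), y_min = c(0, 10),
                    x_max = c(2, 12), y_max = c(2, 12))
  # duplicate-perfect detections: all TP
  dets <- data.frame(x_min = c(0, 10), y_min = c(0, 10),
                     x_max = c(2, 12), y_max = c(2, 12),
                     confidence = c(0.9, 0.8))
  m <- match_detections(dets, gts)
  expect_true(all(m$tp))
  expect_identical(m$n_fn, 0L)

  # 3 detections: hits gt1, hits nothing, hits gt2 -> TP, FP, TP
  dets3 <- data.frame(x_min = c(0, 100, 10), y_min = c(0, 100, 10),
                      x_max = c(2, 102, 12), y_max = c(2, 102, 12),
                      confidence = c(0.9, 0.8, 0.7))
  m3 <- match_detections(dets3, gts)
  expect_identical(m3$tp, c(TRUE, FALSE, TRUE))

  # IoU exactly 0.4 (inter 4 / union 10) < threshold 0.5 -> FP and FN
  one_gt <- data.frame(x_min = 0, y_min = 0, x_max = 4, y_max = 1)
  det_low <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 1,
                        confidence = 0.9)
  m4 <- match_detections(det_low, one_gt, iou_threshold = 0.5)
  expect_false(any(m4$tp))
  expect_identical(m4$n_fn, 1L)

  # a gt can be claimed once: the higher-confidence duplicate wins
  dup <- data.frame(x_min = c(0, 0), y_min = c(0, 0), x_max = c(2, 2),
                    y_max = c(2, 2), confidence = c(0.6, 0.9))
  md <- match_detections(dup, gts[1, ])
  expect_identical(md$tp, c(FALSE, TRUE))
})

test_that("precision and recall follow the counting formulas", {
  pr <- precision_recall(28690, 0, 180)
  expect_equal(pr[["recall"]], 28690 / 28870, tolerance = 1e-12)
  expect_equal(round(pr[["recall"]], 4), 0.9938)
  expect_identical(unname(precision_recall(10, 0, 0)),
                   c(1, 1))
  expect_warning(p0 <- precision_recall(0, 5, 0))
  expect_identical(p0[["precision"]], 0)
  expect_error(precision_recall(-1, 0, 0), class = "perclos_input_error")
})

test_that("AP integrates the interpolated precision envelope", {
  # hand case: points (0.5, 1), (0.5, 0.5), (1, 2/3)
  cv <- data.frame(recall = c(0.5, 0.5, 1), precision = c(1, 0.5, 2 / 3))
  expect_equal(average_precision(cv), 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-12)
  # perfect detector
  gts <- data.frame(x_min = c(0, 10), y_min = c(0, 10),
                    x_max = c(2, 12), y_max = c(2, 12))
  dets <- data.frame(x_min = c(0, 10), y_min = c(0, 10),
                     x_max = c(2, 12), y_max = c(2, 12),
                     confidence = c(0.9, 0.8))
  expect_identical(average_precision(pr_curve(dets, gts)), 1)
  expect_warning(e0 <- average_precision(data.frame(recall = numeric(),
                                                    precision = numeric())))
  expect_identical(e0, 0)
})

test_that("AP equals a grid-integrated envelope oracle for small sweeps", {
  # oracle: numerically integrate max{precision at recall >= r} on a fine grid
  oracle_ap <- function(curve) {
    grid <- seq(1e-6, 1, length.out = 20000)
    penv <- vapply(grid, function(r) {
      sel <- curve$recall >= r - 1e-12
      if (any(sel)) max(curve$precision[sel]) else 0
    }, numeric(1))
    mean(penv)  # equal-weight grid over (0, 1]
  }
  set.seed(21)
  gts <- data.frame(x_min = c(0, 10, 20), y_min = 0,
                    x_max = c(2, 12, 22), y_max = 2)
  for (k in 1:10) {
    nd <- sample(1:5, 1)
    hit <- sample(c(TRUE, FALSE), nd, replace = TRUE)
    gtpick <- sample(1:3, nd, replace = TRUE)
    dets <- data.frame(
      x_min = ifelse(hit, gts$x_min[gtpick], 100 + 10 * seq_len(nd)),
      y_min = 0,
      x_max = ifelse(hit, gts$x_max[gtpick], 102 + 10 * seq_len(nd)),
      y_max = 2,
      confidence = round(stats::runif(nd), 3))
    cv <- pr_curve(dets, gts)
    expect_equal(average_precision(cv), oracle_ap(cv), tolerance = 2e-4)
  }
})

test_that("mAP averages per-class APs, skipping classes without ground truth", {
  expect_identical(mean_average_precision(c(1, 1, 1, 1, 0)), 0.8)
  gts <- data.frame(class = c("face", "o_eyes"),
                    x_min = c(0, 10), y_min = 0, x_max = c(5, 15), y_max = 5)
  dets <- data.frame(class = c("face", "o_eyes", "ghost"),
                     x_min = c(0, 10, 50), y_min = 0,
                     x_max = c(5, 15, 55), y_max = 5,
                     confidence = c(0.9, 0.9, 0.9))
  expect_warning(res <- evaluate_detections(dets, gts), "ghost")
  expect_identical(res$map, 1)
  expect_true(is.na(res$per_class$ap[res$per_class$class == "ghost"]))
  # a gt class with no detections contributes AP 0
  gts2 <- rbind(gts, data.frame(class = "c_eyes", x_min = 30, y_min = 0,
                                x_max = 35, y_max = 5))
  expect_warning(res2 <- evaluate_detections(dets, gts2))
  expect_equal(res2$map, (1 + 1 + 0) / 3)
})
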