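# Bounding-box geometry (IoU / CIoU) and detection evaluation (precision,
# recall, AP, mAP) with greedy confidence-ordered matching. Boxes are
# min/max corner pairs in pixel-like units, origin top-left.

#' Axis-aligned bounding box
#'
#' @param x_min,y_min,x_max,y_max corners; `x_max > x_min`, `y_max > y_min`.
#' @return Named numeric vector of class `"bbox"`.
#' @export
box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (any(!is.finite(b)) || b["x_max"] <= b["x_min"] ||
      b["y_max"] <= b["y_min"])
    stop_input("degenerate box: need finite corners with max > min")
  structure(b, class = "bbox")
}

as_box <- function(b) {
  if (inherits(b, "bbox")) return(b)
  if (is.numeric(b) && length(b) == 4L) return(box(b[1L], b[2L], b[3L], b[4L]))
  if (is.list(b) || is.data.frame(b))
    return(box(b$x_min, b$y_min, b$x_max, b$y_max))
  stop_input("cannot interpret box")
}

iou_pair <- function(a, b) {
  iw <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  ih <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  inter <- max(0, iw) * max(0, ih)
  area <- function(z) (z["x_max"] - z["x_min"]) * (z["y_max"] - z["y_min"])
  unname(inter / (area(a) + area(b) - inter))
}

#' Complete IoU between a predicted and a ground-truth box
#'
#' Breaks the complete-IoU score into its terms:
#' \deqn{CIoU = IoU - \rho^2/c^2 - \alpha v, \quad
#'       L_{CIoU} = 1 - IoU + \rho^2/c^2 + \alpha v}
#' where \eqn{\rho^2} is the squared distance between box centres, \eqn{c^2}
#' the squared diagonal of the minimal enclosing rectangle,
#' \eqn{v = \frac{4}{\pi^2}\left(\arctan\frac{\omega^{gt}}{h^{gt}} -
#' \arctan\frac{\omega}{h}\right)^2} the aspect-ratio similarity, and
#' \eqn{\alpha = v / (1 - IoU + v)} its weight. \eqn{\alpha} is taken as 0
#' when \eqn{v = 0} (the 0/0 limit at perfect overlap, continuous and
#' standard practice). `v`, and therefore CIoU, is not symmetric in its
#' arguments: the first box is the prediction, the second the ground truth.
#'
#' @param pred,gt boxes ([box()], length-4 numeric `c(x_min, y_min, x_max,
#'   y_max)`, or a list/data frame row with those fields).
#' @return List of class `"ciou_breakdown"` with elements `iou`, `rho2`,
#'   `c2`, `v`, `alpha`, `ciou`, `l_ciou`.
#' @examples
#' ciou(c(0, 0, 2, 2), c(1, 1, 3, 3))$l_ciou  # 1 - 1/7 + 1/9
#' @export
ciou <- function(pred, gt) {
  p <- as_box(pred); g <- as_box(gt)
  iou <- iou_pair(p, g)
  cpx <- (p["x_min"] + p["x_max"]) / 2; cpy <- (p["y_min"] + p["y_max"]) / 2
  cgx <- (g["x_min"] + g["x_max"]) / 2; cgy <- (g["y_min"] + g["y_max"]) / 2
  rho2 <- unname((cpx - cgx)^2 + (cpy - cgy)^2)
  ex <- max(p["x_max"], g["x_max"]) - min(p["x_min"], g["x_min"])
  ey <- max(p["y_max"], g["y_max"]) - min(p["y_min"], g["y_min"])
  c2 <- unname(ex^2 + ey^2)
  wp <- unname(p["x_max"] - p["x_min"]); hp <- unname(p["y_max"] - p["y_min"])
  wg <- unname(g["x_max"] - g["x_min"]); hg <- unname(g["y_max"] - g["y_min"])
  v <- 4 / pi^2 * (atan(wg / hg) - atan(wp / hp))^2
  alpha <- if (v == 0) 0 else v / (1 - iou + v)
  structure(list(iou = iou, rho2 = rho2, c2 = c2, v = v, alpha = alpha,
                 ciou = iou - rho2 / c2 - alpha * v,
                 l_ciou = 1 - iou + rho2 / c2 + alpha * v),
            class = "ciou_breakdown")
}

#' @export
print.ciou_breakdown <- function(x, ...) {
  cat(sprintf(
    "CIoU breakdown: IoU %.4f  rho2 %.4g  c2 %.4g  v %.4g  alpha %.4g\n  CIoU %.4f  L_CIoU %.4f\n",
    x$iou, x$rho2, x$c2, x$v, x$alpha, x$ciou, x$l_ciou))
  invisible(x)
}

box_cols <- c("x_min", "y_min", "x_max", "y_max")

#' Greedy matching of detections to ground truth
#'
#' Detections are processed in descending confidence (ties keep input
#' order); each claims the highest-IoU still-unmatched ground-truth box with
#' IoU at or above the threshold. Every ground truth is matched at most
#' once; unmatched ground truths are false negatives. Call per class (or on
#' pre-partitioned inputs).
#'
#' @param detections data frame with columns `x_min`, `y_min`, `x_max`,
#'   `y_max`, `confidence`.
#' @param gts data frame of ground-truth boxes (same corner columns).
#' @param iou_threshold minimum IoU for a match, default 0.5.
#' @return List with `tp` (logical per detection, input order), `gt_matched`
#'   (logical per ground truth), and counts `n_tp`, `n_fp`, `n_fn`.
#' @export
match_detections <- function(detections, gts, iou_threshold = 0.5) {
  nd <- nrow(detections); ng <- if (is.null(gts)) 0L else nrow(gts)
  tp <- logical(nd); gt_used <- logical(ng)
  ord <- order(-detections$confidence)  # stable: ties keep input order
  for (i in ord) {
    if (ng == 0L) break
    d <- box(detections$x_min[i], detections$y_min[i],
             detections$x_max[i], detections$y_max[i])
    best <- -1; best_j <- 0L
    for (j in seq_len(ng)) {
      if (gt_used[j]) next
      g <- box(gts$x_min[j], gts$y_min[j], gts$x_max[j], gts$y_max[j])
      ov <- iou_pair(d, g)
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      tp[i] <- TRUE; gt_used[best_j] <- TRUE
    }
  }
  list(tp = tp, gt_matched = gt_used,
       n_tp = sum(tp), n_fp = nd - sum(tp), n_fn = ng - sum(gt_used))
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. A zero denominator yields 0
#' with a warning (convention for empty detection or ground-truth sets).
#'
#' @param tp,fp,fn non-negative counts.
#' @return Named numeric `c(precision, recall)`.
#' @examples
#' precision_recall(28690, 0, 180)[["recall"]]  # ~0.9938
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop_input("counts must be non-negative")
  p <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no detections: precision defined as 0"); 0
  }
  r <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no ground truths: recall defined as 0"); 0
  }
  c(precision = p, recall = r)
}

#' Precision-recall curve over a confidence sweep
#'
#' Greedy-matches the detections once (confidence order), then accumulates
#' TP/FP down the ranking: point k of the curve is the precision/recall of
#' keeping the k highest-confidence detections. Recall is non-decreasing
#' along the sweep.
#'
#' @inheritParams match_detections
#' @return Data frame of class `"pr_curve"` with columns `confidence`,
#'   `tp`, `fp`, `fn`, `recall`, `precision`; attribute `n_gt`.
#' @export
pr_curve <- function(detections, gts, iou_threshold = 0.5) {
  ng <- if (is.null(gts)) 0L else nrow(gts)
  m <- match_detections(detections, gts, iou_threshold)
  ord <- order(-detections$confidence)
  tp_cum <- cumsum(m$tp[ord])
  fp_cum <- cumsum(!m$tp[ord])
  out <- data.frame(confidence = detections$confidence[ord],
                    tp = tp_cum, fp = fp_cum, fn = ng - tp_cum,
                    recall = if (ng > 0) tp_cum / ng else 0,
                    precision = tp_cum / (tp_cum + fp_cum))
  structure(out, class = c("pr_curve", "data.frame"), n_gt = ng)
}

#' Average precision of one class
#'
#' All-point interpolated area under the precision-recall curve: at each
#' recall level the precision envelope (the maximum precision attained at
#' that recall or higher) is integrated over recall, the step-function form
#' of \eqn{AP = \int_0^1 P(R)\,dR}.
#'
#' @param curve a [pr_curve()], or any data frame with `recall` and
#'   `precision` columns.
#' @return AP in \[0, 1\]; an empty curve gives 0 with a warning.
#' @export
average_precision <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0L) {
    warning("empty precision-recall curve: AP defined as 0")
    return(0)
  }
  ord <- order(curve$recall)
  r <- curve$recall[ord]; p <- curve$precision[ord]
  penv <- rev(cummax(rev(p)))  # max precision at this recall or higher
  keep <- !duplicated(r)  # envelope is non-increasing: first point per recall
  r <- r[keep]; penv <- penv[keep]
  sum(diff(c(0, r)) * penv)
}

#' Mean average precision over classes
#'
#' Arithmetic mean of per-class APs. Use [evaluate_detections()] to go from
#' raw detection/ground-truth tables to per-class APs and mAP in one call.
#'
#' @param aps numeric vector of per-class AP values.
#' @return mAP.
#' @export
mean_average_precision <- function(aps) {
  if (length(aps) == 0L) stop_input("no per-class APs supplied")
  mean(aps)
}

#' Per-class AP and mAP from detection and ground-truth tables
#'
#' Partitions by class, sweeps each class's detections by confidence, and
#' averages the per-class APs. Classes present in the ground truth but with
#' no detections score AP 0; classes with detections but no ground truth are
#' excluded from the mean with a warning.
#'
#' @param detections data frame with columns `class`, corner columns and
#'   `confidence`.
#' @param gts data frame with columns `class` and corner columns.
#' @param iou_threshold minimum IoU for a match.
#' @return List with `per_class` (data frame `class`, `n_gt`, `n_det`, `ap`)
#'   and `map`.
#' @export
evaluate_detections <- function(detections, gts, iou_threshold = 0.5) {
  classes <- sort(unique(c(as.character(detections$class),
                           as.character(gts$class))))
  rows <- lapply(classes, function(cl) {
    d <- detections[detections$class == cl, , drop = FALSE]
    g <- gts[gts$class == cl, , drop = FALSE]
    ap <- if (nrow(g) == 0L) NA_real_
    else if (nrow(d) == 0L) 0
    else average_precision(pr_curve(d, g, iou_threshold))
    data.frame(class = cl, n_gt = nrow(g), n_det = nrow(d), ap = ap)
  })
  per_class <- do.call(rbind, rows)
  if (anyNA(per_class$ap))
    warning(sprintf("class(es) with no ground truth excluded from mAP: %s",
                    paste(per_class$class[is.na(per_class$ap)],
                          collapse = ", ")))
  list(per_class = per_class,
       map = mean_average_precision(per_class$ap[!is.na(per_class$ap)]))
}
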