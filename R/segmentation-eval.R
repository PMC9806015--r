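#' Match predicted nuclei to ground truth by intersection-over-union
#'
#' Computes the pairwise IoU between every ground-truth and predicted
#' nucleus, then forms a one-to-one matching greedily in descending IoU
#' (ties broken by the smaller ground-truth label). Pairs are kept only when
#' IoU strictly exceeds `iou_threshold` (default 0.6). Matched pairs are true
#' positives; unmatched ground-truth nuclei are false negatives and unmatched
#' predictions false positives.
#'
#' @param gt_labels,pred_labels Integer label matrices of equal dimensions
#'   (0 = background).
#' @param iou_threshold Matching threshold (strict `>`; default 0.6).
#' @return An object of class `match_result`: list with `matches` (data.frame
#'   `gt`, `pred`, `iou`), `tp`, `fp`, `fn`, `detection_coverage`,
#'   `precision`, `recall`, `f1` and `pixel_accuracy`.
#' @export
match_nuclei <- function(gt_labels, pred_labels, iou_threshold = 0.6) {
  if (!identical(dim(gt_labels), dim(pred_labels))) {
    stop("label masks must share dimensions")
  }
  iou <- iou_pairs(gt_labels, pred_labels)
  n_gt <- length(unique(gt_labels[gt_labels > 0]))
  n_pred <- length(unique(pred_labels[pred_labels > 0]))
  # greedy: descending IoU, ties by smaller GT label then smaller pred label
  iou <- iou[order(-iou$iou, iou$gt, iou$pred), , drop = FALSE]
  used_gt <- integer(0); used_pred <- integer(0)
  keep <- logical(nrow(iou))
  for (k in seq_len(nrow(iou))) {
    if (iou$iou[k] <= iou_threshold) break
    if (iou$gt[k] %in% used_gt || iou$pred[k] %in% used_pred) next
    keep[k] <- TRUE
    used_gt <- c(used_gt, iou$gt[k])
    used_pred <- c(used_pred, iou$pred[k])
  }
  matches <- iou[keep, , drop = FALSE]
  rownames(matches) <- NULL
  tp <- nrow(matches)
  fp <- n_pred - tp
  fn <- n_gt - tp
  prf <- f1_score(tp, fp, fn, quiet = TRUE)
  structure(
    list(matches = matches, tp = tp, fp = fp, fn = fn,
         detection_coverage = if (n_gt > 0) tp / n_gt else NA_real_,
         precision = prf$precision, recall = prf$recall, f1 = prf$f1,
         pixel_accuracy = pixel_accuracy(gt_labels > 0, pred_labels > 0)),
    class = "match_result"
  )
}

# All (gt, pred, iou) pairs with positive intersection, via a joint
# contingency tabulation of the two label images.
iou_pairs <- function(gt_labels, pred_labels) {
  ov <- which(gt_labels > 0 & pred_labels > 0)
  gt_sizes <- table(gt_labels[gt_labels > 0])
  pred_sizes <- table(pred_labels[pred_labels > 0])
  if (length(ov) == 0L) {
    return(data.frame(gt = integer(0), pred = integer(0), iou = numeric(0)))
  }
  inter <- table(gt = gt_labels[ov], pred = pred_labels[ov])
  idx <- which(inter > 0, arr.ind = TRUE)
  gt <- as.integer(rownames(inter))[idx[, 1L]]
  pred <- as.integer(colnames(inter))[idx[, 2L]]
  i <- as.numeric(inter[idx])
  u <- as.numeric(gt_sizes[as.character(gt)]) +
    as.numeric(pred_sizes[as.character(pred)]) - i
  data.frame(gt = gt, pred = pred, iou = i / u)
}

#' Precision, recall and F1 from detection counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)` (the harmonic mean).
#' When a denominator is zero the corresponding metric is defined as 0, with
#' a warning for the all-zero case.
#'
#' @param tp,fp,fn Non-negative counts.
#' @param quiet Suppress the all-zero warning.
#' @return List with `precision`, `recall`, `f1`.
#' @examples
#' f1_score(8, 2, 2)  # all 0.8
#' @export
f1_score <- function(tp, fp, fn, quiet = FALSE) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fp + fn == 0) {
    if (!quiet) warning("all counts zero; metrics defined as 0")
    return(list(precision = 0, recall = 0, f1 = 0))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Pixel accuracy of a binary segmentation
#'
#' Fraction of pixels whose foreground/background classification agrees
#' between the two masks (labels above zero count as foreground).
#'
#' @param gt,pred Matrices of equal dimensions (logical or label).
#' @return A fraction in [0, 1].
#' @export
pixel_accuracy <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred))) stop("masks must share dimensions")
  mean((gt > 0) == (pred > 0))
}

#' Detection coverage
#'
#' The ratio between matched (identified) nuclei and the total ground-truth
#' nuclei.
#'
#' @param n_matched,n_gt Counts; `n_gt` must be positive.
#' @return A fraction.
#' @export
detection_coverage <- function(n_matched, n_gt) {
  if (n_gt <= 0) {
    warning("no ground-truth nuclei; coverage undefined")
    return(NA_real_)
  }
  n_matched / n_gt
}
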