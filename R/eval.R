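# Detection metrics: IoU, greedy confidence-ordered matching, per-class AP
# with COCO-style 101-point interpolation, mAP50 / mAP50-95, and a confusion
# matrix with a background row/column.
#
# Boxes cross this module as normalized corner coordinates (x1, y1, x2, y2).
# Detections and ground truths are data.frames with columns
#   class_id, x1, y1, x2, y2 [, confidence] [, image]
# where `image` identifies the image a row belongs to (any atomic type).

#' Intersection over union of two corner-format boxes
#' @param a,b numeric (x1, y1, x2, y2)
#' @return IoU in `[0,1]`
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[[3]], b[[3]]) - max(a[[1]], b[[1]]))
  iy <- max(0, min(a[[4]], b[[4]]) - max(a[[2]], b[[2]]))
  inter <- ix * iy
  ua <- (a[[3]] - a[[1]]) * (a[[4]] - a[[2]]) +
    (b[[3]] - b[[1]]) * (b[[4]] - b[[2]]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

# vectorized IoU of one box against a matrix of boxes (rows)
.iou_vec <- function(a, B) {
  if (!nrow(B)) return(numeric(0))
  ix <- pmax(0, pmin(a[3], B[, 3]) - pmax(a[1], B[, 1]))
  iy <- pmax(0, pmin(a[4], B[, 4]) - pmax(a[2], B[, 2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) +
    (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
  ifelse(ua <= 0, 0, inter / ua)
}

#' Convert center-format annotations to corner-format ground truths
#' @param anns annotations data.frame (class_id, cx, cy, w, h)
#' @param image image identifier attached to every row
#' @return corner-format data.frame
#' @export
anns_to_gt <- function(anns, image = 1L) {
  if (!nrow(anns)) {
    return(data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), image = rep(image, 0)))
  }
  data.frame(class_id = anns$class_id,
             x1 = anns$cx - anns$w / 2, y1 = anns$cy - anns$h / 2,
             x2 = anns$cx + anns$w / 2, y2 = anns$cy + anns$h / 2,
             image = image)
}

#' Greedy one-to-one matching of detections to ground truths
#'
#' Detections are processed in order of descending confidence, per class and
#' per image; each detection claims the unmatched ground truth with the
#' highest IoU at or above the threshold.
#'
#' @param preds detections data.frame (class_id, x1..y2, confidence, image)
#' @param gts ground-truth data.frame (class_id, x1..y2, image)
#' @param iou_thresh matching threshold
#' @return list: `tp` logical per prediction (confidence-sorted order),
#'   `confidence` sorted confidences, `pred_gt` matched gt row index (NA for
#'   FP), `fn` number of unmatched ground truths
#' @export
match_detections <- function(preds, gts, iou_thresh = 0.5) {
  if (!nrow(preds)) {
    return(list(tp = logical(0), confidence = numeric(0),
                pred_gt = integer(0), fn = nrow(gts)))
  }
  ord <- order(-preds$confidence)
  preds <- preds[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(preds))
  pred_gt <- rep(NA_integer_, nrow(preds))
  gmat <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  for (i in seq_len(nrow(preds))) {
    cand <- which(!taken & gts$class_id == preds$class_id[i] &
                    gts$image == preds$image[i])
    if (!length(cand)) next
    ious <- .iou_vec(as.numeric(preds[i, c("x1", "y1", "x2", "y2")]),
                     gmat[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      tp[i] <- TRUE
      taken[cand[j]] <- TRUE
      pred_gt[i] <- cand[j]
    }
  }
  list(tp = tp, confidence = preds$confidence, pred_gt = pred_gt,
       fn = sum(!taken))
}

# 101-point interpolated AP from confidence-sorted TP flags
.ap_101 <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope, then mean over 101 recall sample points
  rp <- seq(0, 1, by = 0.01)
  env <- rev(cummax(rev(precision)))
  p <- vapply(rp, function(r) {
    i <- which(recall >= r)[1]
    if (is.na(i)) 0 else env[i]
  }, numeric(1))
  mean(p)
}

#' Evaluate detections: per-class AP, mAP50, mAP50-95, precision, recall
#'
#' AP uses 101-point interpolated precision-recall integration per class and
#' IoU threshold; mAP50-95 averages the 10 thresholds 0.5, 0.55, ..., 0.95.
#' Precision and recall are reported at IoU 0.5 over all detections.
#' Classes absent from the ground truth are excluded with a warning.
#'
#' @param preds detections data.frame (class_id, x1..y2, confidence, image)
#' @param gts ground truths (class_id, x1..y2, image)
#' @param num_classes number of classes (default: inferred)
#' @return an `eval_result` list
#' @export
compute_map <- function(preds, gts, num_classes = NULL) {
  K <- num_classes %||% (max(c(preds$class_id, gts$class_id, 0L)) + 1L)
  ths <- seq(0.5, 0.95, by = 0.05)
  ap <- matrix(NA_real_, nrow = K, ncol = length(ths))
  for (k in seq_len(K) - 1L) {
    gk <- gts[gts$class_id == k, , drop = FALSE]
    pk <- preds[preds$class_id == k, , drop = FALSE]
    if (!nrow(gk)) {
      if (nrow(pk)) warning(sprintf("compute_map: class %d absent from ground truth, excluded", k))
      next
    }
    for (t in seq_along(ths)) {
      mm <- match_detections(pk, gk, ths[t])
      ap[k + 1L, t] <- .ap_101(mm$tp, nrow(gk))
    }
  }
  m50 <- mean(ap[, 1], na.rm = TRUE)
  m5095 <- mean(ap, na.rm = TRUE)
  mm <- match_detections(preds, gts, 0.5)
  ntp <- sum(mm$tp)
  precision <- if (length(mm$tp)) ntp / length(mm$tp) else 0
  recall <- if (nrow(gts)) ntp / nrow(gts) else 0
  structure(list(ap50 = ap[, 1], ap_table = ap, map50 = m50,
                 map50_95 = m5095, precision = precision, recall = recall),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("mAP50 %.4f | mAP50-95 %.4f | P %.4f | R %.4f\n",
              x$map50, x$map50_95, x$precision, x$recall))
  cat("per-class AP50:", paste(sprintf("%.4f", x$ap50), collapse = " "), "\n")
  invisible(x)
}

#' Precision-recall curve for one class at one IoU threshold
#' @param preds,gts as in [compute_map()]
#' @param class_id class to trace
#' @param iou_thresh matching threshold
#' @return data.frame (confidence, precision, recall)
#' @export
pr_curve <- function(preds, gts, class_id, iou_thresh = 0.5) {
  gk <- gts[gts$class_id == class_id, , drop = FALSE]
  pk <- preds[preds$class_id == class_id, , drop = FALSE]
  mm <- match_detections(pk, gk, iou_thresh)
  if (!length(mm$tp)) {
    return(data.frame(confidence = numeric(0), precision = numeric(0),
                      recall = numeric(0)))
  }
  cum_tp <- cumsum(mm$tp)
  cum_fp <- cumsum(!mm$tp)
  data.frame(confidence = mm$confidence,
             precision = cum_tp / (cum_tp + cum_fp),
             recall = if (nrow(gk)) cum_tp / nrow(gk) else 0)
}

#' Detection confusion matrix with a background row and column
#'
#' Detections above `conf_thresh` are matched (any-class IoU) against
#' ground truths at `iou_thresh`; matched pairs increment cell
#' (gt class, predicted class), unmatched ground truths fall into the
#' background column and unmatched detections into the background row.
#'
#' @param preds,gts as in [compute_map()]
#' @param num_classes K
#' @param iou_thresh IoU for matching (default 0.45)
#' @param conf_thresh detection confidence floor (default 0.25)
#' @param normalize row-normalize counts
#' @return (K+1) x (K+1) matrix, labelled with class ids and "background"
#' @export
confusion_matrix <- function(preds, gts, num_classes,
                             iou_thresh = 0.45, conf_thresh = 0.25,
                             normalize = FALSE) {
  K <- num_classes
  M <- matrix(0, K + 1L, K + 1L,
              dimnames = list(c(paste0("gt", seq_len(K) - 1L), "background"),
                              c(paste0("pred", seq_len(K) - 1L), "background")))
  preds <- preds[preds$confidence >= conf_thresh, , drop = FALSE]
  if (nrow(preds)) preds <- preds[order(-preds$confidence), , drop = FALSE]
  taken <- rep(FALSE, nrow(gts))
  gmat <- as.matrix(gts[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  for (i in seq_len(nrow(preds))) {
    cand <- which(!taken & gts$image == preds$image[i])
    ious <- if (length(cand))
      .iou_vec(as.numeric(preds[i, c("x1", "y1", "x2", "y2")]),
               gmat[cand, , drop = FALSE]) else numeric(0)
    if (length(ious) && max(ious) >= iou_thresh) {
      j <- cand[which.max(ious)]
      taken[j] <- TRUE
      M[gts$class_id[j] + 1L, preds$class_id[i] + 1L] <-
        M[gts$class_id[j] + 1L, preds$class_id[i] + 1L] + 1
    } else {
      M[K + 1L, preds$class_id[i] + 1L] <- M[K + 1L, preds$class_id[i] + 1L] + 1
    }
  }
  for (j in which(!taken))
    M[gts$class_id[j] + 1L, K + 1L] <- M[gts$class_id[j] + 1L, K + 1L] + 1
  if (normalize) {
    rs <- rowSums(M)
    M <- sweep(M, 1, pmax(rs, 1), "/")
  }
  M
}
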