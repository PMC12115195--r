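# Box decoding and non-maximum suppression.
#
# Each head cell predicts (tx, ty, tw, th, obj, class logits...):
#   center = (cell + 2*sigmoid(tx,ty) - 0.5) * stride / input_size
#   size   = (2*sigmoid(tw,th))^3 * stride / input_size
# The offset range (-0.5, 1.5) lets neighbouring cells contribute to the
# same object and the bounded size transform spans (0, 8) strides without
# the blow-up risk of an exponential. Confidence is
# sigmoid(obj) * max_c sigmoid(class_c).

.sigm <- function(x) 1 / (1 + exp(-x))

# decode one head grid (H,W,5+nc) -> data.frame of candidates
decode_head <- function(grid, stride, input_size, num_classes,
                        conf_thresh = 0.25) {
  d <- dim(grid)
  gh <- d[1]; gw <- d[2]
  obj <- .sigm(grid[, , 5L])
  cls <- array(.sigm(grid[, , 5L + seq_len(num_classes)]),
               c(gh, gw, num_classes))
  best_c <- apply(cls, c(1, 2), which.max)
  best_p <- apply(cls, c(1, 2), max)
  conf <- obj * best_p
  keep <- which(conf >= conf_thresh, arr.ind = TRUE)
  if (!nrow(keep)) {
    return(data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), confidence = numeric(0)))
  }
  r <- keep[, 1]; cix <- keep[, 2]
  lin <- cbind(r, cix)
  tx <- grid[, , 1L][lin]; ty <- grid[, , 2L][lin]
  tw <- grid[, , 3L][lin]; th <- grid[, , 4L][lin]
  sn <- stride / input_size
  cx <- ((cix - 1) + 2 * .sigm(tx) - 0.5) * sn
  cy <- ((r - 1) + 2 * .sigm(ty) - 0.5) * sn
  bw <- (2 * .sigm(tw))^3 * sn
  bh <- (2 * .sigm(th))^3 * sn
  data.frame(class_id = best_c[lin] - 1L,
             x1 = pmax(0, cx - bw / 2), y1 = pmax(0, cy - bh / 2),
             x2 = pmin(1, cx + bw / 2), y2 = pmin(1, cy + bh / 2),
             confidence = conf[lin])
}

#' Greedy non-maximum suppression
#' @param boxes matrix/data.frame with x1, y1, x2, y2
#' @param scores confidences
#' @param iou_thresh suppression threshold
#' @return indices of surviving boxes, in descending score order
#' @export
nms <- function(boxes, scores, iou_thresh = 0.45) {
  b <- as.matrix(boxes[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  ord <- order(-scores)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    ious <- .iou_vec(b[i, ], b[rest, , drop = FALSE])
    ord <- rest[ious <= iou_thresh]
  }
  keep
}

#' Run the detector on one image
#'
#' @param model an `rd_model`
#' @param image H x W x 3 array in `[0,1]` (letterboxed square input)
#' @param conf_thresh confidence floor
#' @param iou_thresh class-wise NMS threshold
#' @param max_det maximum detections returned
#' @return detections data.frame (class_id, x1..y2 normalized, confidence),
#'   boxes clipped to the image
#' @export
rd_predict <- function(model, image, conf_thresh = 0.25, iou_thresh = 0.45,
                       max_det = 300L) {
  heads <- model_forward(model, image)
  nc <- model$spec$num_classes
  sz <- dim(image)[1]
  cands <- do.call(rbind, lapply(names(heads), function(nm) {
    stride <- as.integer(sub("stride", "", nm))
    decode_head(heads[[nm]], stride, sz, nc, conf_thresh)
  }))
  if (is.null(cands) || !nrow(cands)) {
    return(data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), confidence = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(cands, cands$class_id), function(ck) {
    ck[nms(ck, ck$confidence, iou_thresh), , drop = FALSE]
  }))
  out <- out[order(-out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_det)
}

#' Export detections as YOLO-format label text
#' @param dets detections data.frame
#' @param path output file
#' @export
write_detections_yolo <- function(dets, path) {
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f %.4f",
                     dets$class_id,
                     (dets$x1 + dets$x2) / 2, (dets$y1 + dets$y2) / 2,
                     dets$x2 - dets$x1, dets$y2 - dets$y1,
                     dets$confidence), path)
}

#' Export detections as COCO-style JSON
#' @param dets detections data.frame
#' @param path output file
#' @param image_id image identifier
#' @param size image side in pixels used to scale the normalized boxes
#' @export
write_detections_coco <- function(dets, path, image_id = 1L, size = 640L) {
  items <- lapply(seq_len(nrow(dets)), function(i) {
    list(image_id = image_id,
         category_id = dets$class_id[i],
         bbox = c(dets$x1[i], dets$y1[i],
                  dets$x2[i] - dets$x1[i], dets$y2[i] - dets$y1[i]) * size,
         score = dets$confidence[i])
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = 6)
}
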