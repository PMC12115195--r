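# Training: SGD with momentum, linear lr decay with warmup, and a composite
# detection loss on an anchor-free center-cell assignment:
#   - objectness: BCE over every grid cell of every head
#   - class: BCE over the one-hot class logits of assigned cells
#   - box: complete-IoU (CIoU) between decoded and ground-truth boxes
# Assignment is multi-scale: every head whose decode range covers a box
# (0.75 to 8 strides) trains on it, at the center cell plus the two nearest
# neighbour cells.

#' Training hyperparameters
#'
#' Defaults follow the reference protocol: SGD, lr0 0.01 with final fraction
#' lrf 0.01, momentum 0.937, weight decay 0.005, 3 warmup epochs at momentum
#' 0.8, batch size 32, 640 px inputs, 300 epochs.
#'
#' @param epochs,batch,imgsz,lr0,lrf,momentum,weight_decay,warmup_epochs,warmup_momentum
#'   training controls
#' @param box,obj,cls loss-term weights
#' @param clip_norm global gradient-norm clip (Inf disables)
#' @param seed RNG seed
#' @return an `rd_hyper` list
#' @export
rd_hyper <- function(epochs = 300L, batch = 32L, imgsz = 640L,
                     lr0 = 0.01, lrf = 0.01, momentum = 0.937,
                     weight_decay = 0.005, warmup_epochs = 3L,
                     warmup_momentum = 0.8, optimizer = c("sgd", "adam"),
                     box = 5, obj = 1, cls = 1, clip_norm = 10,
                     seed = 0L) {
  optimizer <- match.arg(optimizer)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 imgsz = as.integer(imgsz), lr0 = lr0, lrf = lrf,
                 momentum = momentum, weight_decay = weight_decay,
                 warmup_epochs = warmup_epochs,
                 warmup_momentum = warmup_momentum, optimizer = optimizer,
                 box = box, obj = obj, cls = cls, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "rd_hyper")
}

# binary cross-entropy on logits, mean reduction with optional weights
ag_bce_logits <- function(x, target, weight = NULL) {
  xv <- x$v
  w <- weight %||% array(1, dim(xv) %||% length(xv))
  sw <- sum(w)
  sp <- pmax(xv, 0) - target * xv + log1p(exp(-abs(xv)))
  ag_node(sum(w * sp) / sw, list(x), function(g) {
    list(g * w * (1 / (1 + exp(-xv)) - target) / sw)
  })
}

# complete-IoU between decoded prediction nodes and constant gt boxes
# (all arguments center-format, normalized); returns per-box CIoU node
ag_ciou <- function(pcx, pcy, pw, ph, g) {
  eps <- 1e-9
  px1 <- ag_sub(pcx, ag_scale(pw, 0.5)); px2 <- ag_add(pcx, ag_scale(pw, 0.5))
  py1 <- ag_sub(pcy, ag_scale(ph, 0.5)); py2 <- ag_add(pcy, ag_scale(ph, 0.5))
  gx1 <- g$cx - g$w / 2; gx2 <- g$cx + g$w / 2
  gy1 <- g$cy - g$h / 2; gy2 <- g$cy + g$h / 2
  iw <- ag_clamp_min(ag_sub(ag_pmin(px2, ag_const(gx2)), ag_pmax(px1, ag_const(gx1))), 0)
  ih <- ag_clamp_min(ag_sub(ag_pmin(py2, ag_const(gy2)), ag_pmax(py1, ag_const(gy1))), 0)
  inter <- ag_mul(iw, ih)
  union_ <- ag_add(ag_sub(ag_add(ag_mul(pw, ph), ag_const(g$w * g$h + eps)), inter),
                   ag_const(eps))
  iou <- ag_div(inter, union_)
  rho2 <- ag_add(ag_pow(ag_sub(pcx, ag_const(g$cx)), 2),
                 ag_pow(ag_sub(pcy, ag_const(g$cy)), 2))
  cw <- ag_sub(ag_pmax(px2, ag_const(gx2)), ag_pmin(px1, ag_const(gx1)))
  chh <- ag_sub(ag_pmax(py2, ag_const(gy2)), ag_pmin(py1, ag_const(gy1)))
  c2 <- ag_add(ag_add(ag_pow(cw, 2), ag_pow(chh, 2)), ag_const(eps))
  v <- ag_scale(ag_pow(ag_sub(ag_const(atan(g$w / g$h)),
                              ag_atan(ag_div(pw, ag_add(ph, ag_const(eps))))), 2),
                4 / pi^2)
  alpha <- ag_value(v) / (1 - ag_value(iou) + ag_value(v) + eps)  # detached
  ag_sub(ag_sub(iou, ag_div(rho2, c2)), ag_mul(v, ag_const(alpha)))
}

# assign ground truths to (head, cell); besides the center cell, the two
# neighbouring cells closest to the center get the same target (the decode
# offset range covers them), giving small training sets a denser signal
.build_targets <- function(anns_list, strides, grids, imgsz, num_classes) {
  lapply(seq_along(strides), function(si) {
    st <- strides[si]
    gh <- grids[[si]][1]; gw <- grids[[si]][2]
    pos <- list()
    seen <- new.env(parent = emptyenv())
    for (n in seq_along(anns_list)) {
      anns <- anns_list[[n]]
      if (!nrow(anns)) next
      for (b in seq_len(nrow(anns))) {
        # multi-scale assignment: every head whose decode range covers the
        # box trains on it (size between 0.75 and 8 strides); boxes too
        # large for every head fall back to the coarsest stride
        m <- max(anns$w[b], anns$h[b]) * imgsz
        ratio <- m / strides
        ok <- ratio >= 0.75 & ratio < 8
        if (!any(ok)) ok[length(strides)] <- TRUE
        if (!ok[si]) next
        gx <- anns$cx[b] * gw; gy <- anns$cy[b] * gh
        c0 <- min(gw - 1L, floor(gx)); r0 <- min(gh - 1L, floor(gy))
        cells <- list(c(c0, r0))
        dc <- if (gx - c0 < 0.5) -1L else 1L
        dr <- if (gy - r0 < 0.5) -1L else 1L
        if (c0 + dc >= 0L && c0 + dc < gw) cells <- c(cells, list(c(c0 + dc, r0)))
        if (r0 + dr >= 0L && r0 + dr < gh) cells <- c(cells, list(c(c0, r0 + dr)))
        for (cl in cells) {
          col <- cl[2] + gh * (cl[1] + gw * (n - 1L)) + 1L
          key <- as.character(col)
          if (!is.null(seen[[key]])) next  # first (center-most) claim wins
          seen[[key]] <- TRUE
          pos[[length(pos) + 1L]] <- list(
            col = col, cell = cl, cls = anns$class_id[b],
            box = c(anns$cx[b], anns$cy[b], anns$w[b], anns$h[b]))
        }
      }
    }
    list(stride = st, gh = gh, gw = gw, pos = pos)
  })
}

# loss over one batch; returns list(node, parts)
.batch_loss <- function(model, xb, anns_list, hyper) {
  out <- model$forward(ag_const(xb))
  strides <- model$strides
  nc <- model$spec$num_classes
  imgsz <- dim(xb)[1]
  N <- dim(xb)[4]
  grids <- lapply(out, function(o) dim(o$v)[1:2])
  tg <- .build_targets(anns_list, strides, grids, imgsz, nc)
  l_obj <- NULL; l_cls <- NULL; l_box <- NULL
  npos_total <- 0L
  for (si in seq_along(out)) {
    flat <- ag_flatten_cells(out[[si]])     # (5+nc) x (gh*gw*N)
    P <- dim(flat$v)[2]
    pos <- tg[[si]]$pos
    tobj <- numeric(P)
    ciou <- NULL
    if (length(pos)) {
      npos_total <- npos_total + length(pos)
      idx <- vapply(pos, `[[`, numeric(1), "col")
      sel <- ag_cols(flat, idx)
      # class targets
      tcls <- matrix(0, nc, length(pos))
      for (j in seq_along(pos)) tcls[pos[[j]]$cls + 1L, j] <- 1
      lc <- ag_bce_logits(ag_rows(sel, 5L + seq_len(nc)), tcls)
      l_cls <- if (is.null(l_cls)) lc else ag_add(l_cls, lc)
      # box decode (matches decode_head: offsets 2s-0.5, sizes (2s)^3)
      sn <- tg[[si]]$stride / imgsz
      cells <- vapply(pos, `[[`, numeric(2), "cell")  # 2 x Np (c0, r0)
      gt <- list(cx = vapply(pos, function(p) p$box[1], numeric(1)),
                 cy = vapply(pos, function(p) p$box[2], numeric(1)),
                 w = vapply(pos, function(p) p$box[3], numeric(1)),
                 h = vapply(pos, function(p) p$box[4], numeric(1)))
      tx <- ag_rows(sel, 1L); ty <- ag_rows(sel, 2L)
      tw <- ag_rows(sel, 3L); th <- ag_rows(sel, 4L)
      off <- function(t) ag_sub(ag_scale(ag_sigmoid(t), 2), ag_const(matrix(0.5, 1, length(pos))))
      pcx <- ag_scale(ag_add(off(tx), ag_const(matrix(cells[1, ], 1))), sn)
      pcy <- ag_scale(ag_add(off(ty), ag_const(matrix(cells[2, ], 1))), sn)
      pw <- ag_scale(ag_pow(ag_scale(ag_sigmoid(tw), 2), 3), sn)
      ph <- ag_scale(ag_pow(ag_scale(ag_sigmoid(th), 2), 3), sn)
      ciou <- ag_ciou(pcx, pcy, pw, ph, lapply(gt, function(v) matrix(v, 1)))
      lb <- ag_mean(ag_sub(ag_const(matrix(1, 1, length(pos))), ciou))
      l_box <- if (is.null(l_box)) lb else ag_add(l_box, lb)
      # quality-aware objectness target: blend a fixed floor with the
      # detached CIoU of the assigned box so early low-quality boxes still
      # learn to fire while ranking tracks box quality later
      q <- pmin(1, pmax(0, as.numeric(ag_value(ciou))))
      tobj[idx] <- 0.5 + 0.5 * q
    }
    obj_logits <- ag_rows(flat, 5L)
    # balance positives against the much larger negative cell count
    wobj <- matrix(1, 1, P)
    if (length(pos)) wobj[1, tobj > 0] <- (P - length(pos)) / length(pos)
    lo <- ag_bce_logits(obj_logits, matrix(tobj, nrow = 1), weight = wobj)
    l_obj <- if (is.null(l_obj)) lo else ag_add(l_obj, lo)
  }
  zero <- ag_const(0)
  total <- ag_add(ag_scale(l_obj %||% zero, hyper$obj),
                  ag_add(ag_scale(l_cls %||% zero, hyper$cls),
                         ag_scale(l_box %||% zero, hyper$box)))
  list(node = total,
       parts = c(obj = if (is.null(l_obj)) 0 else ag_value(l_obj),
                 cls = if (is.null(l_cls)) 0 else ag_value(l_cls),
                 box = if (is.null(l_box)) 0 else ag_value(l_box)),
       npos = npos_total)
}

# fetch the training image for a record at the target size
.record_image <- function(rec, imgsz) {
  img <- render_record(rec)
  if (dim(img)[1] != imgsz || dim(img)[2] != imgsz)
    img <- preprocess(img, imgsz)$image
  img
}

#' Train a detector on a manifest
#'
#' Runs plain SGD with momentum over the records tagged `split == "train"`
#' (or all records when untagged). Deterministic given `hyper$seed` under
#' single-threaded execution.
#'
#' @param model an `rd_model` (modified in place)
#' @param manifest a `dataset_manifest` whose records carry annotations and
#'   either image files or synthetic scene configs
#' @param hyper an [rd_hyper()]
#' @param max_iter optional hard cap on optimizer steps
#' @param verbose print per-epoch loss
#' @return list(model, log): `log` is a data.frame with one row per epoch
#'   (mean total/obj/cls/box loss)
#' @export
rd_train <- function(model, manifest, hyper = rd_hyper(), max_iter = Inf,
                     verbose = FALSE) {
  recs <- manifest$records
  tags <- manifest_splits(manifest)
  if (any(!is.na(tags))) recs <- recs[tags == "train"]
  if (!length(recs)) stop("rd_train: empty training manifest")
  set.seed(hyper$seed)
  params <- collect_params(model)
  vel <- lapply(params, function(p) p$v * 0)
  vel2 <- lapply(params, function(p) p$v * 0)
  adam <- identical(hyper$optimizer, "adam")
  nb <- max(1L, ceiling(length(recs) / hyper$batch))
  total_iters <- min(max_iter, hyper$epochs * nb)
  wu_iters <- max(1, hyper$warmup_epochs * nb)
  it <- 0L
  log <- list()
  was <- set_training(TRUE)
  on.exit(set_training(was))
  # cache rendered images (desk-scale sets fit in memory)
  imgs <- lapply(recs, .record_image, imgsz = hyper$imgsz)
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample.int(length(recs))
    ep_losses <- NULL
    for (bi in seq_len(nb)) {
      if (it >= total_iters) break
      idx <- ord[((bi - 1L) * hyper$batch + 1L):min(bi * hyper$batch, length(recs))]
      xb <- array(0, c(hyper$imgsz, hyper$imgsz, 3L, length(idx)))
      for (j in seq_along(idx)) xb[, , , j] <- imgs[[idx[j]]]
      anns_list <- lapply(recs[idx], `[[`, "annotations")
      for (p in params) p$grad <- NULL
      bl <- .batch_loss(model, xb, anns_list, hyper)
      if (!is.finite(ag_value(bl$node)))
        stop(sprintf("rd_train: non-finite loss at iteration %d (obj=%.3g cls=%.3g box=%.3g)",
                     it + 1L, bl$parts[1], bl$parts[2], bl$parts[3]))
      ag_backward(bl$node)
      it <- it + 1L
      prog <- it / total_iters
      lr <- hyper$lr0 * (1 - prog * (1 - hyper$lrf))
      mom <- hyper$momentum
      if (it <= wu_iters) {
        f <- it / wu_iters
        lr <- lr * f
        mom <- hyper$warmup_momentum + f * (hyper$momentum - hyper$warmup_momentum)
      }
      # global gradient-norm clipping stabilizes the spiky balanced
      # objectness term on sparse-positive batches
      cn <- hyper$clip_norm %||% Inf
      if (is.finite(cn)) {
        gn <- sqrt(sum(vapply(params, function(p)
          if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
        if (gn > cn) for (p in params)
          if (!is.null(p$grad)) p$grad <- p$grad * (cn / gn)
      }
      for (k in seq_along(params)) {
        p <- params[[k]]
        if (is.null(p$grad)) next
        g <- p$grad + hyper$weight_decay * p$v
        if (adam) {
          vel[[k]] <- 0.9 * vel[[k]] + 0.1 * g
          vel2[[k]] <- 0.999 * vel2[[k]] + 0.001 * g^2
          mhat <- vel[[k]] / (1 - 0.9^it)
          vhat <- vel2[[k]] / (1 - 0.999^it)
          p$v <- p$v - lr * mhat / (sqrt(vhat) + 1e-8)
        } else {
          vel[[k]] <- mom * vel[[k]] + g
          p$v <- p$v - lr * vel[[k]]
        }
      }
      ep_losses <- rbind(ep_losses,
                         c(total = ag_value(bl$node), bl$parts))
    }
    if (!is.null(ep_losses)) {
      row <- colMeans(ep_losses)
      log[[length(log) + 1L]] <- c(epoch = ep, row)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f (obj %.4f cls %.4f box %.4f)",
                        ep, row[1], row[2], row[3], row[4]))
    }
    if (it >= total_iters) break
  }
  list(model = model,
       log = as.data.frame(do.call(rbind, log)))
}

#' Evaluate a model over a manifest split
#' @param model an `rd_model`
#' @param manifest a `dataset_manifest`
#' @param split split tag to evaluate (`NULL` for all records)
#' @param imgsz evaluation input size
#' @param conf_thresh,iou_thresh prediction thresholds
#' @return an `eval_result`
#' @export
rd_evaluate <- function(model, manifest, split = NULL, imgsz = NULL,
                        conf_thresh = 0.01, iou_thresh = 0.45) {
  recs <- manifest$records
  if (!is.null(split)) recs <- recs[manifest_splits(manifest) == split]
  imgsz <- imgsz %||% model$spec$input_size
  preds <- list(); gts <- list()
  for (i in seq_along(recs)) {
    img <- .record_image(recs[[i]], imgsz)
    det <- rd_predict(model, img, conf_thresh = conf_thresh,
                      iou_thresh = iou_thresh)
    if (nrow(det)) { det$image <- i; preds[[length(preds) + 1L]] <- det }
    gts[[length(gts) + 1L]] <- anns_to_gt(recs[[i]]$annotations, image = i)
  }
  preds <- if (length(preds)) do.call(rbind, preds) else
    data.frame(class_id = integer(0), x1 = numeric(0), y1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0), confidence = numeric(0),
               image = integer(0))
  gts <- do.call(rbind, gts)
  compute_map(preds, gts, num_classes = model$spec$num_classes)
}
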