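# exhaustive-threshold PR oracle: recompute matches from scratch at every
# distinct confidence cutoff, build the precision envelope and sample the
# same 101 recall points — fully independent of the cumulative-TP route
ap_oracle <- function(preds, gts, iou_thresh) {
  if (!nrow(gts)) return(NA_real_)
  if (!nrow(preds)) return(0)
  cuts <- sort(unique(preds$confidence), decreasing = TRUE)
  pr <- t(vapply(cuts, function(ct) {
    sub <- preds[preds$confidence >= ct, , drop = FALSE]
    mm <- match_detections(sub, gts, iou_thresh)
    c(p = sum(mm$tp) / nrow(sub), r = sum(mm$tp) / nrow(gts))
  }, c(p = 0, r = 0)))
  rp <- seq(0, 1, by = 0.01)
  vapply(rp, function(r) {
    ok <- pr[, "r"] >= r
    if (!any(ok)) 0 else max(pr[ok, "p"])
  }, numeric(1)) |> mean()
}

mk_boxes <- function(n, seed, K = 3) {
  set.seed(seed)
  cx <- runif(n, 0.2, 0.8); cy <- runif(n, 0.2, 0.8)
  w <- runif(n, 0.05, 0.2); h <- runif(n, 0.05, 0.2)
  data.frame(class_id = sample(0:(K - 1), n, replace = TRUE),
             x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
             image = sample(1:3, n, replace = TRUE))
}

test_that("IoU matches analytic cases", {
  expect_equal(iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
})

test_that("matching handles the exact, empty and hand-built cases", {
  gts <- mk_boxes(4, seed = 1)
  preds <- gts; preds$confidence <- runif(4, 0.5, 1)
  mm <- match_detections(preds, gts, 0.5)
  expect_true(all(mm$tp)); expect_equal(mm$fn, 0)
  mm0 <- match_detections(preds[0, ], gts, 0.5)
  expect_equal(mm0$fn, nrow(gts))
  # 3 predictions / 2 gts: highest-confidence claims the best-overlap gt
  gts2 <- data.frame(class_id = 0L,
                     x1 = c(0.1, 0.6), y1 = c(0.1, 0.6),
                     x2 = c(0.3, 0.8), y2 = c(0.3, 0.8), image = 1L)
  preds2 <- data.frame(class_id = 0L,
                       x1 = c(0.11, 0.12, 0.61), y1 = c(0.11, 0.12, 0.61),
                       x2 = c(0.31, 0.32, 0.81), y2 = c(0.31, 0.32, 0.81),
                       confidence = c(0.7, 0.9, 0.8), image = 1L)
  mm2 <- match_detections(preds2, gts2, 0.5)
  # order after sorting: conf 0.9 (gt1), 0.8 (gt2), 0.7 (gt1 taken -> FP)
  expect_equal(mm2$tp, c(TRUE, TRUE, FALSE))
  expect_equal(mm2$fn, 0)
})

test_that("perfect and empty detectors give the boundary mAP values", {
  gts <- mk_boxes(12, seed = 2)
  preds <- gts; preds$confidence <- 0.99
  r <- compute_map(preds, gts, 3)
  expect_equal(r$map50, 1); expect_equal(r$map50_95, 1)
  r0 <- compute_map(preds[0, ], gts, 3)
  expect_equal(r0$map50, 0)
  expect_true(r0$map50_95 <= r0$map50)
})

test_that("AP matches the exhaustive-threshold oracle on random sets", {
  for (s in 1:50) {
    gts <- mk_boxes(sample(3:8, 1), seed = 100 + s)
    np <- sample(4:12, 1)
    set.seed(200 + s)
    jit <- mk_boxes(np, seed = 300 + s)
    # mix: some jittered copies of gts (near-hits), some random
    take <- sample(nrow(gts), min(nrow(gts), np %/% 2))
    jit[seq_along(take), c("x1", "y1", "x2", "y2", "class_id", "image")] <-
      gts[take, c("x1", "y1", "x2", "y2", "class_id", "image")] +
      c(runif(length(take) * 4, -0.03, 0.03), rep(0, 2 * length(take)))
    jit$confidence <- runif(np)
    for (k in unique(gts$class_id)) {
      pk <- jit[jit$class_id == k, , drop = FALSE]
      gk <- gts[gts$class_id == k, , drop = FALSE]
      mine <- rdblocks:::.ap_101(match_detections(pk, gk, 0.5)$tp, nrow(gk))
      expect_equal(mine, ap_oracle(pk, gk, 0.5), tolerance = 1e-6)
    }
  }
})

test_that("AP is invariant to monotone confidence transforms", {
  gts <- mk_boxes(6, seed = 5)
  preds <- mk_boxes(10, seed = 6)
  preds$confidence <- runif(10, 0.1, 0.9)
  base <- compute_map(preds, gts, 3)$map50
  for (f in list(function(c) c^3, function(c) 0.1 + 0.8 * c, plogis)) {
    p2 <- preds; p2$confidence <- f(preds$confidence)
    expect_equal(compute_map(p2, gts, 3)$map50, base)
  }
})

test_that("confusion matrix has identity block for perfect predictions", {
  gts <- mk_boxes(9, seed = 7)
  preds <- gts; preds$confidence <- 0.9
  M <- confusion_matrix(preds, gts, 3)
  offdiag <- M[1:3, 1:3]; diag(offdiag) <- 0
  expect_equal(sum(offdiag), 0)
  expect_equal(sum(diag(M[1:3, 1:3])), nrow(gts))
  # zero predictions: everything in the background column
  M0 <- confusion_matrix(preds[0, ], gts, 3)
  expect_equal(sum(M0[, 4]), nrow(gts))
  # a blast box predicted as blight increments exactly one off-diagonal cell
  g1 <- data.frame(class_id = 1L, x1 = 0.1, y1 = 0.1, x2 = 0.3, y2 = 0.3,
                   image = 1L)
  p1 <- g1; p1$class_id <- 2L; p1$confidence <- 0.9
  M1 <- confusion_matrix(p1, g1, 3)
  expect_equal(M1["gt1", "pred2"], 1)
  expect_equal(sum(M1), 1)
})

test_that("PR curve export is monotone in recall and bounded", {
  gts <- mk_boxes(8, seed = 8)
  preds <- mk_boxes(14, seed = 9)
  preds$confidence <- runif(14)
  pc <- pr_curve(preds, gts, class_id = 0)
  if (nrow(pc)) {
    expect_true(all(diff(pc$recall) >= 0))
    expect_true(all(pc$precision >= 0 & pc$precision <= 1))
  }
})
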