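test_that("first-batch loss is finite and deterministic under a seed", {
  spec <- rd_model_spec(scale = "micro", input_size = 96)
  man <- generate_dataset(4, c(4, 3, 3), out_root = NULL, seed = 1,
                          image_size = 96)
  hyper <- rd_hyper(epochs = 1, batch = 4, imgsz = 96, seed = 3)
  set.seed(11); m1 <- build_model(spec)
  r1 <- rd_train(m1, man, hyper, max_iter = 1)
  set.seed(11); m2 <- build_model(spec)
  r2 <- rd_train(m2, man, hyper, max_iter = 1)
  expect_true(is.finite(r1$log$total[1]))
  expect_identical(r1$log$total[1], r2$log$total[1])
  expect_error(rd_train(m1, rdblocks:::new_manifest(list()), hyper), "empty")
})

test_that("CIoU reaches 1 exactly when prediction equals ground truth", {
  gt <- list(cx = matrix(0.4, 1), cy = matrix(0.5, 1),
             w = matrix(0.2, 1), h = matrix(0.1, 1))
  as_node <- function(v) ag_const(matrix(v, 1))
  ci <- rdblocks:::ag_ciou(as_node(0.4), as_node(0.5), as_node(0.2),
                           as_node(0.1), gt)
  expect_equal(as.numeric(ag_value(ci)), 1, tolerance = 1e-6)
  # disjoint boxes score below zero (distance penalty active)
  ci2 <- rdblocks:::ag_ciou(as_node(0.9), as_node(0.9), as_node(0.05),
                            as_node(0.05), gt)
  expect_lt(as.numeric(ag_value(ci2)), 0)
})

test_that("gradient descent on the composite loss reduces it", {
  set.seed(5)
  spec <- rd_model_spec(scale = "micro", input_size = 96)
  m <- build_model(spec)
  man <- generate_dataset(4, c(4, 3, 3), out_root = NULL, seed = 2,
                          image_size = 96)
  hyper <- rd_hyper(epochs = 12, batch = 4, imgsz = 96, lr0 = 0.02,
                    warmup_epochs = 1, seed = 5)
  res <- rd_train(m, man, hyper, max_iter = 12)
  expect_lt(tail(res$log$total, 1), res$log$total[1])
})

test_that("NMS suppresses duplicates and respects the oracle", {
  b <- data.frame(x1 = c(0.1, 0.1), y1 = c(0.1, 0.1),
                  x2 = c(0.3, 0.3), y2 = c(0.3, 0.3))
  expect_equal(nms(b, c(0.9, 0.8), 0.45), 1L)
  # conf_thresh = 1 yields no candidate boxes
  set.seed(6)
  m <- build_model(rd_model_spec(scale = "micro", input_size = 96))
  det <- rd_predict(m, array(runif(96 * 96 * 3), c(96, 96, 3)),
                    conf_thresh = 1.0)
  expect_equal(nrow(det), 0)
  # 4-candidate hand case vs brute-force all-pairs suppression
  b4 <- data.frame(x1 = c(0.10, 0.12, 0.50, 0.52),
                   y1 = c(0.10, 0.12, 0.50, 0.52),
                   x2 = c(0.30, 0.32, 0.70, 0.72),
                   y2 = c(0.30, 0.32, 0.70, 0.72))
  sc <- c(0.9, 0.85, 0.8, 0.95)
  keep <- nms(b4, sc, 0.45)
  # oracle: iterate over descending scores, drop boxes overlapping a keeper
  ord <- order(-sc); kept <- integer(0)
  for (i in ord) {
    over <- FALSE
    for (j in kept) {
      if (iou(as.numeric(b4[i, ]), as.numeric(b4[j, ])) > 0.45) over <- TRUE
    }
    if (!over) kept <- c(kept, i)
  }
  expect_setequal(keep, kept)
})

test_that("decoded boxes land where the logits say", {
  # craft a single-head grid with one confident cell and check the decode
  g <- array(-20, c(8, 8, 8))   # stride 8 at 64 px, 3 classes
  g[3, 5, 5] <- 8               # objectness at row 3, col 5
  g[3, 5, 6] <- 6               # class 0
  g[3, 5, 1:4] <- 0             # centered offsets, unit-stride box
  det <- rdblocks:::decode_head(g, stride = 8, input_size = 64,
                                num_classes = 3, conf_thresh = 0.5)
  expect_equal(nrow(det), 1)
  expect_equal(det$class_id, 0L)
  # offset 2*sigm(0)-0.5 = 0.5 -> center at (cell+0.5)*8/64
  expect_equal((det$x1 + det$x2) / 2, (4 + 0.5) * 8 / 64, tolerance = 1e-9)
  expect_equal((det$y1 + det$y2) / 2, (2 + 0.5) * 8 / 64, tolerance = 1e-9)
  expect_equal(det$x2 - det$x1, 1 * 8 / 64, tolerance = 1e-9)
})
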