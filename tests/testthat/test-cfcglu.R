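test_that("gate weights satisfy the split identities", {
  set.seed(1)
  for (i in 1:10) {
    C <- sample(c(2, 4, 8), 1)
    g <- caformer_gate(rand_fm(C, 6, 6, seed = i), t = runif(1, 0.2, 0.8))
    expect_equal(g$W1 * g$W2, rep(0, C))
    expect_equal(g$W1 + g$W2, g$w)
    expect_true(all(g$w > 0 & g$w < 1))
  }
  # equal gamma normalizes to 1/C
  g <- caformer_gate(rand_fm(4, 5, 5, seed = 99), gamma = rep(2, 4))
  expect_equal(g$W_gamma, rep(0.25, 4))
  expect_error(caformer_gate(rand_fm(4, 5, 5), t = 1.5), "threshold")
})

test_that("gate values match a scalar re-evaluation of the chain", {
  # 2-channel toy with gamma = (3, 1): recompute GN + weighting + sigmoid
  # with plain scalar arithmetic
  set.seed(2)
  x <- rand_fm(2, 4, 4, seed = 2)
  gamma <- c(3, 1); t <- 0.5
  g <- caformer_gate(x, t = t, gamma = gamma, groups = 1)
  flat <- as.vector(unclass(x))
  mu <- mean(flat); sd_ <- sqrt(mean((flat - mu)^2) + 1e-5)
  r <- sapply(1:2, function(c) mean((x[c, , ] - mu) / sd_ * gamma[c]))
  wg <- gamma / sum(gamma)
  w_ref <- 1 / (1 + exp(-(wg * r)))
  expect_equal(g$w, w_ref, tolerance = 1e-10)
  expect_equal(g$W1, w_ref * (w_ref >= t))
})

test_that("cross-reconstruction follows the channel-half exchange", {
  set.seed(3)
  x1 <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  x2 <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  out <- caformer_reconstruct(x1, x2)
  # elementwise reference: first half = X11 + X22, second = X21 + X12
  expect_equal(unclass(out)[1:2, , ], x1[1:2, , ] + x2[3:4, , ])
  expect_equal(unclass(out)[3:4, , ], x2[1:2, , ] + x1[3:4, , ])
  expect_equal(dim(out), dim(x1))
  # zero non-informative branch passes the informative map through
  expect_equal(unclass(caformer_reconstruct(x1, array(0, dim(x1)))), x1)
  expect_error(caformer_reconstruct(x1, array(0, c(4, 2, 3))), "mismatch")
  expect_error(caformer_reconstruct(x1[1:3, , , drop = FALSE],
                                    x2[1:3, , , drop = FALSE]), "even")
})

test_that("CGLU segment arithmetic and degenerate ratios", {
  expect_equal(unname(cglu_segments(64, split_ratios(0.5, 0.25))),
               c(32L, 16L, 16L))
  expect_equal(unname(cglu_segments(10, split_ratios(0.5, 0.3))),
               c(5L, 3L, 2L))
  expect_error(cglu_segments(4, split_ratios(0.05, 0.5)), "empty")
  expect_error(split_ratios(0.8, 0.5), "alpha")
})

test_that("CGLU output width follows the configuration regardless of ratios", {
  set.seed(4)
  x <- rand_fm(16, 8, 8, seed = 4)
  for (r in list(split_ratios(0.5, 0.25), split_ratios(0.25, 0.5),
                 split_ratios(0.5, 0.5))) {
    expect_equal(dim(apply_cglu(x, r, cout = 12)), c(12L, 8L, 8L))
  }
})

test_that("group-wise convolution carries 9 c^2 / g weights", {
  for (g in c(1, 2, 4)) {
    c_ <- 8L
    conv <- rdblocks:::nn_conv2d(c_, c_, 3L, groups = g, bias = FALSE)
    expect_equal(param_count(conv), 9 * c_^2 / g)
  }
  # and the instantiated CGLU upper branch matches
  m <- nn_cglu(16, 16, split_ratios(0.5, 0.25), groups = 2)
  up <- cglu_segments(16, split_ratios(0.5, 0.25))[["upper"]]
  expect_equal(param_count(m$children$gw), 9 * up^2 / 2)
})

test_that("C3k2-CFCGLU preserves shape and reduces parameters", {
  set.seed(5)
  x <- rand_fm(64, 10, 10, seed = 5)
  base <- nn_c3k2(64, 64)
  sub <- nn_c3k2(64, 64, unit = "cfcglu")
  expect_equal(dim(c3k2_cfcglu_block(x, module = sub)), c(64L, 10L, 10L))
  expect_lt(param_count(sub), param_count(base))
})

test_that("all-informative gating reduces CAFormer to its dense branch", {
  set.seed(6)
  C <- 8
  m <- nn_caformer(C, t = 0.5)
  x <- ag_const(rand_t(6, 6, C, 1, seed = 6))
  # reference forward with W2 forced to zero (all weights informative)
  ref <- ag_value(m$forward(x, force_dense = TRUE))
  # manual: reconstruct(concat halves of W1 * dws(X), 0) = W1 * dws(X)
  gnx <- m$children$gn$forward(x)
  gam <- m$children$gn$params$gamma
  wg <- ag_value(gam) / sum(ag_value(gam))
  r <- as.numeric(ag_value(ag_gap(gnx)))
  w <- 1 / (1 + exp(-(wg * r)))
  dws <- ag_value(m$children$l2$forward(m$children$l1$forward(x)))
  manual <- dws * rep(w, each = 36)
  expect_lt(max(abs(ref - manual)), 1e-10)
})
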