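test_that("compression produces descriptors of the right shapes", {
  set.seed(1)
  d <- cscbam_compress(rand_fm(8, 4, 4, seed = 1))
  expect_length(d$channel, 8)
  expect_equal(dim(d$spatial), c(4L, 4L))
})

test_that("pooled descriptors of a constant input coincide pre-MLP", {
  x <- array(0.7, c(6, 6, 5, 1))
  expect_equal(ag_value(ag_gmp(ag_const(x))), ag_value(ag_gap(ag_const(x))))
  expect_equal(ag_value(ag_cmax(ag_const(x))), ag_value(ag_cavg(ag_const(x))))
})

test_that("axis reductions match the brute-force toy computation", {
  set.seed(2)
  x <- rand_t(2, 2, 2, 1, seed = 2)
  expect_equal(as.numeric(ag_value(ag_gmp(ag_const(x)))),
               c(max(x[, , 1, 1]), max(x[, , 2, 1])))
  expect_equal(as.numeric(ag_value(ag_gap(ag_const(x)))),
               c(mean(x[, , 1, 1]), mean(x[, , 2, 1])))
  expect_equal(ag_value(ag_cmax(ag_const(x)))[, , 1, 1],
               pmax(x[, , 1, 1], x[, , 2, 1]))
  expect_equal(ag_value(ag_cavg(ag_const(x)))[, , 1, 1],
               (x[, , 1, 1] + x[, , 2, 1]) / 2)
})

test_that("joint descriptor has length H*W + C and degenerate MLPs behave", {
  set.seed(3)
  pair <- list(channel = abs(rnorm(8)), spatial = matrix(abs(rnorm(16)), 4, 4))
  expect_length(cscbam_interact(pair), 4 * 4 + 8)
  # identity-initialized square MLP reproduces the (non-negative) concat
  expect_equal(cscbam_interact(pair, init = "identity"),
               c(as.numeric(pair$spatial), pair$channel))
  # zero-initialized MLP with zero bias returns the zero vector
  expect_equal(cscbam_interact(pair, init = "zero"), rep(0, 24))
})

test_that("zero-initialized attention halves the map twice (0.25 F)", {
  set.seed(4)
  f <- rand_fm(8, 6, 6, seed = 4)
  out <- cscbam_apply(f, init = "zero")
  expect_lt(max(abs(out - 0.25 * unclass(f))), 1e-12)
})

test_that("gates are bounded so the output never exceeds the input", {
  set.seed(5)
  for (i in 1:5) {
    f <- rand_fm(8, 7, 9, seed = 10 + i)
    out <- cscbam_apply(f)
    expect_true(all(abs(out) <= abs(unclass(f)) + 1e-12))
    expect_equal(dim(out), dim(f))
    nz <- abs(unclass(f)) > 1e-9
    ratio <- abs(out)[nz] / abs(unclass(f))[nz]
    expect_true(all(ratio > 0 & ratio < 1))
  }
})

test_that("the full module matches a scalar re-evaluation of its stages", {
  set.seed(6)
  f <- rand_fm(4, 6, 6, seed = 6)
  mod <- nn_cscbam(cscbam_config(4, spatial_tokens = 6))
  got <- cscbam_apply(f, module = mod)
  # independent scalar recomputation from the module weights
  x <- unclass(f)
  sigm <- function(z) 1 / (1 + exp(-z))
  silu <- function(z) z * sigm(z)
  w1 <- mod$children$mlp1$params$w$v; w2 <- mod$children$mlp2$params$w$v
  gmp <- apply(x, 1, max); gap <- apply(x, 1, mean)
  cd <- as.numeric(w2 %*% silu(w1 %*% gmp)) + as.numeric(w2 %*% silu(w1 %*% gap))
  cmax <- apply(x, c(2, 3), max); cavg <- apply(x, c(2, 3), mean)
  sw <- mod$children$spatial$params$w$v; sb <- mod$children$spatial$params$b$v
  sd_ <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    acc <- sb[1]
    for (a in 1:7) for (b in 1:7) {
      ii <- i + a - 4; jj <- j + b - 4
      if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6)
        acc <- acc + cmax[ii, jj] * sw[a, b, 1, 1] + cavg[ii, jj] * sw[a, b, 2, 1]
    }
    sd_[i, j] <- acc
  }
  # spatial tokens = 6 at a 6x6 input: adaptive pooling is the identity
  joint <- c(as.numeric(sd_), cd)
  iw1 <- mod$children$int1$params$w$v; ib1 <- mod$children$int1$params$b$v
  iw2 <- mod$children$int2$params$w$v; ib2 <- mod$children$int2$params$b$v
  jo <- as.numeric(iw2 %*% silu(iw1 %*% joint + ib1) + ib2)
  sgate <- sigm(matrix(jo[1:36], 6, 6))
  cgate <- sigm(jo[37:40])
  ref <- x * rep(cgate, times = 36)
  dim(ref) <- dim(x)
  for (c in 1:4) ref[c, , ] <- ref[c, , ] * sgate
  expect_lt(max(abs(unclass(got) - ref)), 1e-10)
})

test_that("C3k2-CSCBAM carries exactly one BN and one ReLU and saves params", {
  set.seed(7)
  blk <- nn_c3k2(128, 128, unit = "cscbam")
  expect_equal(count_layers(blk, "bn"), 1L)
  x <- rand_fm(128, 20, 20, seed = 7)
  expect_equal(count_relu_calls(blk, x), 1L)
  expect_equal(dim(c3k2_cscbam_block(x, module = blk)), c(128L, 20L, 20L))
  expect_lt(param_count(blk), param_count(nn_c3k2(128, 128)))
})
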