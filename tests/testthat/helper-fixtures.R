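# shared fixtures: small random feature maps and a finite-difference oracle

rand_fm <- function(C, H, W, seed = 1) {
  set.seed(seed)
  feature_map(array(rnorm(C * H * W), c(C, H, W)))
}

rand_t <- function(H, W, C, N = 1, seed = 1) {
  set.seed(seed)
  array(rnorm(H * W * C * N), c(H, W, C, N))
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

rel_err <- function(got, want) {
  max(abs(got - want)) / max(1e-8, max(abs(want)))
}

# brute-force 2-D valid/same convolution for a single channel (zero padding)
conv2_ref <- function(x, k, dil = 1L) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- dil * (kh - 1) %/% 2; pw <- dil * (kw - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- i + (a - 1) * dil - ph
      jj <- j + (b - 1) * dil - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) acc <- acc + x[ii, jj] * k[a, b]
    }
    out[i, j] <- acc
  }
  out
}
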