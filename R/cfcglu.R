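# CAFormer spatial separation/reconstruction and the CGLU channel mixer.
#
# CAFormer separates informative from redundant spatial content using the
# learnable per-channel scale of a group normalization as an informativeness
# signal: normalized weights W_gamma gate the GN-processed channel response
# through a sigmoid, and a threshold t splits the resulting per-channel
# weights into an informative set W1 (>= t) and a non-informative set W2
# (< t). Gating is soft (the mask multiplies the weight value) so the split
# remains differentiable. The weighted maps are cross-reconstructed by
# channel halves and concatenated. The CGLU then reduces channel redundancy
# through a three-branch split (group-wise + point-wise rich extractor,
# depth-wise separable detail branch, identity bypass) fused by a pooled
# linear gate.

#' Channel split ratios for the CGLU
#' @param alpha,beta fractions in `[0,1]` with `alpha + beta <= 1`; the upper
#'   branch receives `alpha*C` channels, the lower `beta*C`, the bypass the
#'   remainder
#' @return a `split_ratios` list
#' @export
split_ratios <- function(alpha = 0.5, beta = 0.25) {
  if (alpha < 0 || beta < 0 || alpha > 1 || beta > 1 || alpha + beta > 1)
    stop("split_ratios: need 0 <= alpha, beta and alpha + beta <= 1")
  structure(list(alpha = alpha, beta = beta), class = "split_ratios")
}

#' Channel segment sizes implied by split ratios
#' @param C channel count
#' @param ratios a [split_ratios()]
#' @return integer vector (upper, lower, bypass), summing to C
#' @export
cglu_segments <- function(C, ratios) {
  up <- as.integer(round(ratios$alpha * C))
  lo <- as.integer(round(ratios$beta * C))
  by <- as.integer(C - up - lo)
  if (up < 1L || lo < 1L)
    stop("cglu_segments: ratios produce an empty upper or lower segment")
  c(upper = up, lower = lo, bypass = by)
}

#' CAFormer informativeness gate
#'
#' Computes per-channel gate weights from group-normalization statistics:
#' `W_gamma = gamma / sum(gamma)`, multiplied with the per-channel mean
#' response of the normalized map and passed through a sigmoid; the threshold
#' t splits the weights into informative (W1) and non-informative (W2) parts.
#'
#' @param x a C x H x W array
#' @param t threshold in (0,1)
#' @param gamma per-channel GN scale (defaults to 1s)
#' @param beta per-channel GN shift (defaults to 0s)
#' @param groups normalization groups (must divide C)
#' @return a `gate_weights` list: gamma, W_gamma, w, W1, W2, threshold
#' @export
caformer_gate <- function(x, t = 0.5, gamma = NULL, beta = NULL, groups = 1L) {
  if (t <= 0 || t >= 1) stop("caformer_gate: threshold t must lie in (0,1)")
  C <- dim(x)[1]
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- rep(0, C)
  stopifnot(length(gamma) == C, C %% groups == 0)
  xt <- chw_to_t(x)
  gn <- ag_groupnorm(ag_const(xt), ag_const(gamma), ag_const(beta),
                     groups = groups)
  r <- as.numeric(ag_value(ag_gap(gn)))          # per-channel mean response
  W_gamma <- gamma / sum(gamma)
  w <- 1 / (1 + exp(-(W_gamma * r)))
  W1 <- w * (w >= t)
  W2 <- w * (w < t)
  structure(list(gamma = gamma, W_gamma = W_gamma, w = w,
                 W1 = W1, W2 = W2, threshold = t),
            class = "gate_weights")
}

#' Cross-reconstruct two weighted feature maps
#'
#' Splits both inputs into channel halves (contiguous first/second half),
#' cross-adds them (`XW1 = X11 + X22`, `XW2 = X21 + X12`) and concatenates
#' the results, preserving the channel count.
#'
#' @param x1w,x2w C x H x W arrays of identical shape, C even
#' @return reconstructed C x H x W feature map
#' @export
caformer_reconstruct <- function(x1w, x2w) {
  if (!identical(dim(x1w), dim(x2w)))
    stop("caformer_reconstruct: shape mismatch")
  C <- dim(x1w)[1]
  if (C %% 2L != 0L) stop("caformer_reconstruct: channel count must be even")
  h <- C %/% 2L
  x11 <- x1w[seq_len(h), , , drop = FALSE]
  x12 <- x1w[h + seq_len(h), , , drop = FALSE]
  x21 <- x2w[seq_len(h), , , drop = FALSE]
  x22 <- x2w[h + seq_len(h), , , drop = FALSE]
  out <- array(0, dim(x1w))
  out[seq_len(h), , ] <- x11 + x22
  out[h + seq_len(h), , ] <- x21 + x12
  feature_map(out)
}

#' CAFormer separation/reconstruction module
#'
#' @param C channel count (even)
#' @param t gate threshold, default 0.5
#' @param groups GN groups
#' @return an `nn_module` preserving the channel count
#' @export
nn_caformer <- function(C, t = 0.5, groups = NULL, label = "caformer") {
  if (C %% 2L != 0L) stop("nn_caformer: channel count must be even")
  if (t <= 0 || t >= 1) stop("nn_caformer: threshold t must lie in (0,1)")
  if (is.null(groups)) groups <- if (C %% 4L == 0L) 4L else if (C %% 2L == 0L) 2L else 1L
  m <- new_module(label)
  add_child(m, "gn", nn_groupnorm(C, groups))
  # depth-wise separable sub-branch (L1 depth-wise, L2 point-wise)
  add_child(m, "l1", nn_conv2d(C, C, 3L, groups = C, bias = FALSE))
  add_child(m, "l2", nn_conv2d(C, C, 1L, bias = TRUE))
  m$meta <- list(C = C, t = t, groups = groups)
  m$forward <- function(x, force_dense = FALSE) {
    if (dim(x$v)[3] != C) stop("caformer: channel mismatch")
    N <- dim(x$v)[4]
    gnx <- m$children$gn$forward(x)
    gam <- m$children$gn$params$gamma
    wg <- ag_div(gam, ag_sum(gam))
    r <- ag_gap(gnx)                               # C x N
    w <- ag_sigmoid(ag_colwise_mul(r, wg))         # C x N
    mask1 <- ag_value(w) >= m$meta$t
    if (force_dense) mask1[] <- TRUE
    w1 <- ag_mul(w, ag_const(mask1 * 1))
    w2 <- ag_mul(w, ag_const((!mask1) * 1))
    dws <- m$children$l2$forward(m$children$l1$forward(x))
    x1w <- ag_mul(dws, ag_reshape(w1, c(1, 1, C, N)))
    x2w <- ag_mul(x, ag_reshape(w2, c(1, 1, C, N)))
    h <- C %/% 2L
    x11 <- ag_slice_c(x1w, 1L, h);      x12 <- ag_slice_c(x1w, h + 1L, C)
    x21 <- ag_slice_c(x2w, 1L, h);      x22 <- ag_slice_c(x2w, h + 1L, C)
    ag_concat_c(list(ag_add(x11, x22), ag_add(x21, x12)))
  }
  m
}

#' CGLU three-branch channel mixer module
#'
#' @param cin,cout block widths
#' @param ratios a [split_ratios()]
#' @param groups group count of the upper-branch group-wise convolution
#' @return an `nn_module`
#' @export
nn_cglu <- function(cin, cout, ratios = split_ratios(), groups = 2L,
                    label = "cglu") {
  seg <- cglu_segments(cin, ratios)
  up <- seg[["upper"]]; lo <- seg[["lower"]]; by <- seg[["bypass"]]
  g <- if (up %% groups == 0L) groups else 1L
  m <- new_module(label)
  add_child(m, "compress", nn_conv2d(cin, cin, 1L, bias = TRUE))
  add_child(m, "gw", nn_conv2d(up, up, 3L, groups = g, bias = FALSE))
  add_child(m, "pw", nn_conv2d(up, up, 1L, bias = FALSE))
  add_child(m, "dw", nn_conv2d(lo, lo, 3L, groups = lo, bias = FALSE))
  add_child(m, "dpw", nn_conv2d(lo, lo, 1L, bias = TRUE))
  add_child(m, "fuse", nn_linear(up + lo, up + lo))
  add_child(m, "out", nn_conv2d(cin, cout, 1L, bias = TRUE))
  m$meta <- list(cin = cin, cout = cout, seg = seg, groups = g)
  m$forward <- function(x) {
    if (dim(x$v)[3] != cin) stop("cglu: channel mismatch")
    N <- dim(x$v)[4]
    xc <- m$children$compress$forward(x)
    xu <- ag_slice_c(xc, 1L, up)
    xl <- ag_slice_c(xc, up + 1L, up + lo)
    y1 <- ag_add(m$children$gw$forward(xu), m$children$pw$forward(xu))
    y2 <- ag_gelu(m$children$dpw$forward(m$children$dw$forward(xl)))
    pooled <- ag_rbind(ag_gap(y1), ag_gap(y2))
    s <- ag_sigmoid(m$children$fuse$forward(pooled))
    s1 <- ag_reshape(ag_rows(s, seq_len(up)), c(1, 1, up, N))
    s2 <- ag_reshape(ag_rows(s, up + seq_len(lo)), c(1, 1, lo, N))
    parts <- list(ag_mul(y1, s1), ag_mul(y2, s2))
    if (by > 0L) parts <- c(parts, list(ag_slice_c(xc, up + lo + 1L, cin)))
    m$children$out$forward(ag_concat_c(parts))
  }
  m
}

#' Apply a CGLU mixer to a feature map
#' @param xw a C x H x W array
#' @param ratios a [split_ratios()]
#' @param cout output channels (default: same as input)
#' @param module optional pre-built [nn_cglu()]
#' @return mixed feature map with `cout` channels
#' @export
apply_cglu <- function(xw, ratios = split_ratios(), cout = NULL, module = NULL) {
  C <- dim(xw)[1]
  mod <- module %||% nn_cglu(C, cout %||% C, ratios)
  if (dim(xw)[1] != mod$meta$cin) stop("apply_cglu: channel mismatch")
  module_apply(mod, xw)
}
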