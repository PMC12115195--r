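# Large-Separable-Kernel Attention with Convolution (LSKAC).
#
# A large k x k depth-wise convolution is decomposed into (i) a cascaded pair
# of 1-D depth-wise kernels of length 2d-1 capturing the local neighbourhood,
# (ii) a floor(k/d) x floor(k/d) depth-wise convolution with dilation d
# covering the long-range context (its separable composition is what the
# cascade of 1-D sparse kernels computes), and (iii) a 1x1 channel-mixing
# convolution. The resulting attention map gates the input by an elementwise
# (Hadamard) product. All convolutions are bias-free so the parameter count
# matches the closed form exactly.

#' LSKAC configuration
#'
#' @param channels number of feature-map channels C
#' @param k large-kernel size being decomposed (default 23)
#' @param d dilation rate, `d <= k` (default 3)
#' @return an `lskac_config` list with fields channels, k, d
#' @export
lskac_config <- function(channels, k = 23L, d = 3L) {
  if (length(channels) != 1L || channels < 1L || channels != round(channels))
    stop("lskac_config: channels must be a positive integer")
  if (k < 1L || d < 1L) stop("lskac_config: k and d must be positive")
  if (d > k) stop("lskac_config: dilation d must not exceed kernel size k")
  if ((2L * d - 1L) < 1L || (k %/% d) < 1L)
    stop("lskac_config: derived kernel lengths must be >= 1")
  structure(list(channels = as.integer(channels), k = as.integer(k),
                 d = as.integer(d)), class = "lskac_config")
}

#' LSKAC attention module
#'
#' Builds the decomposed large-kernel attention operator. The forward pass
#' produces an attention map of the same shape as the input and returns the
#' gated map `A * F`.
#'
#' @param cfg an [lskac_config()]
#' @return an `nn_module`
#' @export
nn_lskac <- function(cfg, label = "lskac") {
  stopifnot(inherits(cfg, "lskac_config"))
  C <- cfg$channels; d <- cfg$d
  kd <- cfg$k %/% d
  kl <- 2L * d - 1L
  m <- new_module(label)
  add_child(m, "dw_h", nn_conv2d(C, C, c(1L, kl), groups = C, bias = FALSE))
  add_child(m, "dw_v", nn_conv2d(C, C, c(kl, 1L), groups = C, bias = FALSE))
  add_child(m, "dw_dil", nn_conv2d(C, C, c(kd, kd), dil = d, groups = C,
                                   bias = FALSE))
  add_child(m, "mix", nn_conv2d(C, C, 1L, bias = FALSE))
  m$meta <- list(cfg = cfg)
  # the pure convolution chain producing the attention map (no nonlinearity)
  m$attention <- function(x) {
    z <- m$children$dw_v$forward(m$children$dw_h$forward(x))
    z <- m$children$dw_dil$forward(z)
    m$children$mix$forward(z)
  }
  m$forward <- function(x) {
    if (dim(x$v)[3] != C) stop("lskac: channel mismatch")
    ag_mul(m$attention(x), x)
  }
  m
}

#' Apply LSKAC attention to a feature map
#'
#' @param f a C x H x W array (channel, row, col)
#' @param cfg an [lskac_config()] with `channels == dim(f)[1]`, or an
#'   already-built [nn_lskac()] module
#' @return gated feature map of identical shape
#' @export
apply_lskac <- function(f, cfg) {
  mod <- if (inherits(cfg, "nn_module")) cfg else nn_lskac(cfg)
  if (dim(f)[1] != mod$meta$cfg$channels)
    stop("apply_lskac: feature map channels do not match configuration")
  module_apply(mod, f)
}

#' Closed-form parameter and FLOP accounting for LSKAC / LSKA
#'
#' Parameters: LSKAC `(2d-1)*C*2 + floor(k/d)^2*C + C^2`;
#' LSKA `(2d-1)^2*C + floor(k/d)^2*C + C^2`. FLOPs are the parameter
#' expression times `H*W` (one multiply-accumulate per kernel weight and
#' output position).
#'
#' @param variant `"lskac"` or `"lska"`
#' @param cfg an [lskac_config()]
#' @param H,W spatial size of the feature grid
#' @return a `complexity_report`: parameter_count, flop_count, breakdown
#' @export
lskac_complexity <- function(variant = c("lskac", "lska"), cfg, H, W) {
  variant <- match.arg(variant)
  stopifnot(inherits(cfg, "lskac_config"))
  C <- cfg$channels; d <- cfg$d
  kd <- cfg$k %/% d
  local_p <- switch(variant,
    lskac = (2 * d - 1) * C * 2,
    lska  = (2 * d - 1)^2 * C)
  rows <- data.frame(
    layer = c(sprintf("local depth-wise (%s)",
                      if (variant == "lskac") "1D cascade" else "2D dense"),
              sprintf("dilated depth-wise %dx%d", kd, kd),
              "1x1 channel mix"),
    params = c(local_p, kd^2 * C, C * C))
  rows$flops <- rows$params * H * W
  complexity_report(rows)
}

#' @rdname lskac_complexity
#' @export
complexity_of <- lskac_complexity

# dense LSKA counterpart, used for structural counting cross-checks
nn_lska <- function(cfg, label = "lska") {
  C <- cfg$channels; d <- cfg$d
  kd <- cfg$k %/% d
  kl <- 2L * d - 1L
  m <- new_module(label)
  add_child(m, "dw", nn_conv2d(C, C, c(kl, kl), groups = C, bias = FALSE))
  add_child(m, "dw_dil", nn_conv2d(C, C, c(kd, kd), dil = d, groups = C,
                                   bias = FALSE))
  add_child(m, "mix", nn_conv2d(C, C, 1L, bias = FALSE))
  m$meta <- list(cfg = cfg)
  m$forward <- function(x) {
    a <- m$children$mix$forward(m$children$dw_dil$forward(m$children$dw$forward(x)))
    ag_mul(a, x)
  }
  m
}

#' Complexity report container
#' @param breakdown data.frame with columns layer, params, flops
#' @return list with parameter_count, flop_count and the breakdown
#' @export
complexity_report <- function(breakdown) {
  structure(list(parameter_count = sum(breakdown$params),
                 flop_count = sum(breakdown$flops),
                 breakdown = breakdown),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("complexity: %s parameters, %s FLOPs (multiply-accumulates)\n",
              format(x$parameter_count, big.mark = ","),
              format(x$flop_count, big.mark = ",")))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}
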