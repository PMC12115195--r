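# SPPFLKC: the SPPF pooling pyramid rebuilt around LSKAC.
#
# Wiring: 1x1 reduce conv -> LSKAC gate -> three serial stride-1 max-pools
# plus one parallel average-pool branch -> concat of the five maps ->
# single-head channel self-attention (softmax over the global-average-pooled
# channel descriptor, applied as a residual channel gate) -> 1x1 conv to the
# output width. Max-pool padding uses -Inf semantics; average pooling
# excludes padded cells.

#' SPPFLKC configuration
#'
#' @param in_channels,out_channels block widths
#' @param pool_kernel odd stride-1 pooling kernel (default 5)
#' @param lskac an [lskac_config()] for the gate; channel count is forced to
#'   the reduced width `in_channels / 2`
#' @return an `sppflkc_config`
#' @export
sppflkc_config <- function(in_channels, out_channels, pool_kernel = 5L,
                           lskac = NULL) {
  if (pool_kernel %% 2L == 0L)
    stop("sppflkc_config: pool_kernel must be odd")
  hidden <- max(2L, in_channels %/% 2L)
  lk <- if (is.null(lskac)) lskac_config(hidden)
        else lskac_config(hidden, lskac$k, lskac$d)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 pool_kernel = as.integer(pool_kernel),
                 hidden = hidden, lskac = lk),
            class = "sppflkc_config")
}

#' SPPFLKC module
#' @param cfg an [sppflkc_config()]
#' @return an `nn_module`
#' @export
nn_sppflkc <- function(cfg, label = "sppflkc") {
  stopifnot(inherits(cfg, "sppflkc_config"))
  h <- cfg$hidden
  m <- new_module(label)
  add_child(m, "reduce", nn_cbs(cfg$in_channels, h, 1L))
  add_child(m, "lskac", nn_lskac(cfg$lskac))
  add_child(m, "out", nn_cbs(5L * h, cfg$out_channels, 1L))
  m$meta <- list(cfg = cfg)
  m$forward <- function(x) {
    if (dim(x$v)[3] != cfg$in_channels) stop("sppflkc: channel mismatch")
    g <- m$children$lskac$forward(m$children$reduce$forward(x))
    p1 <- ag_maxpool(g, cfg$pool_kernel, 1L)
    p2 <- ag_maxpool(p1, cfg$pool_kernel, 1L)
    p3 <- ag_maxpool(p2, cfg$pool_kernel, 1L)
    pa <- ag_avgpool(g, cfg$pool_kernel, 1L)
    u <- ag_concat_c(list(g, p1, p2, p3, pa))
    # channel self-attention: softmax over the pooled channel descriptor,
    # folded back as a residual multiplicative gate
    a <- ag_softmax(ag_gap(u))
    nch <- dim(u$v)[3]
    gate <- ag_add(ag_const(array(1, c(1, 1, nch, dim(u$v)[4]))),
                   ag_scale(ag_reshape(a, c(1, 1, nch, dim(u$v)[4])), nch))
    m$children$out$forward(ag_mul(u, gate))
  }
  m
}

#' Apply an SPPFLKC block to a feature map
#' @param f a C x H x W array
#' @param cfg an [sppflkc_config()] or built [nn_sppflkc()] module
#' @return feature map of shape out_channels x H x W
#' @export
apply_sppflkc <- function(f, cfg) {
  mod <- if (inherits(cfg, "nn_module")) cfg else nn_sppflkc(cfg)
  if (dim(f)[1] != mod$meta$cfg$in_channels)
    stop("apply_sppflkc: feature map channels do not match configuration")
  module_apply(mod, f)
}
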