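# CSCBAM: joint channel-spatial attention in three stages.
#
# Compression: max and average pooling produce channel descriptors (through a
# shared bottleneck MLP, added) and spatial descriptors (stacked and fused by
# a 7x7 convolution). Interaction: the spatial descriptor is adaptively
# pooled to a fixed S x S token grid, flattened, concatenated with the
# channel descriptor to a (S*S + C) vector, and passed through an MLP so
# global channel and spatial statistics exchange information. Separation: the
# joint vector is split back, squashed by a sigmoid, and both gates multiply
# the input (channel gate first, then spatial).

#' CSCBAM configuration
#' @param channels feature-map channels C
#' @param reduction shared-MLP bottleneck reduction ratio (default 16)
#' @param interact_hidden_ratio hidden width of the interaction MLP as a
#'   fraction of its input length (default 0.25)
#' @param spatial_tokens side length S of the pooled spatial token grid
#' @return a `cscbam_config`
#' @export
cscbam_config <- function(channels, reduction = 16L,
                          interact_hidden_ratio = 0.25, spatial_tokens = 8L) {
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 interact_hidden_ratio = interact_hidden_ratio,
                 spatial_tokens = as.integer(spatial_tokens)),
            class = "cscbam_config")
}

#' CSCBAM attention module
#' @param cfg a [cscbam_config()] (or channel count, taking defaults)
#' @param init `"random"` (default) or `"zero"` for all-zero MLP weights
#' @return an `nn_module` preserving shape
#' @export
nn_cscbam <- function(cfg, init = "random", label = "cscbam") {
  if (is.numeric(cfg)) cfg <- cscbam_config(cfg)
  C <- cfg$channels
  cr <- max(1L, C %/% cfg$reduction)
  S <- cfg$spatial_tokens
  D <- S * S + C
  hidden <- max(4L, as.integer(round(cfg$interact_hidden_ratio * D)))
  m <- new_module(label)
  add_child(m, "mlp1", nn_linear(C, cr, bias = FALSE))
  add_child(m, "mlp2", nn_linear(cr, C, bias = FALSE))
  add_child(m, "spatial", nn_conv2d(2L, 1L, 7L, bias = TRUE))
  add_child(m, "int1", nn_linear(D, hidden))
  add_child(m, "int2", nn_linear(hidden, D))
  if (identical(init, "zero")) {
    for (ch in m$children) for (p in ch$params) p$v[] <- 0
  }
  m$meta <- list(cfg = cfg, D = D, hidden = hidden)

  # SiLU inside the descriptor MLPs: the substituted C3k2 block reserves its
  # single ReLU for the pre-fusion stage
  m$compress <- function(x) {
    cd <- ag_add(m$children$mlp2$forward(ag_silu(m$children$mlp1$forward(ag_gmp(x)))),
                 m$children$mlp2$forward(ag_silu(m$children$mlp1$forward(ag_gap(x)))))
    sd <- m$children$spatial$forward(ag_concat_c(list(ag_cmax(x), ag_cavg(x))))
    list(channel = cd, spatial = sd)                 # C x N, (H,W,1,N)
  }
  m$interact <- function(desc) {
    tok <- ag_flatten(ag_adapt_avg(desc$spatial, S)) # S*S x N
    joint <- ag_rbind(tok, desc$channel)             # (S*S + C) x N
    m$children$int2$forward(ag_silu(m$children$int1$forward(joint)))
  }
  m$forward <- function(x) {
    d <- dim(x$v)
    if (d[3] != C) stop("cscbam: channel mismatch")
    desc <- m$compress(x)
    joint <- m$interact(desc)
    sgate <- ag_sigmoid(ag_reshape(ag_rows(joint, seq_len(S * S)),
                                   c(S, S, 1L, d[4])))
    cgate <- ag_sigmoid(ag_reshape(ag_rows(joint, S * S + seq_len(C)),
                                   c(1, 1, C, d[4])))
    y <- ag_mul(x, cgate)                            # channel gate first
    ag_mul(y, ag_upsample_to(sgate, d[1], d[2]))
  }
  m
}

#' Compress a feature map into channel and spatial descriptors
#' @param f a C x H x W array
#' @param module optional pre-built [nn_cscbam()]
#' @param init weight init when building a fresh module
#' @return list with `channel` (length C) and `spatial` (H x W matrix)
#' @export
cscbam_compress <- function(f, module = NULL, init = "random") {
  mod <- module %||% nn_cscbam(dim(f)[1], init = init)
  d <- mod$compress(ag_const(chw_to_t(f)))
  list(channel = as.numeric(ag_value(d$channel)),
       spatial = matrix(ag_value(d$spatial), dim(f)[2], dim(f)[3]))
}

#' Joint channel-spatial interaction
#'
#' Flattens the spatial descriptor, concatenates it with the channel
#' descriptor to a vector of length `H*W + C` and runs the interaction MLP
#' at that size (identity or zero initialization reproduce the raw
#' concatenation or the zero vector respectively).
#'
#' @param pair list with `channel` (length C) and `spatial` (H x W matrix)
#' @param init `"random"`, `"zero"` or `"identity"`
#' @param hidden_ratio hidden width fraction (ignored for `"identity"`,
#'   which requires a square MLP)
#' @return numeric joint descriptor of length `H*W + C`
#' @export
cscbam_interact <- function(pair, init = "random", hidden_ratio = 0.25) {
  v <- c(as.numeric(pair$spatial), as.numeric(pair$channel))
  D <- length(v)
  hidden <- if (identical(init, "identity")) D
            else max(4L, as.integer(round(hidden_ratio * D)))
  l1 <- nn_linear(D, hidden); l2 <- nn_linear(hidden, D)
  if (identical(init, "zero")) {
    l1$params$w$v[] <- 0; l2$params$w$v[] <- 0
    l1$params$b$v[] <- 0; l2$params$b$v[] <- 0
  } else if (identical(init, "identity")) {
    l1$params$w$v <- diag(D); l2$params$w$v <- diag(D)
    l1$params$b$v[] <- 0; l2$params$b$v[] <- 0
  }
  as.numeric(ag_value(l2$forward(ag_relu(l1$forward(ag_const(matrix(v, ncol = 1)))))))
}

#' Apply CSCBAM attention to a feature map
#' @param f a C x H x W array
#' @param module optional pre-built [nn_cscbam()]
#' @param init weight init when building a fresh module
#' @return gated feature map, same shape; all gates lie strictly in (0,1)
#' @export
cscbam_apply <- function(f, module = NULL, init = "random") {
  mod <- module %||% nn_cscbam(dim(f)[1], init = init)
  module_apply(mod, f)
}
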