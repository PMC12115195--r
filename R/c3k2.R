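# C3k2 cross-stage-partial blocks and the CFCGLU / CSCBAM substitutions.
#
# Baseline wiring: a 1x1 conv widens to two hidden halves; the second half
# passes through a chain of units whose outputs are all concatenated with
# both halves before a 1x1 fusion conv. The substituted variants keep this
# skeleton and replace the bottleneck units: CFCGLU uses a CAFormer
# separation/reconstruction unit followed by a CGLU mixer; CSCBAM replaces
# every unit with a joint channel-spatial attention gate, and the block then
# carries exactly one BN and one ReLU (inserted before the fusion conv), so
# its plain convolutions run without their own normalization.

#' C3k2 block (baseline or substituted variant)
#'
#' @param cin,cout block widths
#' @param n number of chained units (default 2)
#' @param unit `"bottleneck"` (baseline), `"cfcglu"` or `"cscbam"`
#' @param e hidden expansion ratio (default 0.5)
#' @param opts options list for the substituted units: `t`, `ratios`,
#'   `groups` (cfcglu); a [cscbam_config()] template under `cscbam`
#' @return an `nn_module`
#' @export
nn_c3k2 <- function(cin, cout, n = 2L, unit = "bottleneck", e = 0.5,
                    opts = list(), label = paste0("c3k2_", unit)) {
  h <- max(2L, round_to(cout * e, 2L))
  m <- new_module(label)
  plain <- identical(unit, "cscbam")   # single-BN variant: no BN in the convs
  if (plain) {
    add_child(m, "cv1", nn_conv2d(cin, 2L * h, 1L, bias = TRUE))
    add_child(m, "bn", nn_bn2d((2L + n) * h))
    add_child(m, "cv2", nn_conv2d((2L + n) * h, cout, 1L, bias = TRUE))
  } else {
    add_child(m, "cv1", nn_cbs(cin, 2L * h, 1L))
    add_child(m, "cv2", nn_cbs((2L + n) * h, cout, 1L))
  }
  units <- list()
  for (i in seq_len(n)) {
    u <- switch(unit,
      bottleneck = nn_bottleneck(h),
      cfcglu = if (i == 1L)
          nn_caformer(h, t = opts$t %||% 0.5)
        else
          nn_cglu(h, h, ratios = opts$ratios %||% split_ratios(),
                  groups = opts$groups %||% 2L),
      cscbam = nn_cscbam(cscbam_config(
        h,
        reduction = opts$reduction %||% 16L,
        interact_hidden_ratio = opts$interact_hidden_ratio %||% 0.25,
        spatial_tokens = opts$spatial_tokens %||% 8L)),
      stop("nn_c3k2: unknown unit kind"))
    units[[i]] <- add_child(m, paste0("u", i), u)
  }
  m$meta <- list(cin = cin, cout = cout, n = n, unit = unit, h = h)
  m$forward <- function(x) {
    if (dim(x$v)[3] != cin) stop("c3k2: channel mismatch")
    y0 <- m$children$cv1$forward(x)
    if (plain) y0 <- ag_silu(y0)
    a <- ag_slice_c(y0, 1L, h)
    b <- ag_slice_c(y0, h + 1L, 2L * h)
    outs <- list(a, b)
    cur <- b
    for (i in seq_len(n)) {
      cur <- m$children[[paste0("u", i)]]$forward(cur)
      outs[[length(outs) + 1L]] <- cur
    }
    z <- ag_concat_c(outs)
    if (plain) z <- ag_relu(m$children$bn$forward(z))
    m$children$cv2$forward(z)
  }
  m
}

#' Run a C3k2-CFCGLU block on a feature map
#' @param x a C x H x W array
#' @param cout output channels (default: input channels)
#' @param t CAFormer threshold
#' @param ratios CGLU [split_ratios()]
#' @param module optional pre-built block
#' @return feature map with `cout` channels and unchanged spatial size
#' @export
c3k2_cfcglu_block <- function(x, cout = NULL, t = 0.5,
                              ratios = split_ratios(), module = NULL) {
  mod <- module %||% nn_c3k2(dim(x)[1], cout %||% dim(x)[1], unit = "cfcglu",
                             opts = list(t = t, ratios = ratios))
  module_apply(mod, x)
}

#' Run a C3k2-CSCBAM block on a feature map
#' @param x a C x H x W array
#' @param cout output channels (default: input channels)
#' @param module optional pre-built block
#' @return feature map with `cout` channels and unchanged spatial size
#' @export
c3k2_cscbam_block <- function(x, cout = NULL, module = NULL) {
  mod <- module %||% nn_c3k2(dim(x)[1], cout %||% dim(x)[1], unit = "cscbam")
  module_apply(mod, x)
}

#' Count primitive layers of a given kind in a module tree
#' @param mod an `nn_module`
#' @param kind module label to count, e.g. `"bn"`
#' @return integer count
#' @export
count_layers <- function(mod, kind) {
  n <- as.integer(identical(mod$label, kind))
  for (ch in mod$children) n <- n + count_layers(ch, kind)
  n
}

#' Count ReLU applications in one forward pass of a module
#' @param mod an `nn_module`
#' @param x a C x H x W array to feed through
#' @return integer number of ReLU op calls
#' @export
count_relu_calls <- function(mod, x) {
  .ag_state$relu_count <- 0L
  on.exit(.ag_state$relu_count <- NULL)
  invisible(mod$forward(ag_const(chw_to_t(x))))
  .ag_state$relu_count
}
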