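# Full detector assembly.
#
# Layout (stages indexed from 0, strides in parentheses):
#   backbone: conv/2, conv/2, C3k2 (P2, /4), conv/2, C3k2 (P3, /8),
#             conv/2, C3k2 (P4, /16), conv/2, C3k2 (/32), SPPF (P5, /32)
#   neck:     top-down FPN (two upsampling C3k2 blocks), bottom-up PAN
#   heads:    strides 8/16/32, plus an optional stride-4 small-object branch
#             fed by the backbone P2 tap merged with an SPPFLKC-gated context
#             path and terminated by a detail-enhanced-convolution head.
#
# Substitution flags mirror the ablation columns: `cfcglu` replaces the
# backbone C3k2 blocks, `sppflkc` the SPPF, `cscbam` the two upsampling neck
# C3k2 blocks (and the small-object branch block), `sdl` enables the
# stride-4 head.

.rd_scales <- list(
  # official nano-width reference
  official_n = list(channels = c(16L, 32L, 64L, 128L, 256L), n_units = 1L),
  # calibrated so the unmodified baseline reproduces the printed complexity
  # of the reference model this package re-implements (see vignette)
  calibrated = list(channels = c(16L, 32L, 80L, 200L, 488L), n_units = 2L),
  # desk-scale configuration for tests and the overfit sanity run
  micro = list(channels = c(8L, 16L, 24L, 32L, 48L), n_units = 1L)
)

#' Model specification
#'
#' @param num_classes number of object classes (default 3 disease classes)
#' @param input_size square input resolution in pixels
#' @param scale `"calibrated"`, `"official_n"`, `"micro"`, or a list with
#'   `channels` (5 stage widths) and `n_units`
#' @param sdl,sppflkc,cfcglu,cscbam substitution flags
#' @param head_stride stride of the small-object head (default 4)
#' @param lskac list with `k`, `d` for all LSKAC gates
#' @param cfcglu_opts list: `t` (CAFormer threshold), `alpha`, `beta` (CGLU
#'   split ratios), `groups` (group-wise conv groups)
#' @param cscbam_opts list: `reduction`, `interact_hidden_ratio`,
#'   `spatial_tokens`
#' @param pool_kernel SPPF/SPPFLKC pooling kernel (odd, default 5)
#' @return an `rd_model_spec`
#' @export
rd_model_spec <- function(num_classes = 3L, input_size = 640L,
                          scale = "calibrated",
                          sdl = FALSE, sppflkc = FALSE,
                          cfcglu = FALSE, cscbam = FALSE,
                          head_stride = 4L,
                          lskac = list(k = 23L, d = 3L),
                          cfcglu_opts = list(t = 0.5, alpha = 0.5,
                                             beta = 0.25, groups = 2L),
                          cscbam_opts = list(reduction = 16L,
                                             interact_hidden_ratio = 0.25,
                                             spatial_tokens = 8L),
                          pool_kernel = 5L) {
  sc <- if (is.character(scale)) {
    if (!scale %in% names(.rd_scales)) stop("rd_model_spec: unknown scale")
    .rd_scales[[scale]]
  } else scale
  if (length(sc$channels) != 5L) stop("rd_model_spec: need 5 stage widths")
  if (!head_stride %in% c(2L, 4L)) stop("rd_model_spec: head_stride must be 2 or 4")
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 scale = sc, scale_name = if (is.character(scale)) scale else "custom",
                 flags = list(sdl = isTRUE(sdl), sppflkc = isTRUE(sppflkc),
                              cfcglu = isTRUE(cfcglu), cscbam = isTRUE(cscbam)),
                 head_stride = as.integer(head_stride),
                 lskac = lskac, cfcglu_opts = cfcglu_opts,
                 cscbam_opts = cscbam_opts,
                 pool_kernel = as.integer(pool_kernel)),
            class = "rd_model_spec")
}

# plain SPPF baseline block
nn_sppf <- function(cin, cout, k = 5L, label = "sppf") {
  h <- max(2L, cin %/% 2L)
  m <- new_module(label)
  add_child(m, "cv1", nn_cbs(cin, h, 1L))
  add_child(m, "cv2", nn_cbs(4L * h, cout, 1L))
  m$forward <- function(x) {
    a <- m$children$cv1$forward(x)
    p1 <- ag_maxpool(a, k, 1L)
    p2 <- ag_maxpool(p1, k, 1L)
    p3 <- ag_maxpool(p2, k, 1L)
    m$children$cv2$forward(ag_concat_c(list(a, p1, p2, p3)))
  }
  m
}

#' Build the detector
#'
#' @param spec an [rd_model_spec()]
#' @return an `rd_model`: a module tree with `$forward(x)` mapping an
#'   (H,W,3,N) input tensor to a named list of per-stride head grids
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "rd_model_spec"))
  ch <- spec$scale$channels
  nu <- spec$scale$n_units
  fl <- spec$flags
  nc <- spec$num_classes
  lk <- function(C) lskac_config(C, spec$lskac$k %||% 23L, spec$lskac$d %||% 3L)
  bb_unit <- if (fl$cfcglu) "cfcglu" else "bottleneck"
  up_unit <- if (fl$cscbam) "cscbam" else "bottleneck"
  # cfcglu alternates CAFormer/CGLU, so its chains need an even unit count
  bb_n <- if (fl$cfcglu) max(2L, nu) else nu
  co <- spec$cfcglu_opts
  bb_opts <- list(t = co$t, ratios = split_ratios(co$alpha %||% 0.5,
                                                  co$beta %||% 0.25),
                  groups = co$groups)
  up_opts <- spec$cscbam_opts

  M <- new_module("model")
  add_child(M, "b0", nn_cbs(3L, ch[1], 3L, stride = 2L))
  add_child(M, "b1", nn_cbs(ch[1], ch[2], 3L, stride = 2L))
  add_child(M, "b2", nn_c3k2(ch[2], ch[2], n = bb_n, unit = bb_unit, opts = bb_opts))
  add_child(M, "b3", nn_cbs(ch[2], ch[3], 3L, stride = 2L))
  add_child(M, "b4", nn_c3k2(ch[3], ch[3], n = bb_n, unit = bb_unit, opts = bb_opts))
  add_child(M, "b5", nn_cbs(ch[3], ch[4], 3L, stride = 2L))
  add_child(M, "b6", nn_c3k2(ch[4], ch[4], n = bb_n, unit = bb_unit, opts = bb_opts))
  add_child(M, "b7", nn_cbs(ch[4], ch[5], 3L, stride = 2L))
  add_child(M, "b8", nn_c3k2(ch[5], ch[5], n = bb_n, unit = bb_unit, opts = bb_opts))
  if (fl$sppflkc) {
    add_child(M, "b9", nn_sppflkc(sppflkc_config(ch[5], ch[5],
                                              pool_kernel = spec$pool_kernel,
                                              lskac = spec$lskac)))
  } else {
    add_child(M, "b9", nn_sppf(ch[5], ch[5], k = spec$pool_kernel))
  }
  # top-down
  add_child(M, "n1", nn_c3k2(ch[5] + ch[4], ch[4], n = nu, unit = up_unit, opts = up_opts))
  add_child(M, "n2", nn_c3k2(ch[4] + ch[3], ch[3], n = nu, unit = up_unit, opts = up_opts))
  # bottom-up
  add_child(M, "n3d", nn_cbs(ch[3], ch[3], 3L, stride = 2L))
  add_child(M, "n3", nn_c3k2(ch[3] + ch[4], ch[4], n = nu))
  add_child(M, "n4d", nn_cbs(ch[4], ch[4], 3L, stride = 2L))
  add_child(M, "n4", nn_c3k2(ch[4] + ch[5], ch[5], n = nu))
  # heads
  add_child(M, "h3", nn_head(ch[3], nc))
  add_child(M, "h4", nn_head(ch[4], nc))
  add_child(M, "h5", nn_head(ch[5], nc))
  if (fl$sdl) {
    add_child(M, "s_ctx", nn_sppflkc(sppflkc_config(ch[3], ch[2],
                                              pool_kernel = spec$pool_kernel,
                                              lskac = spec$lskac)))
    add_child(M, "s_blk", nn_c3k2(2L * ch[2], ch[2], n = nu, unit = up_unit, opts = up_opts))
    add_child(M, "h2", nn_head(ch[2], nc, deconv = TRUE))
  }
  M$spec <- spec
  strides <- c(if (fl$sdl) spec$head_stride, 8L, 16L, 32L)
  M$strides <- strides
  M$forward <- function(x) {
    p2 <- with_label("backbone", {
      x1 <- M$children$b1$forward(M$children$b0$forward(x))
      M$children$b2$forward(x1)
    })
    p3 <- with_label("backbone", M$children$b4$forward(M$children$b3$forward(p2)))
    p4 <- with_label("backbone", M$children$b6$forward(M$children$b5$forward(p3)))
    p5 <- with_label("backbone", M$children$b9$forward(
      M$children$b8$forward(M$children$b7$forward(p4))))
    t4 <- with_label("neck", M$children$n1$forward(
      ag_concat_c(list(ag_upsample(p5, 2L), p4))))
    t3 <- with_label("neck", M$children$n2$forward(
      ag_concat_c(list(ag_upsample(t4, 2L), p3))))
    t4b <- with_label("neck", M$children$n3$forward(
      ag_concat_c(list(M$children$n3d$forward(t3), t4))))
    t5 <- with_label("neck", M$children$n4$forward(
      ag_concat_c(list(M$children$n4d$forward(t4b), p5))))
    out <- list()
    if (fl$sdl) {
      t2 <- with_label("sdl", {
        up <- ag_upsample(t3, 2L)
        if (spec$head_stride == 2L) up <- ag_upsample(up, 2L)
        ctx <- M$children$s_ctx$forward(up)
        base <- if (spec$head_stride == 2L) ag_upsample(p2, 2L) else p2
        M$children$s_blk$forward(ag_concat_c(list(base, ctx)))
      })
      out[[paste0("stride", spec$head_stride)]] <-
        with_label("head2", M$children$h2$forward(t2))
    }
    out$stride8 <- with_label("head3", M$children$h3$forward(t3))
    out$stride16 <- with_label("head4", M$children$h4$forward(t4b))
    out$stride32 <- with_label("head5", M$children$h5$forward(t5))
    out
  }
  class(M) <- c("rd_model", class(M))
  M
}

#' Structural complexity of an assembled model
#'
#' Parameters are counted from the stored weight arrays; FLOPs (one
#' multiply-accumulate counted as one FLOP) are measured by tracing a forward
#' pass at the requested input size, so the totals reflect the graph that
#' actually executes.
#'
#' @param model an `rd_model`
#' @param input_size square input resolution (defaults to the spec's)
#' @return a `complexity_report` with a per-stage breakdown
#' @export
count_complexity <- function(model, input_size = NULL) {
  sz <- input_size %||% model$spec$input_size
  x <- ag_const(array(0, c(sz, sz, 3L, 1L)))
  was <- set_training(FALSE)
  on.exit(set_training(was))
  ag_trace_start()
  invisible(model$forward(x))
  tr <- ag_trace_stop()
  stage <- sub("/.*", "", tr$label)
  agg <- stats::aggregate(cbind(params, flops) ~ stage, data =
                            transform(tr, stage = stage), FUN = sum)
  names(agg)[1] <- "layer"
  rep <- complexity_report(agg)
  # parameters: authoritative count from the stored weights (the trace
  # misses none because every layer runs exactly once, but DEConv executes
  # in re-parameterized form; stored weights are the source of truth)
  rep$parameter_count <- param_count(model)
  rep
}

#' Trace-level complexity (independent per-layer measurement)
#' @param model an `rd_model`
#' @param input_size square input resolution
#' @return data.frame with one row per executed layer (label, params, flops)
#' @export
complexity_trace <- function(model, input_size = NULL) {
  sz <- input_size %||% model$spec$input_size
  was <- set_training(FALSE)
  on.exit(set_training(was))
  ag_trace_start()
  invisible(model$forward(ag_const(array(0, c(sz, sz, 3L, 1L)))))
  ag_trace_stop()
}

#' @export
print.rd_model <- function(x, ...) {
  cat(sprintf("rd_model (%s scale): flags %s; %s parameters; strides %s\n",
              x$spec$scale_name,
              paste(names(Filter(isTRUE, x$spec$flags)), collapse = "+"),
              format(param_count(x), big.mark = ","),
              paste(x$strides, collapse = "/")))
  invisible(x)
}

#' Forward pass on one image
#' @param model an `rd_model`
#' @param img H x W x 3 array in `[0,1]`
#' @return named list of head grids (H,W,5+nc) per stride
#' @export
model_forward <- function(model, img) {
  d <- dim(img)
  x <- ag_const(array(img, c(d[1], d[2], 3L, 1L)))
  was <- set_training(FALSE)
  on.exit(set_training(was))
  out <- model$forward(x)
  lapply(out, function(o) array(ag_value(o), dim(o$v)[1:3]))
}
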