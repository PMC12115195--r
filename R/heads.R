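# Detection heads. Each head predicts, per grid cell, box offsets
# (tx, ty, tw, th), an objectness logit and per-class logits. The
# small-object head uses a detail-enhanced convolution (DEConv): the sum of a
# vanilla 3x3 kernel and four difference-constrained kernels (central,
# angular, horizontal, vertical), which collapses to a single 3x3 kernel by
# linearity and is executed in that re-parameterized form.

# effective-kernel transforms of the difference branches; each takes the raw
# weight node (3,3,cin,cout) and returns the constrained kernel node
.deconv_transforms <- function() {
  sub_bcast <- function(theta, red, expand) {
    tv <- theta$v
    ag_node(tv - expand(red(tv)), list(theta), function(g)
      list(g - expand(red(g))))
  }
  list(
    vanilla = function(theta) theta,
    central = function(theta) {
      tv <- theta$v
      v <- tv
      s <- apply(tv, c(3, 4), sum)
      v[2, 2, , ] <- v[2, 2, , ] - s
      # K[i,j] = theta[i,j] - [i=j=2]*sum(theta)  =>  dtheta = g - g[2,2]
      ag_node(v, list(theta), function(g) {
        gs <- g[2, 2, , ]
        gg <- g
        for (i in 1:3) for (j in 1:3) gg[i, j, , ] <- g[i, j, , ] - gs
        list(gg)
      })
    },
    angular = function(theta) sub_bcast(theta,
      red = function(v) apply(v, c(3, 4), mean),
      expand = function(r) {
        out <- array(0, dim(theta$v))
        for (i in 1:3) for (j in 1:3) out[i, j, , ] <- r
        out
      }),
    horizontal = function(theta) sub_bcast(theta,
      red = function(v) apply(v, c(1, 3, 4), mean),
      expand = function(r) {
        out <- array(0, dim(theta$v))
        for (j in 1:3) out[, j, , ] <- r
        out
      }),
    vertical = function(theta) sub_bcast(theta,
      red = function(v) apply(v, c(2, 3, 4), mean),
      expand = function(r) {
        out <- array(0, dim(theta$v))
        for (i in 1:3) out[i, , , ] <- r
        out
      })
  )
}

#' Detail-enhanced convolution (sum of five constrained 3x3 kernels)
#' @param cin,cout channel widths
#' @return an `nn_module`; `$effective_kernel()` yields the re-parameterized
#'   single 3x3 kernel
#' @export
nn_deconv <- function(cin, cout, label = "deconv") {
  m <- new_module(label)
  tr <- .deconv_transforms()
  for (nm in names(tr))
    add_param(m, nm, .kaiming(c(3, 3, cin, cout), fan_in = 9 * cin) / length(tr))
  add_param(m, "b", numeric(cout))
  m$meta <- list(cin = cin, cout = cout)
  m$effective <- function() {
    ks <- lapply(names(tr), function(nm) tr[[nm]](m$params[[nm]]))
    Reduce(ag_add, ks)
  }
  m$effective_kernel <- function() ag_value(m$effective())
  m$forward <- function(x) {
    ag_conv2d(x, m$effective(), m$params$b)
  }
  m
}

# plain detection head tower
nn_head <- function(cin, num_classes, hidden = NULL, deconv = FALSE,
                    label = "head") {
  hh <- hidden %||% max(16L, round_to(cin / 2, 2L))
  nout <- 5L + num_classes
  m <- new_module(label)
  if (deconv) add_child(m, "t1", nn_deconv(cin, hh))
  else add_child(m, "t1", nn_cbs(cin, hh, 3L))
  add_child(m, "t2", nn_cbs(hh, hh, 3L))
  add_child(m, "out", nn_conv2d(hh, nout, 1L, bias = TRUE))
  # start with a low objectness prior so early decoding is conservative
  m$children$out$params$b$v[5L] <- -4
  m$forward <- function(x) {
    z <- m$children$t1$forward(x)
    if (deconv) z <- ag_silu(z)
    m$children$out$forward(m$children$t2$forward(z))
  }
  m
}
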