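# Reverse-mode define-by-run tape over dense arrays.
#
# Tensors are numeric arrays with dim (H, W, C, N); vector-valued
# intermediates (descriptors, logits gathered per grid cell) are D x N
# matrices. Every op returns an `ag` node: an environment holding the value,
# its parents and a closure computing parent gradients.

.ag_state <- new.env(parent = emptyenv())
.ag_state$counter <- 0L

ag_node <- function(v, parents = list(), backfn = NULL) {
  # force the promises before taking a tape id: argument expressions may
  # themselves create parent nodes, and topological order follows the id
  force(parents); force(v); force(backfn)
  e <- new.env(parent = emptyenv())
  .ag_state$counter <- .ag_state$counter + 1L
  e$nid <- .ag_state$counter
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$requires <- length(parents) > 0L &&
    any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  class(e) <- "ag"
  e
}

#' Create a trainable parameter node
#' @param v numeric array of initial values
#' @return an `ag` leaf node with gradient tracking enabled
#' @export
ag_param <- function(v) {
  e <- ag_node(v)
  e$requires <- TRUE
  e
}

#' Wrap a value as a non-tracked tape node
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_const <- function(v) ag_node(v)

#' Coerce to a tape node
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
as_ag <- function(x) if (inherits(x, "ag")) x else ag_const(x)

#' Extract the value of a tape node
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_value <- function(x) x$v

# accumulate gradient g into node p
.ag_acc <- function(p, g) {
  if (!isTRUE(p$requires)) return(invisible(NULL))
  if (is.null(g)) return(invisible(NULL))
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(NULL)
}

#' Run reverse-mode differentiation from a scalar root
#' @param root an `ag` node holding a scalar value
#' @return the root, invisibly; leaf gradients are in `$grad`
#' @export
ag_backward <- function(root) {
  stopifnot(length(root$v) == 1L)
  # collect reachable nodes, ordered by creation id
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$nid)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[key]] <- nd
    for (p in nd$parents) if (isTRUE(p$requires)) stack[[length(stack) + 1L]] <- p
  }
  ids <- sort(as.integer(names(nodes)), decreasing = TRUE)
  root$grad <- 1
  for (id in ids) {
    nd <- nodes[[as.character(id)]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) .ag_acc(nd$parents[[i]], gs[[i]])
    if (!is.null(nd$backfn)) nd$grad <- nd$grad  # keep for diagnostics
  }
  invisible(root)
}

.same_dim <- function(a, b) identical(dim(a) %||% length(a), dim(b) %||% length(b))

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise arithmetic ------------------------------------------------

# broadcast patterns supported for 4-D tensors:
#   b has dim (1,1,C,N)  -> channel-wise broadcast
#   b has dim (H,W,1,N)  -> spatial broadcast
# expansion/reduction work on flat vectors to avoid apply() overhead
.bcast_mul <- function(bv, xdim) {
  bd <- dim(bv)
  if (identical(bd, xdim)) return(bv)
  HW <- xdim[1] * xdim[2]
  if (length(bd) == 4L && bd[1] == 1L && bd[2] == 1L) {
    out <- rep(as.vector(bv), each = HW)
    dim(out) <- xdim
    out
  } else if (length(bd) == 4L && bd[3] == 1L) {
    bm <- matrix(bv, HW, xdim[4])
    out <- bm[, rep(seq_len(xdim[4]), each = xdim[3]), drop = FALSE]
    dim(out) <- xdim
    out
  } else stop("unsupported broadcast")
}

.bcast_reduce <- function(g, bdim) {
  gd <- dim(g)
  if (identical(gd, bdim)) return(g)
  HW <- gd[1] * gd[2]; C <- gd[3]; N <- gd[4]
  if (bdim[1] == 1L && bdim[2] == 1L) {
    out <- .colSums(g, HW, C * N)
    dim(out) <- bdim
    out
  } else if (bdim[3] == 1L) {
    gm <- matrix(g, HW, C * N)
    out <- matrix(0, HW, N)
    for (n in seq_len(N)) out[, n] <- rowSums(gm[, (n - 1L) * C + seq_len(C), drop = FALSE])
    dim(out) <- bdim
    out
  } else stop("unsupported broadcast reduce")
}

#' Engine op: `ag_add`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  if (!is.null(dim(a$v)) && !is.null(dim(b$v)) &&
      length(dim(a$v)) == 4L && !identical(dim(a$v), dim(b$v))) {
    bd <- dim(b$v); xd <- dim(a$v)
    v <- a$v + .bcast_mul(b$v, xd)
    return(ag_node(v, list(a, b), function(g) list(g, .bcast_reduce(g, bd))))
  }
  ag_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

#' Engine op: `ag_sub`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

#' Engine op: `ag_mul`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$v; bv <- b$v
  if (!is.null(dim(av)) && length(dim(av)) == 4L && !is.null(dim(bv)) &&
      !identical(dim(av), dim(bv))) {
    xd <- dim(av); bd <- dim(bv)
    bb <- .bcast_mul(bv, xd)
    return(ag_node(av * bb, list(a, b), function(g)
      list(g * bb, .bcast_reduce(g * av, bd))))
  }
  ag_node(av * bv, list(a, b), function(g) {
    ga <- g * bv
    gb <- g * av
    if (length(av) > 1 && length(bv) == 1) gb <- sum(gb)
    if (length(bv) > 1 && length(av) == 1) ga <- sum(ga)
    list(ga, gb)
  })
}

# m (D x N) scaled per row by vec (length D)
#' Engine op: `ag_colwise_mul`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_colwise_mul <- function(m, vec) {
  mv <- m$v; vv <- vec$v
  ag_node(mv * vv, list(m, vec), function(g)
    list(g * vv, rowSums(g * mv)))
}

#' Engine op: `ag_scale`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_scale <- function(a, s) {  # s plain numeric scalar
  a <- as_ag(a)
  ag_node(a$v * s, list(a), function(g) list(g * s))
}

#' Engine op: `ag_div`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$v; bv <- b$v
  ag_node(av / bv, list(a, b), function(g) {
    gb <- -g * av / bv^2
    if (length(av) > 1 && length(bv) == 1) gb <- sum(gb)
    list(g / bv, gb)
  })
}

#' Engine op: `ag_pow`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_pow <- function(a, p) {
  a <- as_ag(a)
  ag_node(a$v^p, list(a), function(g) list(g * p * a$v^(p - 1)))
}

#' Engine op: `ag_pmax`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_pmax <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  m <- a$v >= b$v
  ag_node(pmax(a$v, b$v), list(a, b), function(g) list(g * m, g * !m))
}

#' Engine op: `ag_pmin`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_pmin <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  m <- a$v <= b$v
  ag_node(pmin(a$v, b$v), list(a, b), function(g) list(g * m, g * !m))
}

#' Engine op: `ag_clamp_min`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_clamp_min <- function(a, lo) {
  a <- as_ag(a)
  m <- a$v > lo
  ag_node(pmax(a$v, lo), list(a), function(g) list(g * m))
}

# ---- nonlinearities --------------------------------------------------------

#' Engine op: `ag_relu`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_relu <- function(a) {
  if (!is.null(.ag_state$relu_count))
    .ag_state$relu_count <- .ag_state$relu_count + 1L
  m <- a$v > 0
  ag_node(a$v * m, list(a), function(g) list(g * m))
}

#' Engine op: `ag_sigmoid`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

#' Engine op: `ag_silu`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_silu <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ag_node(a$v * s, list(a), function(g) list(g * (s * (1 + a$v * (1 - s)))))
}

#' Engine op: `ag_gelu`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_gelu <- function(a) {  # tanh approximation
  x <- a$v
  k <- sqrt(2 / pi)
  t <- tanh(k * (x + 0.044715 * x^3))
  y <- 0.5 * x * (1 + t)
  ag_node(y, list(a), function(g) {
    dt <- (1 - t^2) * k * (1 + 3 * 0.044715 * x^2)
    list(g * (0.5 * (1 + t) + 0.5 * x * dt))
  })
}

#' Engine op: `ag_exp`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_exp <- function(a) {
  e <- exp(a$v)
  ag_node(e, list(a), function(g) list(g * e))
}

#' Engine op: `ag_log`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_log <- function(a) ag_node(log(a$v), list(a), function(g) list(g / a$v))

#' Engine op: `ag_sqrt`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_sqrt <- function(a) {
  s <- sqrt(a$v)
  ag_node(s, list(a), function(g) list(g * 0.5 / s))
}

#' Engine op: `ag_atan`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_atan <- function(a) ag_node(atan(a$v), list(a), function(g) list(g / (1 + a$v^2)))

#' Engine op: `ag_tanh`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_tanh <- function(a) {
  t <- tanh(a$v)
  ag_node(t, list(a), function(g) list(g * (1 - t^2)))
}

# softmax over rows of a D x N matrix (per column / per sample)
#' Engine op: `ag_softmax`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_softmax <- function(a) {
  v <- a$v
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  mx <- apply(v, 2, max)
  e <- exp(sweep(v, 2, mx))
  s <- sweep(e, 2, colSums(e), "/")
  if (is.null(dim(a$v))) s_out <- drop(s) else s_out <- s
  ag_node(s_out, list(a), function(g) {
    gm <- if (is.null(dim(g))) matrix(g, ncol = 1) else g
    dot <- colSums(gm * s)
    out <- s * sweep(gm, 2, dot)
    list(if (is.null(dim(a$v))) drop(out) else out)
  })
}

# ---- reductions ------------------------------------------------------------

.full_like <- function(v, fill) {
  out <- rep(fill, length.out = length(v))
  dim(out) <- dim(v)
  out
}

#' Engine op: `ag_sum`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_sum <- function(a) ag_node(sum(a$v), list(a), function(g) list(.full_like(a$v, g)))

#' Engine op: `ag_mean`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_mean <- function(a) {
  n <- length(a$v)
  ag_node(sum(a$v) / n, list(a), function(g) list(.full_like(a$v, g / n)))
}

# ---- structural ops --------------------------------------------------------

# channel concat of 4-D tensors
#' Engine op: `ag_concat_c`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_concat_c <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$v))
  Cs <- vapply(dims, function(d) d[3], numeric(1))
  d1 <- dims[[1]]
  v <- array(0, c(d1[1], d1[2], sum(Cs), d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x$v)[3]
    v[, , at + seq_len(cc), ] <- x$v
    at <- at + cc
  }
  offs <- cumsum(c(0, Cs))
  ag_node(v, xs, function(g) {
    lapply(seq_along(xs), function(i)
      array(g[, , offs[i] + seq_len(Cs[i]), , drop = FALSE],
            dim = c(d1[1], d1[2], Cs[i], d1[4])))
  })
}

#' Engine op: `ag_slice_c`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_slice_c <- function(x, from, to) {
  d <- dim(x$v)
  v <- array(x$v[, , from:to, , drop = FALSE], dim = c(d[1], d[2], to - from + 1L, d[4]))
  ag_node(v, list(x), function(g) {
    out <- array(0, d)
    out[, , from:to, ] <- g
    list(out)
  })
}

# rbind for D x N matrices
#' Engine op: `ag_rbind`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_rbind <- function(a, b) {
  av <- a$v; bv <- b$v
  na <- nrow(av)
  ag_node(rbind(av, bv), list(a, b), function(g)
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE]))
}

#' Engine op: `ag_rows`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_rows <- function(x, idx) {
  d <- dim(x$v)
  ag_node(x$v[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, d[1], d[2])
    out[idx, ] <- out[idx, ] + g
    list(out)
  })
}

#' Engine op: `ag_cols`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_cols <- function(x, idx) {
  d <- dim(x$v)
  ag_node(x$v[, idx, drop = FALSE], list(x), function(g) {
    out <- matrix(0, d[1], d[2])
    # idx may repeat; accumulate
    for (j in seq_along(idx)) out[, idx[j]] <- out[, idx[j]] + g[, j]
    list(out)
  })
}

# flatten (H,W,C,N) -> (C x H*W*N) with channel first; cells ordered (h,w,n)
#' Engine op: `ag_flatten_cells`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_flatten_cells <- function(x) {
  d <- dim(x$v)
  v <- aperm(x$v, c(3, 1, 2, 4))
  dim(v) <- c(d[3], d[1] * d[2] * d[4])
  ag_node(v, list(x), function(g) {
    dim(g) <- c(d[3], d[1], d[2], d[4])
    list(aperm(g, c(2, 3, 1, 4)))
  })
}

# flatten (H,W,C,N) -> (H*W*C x N)
#' Engine op: `ag_flatten`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_flatten <- function(x) {
  d <- dim(x$v)
  v <- x$v
  dim(v) <- c(d[1] * d[2] * d[3], d[4])
  ag_node(v, list(x), function(g) { dim(g) <- d; list(g) })
}

#' Engine op: `ag_reshape`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_reshape <- function(x, newdim) {
  d <- dim(x$v) %||% length(x$v)
  v <- x$v
  dim(v) <- newdim
  ag_node(v, list(x), function(g) { dim(g) <- d; list(g) })
}

# ---- linear algebra --------------------------------------------------------

# y = W %*% x + b ; x: D x N, W: out x D, b: out
#' Engine op: `ag_linear`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_linear <- function(x, W, b = NULL) {
  xv <- x$v
  yv <- W$v %*% xv
  if (!is.null(b)) yv <- yv + b$v
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  ag_node(yv, parents, function(g) {
    gs <- list(t(W$v) %*% g, g %*% t(xv))
    if (!is.null(b)) gs <- c(gs, list(rowSums(g)))
    gs
  })
}

# ---- convolution / pooling / resampling ------------------------------------

# same-padding helper: total pad = dil*(k-1), split floor/ceil
.pad_same <- function(k, dil = 1L) {
  tot <- dil * (k - 1L)
  c(tot %/% 2L, tot - tot %/% 2L)
}

#' Engine op: `ag_conv2d`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_conv2d <- function(x, w, b = NULL, stride = 1L, dil = 1L, groups = 1L,
                      pad = NULL) {
  wd <- dim(w$v)
  if (is.null(pad)) {
    ph <- .pad_same(wd[1], dil); pw <- .pad_same(wd[2], dil)
  } else {
    ph <- pad[[1]]; pw <- pad[[2]]
  }
  has_bias <- !is.null(b)
  bv <- if (has_bias) b$v else numeric(1)
  y <- .conv2d_fwd(x$v, w$v, bv, as.integer(stride), as.integer(dil),
                   ph[1], ph[2], pw[1], pw[2], as.integer(groups), has_bias)
  .ag_trace_conv(dim(x$v), wd, dim(y), groups, has_bias)
  parents <- c(list(x, w), if (has_bias) list(b))
  ag_node(y, parents, function(g) {
    r <- .conv2d_bwd(x$v, w$v, g, as.integer(stride), as.integer(dil),
                     ph[1], ph[2], pw[1], pw[2], as.integer(groups), has_bias)
    gs <- list(r$dx, r$dw)
    if (has_bias) gs <- c(gs, list(as.numeric(r$db)))
    gs
  })
}

#' Engine op: `ag_maxpool`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_maxpool <- function(x, k, stride = 1L) {
  p <- if (stride == 1L) (k - 1L) %/% 2L else 0L
  r <- .maxpool_fwd(x$v, as.integer(k), as.integer(stride), p, p)
  d <- dim(x$v)
  ag_node(r$y, list(x), function(g)
    list(.maxpool_bwd(g, r$arg, d[1], d[2], d[3], d[4])))
}

#' Engine op: `ag_avgpool`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_avgpool <- function(x, k, stride = 1L) {
  p <- if (stride == 1L) (k - 1L) %/% 2L else 0L
  y <- .avgpool_fwd(x$v, as.integer(k), as.integer(stride), p, p)
  d <- dim(x$v)
  ag_node(y, list(x), function(g)
    list(.avgpool_bwd(g, as.integer(k), as.integer(stride), p, p,
                      d[1], d[2], d[3], d[4])))
}

# global average pool -> C x N matrix
#' Engine op: `ag_gap`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_gap <- function(x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  v <- .colMeans(x$v, HW, d[3] * d[4])
  dim(v) <- c(d[3], d[4])
  ag_node(v, list(x), function(g) {
    out <- rep(as.vector(g) / HW, each = HW)
    dim(out) <- d
    list(out)
  })
}

# global max pool over spatial -> C x N
#' Engine op: `ag_gmp`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_gmp <- function(x) {
  d <- dim(x$v)
  HW <- d[1] * d[2]
  xm <- x$v; dim(xm) <- c(HW, d[3], d[4])
  idx <- apply(xm, c(2, 3), which.max)
  v <- apply(xm, c(2, 3), max)
  dim(v) <- c(d[3], d[4])
  ag_node(v, list(x), function(g) {
    out <- array(0, c(HW, d[3], d[4]))
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      out[idx[c, n], c, n] <- g[c, n]
    dim(out) <- d
    list(out)
  })
}

# per-position max / mean over channels -> (H,W,1,N)
#' Engine op: `ag_cmax`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_cmax <- function(x) {
  d <- dim(x$v)
  idx <- apply(x$v, c(1, 2, 4), which.max)
  v <- apply(x$v, c(1, 2, 4), max)
  dim(v) <- c(d[1], d[2], 1L, d[4])
  ag_node(v, list(x), function(g) {
    out <- array(0, d)
    for (n in seq_len(d[4])) for (w in seq_len(d[2])) for (h in seq_len(d[1]))
      out[h, w, idx[h, w, n], n] <- g[h, w, 1, n]
    list(out)
  })
}

#' Engine op: `ag_cavg`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_cavg <- function(x) {
  d <- dim(x$v)
  v <- apply(x$v, c(1, 2, 4), mean)
  dim(v) <- c(d[1], d[2], 1L, d[4])
  ag_node(v, list(x), function(g) {
    out <- array(0, d)
    for (c in seq_len(d[3])) out[, , c, ] <- g[, , 1, ] / d[3]
    list(out)
  })
}

# nearest-neighbour integer upsample by factor f
#' Engine op: `ag_upsample`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_upsample <- function(x, f = 2L) {
  d <- dim(x$v)
  hi <- rep(seq_len(d[1]), each = f)
  wi <- rep(seq_len(d[2]), each = f)
  v <- x$v[hi, wi, , , drop = FALSE]
  ag_node(v, list(x), function(g) {
    # sum f x f blocks: collapse the two interleaved factors in turn
    g1 <- .colSums(g, f, length(g) / f)                 # over row factor
    dim(g1) <- c(d[1], f, d[2] * d[3] * d[4])
    g1 <- aperm(g1, c(2, 1, 3))
    g2 <- .colSums(g1, f, length(g1) / f)               # over col factor
    dim(g2) <- d
    list(g2)
  })
}

# adaptive average pooling to S x S (bin edges floor(i*H/S))
#' Engine op: `ag_adapt_avg`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_adapt_avg <- function(x, S) {
  d <- dim(x$v)
  hb <- floor(seq(0, d[1], length.out = S + 1))
  wb <- floor(seq(0, d[2], length.out = S + 1))
  v <- array(0, c(S, S, d[3], d[4]))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    hs <- (hb[i] + 1):hb[i + 1]; ws <- (wb[j] + 1):wb[j + 1]
    v[i, j, , ] <- apply(x$v[hs, ws, , , drop = FALSE], c(3, 4), mean)
  }
  ag_node(v, list(x), function(g) {
    out <- array(0, d)
    for (i in seq_len(S)) for (j in seq_len(S)) {
      hs <- (hb[i] + 1):hb[i + 1]; ws <- (wb[j] + 1):wb[j + 1]
      cnt <- length(hs) * length(ws)
      for (n in seq_len(d[4]))
        out[hs, ws, , n] <- as.vector(out[hs, ws, , n, drop = FALSE]) +
          rep(g[i, j, , n] / cnt, each = cnt)
    }
    list(out)
  })
}

# nearest upsample of (S,S,C,N) to (H,W,C,N); inverse map h -> floor(h*S/H)
#' Engine op: `ag_upsample_to`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_upsample_to <- function(x, H, W) {
  d <- dim(x$v)
  hi <- pmin(d[1], floor((seq_len(H) - 1) * d[1] / H) + 1)
  wi <- pmin(d[2], floor((seq_len(W) - 1) * d[2] / W) + 1)
  v <- x$v[hi, wi, , , drop = FALSE]
  ag_node(v, list(x), function(g) {
    out <- array(0, d)
    for (h in seq_len(H)) for (w in seq_len(W))
      out[hi[h], wi[w], , ] <- out[hi[h], wi[w], , ] + g[h, w, , ]
    list(out)
  })
}

# ---- normalization ---------------------------------------------------------

# batch norm over (H,W,N) per channel
#' Engine op: `ag_bn`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_bn <- function(x, gamma, beta, rm, rv, training, momentum = 0.03, eps = 1e-5) {
  d <- dim(x$v)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  csum <- function(a) {  # per-channel sums over (H,W,N)
    s <- .colSums(a, HW, C * N)
    dim(s) <- c(C, N)
    rowSums(s)
  }
  if (training) {
    mu <- csum(x$v) / (HW * N)
    va <- csum(x$v^2) / (HW * N) - mu^2
    rm$v <- (1 - momentum) * rm$v + momentum * mu
    rv$v <- (1 - momentum) * rv$v + momentum * va
  } else {
    mu <- rm$v; va <- rv$v
  }
  sd_ <- sqrt(pmax(va, 0) + eps)
  xhat <- (x$v - rep(mu, each = HW)) / rep(sd_, each = HW)
  y <- xhat * rep(gamma$v, each = HW) + rep(beta$v, each = HW)
  m <- HW * N
  ag_node(y, list(x, gamma, beta), function(g) {
    gg <- csum(g * xhat)
    gb <- csum(g)
    gam_sd <- gamma$v / sd_
    if (training) {
      # full batch-norm gradient
      gx <- g * rep(gam_sd, each = HW) -
        xhat * rep(gam_sd * gg / m, each = HW) -
        rep(gam_sd * gb / m, each = HW)
    } else {
      gx <- g * rep(gam_sd, each = HW)
    }
    list(gx, gg, gb)
  })
}

# (x - mu)/sd per channel, dims (H,W,C,N); retained for block-level code
sweep_hw <- function(x, mu, sd_) {
  HW <- dim(x)[1] * dim(x)[2]
  (x - rep(mu, each = HW)) / rep(sd_, each = HW)
}

sweep_mul <- function(x, s) {
  x * rep(s, each = dim(x)[1] * dim(x)[2])
}

# group norm per sample; gamma/beta length C
#' Engine op: `ag_groupnorm`
#' @param ... see the engine source; operates on tape nodes
#' @return an `ag` node (or numeric for `ag_value`)
#' @export
ag_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$v)
  C <- d[3]
  stopifnot(C %% groups == 0)
  cpg <- C %/% groups
  mu <- array(0, c(groups, d[4])); va <- array(0, c(groups, d[4]))
  xhat <- x$v
  for (n in seq_len(d[4])) for (g in seq_len(groups)) {
    cs <- ((g - 1) * cpg + 1):(g * cpg)
    sl <- x$v[, , cs, n]
    mu[g, n] <- mean(sl)
    va[g, n] <- mean((sl - mu[g, n])^2)
    xhat[, , cs, n] <- (sl - mu[g, n]) / sqrt(va[g, n] + eps)
  }
  y <- xhat
  for (c in seq_len(C)) y[, , c, ] <- xhat[, , c, ] * gamma$v[c] + beta$v[c]
  m <- d[1] * d[2] * cpg
  ag_node(y, list(x, gamma, beta), function(gr) {
    gg <- apply(gr * xhat, 3, sum)
    gb <- apply(gr, 3, sum)
    gx <- array(0, d)
    for (n in seq_len(d[4])) for (g in seq_len(groups)) {
      cs <- ((g - 1) * cpg + 1):(g * cpg)
      sdg <- sqrt(va[g, n] + eps)
      gy <- gr[, , cs, n]
      for (i in seq_along(cs)) gy[, , i] <- gy[, , i] * gamma$v[cs[i]]
      xh <- xhat[, , cs, n]
      gx[, , cs, n] <- (gy - mean(gy) - xh * mean(gy * xh)) / sdg
    }
    list(gx, gg, gb)
  })
}
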