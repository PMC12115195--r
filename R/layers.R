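# Module framework: a module is an environment carrying parameter nodes,
# child modules and a forward closure. Complexity accounting hooks into the
# primitive ops via a trace collector, so parameter and multiply-accumulate
# totals are measured on the graph actually executed.

.ag_state$training <- FALSE
.ag_state$trace <- NULL
.ag_state$labels <- character(0)

set_training <- function(on) {
  old <- .ag_state$training
  .ag_state$training <- isTRUE(on)
  invisible(old)
}

is_training <- function() isTRUE(.ag_state$training)

ag_trace_start <- function() {
  .ag_state$trace <- new.env(parent = emptyenv())
  .ag_state$trace$rows <- list()
  invisible(NULL)
}

ag_trace_stop <- function() {
  tr <- .ag_state$trace
  .ag_state$trace <- NULL
  if (is.null(tr) || !length(tr$rows)) {
    return(data.frame(label = character(0), params = numeric(0), flops = numeric(0)))
  }
  do.call(rbind, lapply(tr$rows, function(r)
    data.frame(label = r$label, params = r$params, flops = r$flops,
               stringsAsFactors = FALSE)))
}

.ag_trace <- function(what, params, flops) {
  tr <- .ag_state$trace
  if (is.null(tr)) return(invisible(NULL))
  lab <- paste(c(.ag_state$labels, what), collapse = "/")
  tr$rows[[length(tr$rows) + 1L]] <- list(label = lab, params = params, flops = flops)
  invisible(NULL)
}

# called from ag_conv2d; FLOPs counted as multiply-accumulates per sample
.ag_trace_conv <- function(xd, wd, yd, groups, has_bias) {
  if (is.null(.ag_state$trace)) return(invisible(NULL))
  params <- prod(wd) + if (has_bias) wd[4] else 0
  macs <- prod(wd) * yd[1] * yd[2]  # kh*kw*cpg*cout * Ho*Wo
  .ag_trace("conv", params, macs)
}

with_label <- function(lab, expr) {
  .ag_state$labels <- c(.ag_state$labels, lab)
  on.exit(.ag_state$labels <- .ag_state$labels[-length(.ag_state$labels)])
  expr
}

new_module <- function(label) {
  e <- new.env(parent = emptyenv())
  e$label <- label
  e$params <- list()
  e$children <- list()
  e$forward <- NULL
  class(e) <- "nn_module"
  e
}

add_param <- function(mod, name, value) {
  p <- ag_param(value)
  mod$params[[name]] <- p
  p
}

add_child <- function(mod, name, child) {
  mod$children[[name]] <- child
  child
}

#' Collect all parameter nodes of a module tree
#' @param mod an `nn_module`
#' @return named list of parameter nodes
#' @export
collect_params <- function(mod) {
  out <- mod$params
  if (length(out)) names(out) <- paste(mod$label, names(out), sep = ".")
  for (ch in mod$children) out <- c(out, collect_params(ch))
  out
}

#' Count trainable parameters of a module tree
#' @param mod an `nn_module`
#' @return integer total of parameter array lengths
#' @export
param_count <- function(mod) {
  sum(vapply(collect_params(mod), function(p) length(p$v), numeric(1)))
}

# Kaiming-uniform init
.kaiming <- function(dims, fan_in, gain = sqrt(2)) {
  b <- gain * sqrt(3 / fan_in)
  array(stats::runif(prod(dims), -b, b), dims)
}

# ---- primitive layers ------------------------------------------------------

nn_conv2d <- function(cin, cout, k, stride = 1L, dil = 1L, groups = 1L,
                      bias = TRUE, label = "conv") {
  if (length(k) == 1L) k <- c(k, k)
  stopifnot(cin %% groups == 0, cout %% groups == 0)
  m <- new_module(label)
  cpg <- cin %/% groups
  add_param(m, "w", .kaiming(c(k[1], k[2], cpg, cout), fan_in = k[1] * k[2] * cpg))
  if (bias) add_param(m, "b", numeric(cout))
  m$meta <- list(cin = cin, cout = cout, k = k, stride = stride, dil = dil,
                 groups = groups, bias = bias)
  m$forward <- function(x) {
    ag_conv2d(x, m$params$w, m$params$b, stride = stride, dil = dil,
              groups = groups)
  }
  m
}

nn_bn2d <- function(C, label = "bn") {
  m <- new_module(label)
  add_param(m, "gamma", rep(1, C))
  add_param(m, "beta", numeric(C))
  m$rm <- ag_const(numeric(C))
  m$rv <- ag_const(rep(1, C))
  m$forward <- function(x) {
    d <- dim(x$v)
    .ag_trace("bn", 2 * C, d[1] * d[2] * C)
    ag_bn(x, m$params$gamma, m$params$beta, m$rm, m$rv, training = is_training())
  }
  m
}

nn_groupnorm <- function(C, groups, label = "gn") {
  m <- new_module(label)
  add_param(m, "gamma", rep(1, C))
  add_param(m, "beta", numeric(C))
  m$forward <- function(x) {
    d <- dim(x$v)
    .ag_trace("gn", 2 * C, d[1] * d[2] * C)
    ag_groupnorm(x, m$params$gamma, m$params$beta, groups = groups)
  }
  m
}

nn_linear <- function(din, dout, bias = TRUE, label = "linear") {
  m <- new_module(label)
  add_param(m, "w", matrix(stats::runif(dout * din, -sqrt(3 / din), sqrt(3 / din)),
                           dout, din))
  if (bias) add_param(m, "b", numeric(dout))
  m$forward <- function(x) {
    .ag_trace("linear", din * dout + if (bias) dout else 0, din * dout)
    ag_linear(x, m$params$w, m$params$b)
  }
  m
}

# standard Conv-BN-SiLU unit used throughout the assembly
nn_cbs <- function(cin, cout, k = 1L, stride = 1L, groups = 1L, label = "cbs") {
  m <- new_module(label)
  add_child(m, "conv", nn_conv2d(cin, cout, k, stride = stride, groups = groups,
                                 bias = FALSE))
  add_child(m, "bn", nn_bn2d(cout))
  m$meta <- list(cin = cin, cout = cout)
  m$forward <- function(x) {
    ag_silu(m$children$bn$forward(m$children$conv$forward(x)))
  }
  m
}

# classic YOLO bottleneck: two 3x3 convs with optional residual
nn_bottleneck <- function(c_, shortcut = TRUE, label = "bottleneck") {
  m <- new_module(label)
  add_child(m, "cv1", nn_cbs(c_, c_, 3))
  add_child(m, "cv2", nn_cbs(c_, c_, 3))
  m$forward <- function(x) {
    y <- m$children$cv2$forward(m$children$cv1$forward(x))
    if (shortcut) ag_add(y, x) else y
  }
  m
}
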