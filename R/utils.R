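# Feature maps cross the public API as C x H x W arrays (channel, row, col);
# the engine computes on H x W x C x N tensors.

#' Construct a feature map
#'
#' @param values numeric array indexed (channel, row, col)
#' @return a `feature_map`: the array with class attribute, validated
#' @export
feature_map <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L || any(d < 1L))
    stop("feature_map: values must be a C x H x W array with all dims >= 1")
  if (!all(is.finite(values))) stop("feature_map: values must be finite")
  structure(values, class = "feature_map")
}

fm_channels <- function(x) dim(x)[1]
fm_height <- function(x) dim(x)[2]
fm_width <- function(x) dim(x)[3]

# C x H x W -> engine tensor (H,W,C,1)
chw_to_t <- function(x) {
  d <- dim(x)
  array(aperm(unclass(x), c(2, 3, 1)), c(d[2], d[3], d[1], 1))
}

# engine tensor (H,W,C,1) -> C x H x W
t_to_chw <- function(x) {
  d <- dim(x)
  feature_map(aperm(array(x, d[1:3]), c(3, 1, 2)))
}

round_to <- function(x, m) as.integer(max(m, round(x / m) * m))

#' Run a module on a feature map
#' @param mod an `nn_module`
#' @param x a C x H x W array
#' @return the resulting feature map (C' x H' x W')
#' @export
module_apply <- function(mod, x) {
  t_to_chw(ag_value(mod$forward(ag_const(chw_to_t(x)))))
}
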