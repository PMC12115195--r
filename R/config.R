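# YAML run configuration.
#
# Example:
#   model:
#     num_classes: 3
#     input_size: 640
#     scale: calibrated
#     flags: {sdl: true, sppflkc: true, cfcglu: true, cscbam: true}
#     head_stride: 4
#     lskac: {k: 23, d: 3}
#     sppflkc: {pool_kernel: 5}
#     cfcglu: {t: 0.5, alpha: 0.5, beta: 0.25, groups: 2}
#     cscbam: {reduction: 16, interact_hidden_ratio: 0.25, spatial_tokens: 8}
#   train:
#     epochs: 300
#     batch: 32
#     ...

#' Read a YAML run configuration
#' @param path YAML file
#' @return nested list
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Build a model spec from a configuration list
#' @param cfg list as returned by [read_config()] (uses `cfg$model`)
#' @return an [rd_model_spec()]
#' @export
config_to_spec <- function(cfg) {
  mc <- cfg$model %||% cfg
  fl <- mc$flags %||% list()
  defaults <- formals(rd_model_spec)
  rd_model_spec(
    num_classes = mc$num_classes %||% 3L,
    input_size = mc$input_size %||% 640L,
    scale = mc$scale %||% "calibrated",
    sdl = fl$sdl %||% FALSE, sppflkc = fl$sppflkc %||% FALSE,
    cfcglu = fl$cfcglu %||% FALSE, cscbam = fl$cscbam %||% FALSE,
    head_stride = mc$head_stride %||% 4L,
    lskac = mc$lskac %||% list(k = 23L, d = 3L),
    cfcglu_opts = utils::modifyList(eval(defaults$cfcglu_opts),
                                    mc$cfcglu %||% list()),
    cscbam_opts = utils::modifyList(eval(defaults$cscbam_opts),
                                    mc$cscbam %||% list()),
    pool_kernel = (mc$sppflkc %||% list())$pool_kernel %||% 5L)
}

#' Build hyperparameters from a configuration list
#' @param cfg list (uses `cfg$train`)
#' @return an [rd_hyper()]
#' @export
config_to_hyper <- function(cfg) {
  tc <- cfg$train %||% list()
  do.call(rd_hyper, tc[intersect(names(tc), names(formals(rd_hyper)))])
}
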