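#' Read an experiment configuration from YAML
#'
#' The file may contain any of the sections `backbone`, `loss`, `train` and
#' `synth`; each is passed as arguments to the corresponding constructor
#' ([backbone_config()], [loss_config()], [train_config()],
#' [synth_params()]).  Missing sections fall back to the constructor
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `backbone`, `loss`, `train`, `synth`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("backbone:",
#'              "  block_channels: [8, 16]",
#'              "  convs_per_block: [1, 1]",
#'              "  input_size: [16, 16]",
#'              "loss:",
#'              "  loss_kind: focal",
#'              "  gamma: 2"), cfg_file)
#' cfg <- read_experiment_config(cfg_file)
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  call_with <- function(fn, args) do.call(fn, args %||% list())
  backbone <- if (!is.null(raw$backbone)) call_with(backbone_config, raw$backbone)
  list(
    backbone = backbone,
    loss = call_with(loss_config, raw$loss),
    train = call_with(train_config, raw$train),
    synth = call_with(synth_params, raw$synth)
  )
}
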