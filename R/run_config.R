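#' Read a YAML run configuration
#'
#' A run config bundles the network, training and peak-extraction settings
#' of an experiment in one auditable file.  Recognised blocks (all
#' optional; missing fields fall back to the package defaults):
#'
#' ```yaml
#' network:
#'   channels: [8, 8, 16, 16, 32, 32]
#'   pool_after: [2, 4]
#'   ppm_bins: [1, 2, 4]
#'   stages: 2
#'   head_channels: 32
#'   bottleneck_channels: 64
#' training:
#'   learning_rate: 1.0e-5
#'   momentum: 0.9
#'   epochs: 30
#'   batch_size: 1
#'   seed: 1
#'   sigma_min: 1.5
#'   sigma_max: 4
#' peaks:
#'   tau: 0.35
#'   delta: 1
#' ```
#'
#' @param path YAML file path.
#' @return list with elements `net` ([network_config]), `control`
#'   ([train_control]) and `peak` ([peak_params]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  nb <- cfg$network %||% list()
  net <- do.call(network_config, nb[names(nb) %in% names(formals(network_config))])
  tb <- cfg$training %||% list()
  stages <- net$stages
  sched <- make_sigma_schedule(tb$sigma_min %||% 1, tb$sigma_max %||% 4,
                               stages)
  control <- train_control(tb$learning_rate %||% 0.001,
                           tb$momentum %||% 0.9,
                           tb$epochs %||% 100L,
                           tb$batch_size %||% 1L,
                           tb$seed %||% 1L,
                           sched)
  pb <- cfg$peaks %||% list()
  peak <- peak_params(pb$tau %||% 0.35, pb$delta %||% 1)
  list(net = net, control = control, peak = peak)
}
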