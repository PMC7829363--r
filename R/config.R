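# YAML configuration: one file describing the environment, ensemble,
# modulation and coactivity parameters, shared by scripts and the CLI.

#' Read a simulation configuration from YAML
#'
#' The file may contain the blocks `environment` (width, height, holes),
#' `ensemble` (s, f, N, a, b), `trajectory` (duration, speed_mean, speed_sd,
#' dt), `modulation` (arguments of [modulation_config()]) and `coactivity`
#' (arguments of [coactivity_config()]). Missing blocks fall back to package
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `env`, `ensemble`, `trajectory`, `mod`,
#'   `cfg`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  envb <- y$environment %||% list(width = 150, height = 150, holes = list())
  holes <- lapply(envb$holes %||% list(), function(h) {
    h$center <- as.numeric(h$center)
    h
  })
  env <- make_environment(envb$width, envb$height, holes)
  ensy <- y$ensemble %||% list()
  # YAML 1.1 reads a bare key `N` as the boolean FALSE; undo that
  names(ensy)[names(ensy) %in% c("FALSE", "F")] <- "N"
  ens <- utils::modifyList(list(s = 23, f = 28, N = 350, a = 0.3, b = 0.3),
                           ensy)
  trj <- utils::modifyList(list(duration = 1500, speed_mean = 20,
                                speed_sd = 8, dt = 0.01),
                           y$trajectory %||% list())
  mod <- do.call(modulation_config, y$modulation %||% list())
  cfg <- do.call(coactivity_config, y$coactivity %||% list())
  list(env = env, ensemble = ens, trajectory = trj, mod = mod, cfg = cfg)
}
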