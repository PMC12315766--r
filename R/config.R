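#' Read a pipeline configuration file
#'
#' Configurations are YAML or JSON mappings holding the channel role map,
#' band definitions and pipeline constants. Any field omitted falls back to
#' the package default from [default_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a named list merged over [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  utils::modifyList(default_config(), cfg)
}

#' Default pipeline configuration
#'
#' @return a named list with the channel role map, the frequency-band
#'   definitions (mu 6-15 Hz, beta 15-30 Hz, mu-beta 6-30 Hz, with 3 Hz
#'   filter banks), the superlet parameters, and the decoding constants.
#' @export
default_config <- function() {
  list(
    roles = list(left_motor = "C3", right_motor = "C4",
                 burst_cluster = c("C3", "C4")),
    bands = list(mu = c(6, 15), beta = c(15, 30), mu_beta = c(6, 30)),
    bank_width = 3,
    superlet = list(f_min = 1, f_max = 43, f_step = 0.5,
                    o_min = 1, o_max = 40, c = 4),
    burst_band = c(15, 30),
    waveform_duration = 0.260,
    sample_fraction = 0.10,
    n_csp = 4,
    n_repeats = 10,
    n_folds = 5)
}

config_roles <- function(cfg) {
  do.call(channel_roles, cfg$roles)
}
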