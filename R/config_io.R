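#' Write a run specification to a structured-text config file
#'
#' Serialises the full run specification (neuron, network, protocol,
#' learning sections) as YAML. All durations are in ms except the protocol
#' duration, which is in seconds. Every default is written out explicitly
#' so the file is self-describing.
#'
#' @param spec A `run_spec` (e.g. from [make_preset()]) or a list with
#'   `config`, `params`, `protocol`, `learning`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(spec, path) {
  x <- list(
    neuron = list(tau_membrane_ms = spec$params$tau_membrane,
                  v_rest = spec$params$v_rest,
                  v_threshold = spec$params$v_threshold,
                  refractory_ms = spec$params$refractory),
    network = list(delays_ms = spec$config$delays,
                   dendrite_of = spec$config$dendrite_of,
                   w_syn = spec$config$w_syn,
                   w_dend = spec$config$w_dend,
                   mode = spec$config$mode),
    protocol = list(rate_hz = spec$protocol$rate,
                    duration_s = spec$protocol$duration),
    learning = list(amplitude = spec$learning$amplitude,
                    tau_learn_ms = spec$learning$tau_learn,
                    cutoff_ms = spec$learning$cutoff,
                    weight_floor = spec$learning$weight_floor))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a run specification from a structured-text config file
#'
#' Inverse of [write_config()]; missing sections fall back to package
#' defaults.
#'
#' @param path Path to a YAML config written by [write_config()] or by
#'   hand with the same section layout.
#' @return A list of class `run_spec` with `config`, `params`, `protocol`,
#'   `learning`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$network)) stop("config file has no 'network' section",
                               call. = FALSE)
  params <- if (is.null(x$neuron)) neuron_params() else
    neuron_params(tau_membrane = x$neuron$tau_membrane_ms %||% 20,
                  v_rest = x$neuron$v_rest %||% 0,
                  v_threshold = x$neuron$v_threshold %||% 1,
                  refractory = x$neuron$refractory_ms %||% 2)
  config <- network_config(delays = x$network$delays_ms,
                           dendrite_of = x$network$dendrite_of,
                           w_syn = x$network$w_syn,
                           w_dend = x$network$w_dend,
                           mode = x$network$mode %||% "dendritic")
  protocol <- if (is.null(x$protocol)) stim_protocol() else
    stim_protocol(rate = x$protocol$rate_hz %||% 10,
                  duration = x$protocol$duration_s %||% 200)
  learning <- if (is.null(x$learning)) learning_curve() else
    learning_curve(amplitude = x$learning$amplitude %||% 0.05,
                   tau_learn = x$learning$tau_learn_ms %||% 15,
                   cutoff = x$learning$cutoff_ms %||% 50,
                   weight_floor = x$learning$weight_floor %||% 0.001)
  structure(list(id = x$id %||% "custom", variant = x$variant %||% "custom",
                 config = config, params = params,
                 protocol = protocol, learning = learning),
            class = "run_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
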