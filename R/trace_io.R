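#' Write a simulation trace to a directory
#'
#' Serialises a trace as tab-separated files plus a JSON metadata sidecar:
#' `arrivals.tsv` (time_ms, input, dendrite, eff_weight, caused_spike,
#' during_refractory), `spikes.tsv` (time_ms, input, dendrite),
#' `pairs.tsv` (t_spike_ms, t_sub_ms, delta_ms, mode, target_id, dW,
#' new_weight), `weights.tsv` (cycle, W_1..W_N, WD_1..WD_ND) and
#' `meta.json` (config echo, protocol, learning parameters, seed).
#'
#' @param trace An `lif_trace` from [simulate_network()] with
#'   `record_events = TRUE`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (is.null(trace$arrivals))
    stop("trace was simulated with record_events = FALSE", call. = FALSE)
  tsv(trace$arrivals, "arrivals.tsv")
  tsv(trace$spikes, "spikes.tsv")
  tsv(trace$pairs, "pairs.tsv")
  tsv(trace$weights, "weights.tsv")
  meta <- list(
    package = "dendriteLIF",
    version = as.character(utils::packageVersion("dendriteLIF")),
    seed = trace$seed,
    n_cycles = trace$n_cycles,
    period_ms = trace$period,
    pair_refractory = trace$pair_refractory,
    nearest_only = trace$nearest_only,
    config = trace$config[c("delays", "dendrite_of", "w_syn", "w_dend",
                            "mode")],
    params = unclass(trace$params),
    protocol = unclass(trace$protocol),
    learning = unclass(trace$learning))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a simulation trace back from a directory
#'
#' Inverse of [write_trace()]; reconstructs an `lif_trace` sufficient for
#' re-classification (event tables, weight snapshots and run metadata).
#'
#' @param dir Directory written by [write_trace()].
#' @return An `lif_trace`.
#' @export
read_trace <- function(dir) {
  tsv <- function(name)
    utils::read.table(file.path(dir, name), sep = "\t", header = TRUE,
                      check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  config <- network_config(delays = meta$config$delays,
                           dendrite_of = meta$config$dendrite_of,
                           w_syn = meta$config$w_syn,
                           w_dend = meta$config$w_dend,
                           mode = meta$config$mode)
  trace <- list(arrivals = tsv("arrivals.tsv"),
                spikes = tsv("spikes.tsv"),
                pairs = tsv("pairs.tsv"),
                weights = tsv("weights.tsv"),
                config = config,
                params = do.call(neuron_params,
                                 meta$params[c("tau_membrane", "v_rest",
                                               "v_threshold", "refractory")]),
                protocol = stim_protocol(rate = meta$protocol$rate,
                                         duration = meta$protocol$duration),
                learning = do.call(learning_curve,
                                   meta$learning[c("amplitude", "tau_learn",
                                                   "cutoff", "weight_floor")]),
                seed = meta$seed,
                n_cycles = meta$n_cycles,
                period = meta$period_ms,
                pair_refractory = meta$pair_refractory,
                nearest_only = meta$nearest_only)
  class(trace) <- "lif_trace"
  trace
}
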