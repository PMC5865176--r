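#' Closed-form leak of the membrane voltage
#'
#' Between input arrivals the membrane obeys pure exponential decay toward
#' the resting potential, `V(t + dt) = v_rest + (V(t) - v_rest) *
#' exp(-dt / tau_membrane)`. This is the exact solution of the leak term,
#' which is why the event-driven engine needs no numerical integrator.
#'
#' @param v Voltage(s) at the start of the interval.
#' @param dt Elapsed time in ms, `>= 0` (vectorised).
#' @param params A [neuron_params()].
#' @return Voltage(s) after `dt` ms without input.
#' @export
decay_voltage <- function(v, dt, params = neuron_params()) {
  if (any(dt < 0)) stop("dt must be >= 0", call. = FALSE)
  params$v_rest + (v - params$v_rest) * exp(-dt / params$tau_membrane)
}

#' Merged arrival schedule of a stimulation protocol
#'
#' Every cycle `k = 0, 1, ...` stimulates all inputs simultaneously at
#' `k * period`; input `i`'s pulse reaches the output unit `delays[i]` ms
#' later. Returns one row per arrival, sorted by time with ties broken by
#' ascending input index.
#'
#' @param protocol A [stim_protocol()].
#' @param config A [network_config()].
#' @return A data.frame with columns `time` (ms), `cycle` (1-based),
#'   `input`, `dendrite`.
#' @export
build_arrival_schedule <- function(protocol, config) {
  n_cycles <- floor(protocol$rate * protocol$duration + 1e-9)
  if (n_cycles < 1) stop("protocol duration yields zero stimulation cycles",
                         call. = FALSE)
  k <- rep(seq_len(n_cycles) - 1L, each = config$n_inputs)
  i <- rep(seq_len(config$n_inputs), times = n_cycles)
  df <- data.frame(time = k * protocol$period + config$delays[i],
                   cycle = k + 1L,
                   input = i,
                   dendrite = config$dendrite_of[i])
  df[order(df$time, df$input), , drop = FALSE]
}

#' Process one input arrival against the neuron state
#'
#' Implements the jump part of the dynamics: outside the refractory window
#' the arrival adds its effective weight to the (already decayed) voltage;
#' reaching the threshold (`v >= v_threshold`) emits a spike attributed to
#' this arrival's input and dendrite, resets the voltage to rest and opens
#' a refractory window. During the refractory window the voltage is clamped
#' at rest, so the arrival changes nothing and is flagged
#' `during_refractory`.
#'
#' @param state List with `v` (voltage already decayed to `event$time`) and
#'   `refr_end` (absolute end time of the current refractory window, ms).
#' @param event List with `time`, `input`, `dendrite`, `effective_weight`.
#' @param params A [neuron_params()] in scaled units.
#' @return List with updated `state`, `spike` (list or `NULL`),
#'   `caused_spike` and `during_refractory` flags.
#' @export
apply_arrival <- function(state, event, params = neuron_params()) {
  if (state$refr_end - event$time > 1e-9) {
    return(list(state = state, spike = NULL,
                caused_spike = FALSE, during_refractory = TRUE))
  }
  v <- state$v + event$effective_weight
  if (v >= params$v_threshold) {
    state$v <- params$v_rest
    state$refr_end <- event$time + params$refractory
    spike <- list(time = event$time, input = event$input,
                  dendrite = event$dendrite)
    list(state = state, spike = spike,
         caused_spike = TRUE, during_refractory = FALSE)
  } else {
    state$v <- v
    list(state = state, spike = NULL,
         caused_spike = FALSE, during_refractory = FALSE)
  }
}

#' Simulate the perceptron with plasticity
#'
#' Runs the full event-driven simulation: exponential decay between
#' arrivals, instantaneous jumps at arrivals, threshold crossings, and
#' after every event the pair-based plasticity updates of the active mode
#' (synaptic weights in `"synaptic"` mode, dendritic weights in
#' `"dendritic"` mode; the other set is never modified). Each new
#' sub-threshold stimulation is paired with every earlier evoked spike
#' within the learning-window cutoff, and each new spike with every earlier
#' sub-threshold stimulation, excluding pairs that share an input
#' (synaptic mode) or a dendrite (dendritic mode); the update always
#' targets the sub-threshold event's own weight and is applied at the time
#' of the later event of the pair.
#'
#' The run is fully deterministic: identical inputs give byte-identical
#' traces. `seed` is only echoed into the trace for provenance.
#'
#' @param config A validated [network_config()].
#' @param params A [neuron_params()]; rescaled internally via
#'   [to_scaled_units()].
#' @param protocol A [stim_protocol()].
#' @param learning A [learning_curve()].
#' @param seed Optional integer echoed into the trace.
#' @param pair_refractory Should arrivals falling inside the refractory
#'   window count as sub-threshold stimulations for pairing? Default
#'   `FALSE`: a refractory arrival is silenced by the voltage clamp however
#'   strong its weight, so letting it pair breaks the self-limitation of
#'   the learning dynamics (a dendrite whose arrivals all evoke spikes or
#'   fall in refractory windows could strengthen without bound).
#' @param nearest_only If `TRUE`, each new event pairs only with the most
#'   recent eligible counterpart instead of all of them (sensitivity
#'   toggle).
#' @param record_events Keep per-arrival and per-pair records. Disable for
#'   large ensembles where only spikes and weight snapshots matter.
#' @return An object of class `lif_trace`: list with data.frames
#'   `arrivals`, `spikes`, `pairs`, `weights` (one row per cycle with
#'   columns `W_i` and `WD_j`), plus `config`, `params`, `protocol`,
#'   `learning`, `seed`, `n_cycles`, `period`.
#' @examples
#' cfg <- make_preset("fig2b_dendritic")$config
#' tr <- simulate_network(cfg, protocol = stim_protocol(duration = 1))
#' tr$spikes[1, ]  # first evoked spike, 12 ms after stimulation
#' @export
simulate_network <- function(config, params = neuron_params(),
                             protocol = stim_protocol(),
                             learning = learning_curve(),
                             seed = NULL,
                             pair_refractory = FALSE,
                             nearest_only = FALSE,
                             record_events = TRUE) {
  validate_config(config, params)
  sp <- to_scaled_units(params)
  n_cycles <- floor(protocol$rate * protocol$duration + 1e-9)
  if (n_cycles < 1) stop("protocol duration yields zero stimulation cycles",
                         call. = FALSE)

  res <- .engine_run(config$delays, config$dendrite_of - 1L,
                     config$w_syn, config$w_dend,
                     as.integer(config$mode == "dendritic"),
                     sp$tau_membrane, sp$refractory,
                     protocol$rate, protocol$duration,
                     learning$amplitude, learning$tau_learn,
                     learning$cutoff, learning$weight_floor,
                     pair_refractory, nearest_only, record_events)

  spikes <- data.frame(time_ms = res$spike_time,
                       input = res$spike_input + 1L,
                       dendrite = res$spike_dend + 1L)
  snaps <- res$snapshots
  colnames(snaps) <- c(paste0("W_", seq_len(config$n_inputs)),
                       paste0("WD_", seq_len(config$n_dendrites)))
  weights <- data.frame(cycle = seq_len(n_cycles), snaps,
                        check.names = FALSE)

  trace <- list(spikes = spikes, weights = weights,
                final_w_syn = res$final_w_syn,
                final_w_dend = res$final_w_dend,
                config = config, params = sp, protocol = protocol,
                learning = learning, seed = seed,
                n_cycles = n_cycles, period = protocol$period,
                pair_refractory = pair_refractory,
                nearest_only = nearest_only)
  if (record_events) {
    trace$arrivals <- data.frame(
      time_ms = res$arr_time,
      input = res$arr_input + 1L,
      dendrite = res$arr_dend + 1L,
      eff_weight = res$arr_eff,
      caused_spike = as.logical(res$arr_caused),
      during_refractory = as.logical(res$arr_refr))
    trace$pairs <- data.frame(
      t_spike_ms = res$pair_t_spike,
      t_sub_ms = res$pair_t_sub,
      delta_ms = res$pair_delta,
      mode = rep(config$mode, length(res$pair_delta)),
      target_id = res$pair_target + 1L,
      dW = res$pair_dw,
      new_weight = res$pair_new_w)
  }
  class(trace) <- "lif_trace"
  trace
}

#' @export
print.lif_trace <- function(x, ...) {
  cat(sprintf("<lif_trace> %d cycles at %g Hz, %s learning: %d spikes",
              x$n_cycles, x$protocol$rate, x$config$mode, nrow(x$spikes)))
  if (!is.null(x$pairs)) cat(sprintf(", %d plasticity pairings", nrow(x$pairs)))
  cat("\n")
  invisible(x)
}
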