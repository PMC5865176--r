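#' Membrane parameters of the output neuron
#'
#' The output unit is a leaky integrate-and-fire neuron: its voltage decays
#' exponentially toward the resting potential with time constant
#' `tau_membrane` and jumps instantaneously at input arrivals. Crossing
#' `v_threshold` emits an evoked spike followed by an absolute refractory
#' period during which the voltage is clamped at rest.
#'
#' Parameters may be given either in physical units (resting potential
#' -70 mV, threshold -54 mV) or in scaled units (rest 0, threshold 1); all
#' internal computation uses the scaled form, see [to_scaled_units()].
#'
#' @param tau_membrane Membrane time constant in ms.
#' @param v_rest Resting (stable) membrane potential.
#' @param v_threshold Spiking threshold; must exceed `v_rest`.
#' @param refractory Absolute refractory period in ms.
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params()                              # scaled defaults
#' neuron_params(v_rest = -70, v_threshold = -54)  # physical mV
#' @export
neuron_params <- function(tau_membrane = 20, v_rest = 0, v_threshold = 1,
                          refractory = 2) {
  p <- structure(
    list(tau_membrane = as.numeric(tau_membrane),
         v_rest = as.numeric(v_rest),
         v_threshold = as.numeric(v_threshold),
         refractory = as.numeric(refractory)),
    class = "neuron_params")
  errs <- character()
  if (!is.finite(p$tau_membrane) || p$tau_membrane <= 0)
    errs <- c(errs, "tau_membrane must be > 0")
  if (!(p$v_threshold > p$v_rest))
    errs <- c(errs, "v_threshold must exceed v_rest")
  if (!is.finite(p$refractory) || p$refractory < 0)
    errs <- c(errs, "refractory must be >= 0")
  if (length(errs)) stop("invalid neuron_params: ", paste(errs, collapse = "; "),
                         call. = FALSE)
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> tau=%g ms, rest=%g, threshold=%g, refractory=%g ms\n",
              x$tau_membrane, x$v_rest, x$v_threshold, x$refractory))
  invisible(x)
}

#' Network architecture and initial weights
#'
#' Describes a feedforward perceptron: `n` input units, each connected to a
#' single output unit through one dendrite. Input `i` has a transmission
#' delay `delays[i]` (ms), a synaptic weight `w_syn[i]` and belongs to
#' dendrite `dendrite_of[i]`, which carries a shared dendritic weight
#' `w_dend[dendrite_of[i]]`. The voltage jump caused by an arrival from
#' input `i` is the *effective weight* `w_syn[i] * w_dend[dendrite_of[i]]`.
#'
#' `mode` selects the adaptive parameter set: `"synaptic"` adapts the
#' per-link weights `w_syn` (the conventional locus of plasticity) while
#' `"dendritic"` adapts the per-node weights `w_dend` shared by all inputs
#' on a dendrite; the other set is frozen for the whole simulation.
#'
#' @param delays Per-input transmission delays in ms, all > 0.
#' @param dendrite_of Per-input dendrite index (1-based); every dendrite
#'   must own at least one input.
#' @param w_syn Per-input synaptic weights, all > 0.
#' @param w_dend Per-dendrite weights, all > 0; defaults to 1 for every
#'   dendrite.
#' @param mode `"dendritic"` or `"synaptic"`.
#' @return An object of class `network_config`.
#' @examples
#' network_config(delays = c(12, 7, 15), dendrite_of = c(1, 2, 2),
#'                w_syn = c(1, 0.8, 0.6))
#' @export
network_config <- function(delays, dendrite_of, w_syn,
                           w_dend = NULL,
                           mode = c("dendritic", "synaptic")) {
  mode <- match.arg(mode)
  delays <- as.numeric(delays)
  dendrite_of <- as.integer(dendrite_of)
  w_syn <- as.numeric(w_syn)
  nd <- if (length(dendrite_of)) max(dendrite_of) else 0L
  if (is.null(w_dend)) w_dend <- rep(1, nd)
  structure(
    list(n_inputs = length(delays),
         n_dendrites = length(w_dend),
         delays = delays,
         dendrite_of = dendrite_of,
         w_syn = w_syn,
         w_dend = as.numeric(w_dend),
         mode = mode),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d inputs on %d dendrites, %s learning\n",
              x$n_inputs, x$n_dendrites, x$mode))
  cat("  delays (ms): ", paste(format(x$delays), collapse = ", "), "\n")
  cat("  dendrite_of: ", paste(x$dendrite_of, collapse = ", "), "\n")
  cat("  w_syn:       ", paste(format(x$w_syn), collapse = ", "), "\n")
  cat("  w_dend:      ", paste(format(x$w_dend), collapse = ", "), "\n")
  invisible(x)
}

#' Parameters of the pair-based learning window
#'
#' The relative weight change produced by one (evoked spike, sub-threshold
#' stimulation) pairing is `amplitude * exp(-|delta|/tau_learn) *
#' sign(delta)` where `delta` is the time-lag of the sub-threshold
#' stimulation relative to the spike in ms; pairs further apart than
#' `cutoff` contribute nothing. Updates are multiplicative
#' (`w := w * (1 + dW)`) and adaptive weights are clamped from below at
#' `weight_floor`.
#'
#' @param amplitude Peak relative change per pairing (dimensionless).
#' @param tau_learn Decay constant of the window in ms.
#' @param cutoff Maximum |time-lag| that still produces an update, ms
#'   (boundary inclusive).
#' @param weight_floor Smallest value an adaptive weight may take.
#' @return An object of class `learning_curve`.
#' @export
learning_curve <- function(amplitude = 0.05, tau_learn = 15, cutoff = 50,
                           weight_floor = 0.001) {
  lc <- structure(
    list(amplitude = as.numeric(amplitude),
         tau_learn = as.numeric(tau_learn),
         cutoff = as.numeric(cutoff),
         weight_floor = as.numeric(weight_floor)),
    class = "learning_curve")
  bad <- vapply(lc, function(v) !is.finite(v) || v <= 0, logical(1))
  if (any(bad))
    stop("learning_curve fields must be positive: ",
         paste(names(lc)[bad], collapse = ", "), call. = FALSE)
  lc
}

#' Periodic stimulation protocol
#'
#' All input units are stimulated above threshold simultaneously at `rate`
#' Hz for `duration` seconds, so input `i` produces one arrival at
#' `k * 1000/rate + delays[i]` ms for each cycle `k`.
#'
#' @param rate Stimulation rate in Hz.
#' @param duration Total stimulation time in seconds.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(rate = 10, duration = 200) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  structure(list(rate = as.numeric(rate), duration = as.numeric(duration),
                 period = 1000 / as.numeric(rate)),
            class = "stim_protocol")
}

#' Validate a network configuration
#'
#' Checks every structural invariant of a [network_config()] and returns the
#' configuration unchanged when all of them hold. All violations found are
#' reported together in the error message, each naming the broken
#' invariant.
#'
#' @param config A [network_config()].
#' @param params A [neuron_params()] (checked for internal consistency).
#' @return `config`, invisibly unchanged, if valid.
#' @export
validate_config <- function(config, params = neuron_params()) {
  if (!inherits(config, "network_config"))
    stop("config must be a network_config", call. = FALSE)
  if (!inherits(params, "neuron_params"))
    stop("params must be a neuron_params", call. = FALSE)
  errs <- character()
  n <- config$n_inputs
  if (n < 1) errs <- c(errs, "network must have at least one input")
  if (length(config$delays) != n || length(config$w_syn) != n ||
      length(config$dendrite_of) != n)
    errs <- c(errs, "delays, w_syn and dendrite_of must all have length n_inputs")
  if (any(!is.finite(config$delays)) || any(config$delays <= 0))
    errs <- c(errs, "all delays must be > 0")
  if (any(!is.finite(config$w_syn)) || any(config$w_syn <= 0))
    errs <- c(errs, "all synaptic weights must be > 0")
  if (any(!is.finite(config$w_dend)) || any(config$w_dend <= 0))
    errs <- c(errs, "all dendritic weights must be > 0")
  nd <- config$n_dendrites
  if (nd < 1) errs <- c(errs, "network must have at least one dendrite")
  if (any(is.na(config$dendrite_of)) ||
      any(config$dendrite_of < 1L) || any(config$dendrite_of > nd)) {
    errs <- c(errs, "every input must map to an existing dendrite index in 1..n_dendrites")
  } else if (length(setdiff(seq_len(nd), config$dendrite_of))) {
    errs <- c(errs, sprintf("dendrite(s) %s own no inputs",
                            paste(setdiff(seq_len(nd), config$dendrite_of),
                                  collapse = ", ")))
  }
  if (!config$mode %in% c("synaptic", "dendritic"))
    errs <- c(errs, "mode must be 'synaptic' or 'dendritic'")
  if (length(errs))
    stop("invalid network_config: ", paste(errs, collapse = "; "),
         call. = FALSE)
  invisible(config)
}

#' Rescale neuron parameters to threshold units
#'
#' Applies the affine map `x -> (x - v_rest) / (v_threshold - v_rest)` so
#' that the resting potential becomes 0 and the threshold becomes 1; for
#' example physical values (-70 mV, -54 mV) map to (0, 1). Simulated spike
#' times are identical in scaled and unscaled units, so all internal
#' computation uses the scaled form. The map is idempotent.
#'
#' @param params A [neuron_params()].
#' @return A [neuron_params()] with `v_rest = 0`, `v_threshold = 1`.
#' @export
to_scaled_units <- function(params) {
  if (!inherits(params, "neuron_params"))
    stop("params must be a neuron_params", call. = FALSE)
  span <- params$v_threshold - params$v_rest
  if (span == 0) stop("v_threshold equals v_rest; cannot scale", call. = FALSE)
  neuron_params(tau_membrane = params$tau_membrane,
                v_rest = 0, v_threshold = 1,
                refractory = params$refractory)
}

#' Map a voltage to scaled units under a parameter set
#'
#' Helper for the affine voltage rescaling used by [to_scaled_units()]:
#' `v_rest` maps to 0 and `v_threshold` to 1.
#'
#' @param v Voltage(s) on the scale of `params`.
#' @param params A [neuron_params()] defining the original scale.
#' @return Scaled voltage(s).
#' @export
scale_voltage <- function(v, params) {
  span <- params$v_threshold - params$v_rest
  if (span == 0) stop("v_threshold equals v_rest; cannot scale", call. = FALSE)
  (v - params$v_rest) / span
}
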