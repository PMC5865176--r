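#' Pair-based learning window
#'
#' Relative weight change produced by one pairing of an evoked spike with a
#' sub-threshold stimulation at signed time-lag `delta = t_sub - t_spike`
#' ms: `amplitude * exp(-|delta|/tau_learn) * sign(delta)`. A sub-threshold
#' stimulation arriving after the spike (`delta > 0`) strengthens its
#' weight, one arriving before weakens it; the change vanishes at
#' `delta = 0` and beyond the cutoff (boundary inclusive). The magnitude is
#' bounded by `amplitude`, approached only in the limit `delta -> 0`, and
#' is strictly decreasing in `|delta|` on `(0, cutoff]`.
#'
#' @param delta Signed time-lag(s) in ms (vectorised).
#' @param lc A [learning_curve()].
#' @return Relative weight change(s) `dW`.
#' @examples
#' learning_step(3)    # 0.05 * exp(-3/15)
#' learning_step(-60)  # beyond the 50 ms cutoff: 0
#' @export
learning_step <- function(delta, lc = learning_curve()) {
  ad <- abs(delta)
  out <- lc$amplitude * exp(-ad / lc$tau_learn) * sign(delta)
  out[ad > lc$cutoff + 1e-9] <- 0
  out
}

#' Pairings completed by a new event
#'
#' Given the events recorded so far and one new event (a spike or a
#' sub-threshold stimulation), returns every (spike, sub-threshold) pair
#' that the new event completes: counterparts within the learning-window
#' cutoff, excluding pairs that share an input (synaptic mode) or a
#' dendrite (dendritic mode). The pair's update target is always the
#' sub-threshold event's own input (synaptic) or dendrite (dendritic), and
#' `delta = t_sub - t_spike`. Simultaneous events form a pair with
#' `dW = 0`.
#'
#' @param new_event List with `kind` (`"spike"` or `"sub"`), `time`,
#'   `input`, `dendrite`.
#' @param history data.frame of earlier events with columns `time`,
#'   `input`, `dendrite`, `kind`.
#' @param mode `"synaptic"` or `"dendritic"`.
#' @param lc A [learning_curve()].
#' @return data.frame with columns `t_spike`, `t_sub`, `delta`, `target`,
#'   `dW`, ordered by the earlier event's time.
#' @export
enumerate_pairs <- function(new_event, history, mode, lc = learning_curve()) {
  stopifnot(new_event$kind %in% c("spike", "sub"),
            mode %in% c("synaptic", "dendritic"))
  empty <- data.frame(t_spike = numeric(), t_sub = numeric(),
                      delta = numeric(), target = integer(), dW = numeric())
  if (!nrow(history)) return(empty)
  want <- if (new_event$kind == "spike") "sub" else "spike"
  cand <- history[history$kind == want &
                  abs(history$time - new_event$time) <= lc$cutoff + 1e-9, ,
                  drop = FALSE]
  if (!nrow(cand)) return(empty)
  same <- if (mode == "synaptic") cand$input == new_event$input
          else cand$dendrite == new_event$dendrite
  cand <- cand[!same, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$time, cand$input), , drop = FALSE]
  if (new_event$kind == "spike") {
    t_spike <- rep(new_event$time, nrow(cand)); t_sub <- cand$time
    target <- if (mode == "synaptic") cand$input else cand$dendrite
  } else {
    t_spike <- cand$time; t_sub <- rep(new_event$time, nrow(cand))
    target <- rep(if (mode == "synaptic") new_event$input else
                    new_event$dendrite, nrow(cand))
  }
  delta <- t_sub - t_spike
  data.frame(t_spike = t_spike, t_sub = t_sub, delta = delta,
             target = as.integer(target), dW = learning_step(delta, lc))
}

#' Apply one pairing update to the weight vectors
#'
#' Multiplies the target adaptive weight by `(1 + dW)` and clamps it from
#' below at the weight floor; all other weights are untouched. In synaptic
#' mode the target indexes `w_syn`, in dendritic mode `w_dend`.
#'
#' @param weights List with numeric vectors `w_syn` and `w_dend`.
#' @param pair One pairing as produced by [enumerate_pairs()] (uses fields
#'   `target` and `dW`).
#' @param mode `"synaptic"` or `"dendritic"`.
#' @param lc A [learning_curve()] (supplies the weight floor).
#' @return The updated weights list.
#' @export
apply_update <- function(weights, pair, mode, lc = learning_curve()) {
  slot <- if (mode == "synaptic") "w_syn" else "w_dend"
  w <- weights[[slot]][pair$target] * (1 + pair$dW)
  weights[[slot]][pair$target] <- max(w, lc$weight_floor)
  weights
}

#' Expected per-cycle drift of the adaptive weights
#'
#' For a fixed firing pattern within one stimulation cycle, computes the
#' net relative change each adaptive target would accumulate over the
#' cycle's pairings: `prod(1 + dW_k) - 1`. Arrivals whose delay coincides
#' with a spike time are the spike origins; all other arrivals are
#' sub-threshold. Analytic helper for tests and exploration (ignores the
#' weight floor).
#'
#' @param config A [network_config()].
#' @param spike_times Spike times within the cycle, ms (offsets equal to
#'   the delays of the spiking inputs).
#' @param lc A [learning_curve()].
#' @return Named numeric vector of per-target relative drift (inputs in
#'   synaptic mode, dendrites in dendritic mode).
#' @export
net_cycle_drift <- function(config, spike_times, lc = learning_curve()) {
  is_spike_origin <- vapply(config$delays, function(d)
    any(abs(spike_times - d) < 1e-6), logical(1))
  n_t <- if (config$mode == "synaptic") config$n_inputs else config$n_dendrites
  drift <- rep(1, n_t)
  names(drift) <- if (config$mode == "synaptic")
    paste0("W_", seq_len(n_t)) else paste0("WD_", seq_len(n_t))
  for (i in which(!is_spike_origin)) {
    tgt <- if (config$mode == "synaptic") i else config$dendrite_of[i]
    for (s in spike_times) {
      s_inputs <- which(abs(config$delays - s) < 1e-6)
      excl <- if (config$mode == "synaptic") i %in% s_inputs
              else config$dendrite_of[i] %in% config$dendrite_of[s_inputs]
      if (excl) next
      delta <- config$delays[i] - s
      drift[tgt] <- drift[tgt] * (1 + learning_step(delta, lc))
    }
  }
  drift - 1
}
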