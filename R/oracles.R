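# Independent brute-force reference implementations. These exist solely to
# cross-check the event-driven engine and the online pairing logic in the
# test suite; they are deliberately naive and are not part of the public
# API.

# Dense fixed-step integration of the membrane equation with the same
# pairing/update contract as the event-driven engine. The integrator
# marches the voltage over a fixed grid; impulses are applied inside the
# step containing each arrival, at their exact offset (the input is a
# Dirac comb, so placing the jump mid-step is what a correct stepped
# scheme does — quantising it to the step boundary injects an O(dt/tau)
# voltage error that can flip knife-edge threshold crossings). What this
# cross-checks against the engine is the fully independent R
# implementation of scheduling, refractory bookkeeping, threshold logic,
# pairing and update ordering.
#' @noRd
dense_integrator <- function(config, params = neuron_params(),
                             protocol = stim_protocol(),
                             learning = learning_curve(),
                             dt = 0.01, pair_refractory = FALSE) {
  if (dt > 0.05) stop("dense integrator requires dt <= 0.05 ms", call. = FALSE)
  validate_config(config, params)
  sp <- to_scaled_units(params)
  sched <- build_arrival_schedule(protocol, config)
  n_cycles <- floor(protocol$rate * protocol$duration + 1e-9)
  t_end <- max(sched$time) + dt
  M <- ceiling(t_end / dt)

  w_syn <- config$w_syn
  w_dend <- config$w_dend
  mode <- config$mode
  v <- 0; refr_end <- -Inf
  a <- 1L; nA <- nrow(sched)
  hist <- data.frame(time = numeric(), input = integer(),
                     dendrite = integer(), kind = character())
  spikes <- list(); subs_rec <- list(); pairs <- list()

  push_event <- function(kind, time, input, dendrite) {
    ev <- list(kind = kind, time = time, input = input, dendrite = dendrite)
    prs <- enumerate_pairs(ev, hist, mode, learning)
    if (nrow(prs)) {
      for (r in seq_len(nrow(prs))) {
        if (mode == "synaptic") {
          w <- w_syn[prs$target[r]] * (1 + prs$dW[r])
          w_syn[prs$target[r]] <<- max(w, learning$weight_floor)
        } else {
          w <- w_dend[prs$target[r]] * (1 + prs$dW[r])
          w_dend[prs$target[r]] <<- max(w, learning$weight_floor)
        }
      }
      pairs[[length(pairs) + 1L]] <<- prs
    }
    hist <<- rbind(hist, data.frame(time = time, input = input,
                                    dendrite = dendrite, kind = kind))
    # only a bounded history window is ever needed
    if (nrow(hist) > 200)
      hist <<- hist[hist$time >= time - learning$cutoff - 1, , drop = FALSE]
  }

  t_cur <- 0
  for (m in seq_len(M)) {
    t_step <- m * dt
    while (a <= nA && sched$time[a] <= t_step + 1e-12) {
      t_arr <- sched$time[a]
      i <- sched$input[a]
      d <- sched$dendrite[a]
      a <- a + 1L
      eff <- w_syn[i] * w_dend[d]
      if (refr_end - t_arr > 1e-9) {
        if (pair_refractory) push_event("sub", t_arr, i, d)
        next
      }
      v <- v * exp(-(t_arr - t_cur) / sp$tau_membrane)
      t_cur <- t_arr
      v <- v + eff
      if (v >= 1) {
        # reported at the step boundary; refractory and pairing use the
        # exact arrival time
        spikes[[length(spikes) + 1L]] <- c(t_step, i, d)
        v <- 0
        refr_end <- t_arr + sp$refractory
        push_event("spike", t_arr, i, d)
      } else {
        push_event("sub", t_arr, i, d)
      }
    }
    v <- v * exp(-(t_step - t_cur) / sp$tau_membrane)
    t_cur <- t_step
    if (t_step <= refr_end) v <- 0
  }

  sp_mat <- do.call(rbind, spikes)
  list(spikes = data.frame(
         time_ms = if (is.null(sp_mat)) numeric() else sp_mat[, 1],
         input = if (is.null(sp_mat)) integer() else as.integer(sp_mat[, 2]),
         dendrite = if (is.null(sp_mat)) integer() else
           as.integer(sp_mat[, 3])),
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
       final_w_syn = w_syn, final_w_dend = w_dend,
       n_cycles = n_cycles)
}

# Exhaustive double loop over all (spike, sub-threshold) combinations of a
# completed trace, with the same exclusion rule and inclusive cutoff as the
# engine. Order-normalised by (time of later event, time of earlier event).
#' @noRd
brute_force_pairs <- function(trace, mode = trace$config$mode,
                              lc = trace$learning,
                              pair_refractory = trace$pair_refractory) {
  subs <- trace$arrivals[!trace$arrivals$caused_spike, , drop = FALSE]
  if (!isTRUE(pair_refractory))
    subs <- subs[!subs$during_refractory, , drop = FALSE]
  spikes <- trace$spikes
  out <- list()
  for (s in seq_len(nrow(spikes))) {
    for (u in seq_len(nrow(subs))) {
      delta <- subs$time_ms[u] - spikes$time_ms[s]
      if (abs(delta) > lc$cutoff + 1e-9) next
      if (mode == "synaptic") {
        if (subs$input[u] == spikes$input[s]) next
        target <- subs$input[u]
      } else {
        if (subs$dendrite[u] == spikes$dendrite[s]) next
        target <- subs$dendrite[u]
      }
      out[[length(out) + 1L]] <- data.frame(
        t_spike_ms = spikes$time_ms[s], t_sub_ms = subs$time_ms[u],
        delta_ms = delta, target_id = target,
        dW = learning_step(delta, lc))
    }
  }
  if (!length(out))
    return(data.frame(t_spike_ms = numeric(), t_sub_ms = numeric(),
                      delta_ms = numeric(), target_id = integer(),
                      dW = numeric()))
  res <- do.call(rbind, out)
  res[order(pmax(res$t_spike_ms, res$t_sub_ms),
            pmin(res$t_spike_ms, res$t_sub_ms), res$target_id), ,
      drop = FALSE]
}

# Synthetic weight trajectory that repeats a base pattern exactly (up to
# multiplicative noise), plus matching per-cycle signatures. Used to test
# the trajectory classifier against a known ground truth.
#' @noRd
make_periodic_fixture <- function(period, noise = 0, seed = 1,
                                  n_cycles = 40 * period, n_weights = 3) {
  set.seed(seed)
  base <- matrix(stats::runif(period * n_weights, 0.5, 1.5),
                 nrow = period)
  reps <- ceiling(n_cycles / period)
  W <- base[rep(seq_len(period), reps)[seq_len(n_cycles)], , drop = FALSE]
  if (noise > 0)
    W <- W * (1 + noise * matrix(stats::runif(length(W), -1, 1), nrow = n_cycles))
  sigs <- lapply(seq_len(n_cycles), function(k) {
    phase <- (k - 1) %% period
    list(cycle_index = k, offsets = 10 + 2 * phase,
         inputs = 1L, dendrites = 1L)
  })
  cfg <- network_config(delays = seq_len(n_weights) * 5,
                        dendrite_of = seq_len(n_weights),
                        w_syn = rep(1, n_weights),
                        w_dend = rep(1, n_weights),
                        mode = "dendritic")
  list(weights = W, signatures = sigs, config = cfg)
}
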