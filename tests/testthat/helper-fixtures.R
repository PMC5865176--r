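# Shared fixtures: small random networks for oracle comparisons.
# Everything is regenerated from seeds; nothing is stored on disk.

# A random small feedforward config (N <= 7 inputs on 1-3 dendrites) with
# delays loosely patterned on the published examples. Weights are drawn
# wide enough that traces mix spikes and sub-threshold arrivals.
random_small_config <- function(seed, mode = c("dendritic", "synaptic")) {
  mode <- match.arg(mode)
  set.seed(seed)
  nd <- sample(1:3, 1)
  per <- sample(1:3, nd, replace = TRUE)
  n <- sum(per)
  dendrite_of <- rep(seq_len(nd), times = per)
  delays <- sort(runif(n, 1, 50))
  # enforce a little spacing so arrival order is stable
  delays <- delays + seq_len(n) * 0.11
  network_config(delays = delays, dendrite_of = dendrite_of,
                 w_syn = runif(n, 0.2, 1.4),
                 w_dend = runif(nd, 0.7, 1.3),
                 mode = mode)
}

fig2b_spec <- function(duration = 0.1) make_preset("fig2b_dendritic", duration = duration)
fig3b_spec <- function(duration = 0.1) make_preset("fig3b_dendritic", duration = duration)
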