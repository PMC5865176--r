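#' Specification of the random initial-condition sampler
#'
#' Defines the distribution of random architectures used to probe how
#' common weight oscillations are under dendritic learning. Synaptic delays
#' are drawn uniformly between 1 and 50 ms subject to two constraints: any
#' two delays on the same dendrite differ by at least `min_gap_same_dendrite`
#' ms, and both the globally shortest and the globally longest delay fall
#' on the first dendrite. Synaptic weights are uniform on `weight_range`
#' and, so that firing can start at all, at least one effective weight
#' (initial dendritic weights are all 1) must be at or above threshold.
#'
#' @param n_dendrites Number of dendrites.
#' @param synapses_per_dendrite Number of inputs on each dendrite.
#' @param delay_range Delay range in ms.
#' @param min_gap_same_dendrite Minimum spacing of same-dendrite delays, ms.
#' @param weight_range Synaptic-weight range.
#' @param require_effective_above_threshold Resample weights until at least
#'   one effective weight is `>= 1` (scaled threshold).
#' @param integer_delays Draw whole-millisecond delays instead of
#'   continuous ones (comparison toggle).
#' @param resample_cap Maximum rejection-sampling attempts per
#'   configuration; breaching the cap is an error, never silent.
#' @return A list of class `sampler_spec`.
#' @export
sampler_spec <- function(n_dendrites = 3, synapses_per_dendrite = 3,
                         delay_range = c(1, 50),
                         min_gap_same_dendrite = 3,
                         weight_range = c(0.1, 1.8),
                         require_effective_above_threshold = TRUE,
                         integer_delays = FALSE,
                         resample_cap = 1e5) {
  if (n_dendrites < 1) stop("n_dendrites must be >= 1", call. = FALSE)
  if (synapses_per_dendrite < 1)
    stop("synapses_per_dendrite must be >= 1", call. = FALSE)
  structure(list(n_dendrites = as.integer(n_dendrites),
                 synapses_per_dendrite = as.integer(synapses_per_dendrite),
                 delay_range = as.numeric(delay_range),
                 min_gap_same_dendrite = as.numeric(min_gap_same_dendrite),
                 weight_range = as.numeric(weight_range),
                 require_effective_above_threshold =
                   isTRUE(require_effective_above_threshold),
                 integer_delays = isTRUE(integer_delays),
                 resample_cap = as.integer(resample_cap)),
            class = "sampler_spec")
}

#' Draw one random network configuration
#'
#' Rejection-samples delays and weights until all constraints of the
#' [sampler_spec()] hold; see that help page for the constraint set.
#' Dendritic weights are initialised to 1 and the configuration is returned
#' in dendritic learning mode.
#'
#' @param spec A [sampler_spec()].
#' @param seed Optional integer; if given, seeds the RNG so the draw is
#'   reproducible in isolation.
#' @return A [network_config()].
#' @export
sample_config <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- spec$n_dendrites
  spd <- spec$synapses_per_dendrite
  n <- nd * spd
  dendrite_of <- rep(seq_len(nd), each = spd)
  lo <- spec$delay_range[1]; hi <- spec$delay_range[2]

  draw_delays <- function() {
    if (spec$integer_delays)
      sample(seq(lo, hi), n, replace = TRUE)
    else
      stats::runif(n, lo, hi)
  }
  ok_delays <- function(d) {
    for (k in seq_len(nd)) {
      dk <- sort(d[dendrite_of == k])
      if (length(dk) > 1 &&
          any(diff(dk) < spec$min_gap_same_dendrite - 1e-12)) return(FALSE)
    }
    dendrite_of[which.min(d)] == 1L && dendrite_of[which.max(d)] == 1L
  }

  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > spec$resample_cap)
      stop("sampler resample cap reached for delays; ",
           "constraints are infeasible or nearly so for this spec",
           call. = FALSE)
    d <- draw_delays()
    if (ok_delays(d)) break
  }

  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > spec$resample_cap)
      stop("sampler resample cap reached for weights", call. = FALSE)
    w <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
    if (!spec$require_effective_above_threshold || any(w >= 1)) break
  }

  network_config(delays = d, dendrite_of = dendrite_of, w_syn = w,
                 w_dend = rep(1, nd), mode = "dendritic")
}

#' Monte-Carlo estimate of the oscillatory fraction
#'
#' Samples `n_samples` random initial conditions from the
#' [sampler_spec()], simulates each in dendritic learning mode under
#' periodic stimulation, classifies every weight trajectory with
#' [classify_trace()], and reports the fraction of trajectories classified
#' oscillatory together with an exact binomial 95% confidence interval.
#' Undetermined runs are reported separately and never counted as
#' oscillatory. Per-sample RNG seeds are derived from the master seed by
#' sample index, so the result does not depend on execution order.
#'
#' @param spec A [sampler_spec()].
#' @param n_samples Number of sampled initial conditions, `>= 1`.
#' @param duration Per-sample simulated time in seconds.
#' @param params,protocol_rate,learning Simulation settings.
#' @param settings A [classifier_settings()].
#' @param seed Master integer seed.
#' @param keep_classifications Attach the per-sample `trajectory_class`
#'   list to the report.
#' @param escalate_duration Runs classified `undetermined` at `duration`
#'   are re-simulated once at this longer duration (seconds) before the
#'   label is final. Limit cycles are approached geometrically and some
#'   lock slowly, so a run can need on the order of 10^4 cycles before the
#'   trajectory repeats within tolerance; several full periods must also
#'   fit in the post-burn-in window. Set equal to `duration` to disable.
#' @return A list of class `ensemble_report` with `n_samples`, `counts`
#'   (per label), `oscillatory_fraction`, `ci95`, `seed`, `settings`,
#'   `spec`.
#' @export
oscillatory_fraction <- function(spec, n_samples = 500, duration = 200,
                                 params = neuron_params(),
                                 protocol_rate = 10,
                                 learning = learning_curve(),
                                 settings = classifier_settings(),
                                 seed = 1,
                                 keep_classifications = FALSE,
                                 escalate_duration = 15 * duration) {
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  protocol <- stim_protocol(rate = protocol_rate, duration = duration)
  set.seed(seed)
  sample_seeds <- sample.int(2147483646L, n_samples)
  labels <- c("converged_extreme", "converged_intermediate",
              "oscillatory", "undetermined")
  counts <- stats::setNames(integer(length(labels)), labels)
  classifications <- if (keep_classifications) vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    cfg <- sample_config(spec, seed = sample_seeds[i])
    tr <- simulate_network(cfg, params = params, protocol = protocol,
                           learning = learning, seed = sample_seeds[i],
                           record_events = FALSE)
    cl <- classify_trace(tr, settings)
    if (cl$label == "undetermined" && escalate_duration > duration) {
      tr <- simulate_network(cfg, params = params,
                             protocol = stim_protocol(rate = protocol_rate,
                                                      duration = escalate_duration),
                             learning = learning, seed = sample_seeds[i],
                             record_events = FALSE)
      cl <- classify_trace(tr, settings)
    }
    counts[cl$label] <- counts[cl$label] + 1L
    if (keep_classifications) classifications[[i]] <- cl
  }
  k <- counts[["oscillatory"]]
  ci <- stats::binom.test(k, n_samples)$conf.int
  rep <- list(n_samples = n_samples, counts = counts,
              oscillatory_fraction = k / n_samples,
              ci95 = as.numeric(ci), seed = seed,
              settings = settings, spec = spec, duration = duration)
  if (keep_classifications) rep$classifications <- classifications
  class(rep) <- "ensemble_report"
  rep
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble_report> n = %d, oscillatory fraction = %.3f (95%% CI %.3f-%.3f)\n",
              x$n_samples, x$oscillatory_fraction, x$ci95[1], x$ci95[2]))
  print(x$counts)
  invisible(x)
}
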