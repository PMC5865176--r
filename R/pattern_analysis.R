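#' Per-cycle firing signatures of a trace
#'
#' Splits the output spike train into stimulation cycles and records, for
#' each cycle, the ordered spike offsets within the cycle (quantized to
#' `offset_quantum` ms for comparability) together with the input and
#' dendrite that evoked each spike.
#'
#' @param trace An `lif_trace` from [simulate_network()].
#' @param protocol A [stim_protocol()]; defaults to the one stored in the
#'   trace.
#' @param offset_quantum Quantization step for spike offsets, ms.
#' @return A list with one element per cycle, each a list with
#'   `cycle_index`, `offsets`, `inputs`, `dendrites`.
#' @export
extract_signatures <- function(trace, protocol = trace$protocol,
                               offset_quantum = 0.01) {
  period <- protocol$period
  n_cycles <- trace$n_cycles
  cyc <- pmin(floor(trace$spikes$time_ms / period + 1e-9), n_cycles - 1)
  off <- trace$spikes$time_ms - cyc * period
  off <- round(off / offset_quantum) * offset_quantum
  o <- order(cyc, off)
  by_cycle <- split(o, factor(cyc[o], levels = 0:(n_cycles - 1)))
  out <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    sel <- by_cycle[[k]]
    out[[k]] <- list(cycle_index = k,
                     offsets = off[sel],
                     inputs = trace$spikes$input[sel],
                     dendrites = trace$spikes$dendrite[sel])
  }
  out
}

signature_key <- function(sig, digits = 2) {
  if (!length(sig$offsets)) return("-")
  paste(sprintf("%.*f:%d", digits, sig$offsets, sig$inputs), collapse = "|")
}

signatures_equal <- function(a, b, offset_tol = 0.01) {
  length(a$offsets) == length(b$offsets) &&
    identical(a$inputs, b$inputs) &&
    (length(a$offsets) == 0 ||
       max(abs(a$offsets - b$offsets)) <= offset_tol + 1e-9)
}

#' Classifier settings for weight-trajectory analysis
#'
#' Tunable parameters of [classify_trajectory()]. The underlying model
#' defines no operational convergence or oscillation criterion, so all
#' tolerances are explicit here.
#'
#' @param burn_in_frac Fraction of cycles discarded as transient.
#' @param tol_converged Maximum relative weight excursion over the trailing
#'   `conv_window` cycles for a trajectory to count as converged.
#' @param conv_window Trailing window (cycles) for the convergence test.
#' @param tol_cycle Relative weight tolerance when matching states one
#'   period apart. Limit cycles are approached geometrically, so finite
#'   runs carry a small residual mismatch at the true period; the default
#'   accommodates that while staying far below the weight swings of a real
#'   oscillation.
#' @param offset_tol Spike-offset tolerance (ms) when matching firing
#'   signatures.
#' @param min_repeats Number of full periods over which periodicity must
#'   hold.
#' @param extreme_low Weight at or below which an adaptive weight counts as
#'   vanished when labelling a converged state extreme.
#' @return A list of class `classifier_settings`.
#' @export
classifier_settings <- function(burn_in_frac = 0.5,
                                tol_converged = 1e-4,
                                conv_window = 100,
                                tol_cycle = 1e-3,
                                offset_tol = 0.01,
                                min_repeats = 3,
                                extreme_low = 0.01) {
  structure(list(burn_in_frac = burn_in_frac,
                 tol_converged = tol_converged,
                 conv_window = conv_window,
                 tol_cycle = tol_cycle,
                 offset_tol = offset_tol,
                 min_repeats = min_repeats,
                 extreme_low = extreme_low),
            class = "classifier_settings")
}

#' Classify a weight trajectory
#'
#' Discards a burn-in prefix, then labels the adaptive-weight trajectory:
#'
#' * `converged_extreme` — weights settled, and every adaptive target is
#'   either vanished (`<= extreme_low`) or carries an effective weight at or
#'   above threshold;
#' * `converged_intermediate` — weights settled away from those extremes;
#' * `oscillatory` — the joint sequence of adaptive weights and firing
#'   signatures recurs with some period `p >= 2` cycles, verified over at
#'   least `min_repeats` full periods, with the firing signature actually
#'   changing within the period;
#' * `undetermined` — none of the above within the available cycles.
#'
#' Periodicity is tested on the joint (weights, signature) state so weight
#' plateaus with changing firing patterns are not misread as converged or
#' periodic. The non-constant-signature requirement reflects the dynamics:
#' under a fixed firing pattern every adaptive weight is multiplied by the
#' same factor each cycle, so its trajectory is constant or monotone —
#' a genuine weight oscillation must cycle through different firing
#' patterns. This also protects against reading a slow monotone drift as a
#' short-period oscillation.
#'
#' @param weights Numeric matrix of adaptive weights, one row per cycle
#'   (synaptic mode: `w_syn` columns; dendritic mode: `w_dend` columns).
#' @param signatures Per-cycle signatures from [extract_signatures()].
#' @param config The [network_config()] that produced the trajectory (used
#'   to evaluate effective weights of converged states).
#' @param settings A [classifier_settings()].
#' @return A list of class `trajectory_class` with `label`,
#'   `period_cycles` (or `NA`), `burn_in_used` and
#'   `asymptotic_signatures` (character keys: one for converged traces, the
#'   periodic sequence for oscillatory ones).
#' @export
classify_trajectory <- function(weights, signatures, config,
                                settings = classifier_settings()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  burn <- floor(settings$burn_in_frac * n)
  if (n < 2 * burn || n - burn < 2)
    stop("trajectory shorter than twice the burn-in", call. = FALSE)
  tail_w <- weights[(burn + 1):n, , drop = FALSE]
  tail_s <- signatures[(burn + 1):n]
  Tn <- nrow(tail_w)

  res <- list(label = "undetermined", period_cycles = NA_integer_,
              burn_in_used = burn, asymptotic_signatures = character())
  class(res) <- "trajectory_class"
  if (any(!is.finite(tail_w))) return(res)

  # convergence: relative excursion over the trailing window, with a
  # stable firing signature (a weight plateau under a changing firing
  # pattern is not a converged state)
  w0 <- max(1, Tn - settings$conv_window + 1)
  win <- tail_w[w0:Tn, , drop = FALSE]
  final <- tail_w[Tn, ]
  span <- apply(win, 2, max) - apply(win, 2, min)
  rel <- span / pmax(abs(final), 1e-12)
  sig_stable <- all(vapply(w0:Tn, function(t)
    signatures_equal(tail_s[[t]], tail_s[[Tn]], settings$offset_tol),
    logical(1)))
  if (max(rel) < settings$tol_converged && sig_stable) {
    res$label <- if (.is_extreme_state(final, config, settings))
      "converged_extreme" else "converged_intermediate"
    res$asymptotic_signatures <- signature_key(tail_s[[Tn]])
    return(res)
  }

  # periodicity on the joint (weights, signature) state
  max_p <- floor(Tn / settings$min_repeats)
  if (max_p >= 2) {
    # candidate periods in one vectorized pass: cycle Tn - p must already
    # match the final cycle in weights (within tolerance) and in firing
    # signature before the full window is worth checking
    final_w <- tail_w[Tn, ]
    d_final <- abs(sweep(tail_w, 2, final_w)) /
      matrix(pmax(abs(final_w), 1e-12), Tn, ncol(tail_w), byrow = TRUE)
    row_max <- do.call(pmax, lapply(seq_len(ncol(d_final)),
                                    function(j) d_final[, j]))
    w_near <- row_max <= settings$tol_cycle
    keys <- vapply(tail_s, signature_key, character(1))
    cand_t <- which(w_near & keys == keys[Tn])
    cand_p <- sort(Tn - cand_t)
    cand_p <- cand_p[cand_p >= 2 & cand_p <= max_p]
    for (p in cand_p) {
      lo <- Tn - settings$min_repeats * p + 1
      idx <- lo:(Tn - p)
      d <- abs(tail_w[idx + p, , drop = FALSE] - tail_w[idx, , drop = FALSE]) /
        pmax(abs(tail_w[idx, , drop = FALSE]), 1e-12)
      if (max(d) > settings$tol_cycle) next
      ok <- TRUE
      for (t in idx) {
        if (!signatures_equal(tail_s[[t]], tail_s[[t + p]],
                              settings$offset_tol)) { ok <- FALSE; break }
      }
      if (!ok) next
      # a true weight oscillation must visit more than one firing pattern
      one_period <- tail_s[(Tn - p + 1):Tn]
      varied <- any(!vapply(one_period[-1], signatures_equal,
                            logical(1), b = one_period[[1]],
                            offset_tol = settings$offset_tol))
      if (!varied) next
      res$label <- "oscillatory"
      res$period_cycles <- as.integer(p)
      res$asymptotic_signatures <-
        vapply(tail_s[(Tn - p + 1):Tn], signature_key, character(1))
      return(res)
    }
  }
  res
}

# A converged state is "extreme" when every adaptive target has either
# vanished or carries an effective weight at/above the (scaled) threshold.
.is_extreme_state <- function(final, config, settings) {
  if (config$mode == "synaptic") {
    eff <- final * config$w_dend[config$dendrite_of]
    all(final <= settings$extreme_low | eff >= 1)
  } else {
    eff <- vapply(seq_len(config$n_dendrites), function(d)
      max(config$w_syn[config$dendrite_of == d]) * final[d], numeric(1))
    all(final <= settings$extreme_low | eff >= 1)
  }
}

#' @export
print.trajectory_class <- function(x, ...) {
  cat(sprintf("<trajectory_class> %s%s (burn-in %d cycles)\n", x$label,
              if (!is.na(x$period_cycles))
                sprintf(", period %d cycles", x$period_cycles) else "",
              x$burn_in_used))
  invisible(x)
}

#' Classify a simulated trace end-to-end
#'
#' Convenience wrapper: extracts the adaptive-weight series and per-cycle
#' firing signatures from a trace and runs [classify_trajectory()].
#'
#' @param trace An `lif_trace` from [simulate_network()].
#' @param settings A [classifier_settings()].
#' @return A `trajectory_class`, see [classify_trajectory()].
#' @export
classify_trace <- function(trace, settings = classifier_settings()) {
  cols <- if (trace$config$mode == "synaptic")
    paste0("W_", seq_len(trace$config$n_inputs))
  else
    paste0("WD_", seq_len(trace$config$n_dendrites))
  W <- as.matrix(trace$weights[, cols, drop = FALSE])
  classify_trajectory(W, extract_signatures(trace), trace$config, settings)
}

#' Count distinct asymptotic firing patterns
#'
#' Deduplicates the asymptotic firing behaviour of a collection of
#' classified trajectories: a converged trace contributes its single
#' stationary signature, an oscillatory trace its periodic signature
#' sequence taken up to cyclic rotation (the same loop entered at a
#' different phase counts once).
#'
#' @param classified List of `trajectory_class` objects (all with labels
#'   other than `undetermined`).
#' @return Integer count of distinct asymptotic firing patterns.
#' @export
count_distinct_signatures <- function(classified) {
  keys <- vapply(classified, function(cl) {
    if (cl$label == "undetermined")
      stop("cannot count signatures of an undetermined trajectory",
           call. = FALSE)
    sigs <- cl$asymptotic_signatures
    if (length(sigs) > 1) {
      rots <- vapply(seq_along(sigs), function(r) {
        paste(sigs[c(r:length(sigs), seq_len(r - 1))], collapse = ">>")
      }, character(1))
      min(rots)
    } else paste(sigs, collapse = ">>")
  }, character(1))
  length(unique(keys))
}
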