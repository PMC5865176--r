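test_that("learning window matches its closed form at reference lags", {
  # frozen values computed independently via R's arbitrary-precision
  # bignum route: 0.05*exp(-3/15) and -0.05*exp(-5/15)
  expect_equal(learning_step(3), 0.040936537653899, tolerance = 1e-10)
  expect_equal(learning_step(-5), -0.035826565528689, tolerance = 1e-10)
  expect_identical(learning_step(0), 0)
  expect_identical(learning_step(-60), 0)   # beyond the 50 ms cutoff
  expect_identical(learning_step(51), 0)
  expect_gt(learning_step(50), 0)           # cutoff boundary inclusive
})

test_that("learning window is antisymmetric, bounded and monotone", {
  lags <- seq(0.01, 50, length.out = 400)
  expect_equal(learning_step(-lags), -learning_step(lags))
  expect_true(all(abs(learning_step(lags)) < learning_curve()$amplitude))
  # supremum approached as the lag vanishes
  expect_equal(learning_step(1e-9), 0.05, tolerance = 1e-9)
  mags <- abs(learning_step(lags))
  expect_true(all(diff(mags[order(lags)]) < 0))
})

test_that("pair enumeration reproduces the two-dendrite worked example", {
  # cycle 0: spike at 12 ms via the left dendrite; sub-threshold arrivals
  # at 7 ms and 15 ms via the right dendrite -> lags -5 and +3 ms
  hist <- data.frame(time = 7, input = 2L, dendrite = 2L, kind = "sub")
  spike <- list(kind = "spike", time = 12, input = 1L, dendrite = 1L)
  p1 <- enumerate_pairs(spike, hist, "dendritic")
  expect_equal(p1$delta, -5)
  expect_identical(p1$target, 2L)
  hist2 <- rbind(hist, data.frame(time = 12, input = 1L, dendrite = 1L,
                                  kind = "spike"))
  p2 <- enumerate_pairs(list(kind = "sub", time = 15, input = 3L,
                             dendrite = 2L), hist2, "dendritic")
  expect_equal(p2$delta, 3)
  expect_identical(p2$target, 2L)
})

test_that("pairs sharing an input or dendrite are excluded by mode", {
  hist <- data.frame(time = 10, input = 1L, dendrite = 1L, kind = "spike")
  same_dend <- list(kind = "sub", time = 14, input = 2L, dendrite = 1L)
  expect_identical(nrow(enumerate_pairs(same_dend, hist, "dendritic")), 0L)
  expect_identical(nrow(enumerate_pairs(same_dend, hist, "synaptic")), 1L)
  same_input_recur <- list(kind = "sub", time = 14, input = 1L,
                           dendrite = 1L)
  expect_identical(nrow(enumerate_pairs(same_input_recur, hist,
                                        "synaptic")), 0L)
})

test_that("pairs beyond the cutoff do not form; the boundary does", {
  hist <- data.frame(time = 40, input = 1L, dendrite = 1L, kind = "spike")
  far <- list(kind = "sub", time = 105, input = 2L, dendrite = 2L)
  expect_identical(nrow(enumerate_pairs(far, hist, "dendritic")), 0L)
  at_cut <- list(kind = "sub", time = 90, input = 2L, dendrite = 2L)
  p <- enumerate_pairs(at_cut, hist, "dendritic")
  expect_identical(nrow(p), 1L)
  expect_equal(p$delta, 50)
})

test_that("multiplicative updates clamp at the weight floor", {
  lc <- learning_curve()
  w <- list(w_syn = c(1, 1), w_dend = 1)
  up <- apply_update(w, list(target = 1L, dW = 0.05), "synaptic", lc)
  expect_equal(up$w_syn, c(1.05, 1))
  dn <- apply_update(list(w_syn = 0.001, w_dend = 1),
                     list(target = 1L, dW = -0.05), "synaptic", lc)
  expect_identical(dn$w_syn, 0.001)
  same <- apply_update(w, list(target = 2L, dW = 0), "synaptic", lc)
  expect_identical(same$w_syn, w$w_syn)
})

test_that("per-cycle drift is the product of the cycle's pairings", {
  ps <- fig2b_spec()
  drift <- net_cycle_drift(ps$config, spike_times = 12)
  # right dendrite: (1 + dW(+3)) * (1 + dW(-5)) - 1, strictly positive --
  # the right dendrite strengthens on average
  expect_equal(unname(drift["WD_2"]),
               (1 + learning_step(3)) * (1 + learning_step(-5)) - 1,
               tolerance = 1e-12)
  expect_equal(unname(drift["WD_2"]), 0.0036434, tolerance = 1e-4)
  expect_gt(drift["WD_2"], 0)
  expect_identical(unname(drift["WD_1"]), 0)
  # silent cycle: no pairs, no drift
  expect_identical(unname(net_cycle_drift(ps$config, numeric())),
                   c(0, 0))
  # a single pair equals one learning step exactly
  cfg1 <- network_config(delays = c(12, 15), dendrite_of = c(1, 2),
                         w_syn = c(1, 0.5))
  expect_equal(unname(net_cycle_drift(cfg1, 12)["WD_2"]),
               learning_step(3))
})

test_that("no adaptive weight in any trace ever dips below the floor", {
  for (seed in 1:10) {
    cfg <- random_small_config(seed)
    tr <- simulate_network(cfg, protocol = stim_protocol(10, 5),
                           record_events = FALSE)
    snaps <- as.matrix(tr$weights[, -1])
    expect_true(all(snaps >= learning_curve()$weight_floor))
  }
})

test_that("synaptic learning drives weights to vanishing or threshold", {
  for (spec in list(make_preset("fig2a_synaptic", duration = 300),
                    make_preset("fig3a_synaptic", duration = 300))) {
    tr <- simulate_network(spec$config, spec$params, spec$protocol,
                           spec$learning, record_events = FALSE)
    w <- tr$final_w_syn
    eff <- w * spec$config$w_dend[spec$config$dendrite_of]
    # every adaptive weight is extinct or strong enough to evoke its spike
    last_cycle <- tr$spikes$time_ms > (tr$n_cycles - 1) * tr$period
    fired_delay <- tr$spikes$time_ms[last_cycle] -
      (tr$n_cycles - 1) * tr$period
    fires <- vapply(spec$config$delays, function(d)
      any(abs(fired_delay - d) < 1e-6), logical(1))
    expect_true(all(w < 0.01 | fires | eff >= 1))
  }
})
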