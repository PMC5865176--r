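test_that("leak decay follows the closed form and matches naive stepping", {
  p <- neuron_params()
  expect_identical(decay_voltage(1, 0, p), 1)
  expect_identical(decay_voltage(0, 123.4, p), 0)  # rest is a fixed point
  # one membrane time constant: v drops to exp(-1); cross-check against a
  # fixed-step explicit Euler integration of dV/dt = -V/tau at dt = 1e-4
  v <- 1; dt <- 1e-4
  for (i in seq_len(20 / dt)) v <- v - dt * v / p$tau_membrane
  expect_equal(decay_voltage(1, 20, p), 0.36788, tolerance = 1e-4)
  expect_equal(decay_voltage(1, 20, p), v, tolerance = 1e-4)
  expect_error(decay_voltage(1, -0.1, p), "dt")
})

test_that("arrival schedules merge per-cycle delays in time order", {
  ps <- fig2b_spec()
  s2 <- build_arrival_schedule(stim_protocol(10, 0.1), ps$config)
  expect_equal(s2$time, c(7, 12, 15))
  ps3 <- fig3b_spec()
  s3 <- build_arrival_schedule(stim_protocol(10, 0.1), ps3$config)
  expect_equal(s3$time, c(5, 10, 20, 25, 40, 46, 50))
  one <- network_config(delays = 12, dendrite_of = 1, w_syn = 1)
  s1 <- build_arrival_schedule(stim_protocol(10, 0.3), one)
  expect_equal(s1$time, c(12, 112, 212))
  expect_error(build_arrival_schedule(stim_protocol(10, 0.05), one),
               "zero")
})

test_that("arrivals jump, cross threshold, and respect the refractory clamp", {
  p <- neuron_params()
  st <- list(v = 0.5, refr_end = -Inf)
  ev <- list(time = 10, input = 1L, dendrite = 1L, effective_weight = 0.6)
  res <- apply_arrival(st, ev, p)
  expect_true(res$caused_spike)
  expect_identical(res$state$v, 0)
  expect_identical(res$state$refr_end, 12)
  res2 <- apply_arrival(list(v = 0, refr_end = -Inf),
                        list(time = 0, input = 1L, dendrite = 1L,
                             effective_weight = 0.99), p)
  expect_false(res2$caused_spike)
  expect_equal(res2$state$v, 0.99)
  # 1 ms after a spike: inside the 2 ms window, voltage must not move
  res3 <- apply_arrival(res$state,
                        list(time = 11, input = 2L, dendrite = 2L,
                             effective_weight = 5), p)
  expect_true(res3$during_refractory)
  expect_identical(res3$state$v, 0)
})

test_that("first-cycle latencies of the worked examples are exact", {
  ps <- fig2b_spec()
  tr <- simulate_network(ps$config, ps$params, ps$protocol, ps$learning)
  expect_equal(tr$spikes$time_ms[1], 12)
  expect_identical(tr$spikes$dendrite[1], 1L)
  ps3 <- fig3b_spec()
  tr3 <- simulate_network(ps3$config, ps3$params, ps3$protocol, ps3$learning)
  expect_equal(tr3$spikes$time_ms[1], 40)
  expect_identical(tr3$spikes$input[1], 6L)
})

test_that("a never-crossing input yields no spikes and frozen weights", {
  cfg <- network_config(delays = 9, dendrite_of = 1, w_syn = 0.5,
                        mode = "synaptic")
  tr <- simulate_network(cfg, protocol = stim_protocol(10, 1))
  expect_identical(nrow(tr$spikes), 0L)
  expect_true(all(tr$weights$W_1 == 0.5))
  expect_identical(nrow(tr$pairs), 0L)
})

test_that("traces are deterministic and reruns byte-identical", {
  ps <- fig3b_spec(duration = 5)
  tr1 <- simulate_network(ps$config, ps$params, ps$protocol, ps$learning,
                          seed = 11L)
  tr2 <- simulate_network(ps$config, ps$params, ps$protocol, ps$learning,
                          seed = 11L)
  expect_identical(tr1, tr2)
  expect_identical(serialize(tr1, NULL), serialize(tr2, NULL))
})

test_that("no two spikes are closer than the refractory period", {
  for (seed in 1:12) {
    cfg <- random_small_config(seed)
    tr <- simulate_network(cfg, protocol = stim_protocol(10, 2),
                           record_events = FALSE)
    if (nrow(tr$spikes) > 1)
      expect_true(all(diff(tr$spikes$time_ms) >=
                        neuron_params()$refractory - 1e-9))
  }
})

test_that("the frozen parameter set never moves in either learning mode", {
  for (seed in 1:8) {
    cfg_d <- random_small_config(seed, mode = "dendritic")
    tr_d <- simulate_network(cfg_d, protocol = stim_protocol(10, 2),
                             record_events = FALSE)
    wcols <- paste0("W_", seq_len(cfg_d$n_inputs))
    expect_equal(unname(as.matrix(tr_d$weights[, wcols])),
                 matrix(cfg_d$w_syn, nrow = tr_d$n_cycles,
                        ncol = cfg_d$n_inputs, byrow = TRUE))
    cfg_s <- random_small_config(seed, mode = "synaptic")
    tr_s <- simulate_network(cfg_s, protocol = stim_protocol(10, 2),
                             record_events = FALSE)
    dcols <- paste0("WD_", seq_len(cfg_s$n_dendrites))
    expect_equal(unname(as.matrix(tr_s$weights[, dcols])),
                 matrix(cfg_s$w_dend, nrow = tr_s$n_cycles,
                        ncol = cfg_s$n_dendrites, byrow = TRUE))
  }
})

test_that("voltage decays monotonically toward rest between arrivals", {
  p <- neuron_params()
  v <- 0.9
  ts <- seq(0, 30, by = 0.5)
  vals <- decay_voltage(v, ts, p)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > p$v_rest))
})
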