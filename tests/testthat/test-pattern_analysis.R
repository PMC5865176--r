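test_that("signatures split spikes into cycles with quantized offsets", {
  ps <- fig2b_spec(duration = 0.3)
  tr <- simulate_network(ps$config, ps$params, ps$protocol, ps$learning)
  sg <- extract_signatures(tr)
  expect_length(sg, 3L)
  expect_equal(sg[[1]]$offsets, 12)
  expect_identical(sg[[1]]$dendrites, 1L)
  # a silent trace has empty offset lists
  quiet <- simulate_network(network_config(delays = 9, dendrite_of = 1,
                                           w_syn = 0.4),
                            protocol = stim_protocol(10, 0.3))
  expect_true(all(lengths(lapply(extract_signatures(quiet),
                                 `[[`, "offsets")) == 0))
})

test_that("the asymptotic two-dendrite state fires spike triplets", {
  ps <- make_preset("fig2b_dendritic", "triplet", duration = 300)
  tr <- simulate_network(ps$config, ps$params, ps$protocol, ps$learning,
                         record_events = FALSE)
  sg <- extract_signatures(tr)
  expect_length(sg[[tr$n_cycles]]$offsets, 3L)
  eff <- tr$final_w_syn * tr$final_w_dend[ps$config$dendrite_of]
  expect_true(all(eff >= 1))
})

test_that("a constant intermediate trajectory is converged_intermediate", {
  n <- 400
  W <- matrix(1.3, n, 2)
  sigs <- lapply(seq_len(n), function(k)
    list(cycle_index = k, offsets = 12, inputs = 1L, dendrites = 1L))
  cfg <- network_config(delays = c(12, 30), dendrite_of = c(1, 2),
                        w_syn = c(0.5, 0.5), mode = "dendritic")
  cl <- classify_trajectory(W, sigs, cfg)
  expect_identical(cl$label, "converged_intermediate")
  # same weights, but strong enough synapses: the state is extreme
  cfg2 <- network_config(delays = c(12, 30), dendrite_of = c(1, 2),
                         w_syn = c(0.9, 0.9), mode = "dendritic")
  expect_identical(classify_trajectory(W, sigs, cfg2)$label,
                   "converged_extreme")
})

test_that("constructed periodic trajectories classify at their period", {
  fx <- make_periodic_fixture(period = 7, noise = 0, seed = 3)
  cl <- classify_trajectory(fx$weights, fx$signatures, fx$config)
  expect_identical(cl$label, "oscillatory")
  expect_identical(cl$period_cycles, 7L)
  # noise far above tolerance destroys the periodicity verdict
  st <- classifier_settings()
  fx2 <- make_periodic_fixture(period = 2, noise = 10 * st$tol_cycle,
                               seed = 4)
  expect_false(identical(
    classify_trajectory(fx2$weights, fx2$signatures, fx2$config, st)$label,
    "oscillatory"))
})

test_that("classification is invariant to appending whole periods", {
  fx <- make_periodic_fixture(period = 5, noise = 0, seed = 9,
                              n_cycles = 200)
  fx_long <- make_periodic_fixture(period = 5, noise = 0, seed = 9,
                                   n_cycles = 400)
  cl <- classify_trajectory(fx$weights, fx$signatures, fx$config)
  cl_long <- classify_trajectory(fx_long$weights, fx_long$signatures,
                                 fx$config)
  expect_identical(cl$label, cl_long$label)
  expect_identical(cl$period_cycles, cl_long$period_cycles)
})

test_that("oscillatory and converged verdicts are mutually exclusive", {
  for (args in list(list("fig2b_dendritic", "triplet", 200),
                    list("fig2b_dendritic", "complex", 200))) {
    ps <- make_preset(args[[1]], args[[2]], duration = args[[3]])
    tr <- simulate_network(ps$config, ps$params, ps$protocol, ps$learning,
                           record_events = FALSE)
    cl <- classify_trace(tr)
    expect_true(cl$label %in% c("converged_extreme",
                                "converged_intermediate", "oscillatory",
                                "undetermined"))
    expect_identical(!is.na(cl$period_cycles), cl$label == "oscillatory")
  }
})

test_that("trajectories shorter than twice the burn-in are rejected", {
  fx <- make_periodic_fixture(period = 3, noise = 0, seed = 5,
                              n_cycles = 12)
  expect_error(
    classify_trajectory(fx$weights[1:2, ], fx$signatures[1:2], fx$config),
    "burn-in")
})

test_that("distinct asymptotic patterns deduplicate up to rotation", {
  conv <- function(key) structure(list(label = "converged_extreme",
                                       period_cycles = NA_integer_,
                                       burn_in_used = 10L,
                                       asymptotic_signatures = key),
                                  class = "trajectory_class")
  osc <- function(keys) structure(list(label = "oscillatory",
                                       period_cycles = length(keys),
                                       burn_in_used = 10L,
                                       asymptotic_signatures = keys),
                                  class = "trajectory_class")
  expect_identical(count_distinct_signatures(list(conv("12:1"),
                                                  conv("12:1"))), 1L)
  expect_identical(count_distinct_signatures(list(conv("12:1"),
                                                  osc(c("a", "b")))), 2L)
  # the same loop entered at a different phase counts once
  expect_identical(count_distinct_signatures(list(osc(c("a", "b", "c")),
                                                  osc(c("b", "c", "a")))),
                   1L)
  expect_error(count_distinct_signatures(list(structure(
    list(label = "undetermined", asymptotic_signatures = character()),
    class = "trajectory_class"))), "undetermined")
})

test_that("synaptic asymptotics are insensitive to initial weights while dendritic differ", {
  # the two initial-weight variants share the synaptic-mode asymptotic
  # firing pattern but diverge under dendritic learning
  asym_key <- function(id, variant, dur) {
    ps <- make_preset(id, variant, duration = dur)
    tr <- simulate_network(ps$config, ps$params, ps$protocol, ps$learning,
                           record_events = FALSE)
    sg <- extract_signatures(tr)
    s <- sg[[tr$n_cycles]]
    paste(sprintf("%.2f:%d", s$offsets, s$inputs), collapse = "|")
  }
  expect_identical(asym_key("fig2a_synaptic", "triplet", 300),
                   asym_key("fig2a_synaptic", "complex", 300))
  expect_false(identical(asym_key("fig2b_dendritic", "triplet", 300),
                         asym_key("fig2b_dendritic", "complex", 300)))
})
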