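test_that("asymmetry index: symmetry, antisymmetry and the weighted average", {
  expect_identical(asymmetry_index(c(1, 1, 1, 1, 1)), 0)
  w <- c(0.5, 0.2, 0.9, 0.4, 0.1)
  expect_equal(asymmetry_index(rev(w)), -asymmetry_index(w))
  # distance weights (2, 1) per side; central weight excluded
  expect_equal(asymmetry_index(c(2, 1, 7, 1, 1)), ((2 * 2 + 1) - (1 + 2)) / 3)
  expect_error(asymmetry_index(c(1, 2, 3, 4)), "central cell")
})

test_that("symmetric sideband circuit responds to fast sweeps of both directions", {
  net <- tilted_sideband(0)
  r <- responded_flags(net)
  rts <- as.numeric(names(r))
  expect_true(any(r))
  # mirror-symmetric responded set
  for (rate in rts[rts > 0]) expect_equal(unname(r[as.character(rate)]),
                                          unname(r[as.character(-rate)]))
  expect_true(r["Inf"] && r["-Inf"])
})

test_that("removing inhibition widens the responded range to a pure summation limit", {
  with_inh <- tilted_sideband(0)
  no_inh <- build_sideband(sideband_spec(w_input_to_inhib = rep(0, 5)))
  r1 <- responded_flags(with_inh)
  r0 <- responded_flags(no_inh)
  expect_gt(sum(r0), sum(r1))       # strictly more rates without inhibition
  expect_true(all(r1[r1] == r0[r1])) # and a superset of the inhibited set
  # without inhibition the set is the summation-limited fast-pass set
  rts <- abs(as.numeric(names(r0)))
  thr <- min(rts[r0])
  expect_true(all(r0[rts >= thr]))
})

test_that("strong asymmetry vetoes fast sweeps in the non-preferred direction", {
  net <- tilted_sideband(0.6)   # weight tilted onto the high-frequency side
  r <- responded_flags(net)
  expect_true(r["320"])          # preferred (upward) fast sweep passes
  expect_false(r["-320"])        # same-rate downward sweep is vetoed
  rts <- as.numeric(names(r))
  expect_gt(sum(r[rts > 0]), sum(r[rts < 0]))
})

test_that("sideband builder validates weights against the firing threshold", {
  expect_error(build_sideband(sideband_spec(w_input_to_output = 1)),
               "suprathreshold")
  expect_error(build_sideband(sideband_spec(w_input_to_output = 0.01)),
               "never fire")
  expect_error(sideband_spec(n_inputs = 4), "odd")
  expect_error(sideband_spec(w_input_to_inhib = c(1, 2, 3)), "length")
})

test_that("facilitation fires only for the delay-matched order and interval", {
  net <- build_facilitation(facilitation_spec())   # preferred interval 10 ms
  pref <- sweep_events(sweep_stimulus(100, 2, onset_ms = 5))
  sim <- simulate_network(net, pref, horizon_ms = 80)
  expect_gt(length(spike_times(sim, 3)), 0)

  wrong_dir <- sweep_events(sweep_stimulus(-100, 2, onset_ms = 5))
  sim2 <- simulate_network(net, wrong_dir, horizon_ms = 80)
  expect_length(spike_times(sim2, 3), 0)

  # simultaneous inputs with a delay difference beyond the window: no spike
  wide <- build_facilitation(facilitation_spec(delay_slow_ms = 16))
  sim3 <- simulate_network(wide, sweep_events(sweep_stimulus(Inf, 2, onset_ms = 5)),
                           horizon_ms = 80)
  expect_length(spike_times(sim3, 3), 0)

  expect_error(facilitation_spec(delay_fast_ms = 5, delay_slow_ms = 5),
               "rate preference")
})

test_that("anti-coincidence duration circuit shows one-less/preferred/one-more tuning", {
  net <- build_duration(duration_spec())
  curve <- duration_curve(net, counts = 1:10)
  pref <- curve$n_spikes[curve$responded]
  expect_gt(length(pref), 0)
  p0 <- min(pref)
  # one spike less: integrator never reaches threshold
  expect_false(curve$responded[curve$n_spikes == p0 - 1])
  # one spike more than the preferred interval: inhibition still present
  expect_false(curve$responded[curve$n_spikes == max(pref) + 1])
  # responded set is an interval
  expect_true(all(diff(pref) == 1))
})

test_that("preferred-duration output spikes just after the inhibition ends", {
  net <- build_duration(duration_spec())
  curve <- duration_curve(net, counts = 1:10)
  p0 <- min(curve$n_spikes[curve$responded])
  ev <- tone_events(tone_train(1, p0, 5, onset_ms = 5))
  sim <- simulate_network(net, ev, horizon_ms = max(ev$time_ms) + 80)
  t_out <- spike_times(sim, 4)
  t_inh <- spike_times(sim, 2)
  expect_gt(t_out[1], max(t_inh))   # response follows the last inhibitory spike
})

test_that("coincidence regime needs the rebound-excitation overlap", {
  spec <- duration_spec("coincidence")
  net <- build_duration(spec)
  curve <- duration_curve(net, counts = 1:12)
  expect_true(any(curve$responded))
  expect_true(all(diff(curve$n_spikes[curve$responded]) == 1))
  # without the delayed excitation the rebound alone is subthreshold
  spec0 <- spec
  spec0$w_mid_to_output <- 0
  net0 <- build_duration(spec0)
  curve0 <- duration_curve(net0, counts = 1:12)
  expect_false(any(curve0$responded))
})

test_that("duration builder rejects degenerate and regime-inconsistent weights", {
  expect_error(build_duration(duration_spec(w_weak = 0.5)), "single input spike")
  expect_error(build_duration(duration_spec("anti", w_mid_to_output = 0.1)),
               "suprathreshold")
  expect_error(build_duration(duration_spec("coincidence", w_mid_to_output = 1)),
               "subthreshold")
})
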