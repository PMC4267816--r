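test_that("STDP kernel constants and time constant", {
  expect_identical(stdp_event_value("pre_before_post", 1, 0), 0.025)
  expect_identical(stdp_event_value("post_before_pre", 1, 0), -0.025)
  expect_equal(stdp_event_value("pre_before_post", 1, 10), 0.025 * exp(-1))
  # multiplicative in strength; kinds symmetric in magnitude
  for (dt in c(0, 3, 10, 25)) {
    expect_equal(stdp_event_value("pre_before_post", 0.4, dt),
                 -stdp_event_value("post_before_pre", 0.4, dt))
  }
  # magnitude non-increasing in |dt|
  v <- vapply(0:30, function(d) stdp_event_value("pre_before_post", 1, d),
              numeric(1))
  expect_false(is.unsorted(rev(v)))
})

test_that("pairing ledger emits one event per adjacent opposite pairing", {
  e <- extract_stdp_events(10, 15)
  expect_equal(nrow(e), 1)
  expect_equal(e$kind, "pre_before_post")
  expect_equal(e$dt_ms, 5)

  # additional post spikes create no additional events
  e2 <- extract_stdp_events(10, c(15, 18))
  expect_equal(nrow(e2), 1)

  e3 <- extract_stdp_events(c(10, 22), 15)
  expect_equal(e3$kind, c("pre_before_post", "post_before_pre"))
  expect_equal(e3$dt_ms, c(5, 7))

  # simultaneous spikes create no event
  expect_equal(nrow(extract_stdp_events(10, 10)), 0)
  expect_equal(nrow(extract_stdp_events(numeric(0), c(1, 2))), 0)

  # interleaved trains: one event per type switch
  e4 <- extract_stdp_events(c(10, 20, 30), c(12, 22, 40))
  expect_equal(e4$kind, c("pre_before_post", "post_before_pre",
                          "pre_before_post", "post_before_pre",
                          "pre_before_post"))
  expect_equal(e4$dt_ms, c(2, 8, 2, 8, 10))
})

test_that("incoming-weight normalization conserves the total exactly", {
  expect_equal(normalize_incoming(c(0.35, 0.3, 0.35), 1), c(0.35, 0.3, 0.35))
  w <- normalize_incoming(c(0.4, 0.3, 0.4), 1, fixed = 1)
  expect_equal(w, c(0.4, 0.3 * 0.6 / 0.7, 0.4 * 0.6 / 0.7))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # permutation equivariance
  v <- c(0.1, 0.5, 0.2)
  expect_equal(normalize_incoming(rev(v), 2), rev(normalize_incoming(v, 2)))
  expect_error(normalize_incoming(c(0, 0), 1), "all-zero")
})

test_that("training potentiates toward the trained direction and conserves weight", {
  net <- build_sideband(sideband_spec(mean_inhib = 0.183, plastic = TRUE))
  sweep <- sweep_stimulus(320, 5, onset_ms = 5)
  fit <- train_direction(net, sweep, n_trials = 120, record_dsi_every = 60,
                         rate_grid = rates_coarse)
  traj <- fit$trajectory
  # |ASY| grows from zero
  expect_equal(traj$asy[1], 0)
  expect_gt(abs(traj$asy[nrow(traj)]), 0.05)
  # trained (upward) preference: stronger high-side weights, negative ASY,
  # DSI moves toward the trained direction
  expect_lt(traj$asy[nrow(traj)], 0)
  expect_gte(traj$dsi[nrow(traj)], traj$dsi[1])
  expect_gt(traj$dsi[nrow(traj)], 0)
  # exact conservation of total incoming plastic weight
  sums <- rowSums(fit$weights)
  expect_true(all(abs(sums - sums[1]) < 1e-12))
})

test_that("training is deterministic and mirror-symmetric", {
  net <- build_sideband(sideband_spec(mean_inhib = 0.183, plastic = TRUE))
  up <- sweep_stimulus(320, 5, onset_ms = 5)
  down <- sweep_stimulus(-320, 5, onset_ms = 5)
  f1 <- train_direction(net, up, n_trials = 40, record_dsi_every = 100,
                        rate_grid = rates_coarse)
  f2 <- train_direction(net, up, n_trials = 40, record_dsi_every = 100,
                        rate_grid = rates_coarse)
  expect_identical(f1$weights, f2$weights)
  f3 <- train_direction(net, down, n_trials = 40, record_dsi_every = 100,
                        rate_grid = rates_coarse)
  # tonotopic reflection: mirrored sweep gives the mirrored weight vector
  expect_equal(unname(f3$weights[41, ]), rev(unname(f1$weights[41, ])),
               tolerance = 1e-12)
  expect_equal(f3$trajectory$asy[41], -f1$trajectory$asy[41])
})

test_that("once the inhibitory cell leads the last input its synapse is depressed", {
  # lagging regime: inhibitory spike follows the last input -> potentiation
  lag_net <- build_sideband(sideband_spec(mean_inhib = 0.183, plastic = TRUE))
  # leading regime: stronger symmetric weights, inhibitory spike precedes
  # the last input -> STDP order reversed for that synapse
  lead_net <- build_sideband(sideband_spec(mean_inhib = 0.219, plastic = TRUE))
  sweep <- sweep_stimulus(320, 5, onset_ms = 5)
  ev <- sweep_events(sweep)

  sim <- simulate_network(lead_net, ev, horizon_ms = max(ev$time_ms) + 55)
  t_inh <- spike_times(sim, 6)
  t_last <- spike_times(sim, 5)
  expect_lt(t_inh[1], t_last[1])   # inhibitory cell leads the last input

  f_lag <- train_direction(lag_net, sweep, n_trials = 30,
                           record_dsi_every = 100, rate_grid = rates_coarse)
  f_lead <- train_direction(lead_net, sweep, n_trials = 30,
                            record_dsi_every = 100, rate_grid = rates_coarse)
  # last-input synapse: potentiated while lagging, depressed while leading
  expect_gt(f_lag$weights[31, 5], f_lag$weights[1, 5])
  expect_lt(f_lead$weights[31, 5], f_lead$weights[1, 5])
  # asymmetry growth is reduced in the leading regime
  expect_lt(abs(f_lead$trajectory$asy[31]), abs(f_lag$trajectory$asy[31]))
})

test_that("zero trials leave the network unchanged", {
  net <- build_sideband(sideband_spec(mean_inhib = 0.183, plastic = TRUE))
  fit <- train_direction(net, sweep_stimulus(320, 5, onset_ms = 5),
                         n_trials = 0, rate_grid = rates_coarse)
  expect_equal(nrow(fit$trajectory), 1)
  expect_identical(fit$network$synapses$g_syn, net$synapses$g_syn)
  expect_error(train_direction(build_sideband(sideband_spec()),
                               sweep_stimulus(320, 5), 5), "plastic")
})
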