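# shared fixtures for the test suite

# coarse signed rate grid (cells/s) used where the full default grid is
# unnecessarily fine
rates_coarse <- c(-Inf, -1000, -320, -100, -32, -10, 10, 32, 100, 320, 1000, Inf)

# sideband circuit with a linear asymmetry tilt of the inhibitory inputs
tilted_sideband <- function(asymmetry, mean_inhib = 0.274, ...) {
  build_sideband(sideband_spec(mean_inhib = mean_inhib,
                               asymmetry = asymmetry, ...))
}

# responded-rate flags of one network over a rate grid
responded_flags <- function(net, rates = rates_coarse, tail_ms = 50) {
  sc <- rate_scan(net, rates = rates, tail_ms = tail_ms)
  setNames(sc$responded, sc$rate)
}

# maximum blocked depolarization of a facilitation circuit for a given
# inter-input interval (ms, positive: cell 1 first)
facilitation_depol <- function(net, interval_ms, onset_ms = 5) {
  t1 <- onset_ms
  t2 <- onset_ms + abs(interval_ms)
  ev <- if (interval_ms >= 0)
    data.frame(cell = c(1, 2), time_ms = c(t1, t2))
  else
    data.frame(cell = c(2, 1), time_ms = c(t1, t2))
  sim <- simulate_network(net, ev, horizon_ms = max(ev$time_ms) + 55,
                          spike_block = net$output_cells)
  sim$max_V[net$output_cells[1]]
}
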