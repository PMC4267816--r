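make_scan <- function(n_up, n_down, n_tot_per_side = 10) {
  rates <- c(-(n_tot_per_side:1), 1:n_tot_per_side)
  responded <- c(rep(FALSE, n_tot_per_side - n_down), rep(TRUE, n_down),
                 rep(TRUE, n_up), rep(FALSE, n_tot_per_side - n_up))
  s <- data.frame(variant = "v", rate = rates, spikes = as.integer(responded),
                  max_V = -1, max_mV = -65, responded = responded)
  class(s) <- c("rate_scan", class(s))
  s
}

test_that("DSI arithmetic and edge cases", {
  expect_equal(dsi(make_scan(5, 5))$dsi, 0)
  expect_equal(dsi(make_scan(10, 0))$dsi, 1)
  expect_equal(dsi(make_scan(6, 2))$dsi, 0.5)
  z <- dsi(make_scan(0, 0))
  expect_true(z$undefined)
  expect_true(is.na(z$dsi))
})

test_that("DSI of a direction-mirrored scan is the exact negative", {
  net <- tilted_sideband(0.4)
  sc <- rate_scan(net, rates = rates_coarse)
  mirrored <- sc
  mirrored$rate <- -mirrored$rate
  class(mirrored) <- class(sc)
  expect_equal(dsi(mirrored)$dsi, -dsi(sc)$dsi)
})

test_that("responded_range counts the responded set", {
  sc <- make_scan(6, 2)
  expect_equal(responded_range(sc, "v"), 8)
  expect_equal(responded_range(make_scan(0, 0), "v"), 0)
  expect_error(responded_range(sc, "nope"), "unknown variant")
})

test_that("sideband responded sets are upward-closed per direction", {
  fam <- sideband_family(mean_grid = c(0.20, 0.30, 0.42))
  sc <- rate_scan(fam, rates = rates_coarse)
  for (v in unique(sc$variant)) {
    s <- sc[sc$variant == v, ]
    for (sgn in c(1, -1)) {
      side <- s[sign(s$rate) == sgn, ]
      side <- side[order(abs(side$rate)), ]
      # once a rate responds, all faster rates respond too
      expect_false(is.unsorted(as.integer(side$responded)))
    }
  }
})

test_that("responded range shrinks as mean inhibitory input grows", {
  fam <- sideband_family(mean_grid = c(0.18, 0.27, 0.37, 0.50))
  sc <- rate_scan(fam, rates = rates_coarse)
  ranges <- vapply(names(fam), function(v) responded_range(sc, v), numeric(1))
  expect_false(is.unsorted(rev(ranges)))   # non-increasing in mean weight
  expect_gt(ranges[1], ranges[length(ranges)])
})

test_that("facilitation interval tuning peaks at the delay difference", {
  # at the preferred interval the blocked-depolarization candidate
  # saturates, so the peak is a plateau containing the delay difference
  tol <- 0.005
  for (d_slow in c(7, 11, 15)) {
    net <- build_facilitation(facilitation_spec(delay_slow_ms = d_slow))
    dd <- d_slow - 1
    iv <- seq(max(0, dd - 8), dd + 8, by = 1)
    md <- vapply(iv, function(x) facilitation_depol(net, x), numeric(1))
    peak <- which(md > max(md) - tol)
    expect_true(all(diff(peak) == 1))        # contiguous peak region
    expect_true((dd - min(iv) + 1) %in% peak) # containing the delay difference
    # unimodal: non-decreasing up to the peak region, non-increasing after
    expect_true(all(diff(md[seq_len(min(peak))]) >= -tol))
    expect_true(all(diff(md[max(peak):length(md)]) <= tol))
  }
})

test_that("preferred rate is inversely proportional to the delay difference", {
  d_slows <- c(5, 7, 9, 11, 15)
  pref_rates <- vapply(d_slows, function(ds) {
    net <- build_facilitation(facilitation_spec(delay_slow_ms = ds))
    dd <- ds - 1
    cand <- 1000 / seq(max(1, dd - 4), dd + 4)   # rates near 1000/dd
    sc <- rate_scan(net, rates = sort(cand), tail_ms = 50)
    mean(sc$rate[sc$responded])
  }, numeric(1))
  expect_true(all(is.finite(pref_rates)))
  ratio <- pref_rates * (d_slows - 1) / 1000
  expect_true(all(ratio > 0.6 & ratio < 1.6))
  expect_false(is.unsorted(rev(pref_rates)))   # longer delay, slower preference
})

test_that("duration preferred counts do not increase with the weak weight", {
  fam <- duration_family(w_weak_grid = c(0.10, 0.12, 0.14, 0.16))
  curve <- duration_curve(fam, counts = 1:12)
  for (v in unique(curve$variant)) {
    s <- curve[curve$variant == v, ]
    pref <- s$n_spikes[s$responded]
    expect_true(all(diff(pref) == 1))   # interval tuning
  }
  mids <- preferred_count(curve)[names(fam)]
  mids <- mids[!is.na(mids)]
  expect_false(is.unsorted(rev(mids)))
  expect_gt(mids[1], mids[length(mids)])
  expect_error(duration_curve(fam[[1]], counts = 0:3), "positive")
})

test_that("blocked depolarization readout is at least the resting level", {
  net <- tilted_sideband(0)
  sc <- rate_scan(net, rates = rates_coarse, mode = "blocked_depolarization")
  rest <- map_rest_state(circuit_cell_params())$V
  expect_true(all(sc$max_V >= rest - 1e-9))
  expect_true(all(sc$spikes == 0))
  # blocked excitation is highest at the rates that spike when unblocked
  sp <- rate_scan(net, rates = rates_coarse)
  expect_gt(min(sc$max_V[sp$responded]), max(sc$max_V[!sp$responded]))
})
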