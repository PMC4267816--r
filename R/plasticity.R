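#' Spike-timing-dependent plasticity rule
#'
#' One STDP event is created per adjacent pre/post spike pairing (see
#' [extract_stdp_events()]); its value is
#'
#' \deqn{\Delta S = k \, S \, e^{-\Delta t / T_c}}
#'
#' with `k = +0.025` for a pre-before-post event, `k = -0.025` for a
#' post-before-pre event, `S` the current strength of the connection, and
#' time constant `Tc = 10` ms.
#'
#' @param k_pre_before_post Potentiation coefficient.
#' @param k_post_before_pre Depression coefficient.
#' @param tc_ms Kernel time constant (ms).
#' @return An object of class `stdp_rule`.
#' @export
stdp_rule <- function(k_pre_before_post = 0.025,
                      k_post_before_pre = -0.025, tc_ms = 10) {
  stopifnot(tc_ms > 0)
  structure(list(k_pre_before_post = k_pre_before_post,
                 k_post_before_pre = k_post_before_pre, tc_ms = tc_ms),
            class = "stdp_rule")
}

#' Value of a single STDP event
#'
#' @param kind `"pre_before_post"` or `"post_before_pre"`.
#' @param S Current strength of the connection (>= 0).
#' @param dt_ms Absolute time difference of the pairing (>= 0).
#' @param rule An [stdp_rule()].
#' @return The weight change `k * S * exp(-dt / Tc)`.
#' @export
#' @examples
#' stdp_event_value("pre_before_post", 1, 0)   #  0.025
#' stdp_event_value("post_before_pre", 1, 0)   # -0.025
stdp_event_value <- function(kind = c("pre_before_post", "post_before_pre"),
                             S, dt_ms, rule = stdp_rule()) {
  kind <- match.arg(kind)
  stopifnot(all(S >= 0), all(dt_ms >= 0))
  k <- if (kind == "pre_before_post") rule$k_pre_before_post
       else rule$k_post_before_pre
  k * S * exp(-dt_ms / rule$tc_ms)
}

#' Extract STDP events from paired spike trains
#'
#' A post-synaptic spike that directly follows a pre-synaptic spike creates
#' one pre-before-post event; additional post spikes before the next pre
#' spike create no further events, and symmetrically for post-before-pre.
#' Operationally, events occur exactly where the merged, time-ordered spike
#' sequence switches type; the event interval is the time between the two
#' spikes at the switch. Simultaneous pre and post spikes (identical times)
#' create no event ("directly follows" requires strict ordering).
#'
#' @param pre_times,post_times Sorted spike times (ms) of the pre- and
#'   postsynaptic cell.
#' @return A data.frame with columns `kind`, `dt_ms` and `t_ms` (time of
#'   the later spike of the pairing); zero rows when either train is empty.
#' @export
#' @examples
#' extract_stdp_events(c(10), c(15, 18))        # one pre_before_post, dt 5
#' extract_stdp_events(c(10, 22), c(15))        # dt 5 potentiation, dt 7 depression
extract_stdp_events <- function(pre_times, post_times) {
  empty <- data.frame(kind = character(0), dt_ms = numeric(0),
                      t_ms = numeric(0))
  if (length(pre_times) == 0 || length(post_times) == 0) return(empty)
  tt <- c(pre_times, post_times)
  ty <- rep(c("pre", "post"), c(length(pre_times), length(post_times)))
  o <- order(tt)
  tt <- tt[o]; ty <- ty[o]
  rows <- empty
  last_t <- c(pre = NA_real_, post = NA_real_)
  last_t[ty[1]] <- tt[1]
  for (j in seq_along(tt)[-1]) {
    if (ty[j] != ty[j - 1]) {
      other <- last_t[if (ty[j] == "pre") "post" else "pre"]
      dt <- tt[j] - other
      if (dt > 0) {
        kind <- if (ty[j] == "post") "pre_before_post" else "post_before_pre"
        rows <- rbind(rows, data.frame(kind = kind, dt_ms = unname(dt),
                                       t_ms = tt[j]))
      }
    }
    last_t[ty[j]] <- tt[j]
  }
  rows
}

#' Rescale incoming weights to a conserved total
#'
#' Enforces conservation of the total incoming synaptic strength of a cell:
#' the returned vector sums exactly to `target_sum`. Indices in `fixed`
#' are left untouched (e.g. the weight just updated by an STDP event) and
#' the remaining weights absorb the difference by proportional rescaling;
#' with no fixed indices all weights are rescaled proportionally.
#'
#' @param weights Non-negative weight vector.
#' @param target_sum Conserved total (> 0).
#' @param fixed Integer indices excluded from rescaling.
#' @return Rescaled weight vector (order preserved).
#' @export
#' @examples
#' normalize_incoming(c(0.4, 0.3, 0.4), 1, fixed = 1)  # others scaled by 0.6/0.7
normalize_incoming <- function(weights, target_sum, fixed = integer(0)) {
  stopifnot(all(weights >= 0), target_sum > 0)
  if (sum(weights) == 0)
    stop("cannot renormalize an all-zero weight vector", call. = FALSE)
  if (length(fixed) == 0) return(weights * target_sum / sum(weights))
  rest <- setdiff(seq_along(weights), fixed)
  need <- target_sum - sum(weights[fixed])
  if (need < 0)
    stop("fixed weights already exceed the conserved total", call. = FALSE)
  if (sum(weights[rest]) == 0) {
    if (need > 1e-12)
      stop("free weights are all zero; cannot reach the conserved total",
           call. = FALSE)
    return(weights)
  }
  weights[rest] <- weights[rest] * need / sum(weights[rest])
  weights
}

#' Train direction selectivity by repeated sweep exposure
#'
#' Presents the same sweep `n_trials` times to a sideband circuit whose
#' input-to-inhibitory synapses are plastic. After each trial, STDP events
#' between each input cell and the inhibitory cell are evaluated with the
#' kernel of `rule` and applied, weights are floored at zero (and clipped
#' at the conserved total with a warning if they run away), and the total
#' incoming plastic weight of the inhibitory cell is renormalized to its
#' initial value. The trajectory records the asymmetry index after every
#' trial and the DSI (computed by a full [rate_scan()] over `rate_grid`)
#' every `record_dsi_every` trials and at both ends.
#'
#' With `normalize = "per_event"` events are applied one at a time in
#' chronological order, renormalizing after each; `"per_trial"` (default)
#' accumulates all of a trial's events first.
#'
#' @param net A plastic sideband [network()] (see [sideband_spec()] with
#'   `plastic = TRUE`).
#' @param sweep A [sweep_stimulus()] used for every trial.
#' @param n_trials Number of training trials (0 returns the network
#'   unchanged with a one-row trajectory).
#' @param rule An [stdp_rule()].
#' @param record_dsi_every Interval (in trials) between DSI evaluations.
#' @param rate_grid Grid used for DSI scans.
#' @param tail_ms Response window used in simulations and scans.
#' @param normalize Normalization schedule, `"per_trial"` or `"per_event"`.
#' @return A list with `network` (trained), `trajectory` (data.frame
#'   `trial`, `asy`, `dsi`) and `weights` (matrix of the plastic weight
#'   vector per recorded trial, rows 0..n_trials).
#' @export
train_direction <- function(net, sweep, n_trials, rule = stdp_rule(),
                            record_dsi_every = 25,
                            rate_grid = default_rate_grid(),
                            tail_ms = 50,
                            normalize = c("per_trial", "per_event")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(net, "map_network"), inherits(sweep, "sweep_stimulus"),
            n_trials >= 0)
  pl <- which(net$synapses$plastic)
  if (length(pl) == 0)
    stop("network has no plastic synapses to train", call. = FALSE)
  post_cell <- unique(net$synapses$post[pl])
  if (length(post_cell) != 1)
    stop("plastic synapses must converge on a single cell", call. = FALSE)
  pl <- pl[order(net$synapses$pre[pl])]
  target <- sum(net$synapses$g_syn[pl])

  ev_sweep <- sweep_events(sweep)
  horizon <- max(ev_sweep$time_ms) + tail_ms + sweep$onset_ms

  asy_of <- function(w) {
    if (length(w) %% 2 == 1) asymmetry_index(w) else NA_real_
  }
  dsi_of <- function(nn) {
    sc <- rate_scan(nn, rates = rate_grid, mode = "spikes",
                    tail_ms = tail_ms)
    dsi(sc)$dsi
  }

  w_hist <- matrix(NA_real_, nrow = n_trials + 1, ncol = length(pl))
  traj <- data.frame(trial = 0:n_trials, asy = NA_real_, dsi = NA_real_)
  w_hist[1, ] <- net$synapses$g_syn[pl]
  traj$asy[1] <- asy_of(w_hist[1, ])
  traj$dsi[1] <- dsi_of(net)

  for (trial in seq_len(n_trials)) {
    sim <- simulate_network(net, ev_sweep, horizon_ms = horizon)
    post_spk <- spike_times(sim, post_cell)
    if (normalize == "per_trial") {
      w <- net$synapses$g_syn[pl]
      dS <- numeric(length(pl))
      for (j in seq_along(pl)) {
        evs <- extract_stdp_events(spike_times(sim, net$synapses$pre[pl[j]]),
                                   post_spk)
        for (r in seq_len(nrow(evs)))
          dS[j] <- dS[j] + stdp_event_value(evs$kind[r], w[j], evs$dt_ms[r],
                                            rule)
      }
      w <- pmax(w + dS, 0)
      if (any(w > target)) {
        warning("runaway weight clipped at the conserved total")
        w <- pmin(w, target)
      }
      w <- normalize_incoming(w, target)
    } else {
      # chronological per-event application
      all_ev <- do.call(rbind, lapply(seq_along(pl), function(j) {
        evs <- extract_stdp_events(spike_times(sim, net$synapses$pre[pl[j]]),
                                   post_spk)
        if (nrow(evs)) evs$syn <- j
        evs
      }))
      w <- net$synapses$g_syn[pl]
      if (!is.null(all_ev) && nrow(all_ev)) {
        all_ev <- all_ev[order(all_ev$t_ms), , drop = FALSE]
        for (r in seq_len(nrow(all_ev))) {
          j <- all_ev$syn[r]
          w[j] <- max(0, w[j] + stdp_event_value(all_ev$kind[r], w[j],
                                                 all_ev$dt_ms[r], rule))
          if (w[j] > target) {
            warning("runaway weight clipped at the conserved total")
            w[j] <- target
          }
          w <- normalize_incoming(w, target, fixed = j)
        }
      }
    }
    net$synapses$g_syn[pl] <- w
    w_hist[trial + 1, ] <- w
    traj$asy[trial + 1] <- asy_of(w)
    if (trial %% record_dsi_every == 0 || trial == n_trials)
      traj$dsi[trial + 1] <- dsi_of(net)
  }
  list(network = net, trajectory = traj, weights = w_hist)
}
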