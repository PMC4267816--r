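#' Default sweep-rate grid
#'
#' Log-spaced rates from 10 to 1000 cells/s in each direction (10 points
#' per direction) plus the two infinite rates (simultaneous activation).
#'
#' @param n_per_direction Points per direction.
#' @param lo,hi Slowest and fastest finite rates (cells/s).
#' @return Numeric vector of signed rates, ascending, including `-Inf` and
#'   `Inf`.
#' @export
default_rate_grid <- function(n_per_direction = 10, lo = 10, hi = 1000) {
  up <- exp(seq(log(lo), log(hi), length.out = n_per_direction))
  c(-Inf, -rev(up), up, Inf)
}

#' Scan circuit responses over a sweep-rate grid
#'
#' Simulates each circuit variant for each sweep rate and records the
#' output-cell spike count and maximum depolarization. In
#' `"blocked_depolarization"` mode the output cells are spike-blocked
#' (clamped to the subthreshold branch) and the readout is the unclamped
#' maximum excitation, as used in the maximum-excitation heat charts.
#'
#' A variant "responds" to a rate when its output cell fires at least one
#' spike between stimulus onset and `tail_ms` (50 ms by default) after the
#' last input activation.
#'
#' @param nets A single [network()] or a (named) list of variants sharing
#'   the output-cell layout.
#' @param rates Signed rate grid; see [default_rate_grid()].
#' @param mode `"spikes"` or `"blocked_depolarization"`.
#' @param onset_ms Stimulus onset within each simulation.
#' @param tail_ms Response window after the last input activation.
#' @return A `rate_scan` data.frame with columns `variant`, `rate`,
#'   `spikes`, `max_V`, `max_mV`, `responded`.
#' @export
rate_scan <- function(nets, rates = default_rate_grid(),
                      mode = c("spikes", "blocked_depolarization"),
                      onset_ms = 5, tail_ms = 50) {
  mode <- match.arg(mode)
  if (inherits(nets, "map_network")) nets <- list(variant = nets)
  if (length(rates) == 0) stop("empty rate grid", call. = FALSE)
  if (is.null(names(nets)))
    names(nets) <- sprintf("variant%02d", seq_along(nets))
  rows <- list()
  for (vn in names(nets)) {
    net <- nets[[vn]]
    out <- net$output_cells[1]
    blocked <- if (mode == "blocked_depolarization") net$output_cells else integer(0)
    for (r in rates) {
      res <- tryCatch({
        ev <- sweep_events(sweep_stimulus(r, length(net$input_cells),
                                          onset_ms = onset_ms))
        hor <- max(ev$time_ms) + tail_ms + onset_ms
        sim <- simulate_network(net, ev, horizon_ms = hor,
                                spike_block = blocked)
        nsp <- length(spike_times(sim, out))
        data.frame(variant = vn, rate = r, spikes = nsp,
                   max_V = sim$max_V[out],
                   max_mV = to_physiological(sim$max_V[out]),
                   responded = nsp > 0)
      }, error = function(e)
        stop(sprintf("scan failed for variant '%s' at rate %g: %s",
                     vn, r, conditionMessage(e)), call. = FALSE))
      rows[[length(rows) + 1]] <- res
    }
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  class(scan) <- c("rate_scan", class(scan))
  attr(scan, "mode") <- mode
  scan
}

#' Direction selectivity index of a rate scan
#'
#' DSI = (number of responded upward sweeps - number of responded downward
#' sweeps) / total responded sweeps, counted on the scan's rate grid
#' (positive rates and `+Inf` are "upward"). Ranges from -1 (only downward)
#' to 1 (only upward); flagged undefined when the circuit responded to no
#' sweep at all.
#'
#' @param scan A [rate_scan()] in `"spikes"` mode.
#' @param variant Variant name; defaults to the single variant present.
#' @return A list with `n_up`, `n_down`, `dsi` and `undefined`.
#' @export
dsi <- function(scan, variant = NULL) {
  stopifnot(inherits(scan, "rate_scan"))
  if (!any(scan$rate > 0) || !any(scan$rate < 0))
    stop("scan must contain both sweep directions", call. = FALSE)
  if (is.null(variant)) {
    v <- unique(scan$variant)
    if (length(v) > 1) stop("multiple variants in scan: name one", call. = FALSE)
    variant <- v
  }
  s <- scan[scan$variant == variant, ]
  if (nrow(s) == 0) stop("unknown variant: ", variant, call. = FALSE)
  n_up <- sum(s$responded & s$rate > 0)
  n_down <- sum(s$responded & s$rate < 0)
  tot <- n_up + n_down
  list(n_up = n_up, n_down = n_down,
       dsi = if (tot == 0) NA_real_ else (n_up - n_down) / tot,
       undefined = tot == 0)
}

#' Count of responded rates for one variant
#'
#' The range of sweep rates a circuit responds to, measured as the number
#' of rates on the scan grid that evoke at least one output spike.
#'
#' @param scan A [rate_scan()].
#' @param variant Variant name.
#' @return Integer count.
#' @export
responded_range <- function(scan, variant) {
  stopifnot(inherits(scan, "rate_scan"))
  s <- scan[scan$variant == variant, ]
  if (nrow(s) == 0) stop("unknown variant: ", variant, call. = FALSE)
  sum(s$responded)
}

#' Duration tuning curves over a spike-count grid
#'
#' Stimulates each duration-circuit variant with tone trains of 1..max
#' spikes and records the output response, giving the tuning curve over
#' tone duration (encoded as spike count). The preferred count of a variant
#' is the responded count (spiking mode) or the count of maximal
#' depolarization (blocked mode).
#'
#' @param nets A [network()] or list of duration-circuit variants.
#' @param counts Grid of spike counts (positive integers).
#' @param mode `"spikes"` or `"blocked_depolarization"`.
#' @param inter_spike_ms Train spacing; defaults to the spec the circuit
#'   was built with.
#' @param onset_ms,tail_ms Stimulus onset and response window after train
#'   end.
#' @return A `duration_curve` data.frame with columns `variant`,
#'   `n_spikes`, `spikes`, `max_V`, `max_mV`, `responded`.
#' @export
duration_curve <- function(nets, counts = 1:12,
                           mode = c("spikes", "blocked_depolarization"),
                           inter_spike_ms = NULL, onset_ms = 5,
                           tail_ms = 80) {
  mode <- match.arg(mode)
  if (inherits(nets, "map_network")) nets <- list(variant = nets)
  if (any(counts < 1)) stop("spike counts must be positive", call. = FALSE)
  if (is.null(names(nets)))
    names(nets) <- sprintf("variant%02d", seq_along(nets))
  rows <- list()
  for (vn in names(nets)) {
    net <- nets[[vn]]
    out <- net$output_cells[1]
    spc <- inter_spike_ms
    if (is.null(spc))
      spc <- if (!is.null(net$meta$spec$inter_spike_ms))
        net$meta$spec$inter_spike_ms else 5
    blocked <- if (mode == "blocked_depolarization") net$output_cells else integer(0)
    for (n in counts) {
      ev <- tone_events(tone_train(1, n, inter_spike_ms = spc,
                                   onset_ms = onset_ms))
      hor <- max(ev$time_ms) + tail_ms
      sim <- simulate_network(net, ev, horizon_ms = hor,
                              spike_block = blocked)
      nsp <- length(spike_times(sim, out))
      rows[[length(rows) + 1]] <-
        data.frame(variant = vn, n_spikes = n, spikes = nsp,
                   max_V = sim$max_V[out],
                   max_mV = to_physiological(sim$max_V[out]),
                   responded = nsp > 0)
    }
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  class(curve) <- c("duration_curve", class(curve))
  attr(curve, "mode") <- mode
  curve
}

#' Preferred spike count per duration-circuit variant
#'
#' @param curve A [duration_curve()].
#' @return Named numeric vector: midpoint of the responded count interval
#'   (spiking mode) or argmax of depolarization (blocked mode) per variant;
#'   `NA` for silent variants.
#' @export
preferred_count <- function(curve) {
  stopifnot(inherits(curve, "duration_curve"))
  vapply(split(curve, curve$variant), function(s) {
    if (attr(curve, "mode") == "blocked_depolarization")
      return(s$n_spikes[which.max(s$max_V)])
    r <- s$n_spikes[s$responded]
    if (length(r) == 0) NA_real_ else mean(range(r))
  }, numeric(1))
}
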