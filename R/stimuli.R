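#' FM sweep stimulus
#'
#' An FM sweep is abstracted as the ordered activation of tonotopic input
#' cells at a signed rate in cells per second: positive rates activate cells
#' in ascending index order (the arbitrarily chosen "upward" direction),
#' negative rates in descending order, and an infinite rate activates all
#' cells simultaneously. Successive activations are spaced `1000 / |rate|`
#' milliseconds apart.
#'
#' @param rate Sweep rate in cells per second; nonzero, may be `Inf`/`-Inf`.
#' @param n_cells Number of tonotopic input cells swept.
#' @param onset_ms Time of the first activation.
#' @return An object of class `sweep_stimulus`.
#' @export
#' @examples
#' sweep_events(sweep_stimulus(100, 5))
sweep_stimulus <- function(rate, n_cells, onset_ms = 0) {
  if (!is.numeric(rate) || is.na(rate) || rate == 0)
    stop("sweep `rate` must be nonzero (cells per second)", call. = FALSE)
  stopifnot(n_cells >= 1, onset_ms >= 0)
  structure(list(rate = rate, n_cells = as.integer(n_cells),
                 onset_ms = onset_ms),
            class = "sweep_stimulus")
}

#' Per-cell activation times of a sweep
#'
#' @param s A [sweep_stimulus()].
#' @return A `data.frame` with columns `cell` (input-cell index, 1-based
#'   within the tonotopic array) and `time_ms`, ordered by activation time.
#' @export
sweep_events <- function(s) {
  stopifnot(inherits(s, "sweep_stimulus"))
  spacing <- if (is.infinite(s$rate)) 0 else 1000 / abs(s$rate)
  times <- s$onset_ms + spacing * (seq_len(s$n_cells) - 1)
  cells <- if (s$rate > 0) seq_len(s$n_cells) else rev(seq_len(s$n_cells))
  data.frame(cell = cells, time_ms = times)
}

#' Tone stimulus as a fixed-rate spike train
#'
#' A tone of a given duration is encoded as a train of equally spaced
#' activations of a single input cell; the number of spikes reflects the
#' tone duration. The default spacing (5 ms, i.e. a 200 spikes/s train) is a
#' calibration constant chosen so that, under the default duration-circuit
#' weights, the inhibitory middle cell fires roughly one spike per input
#' spike over a similar duration.
#'
#' @param target_cell Input-cell index receiving the train.
#' @param n_spikes Number of spikes (>= 1), encoding tone duration.
#' @param inter_spike_ms Spacing between spikes in ms.
#' @param onset_ms Time of the first spike.
#' @return An object of class `tone_train`.
#' @export
tone_train <- function(target_cell, n_spikes, inter_spike_ms = 5,
                       onset_ms = 0) {
  stopifnot(n_spikes >= 1, inter_spike_ms > 0, onset_ms >= 0)
  structure(list(target_cell = as.integer(target_cell),
                 n_spikes = as.integer(n_spikes),
                 inter_spike_ms = inter_spike_ms, onset_ms = onset_ms),
            class = "tone_train")
}

#' Activation times of a tone spike train
#'
#' @param t A [tone_train()].
#' @return A `data.frame` with columns `cell` and `time_ms`.
#' @export
tone_events <- function(t) {
  stopifnot(inherits(t, "tone_train"))
  data.frame(cell = rep(t$target_cell, t$n_spikes),
             time_ms = t$onset_ms + t$inter_spike_ms * (seq_len(t$n_spikes) - 1))
}
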