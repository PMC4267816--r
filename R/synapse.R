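#' Define a synaptic connection
#'
#' Synapses follow a first-order kinetic conductance written as a difference
#' equation on the engine's fixed step: between presynaptic spikes the
#' activation relaxes geometrically, `g_{n+1} = gamma * g_n`; when a
#' (delayed) presynaptic spike arrives the activation is set to its peak
#' value `g_syn` (`mode = "peak"`, the default) or incremented by `g_syn`
#' (`mode = "add"`, used for integrative connections that must sum over a
#' spike train). The synaptic current onto the postsynaptic cell is the
#' driving-force form
#'
#' \deqn{i_{syn} = -g_n (V_{post} - V_{rp})}
#'
#' so the reversal potential `v_rp` decides the synapse type: `v_rp = 0`
#' (above rest) is excitatory, `v_rp` below the resting voltage is
#' inhibitory and can hyperpolarize the cell enough to recruit rebound.
#'
#' Transmission delays are realised by deferring the "presynaptic spike"
#' condition by an integer number of steps; off-grid delays are rounded to
#' the nearest step with a warning. Delays must lie in [0.5, 20] ms.
#'
#' @param pre,post Integer cell ids of the pre- and postsynaptic cells.
#' @param g_syn Coupling strength (>= 0).
#' @param gamma Conductance relaxation factor per step, in [0, 1).
#' @param v_rp Reversal potential in dimensionless voltage units.
#' @param delay_ms Transmission delay in ms, in [0.5, 20].
#' @param plastic Whether the synapse participates in STDP training.
#' @param mode `"peak"` (jump-to-peak on spike) or `"add"` (accumulate).
#' @param step_ms Engine step used to convert the delay to steps.
#' @return A one-row `data.frame` describing the synapse.
#' @export
#' @examples
#' synapse(1, 2, g_syn = 0.2, gamma = 0.9, v_rp = 0, delay_ms = 1)
synapse <- function(pre, post, g_syn, gamma = 0.9, v_rp = 0,
                    delay_ms = 0.5, plastic = FALSE,
                    mode = c("peak", "add"), step_ms = 0.5) {
  mode <- match.arg(mode)
  if (pre == post) stop("self-synapses are not allowed", call. = FALSE)
  if (g_syn < 0) stop("`g_syn` must be >= 0", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("`gamma` must lie in [0, 1)", call. = FALSE)
  if (delay_ms < 0.5 || delay_ms > 20)
    stop("`delay_ms` must lie in [0.5, 20] ms", call. = FALSE)
  steps <- delay_ms / step_ms
  if (abs(steps - round(steps)) > 1e-9) {
    warning(sprintf("delay %g ms is off the %g ms step grid; rounding to %g ms",
                    delay_ms, step_ms, round(steps) * step_ms))
    steps <- round(steps)
  }
  data.frame(pre = as.integer(pre), post = as.integer(post),
             g_syn = g_syn, gamma = gamma, v_rp = v_rp,
             delay_ms = round(steps) * step_ms,
             delay_steps = as.integer(round(steps)),
             plastic = isTRUE(plastic), mode = mode,
             stringsAsFactors = FALSE)
}

#' Advance a synapse state by one step
#'
#' Pure single-synapse update used by the engine (and directly in tests):
#' geometric decay by `gamma`, with the activation set to (or incremented
#' by) `g_syn` when the delayed presynaptic-spike condition holds this step.
#'
#' @param conductance Current activation level (>= 0).
#' @param syn A [synapse()] row.
#' @param spike_arrived Whether a presynaptic spike, emitted `delay_steps`
#'   steps ago, arrives this step.
#' @return The next conductance value.
#' @export
syn_update <- function(conductance, syn, spike_arrived = FALSE) {
  g <- syn$gamma * conductance
  if (isTRUE(spike_arrived)) {
    g <- if (syn$mode == "add") g + syn$g_syn else syn$g_syn
  }
  g
}

#' Synaptic current onto the postsynaptic cell
#'
#' @param conductance Current activation level.
#' @param syn A [synapse()] row.
#' @param V_post Postsynaptic voltage (dimensionless).
#' @return The synaptic current `-conductance * (V_post - v_rp)`.
#' @export
syn_current <- function(conductance, syn, V_post) {
  -conductance * (V_post - syn$v_rp)
}
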