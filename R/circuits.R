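#' Default cell parameters for circuit neurons
#'
#' Circuit cells are phasic: the slow-variable input coupling is disabled
#' (`sigma_input = 0`) so that cells respond transiently to synaptic drive
#' and fall silent when the stimulus ends. With the generic default
#' (`sigma_input = 1`) sustained drive charges the slow variable and cells
#' keep firing after the input stops, which blurs the timing relations the
#' circuits rely on.
#'
#' @param ... Overrides forwarded to [map_params()].
#' @return A [map_params()] object.
#' @export
circuit_cell_params <- function(...) {
  map_params(sigma_input = 0, ...)
}

# memoised single-EPSP firing threshold, keyed by parameter values
.fmnet_cache <- new.env(parent = emptyenv())

#' Minimal synaptic strength that fires a resting cell
#'
#' Bisects the smallest `g_syn` for which one presynaptic spike through an
#' excitatory synapse (reversal 0, the given decay factor and delay) makes a
#' resting cell spike. Circuit builders use this transient threshold to
#' validate "subthreshold" and "suprathreshold" weight declarations. Results
#' are memoised per parameter combination.
#'
#' @param params Postsynaptic cell parameters.
#' @param gamma Synaptic decay factor per step.
#' @param delay_ms Synaptic delay.
#' @param tol Bisection tolerance.
#' @return Threshold coupling strength.
#' @export
epsp_threshold <- function(params = circuit_cell_params(), gamma = 0.9,
                           delay_ms = 1, tol = 1e-4) {
  key <- paste(c(unlist(params), gamma, delay_ms, tol), collapse = "|")
  if (!is.null(.fmnet_cache[[key]])) return(.fmnet_cache[[key]])
  fires <- function(g) {
    net <- network(c("input", "output"),
                   synapse(1, 2, g, gamma = gamma, v_rp = 0,
                           delay_ms = delay_ms, step_ms = params$step_ms),
                   params = params)
    sim <- simulate_network(net, data.frame(cell = 1, time_ms = 5),
                            horizon_ms = 80)
    length(spike_times(sim, 2)) > 0
  }
  if (!fires(2)) stop("no spike even at g_syn = 2; check cell parameters",
                      call. = FALSE)
  lo <- 0; hi <- 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .fmnet_cache[[key]] <- hi
  hi
}

#' Specification of the sideband-inhibition circuit
#'
#' The minimal detector unit has `n_inputs` tonotopic input cells (default
#' 5) that each send a weak direct excitatory synapse to one output cell and
#' an excitatory synapse to one feed-forward inhibitory cell, which in turn
#' strongly inhibits the output. Direct excitation reaches the output one
#' synapse earlier than the di-synaptic inhibition, so sufficiently fast
#' sweeps let excitation summate and fire the output before inhibition
#' arrives ("fast-pass" rate selectivity); for slow sweeps the inhibitory
#' cell fires first and vetoes the response.
#'
#' The mean of the input-to-inhibitory weights sets the rate threshold
#' (stronger drive, earlier inhibition, fewer responded rates); their
#' asymmetry around the central input cell sets direction preference. The
#' weight profile is linear in position:
#' `w_i = mean_inhib * (1 + asymmetry * (i - centre) / 2)`; an explicit
#' `w_input_to_inhib` vector overrides it.
#'
#' @param n_inputs Number of tonotopic input cells (odd, default 5).
#' @param w_input_to_output Direct excitatory weight per input (each
#'   subthreshold alone; several must summate to fire the output).
#' @param mean_inhib Mean input-to-inhibitory weight.
#' @param asymmetry Asymmetry coefficient of the inhibitory input profile;
#'   0 gives a direction-neutral circuit, positive tilts weight onto the
#'   high-frequency side (preference for upward sweeps).
#' @param w_input_to_inhib Optional explicit weight vector (length
#'   `n_inputs`), overriding `mean_inhib`/`asymmetry`.
#' @param w_inhib_to_output Inhibitory weight onto the output cell (strong).
#' @param v_rp_inhib Inhibitory reversal potential (below rest).
#' @param delay_exc_ms,delay_inhib_in_ms,delay_inhib_out_ms Delays of the
#'   direct excitation, input-to-inhibitory and inhibitory-to-output
#'   synapses.
#' @param gamma_exc,gamma_inhib Decay factors of excitatory and inhibitory
#'   conductances.
#' @param plastic Mark the input-to-inhibitory synapses plastic (for STDP
#'   training).
#' @return An object of class `sideband_spec`.
#' @export
sideband_spec <- function(n_inputs = 5, w_input_to_output = 0.183,
                          mean_inhib = 0.274, asymmetry = 0,
                          w_input_to_inhib = NULL,
                          w_inhib_to_output = 2, v_rp_inhib = -1.1,
                          delay_exc_ms = 1, delay_inhib_in_ms = 1,
                          delay_inhib_out_ms = 2,
                          gamma_exc = 0.9, gamma_inhib = 0.95,
                          plastic = FALSE) {
  if (n_inputs < 3 || n_inputs %% 2 == 0)
    stop("`n_inputs` must be odd and >= 3 (defined central cell)", call. = FALSE)
  if (is.null(w_input_to_inhib)) {
    pos <- seq_len(n_inputs)
    centre <- (n_inputs + 1) / 2
    w_input_to_inhib <- mean_inhib * (1 + asymmetry * (pos - centre) / 2)
  }
  if (length(w_input_to_inhib) != n_inputs)
    stop("`w_input_to_inhib` must have length `n_inputs`", call. = FALSE)
  if (any(w_input_to_inhib < 0)) stop("inhibitory input weights must be >= 0",
                                      call. = FALSE)
  structure(list(n_inputs = n_inputs, w_input_to_output = w_input_to_output,
                 w_input_to_inhib = w_input_to_inhib,
                 w_inhib_to_output = w_inhib_to_output,
                 v_rp_inhib = v_rp_inhib,
                 delay_exc_ms = delay_exc_ms,
                 delay_inhib_in_ms = delay_inhib_in_ms,
                 delay_inhib_out_ms = delay_inhib_out_ms,
                 gamma_exc = gamma_exc, gamma_inhib = gamma_inhib,
                 plastic = plastic),
            class = "sideband_spec")
}

#' Build the sideband-inhibition network
#'
#' Cells are numbered 1..n_inputs (input layer), n_inputs+1 (inhibitory),
#' n_inputs+2 (output).
#'
#' @param spec A [sideband_spec()].
#' @param cell_params Shared cell parameters, default [circuit_cell_params()].
#' @return A [network()] with `meta$circuit = "sideband"`.
#' @export
build_sideband <- function(spec, cell_params = circuit_cell_params()) {
  stopifnot(inherits(spec, "sideband_spec"))
  n <- spec$n_inputs
  thr <- epsp_threshold(cell_params, spec$gamma_exc, spec$delay_exc_ms)
  if (spec$w_input_to_output >= thr)
    stop(sprintf(paste0("w_input_to_output (%g) is suprathreshold (single-EPSP ",
                        "threshold %g): a single input alone would fire the output"),
                 spec$w_input_to_output, thr), call. = FALSE)
  if (n * spec$w_input_to_output < thr)
    stop("summed direct excitation is subthreshold: the output can never fire",
         call. = FALSE)
  inh <- n + 1L
  out <- n + 2L
  syn <- do.call(rbind, c(
    lapply(seq_len(n), function(i)
      synapse(i, out, spec$w_input_to_output, gamma = spec$gamma_exc,
              v_rp = 0, delay_ms = spec$delay_exc_ms,
              step_ms = cell_params$step_ms)),
    lapply(seq_len(n), function(i)
      synapse(i, inh, spec$w_input_to_inhib[i], gamma = spec$gamma_exc,
              v_rp = 0, delay_ms = spec$delay_inhib_in_ms,
              plastic = spec$plastic, step_ms = cell_params$step_ms)),
    list(synapse(inh, out, spec$w_inhib_to_output, gamma = spec$gamma_inhib,
                 v_rp = spec$v_rp_inhib, delay_ms = spec$delay_inhib_out_ms,
                 step_ms = cell_params$step_ms))))
  network(c(rep("input", n), "inhibitory", "output"), syn,
          params = cell_params,
          meta = list(circuit = "sideband", spec = spec))
}

#' Asymmetry index of an inhibitory-input weight profile
#'
#' Distance-weighted average of the synaptic strengths on the low-frequency
#' side of the central input cell minus that on the high-frequency side:
#'
#' \deqn{ASY = \frac{\sum_{d} d\, S_{c-d} - \sum_{d} d\, S_{c+d}}{\sum_d d}}
#'
#' where `c` is the central cell and `d` runs over distances 1..(n-1)/2.
#' Distance weights are linear in distance (farther flanks weigh more) and
#' the result is normalised by the per-side sum of distances, so a
#' mirror-symmetric profile gives 0 and reversing the profile flips the
#' sign. Positive ASY (stronger low-frequency side) predicts preference for
#' downward sweeps, negative ASY for upward sweeps. The central weight is
#' excluded.
#'
#' @param w Odd-length weight vector, ordered by input-cell position.
#' @param distance_weights Optional per-side weight vector of length
#'   (n-1)/2, indexed by distance from the centre; default `1:(n-1)/2`
#'   (linear).
#' @return The asymmetry index (dimensionless).
#' @export
#' @examples
#' asymmetry_index(c(1, 1, 1, 1, 1))   # 0
#' asymmetry_index(c(2, 1, 1, 1, 1))   # 2/3
asymmetry_index <- function(w, distance_weights = NULL) {
  n <- length(w)
  if (n %% 2 == 0) stop("even-length weight vector: no central cell",
                        call. = FALSE)
  m <- (n + 1) / 2
  d <- seq_len(m - 1)
  if (is.null(distance_weights)) distance_weights <- d
  if (length(distance_weights) != m - 1)
    stop("`distance_weights` must have one entry per distance", call. = FALSE)
  left <- sum(distance_weights * w[m - d])
  right <- sum(distance_weights * w[m + d])
  (left - right) / sum(distance_weights)
}

#' Specification of the facilitation (coincidence-detection) circuit
#'
#' Two input cells send subthreshold excitatory synapses with different
#' transmission delays onto one output cell. The output fires only when the
#' two EPSPs summate within the coincidence window, which happens when the
#' inter-input spike interval offsets the delay difference: the preferred
#' interval is `delay_slow_ms - delay_fast_ms`, i.e. a preferred sweep rate
#' of `1000 / (delay_slow_ms - delay_fast_ms)` cells/s in the direction
#' that activates the slow-synapse cell first.
#'
#' @param delay_fast_ms,delay_slow_ms The two synaptic delays (ms, in
#'   [0.5, 20], `delay_slow_ms > delay_fast_ms`). The slow synapse is from
#'   the first input cell (activated first by an upward sweep).
#' @param w_each Per-synapse weight; equal for both synapses, each
#'   subthreshold, the pair suprathreshold when coincident.
#' @param gamma Conductance decay factor.
#' @return An object of class `facilitation_spec`.
#' @export
facilitation_spec <- function(delay_fast_ms = 1, delay_slow_ms = 11,
                              w_each = 0.2, gamma = 0.9) {
  if (delay_slow_ms <= delay_fast_ms)
    stop("`delay_slow_ms` must exceed `delay_fast_ms` (no rate preference otherwise)",
         call. = FALSE)
  structure(list(delay_fast_ms = delay_fast_ms, delay_slow_ms = delay_slow_ms,
                 w_each = w_each, gamma = gamma),
            class = "facilitation_spec")
}

#' Build the facilitation network
#'
#' Cells: 1 and 2 (inputs, tonotopic order), 3 (output). The slow synapse
#' originates from cell 1 so that upward sweeps (cell 1 first) at the
#' preferred rate produce coincident arrivals.
#'
#' @param spec A [facilitation_spec()].
#' @param cell_params Shared cell parameters.
#' @return A [network()] with `meta$circuit = "facilitation"`.
#' @export
build_facilitation <- function(spec, cell_params = circuit_cell_params()) {
  stopifnot(inherits(spec, "facilitation_spec"))
  thr <- epsp_threshold(cell_params, spec$gamma, spec$delay_fast_ms)
  if (spec$w_each >= thr)
    stop(sprintf("w_each (%g) is suprathreshold (threshold %g): a single tone would fire the output",
                 spec$w_each, thr), call. = FALSE)
  if (2 * spec$w_each < thr)
    stop("paired excitation is subthreshold even when coincident", call. = FALSE)
  syn <- rbind(
    synapse(1, 3, spec$w_each, gamma = spec$gamma, v_rp = 0,
            delay_ms = spec$delay_slow_ms, step_ms = cell_params$step_ms),
    synapse(2, 3, spec$w_each, gamma = spec$gamma, v_rp = 0,
            delay_ms = spec$delay_fast_ms, step_ms = cell_params$step_ms))
  network(c("input", "input", "output"), syn, params = cell_params,
          meta = list(circuit = "facilitation", spec = spec))
}

#' Specification of the duration-tuning circuit
#'
#' One tone-responsive input cell fires a spike train lasting the tone
#' duration. It drives (i) an inhibitory middle cell through a strong
#' synapse, so inhibition starts at tone onset and tracks the train, and
#' (ii) an excitatory middle cell through a weak integrative synapse
#' (accumulating conductance), so delayed excitation emerges only after a
#' number of input spikes set by `w_weak` (stronger weight, fewer spikes,
#' shorter preferred duration). Both middle cells project to the output.
#'
#' Two regimes of the middle-to-output excitation:
#' * `"anti"` (anti-coincidence): the excitation is suprathreshold on its
#'   own; the output fires when the delayed excitation arrives after the
#'   onset-locked inhibition has decayed (input trains near the integration
#'   count), and is vetoed by ongoing inhibition for longer trains.
#' * `"coincidence"`: the excitation is subthreshold; the inhibition is
#'   deeper (reversal well below rest) and the output cell has a larger
#'   slow-variable rate, so release from hyperpolarization produces a
#'   rebound. The output fires only when the rebound at tone offset
#'   coincides with the delayed excitation (offset-locked spikes).
#'
#' @param regime `"anti"` or `"coincidence"`.
#' @param w_strong Input to inhibitory middle cell (suprathreshold; the
#'   inhibitory cell fires roughly one spike per input spike).
#' @param w_weak Input to excitatory middle cell (integrative,
#'   subthreshold per spike).
#' @param w_mid_to_output Excitatory middle to output weight; default 0.6
#'   (suprathreshold) for `"anti"`, 0.3 (subthreshold) for `"coincidence"`.
#' @param w_inhib_to_output Inhibitory middle to output weight; default 2
#'   for `"anti"`, 1 for `"coincidence"`.
#' @param v_rp_inhib Inhibitory reversal; default -1.1 for `"anti"`, -1.5
#'   for `"coincidence"` (deep enough to recruit rebound).
#' @param mu_out Output-cell slow-variable rate; default 5e-4 for
#'   `"anti"`, 5e-3 for `"coincidence"`.
#' @param mu_exc_mid Excitatory middle cell slow-variable rate (moderate
#'   adaptation keeps its delayed discharge onset-locked).
#' @param gamma_strong,gamma_weak,gamma_inhib,gamma_mid Conductance decay
#'   factors.
#' @param delay_strong_ms,delay_weak_ms,delay_inhib_ms,delay_mid_ms Delays.
#' @param inter_spike_ms Input-train spike spacing this circuit is
#'   calibrated for.
#' @return An object of class `duration_spec`.
#' @export
duration_spec <- function(regime = c("anti", "coincidence"),
                          w_strong = 0.73, w_weak = 0.10,
                          w_mid_to_output = NULL, w_inhib_to_output = NULL,
                          v_rp_inhib = NULL, mu_out = NULL,
                          mu_exc_mid = 0.002,
                          gamma_strong = 0.9, gamma_weak = 0.95,
                          gamma_inhib = 0.95, gamma_mid = 0.9,
                          delay_strong_ms = 1, delay_weak_ms = 1,
                          delay_inhib_ms = 1, delay_mid_ms = 15,
                          inter_spike_ms = 5) {
  regime <- match.arg(regime)
  if (is.null(w_mid_to_output))
    w_mid_to_output <- if (regime == "anti") 0.6 else 0.3
  if (is.null(w_inhib_to_output))
    w_inhib_to_output <- if (regime == "anti") 2 else 1
  if (is.null(v_rp_inhib))
    v_rp_inhib <- if (regime == "anti") -1.1 else -1.5
  if (is.null(mu_out))
    mu_out <- if (regime == "anti") 5e-4 else 5e-3
  structure(list(regime = regime, w_strong = w_strong, w_weak = w_weak,
                 w_mid_to_output = w_mid_to_output,
                 w_inhib_to_output = w_inhib_to_output,
                 v_rp_inhib = v_rp_inhib, mu_out = mu_out,
                 mu_exc_mid = mu_exc_mid,
                 gamma_strong = gamma_strong, gamma_weak = gamma_weak,
                 gamma_inhib = gamma_inhib, gamma_mid = gamma_mid,
                 delay_strong_ms = delay_strong_ms,
                 delay_weak_ms = delay_weak_ms,
                 delay_inhib_ms = delay_inhib_ms,
                 delay_mid_ms = delay_mid_ms,
                 inter_spike_ms = inter_spike_ms),
            class = "duration_spec")
}

#' Build the duration-tuning network
#'
#' Cells: 1 (input), 2 (inhibitory middle), 3 (excitatory middle),
#' 4 (output).
#'
#' @param spec A [duration_spec()].
#' @param cell_params Base cell parameters; the excitatory middle and
#'   output cells get their own `mu` from the spec.
#' @return A [network()] with `meta$circuit = "duration"`.
#' @export
build_duration <- function(spec, cell_params = circuit_cell_params()) {
  stopifnot(inherits(spec, "duration_spec"))
  thr <- epsp_threshold(cell_params, spec$gamma_weak, spec$delay_weak_ms)
  if (spec$w_weak >= thr)
    stop(sprintf(paste0("w_weak (%g) fires the excitatory middle cell on a single ",
                        "input spike (threshold %g): circuit would respond to all durations"),
                 spec$w_weak, thr), call. = FALSE)
  thr_mid <- epsp_threshold(cell_params, spec$gamma_mid, spec$delay_mid_ms)
  if (spec$regime == "anti" && spec$w_mid_to_output < thr_mid)
    stop("anti-coincidence regime requires suprathreshold w_mid_to_output",
         call. = FALSE)
  if (spec$regime == "coincidence" && spec$w_mid_to_output >= thr_mid)
    stop("coincidence regime requires subthreshold w_mid_to_output (rebound-gated)",
         call. = FALSE)
  syn <- rbind(
    synapse(1, 2, spec$w_strong, gamma = spec$gamma_strong, v_rp = 0,
            delay_ms = spec$delay_strong_ms, step_ms = cell_params$step_ms),
    synapse(1, 3, spec$w_weak, gamma = spec$gamma_weak, v_rp = 0,
            delay_ms = spec$delay_weak_ms, mode = "add",
            step_ms = cell_params$step_ms),
    synapse(2, 4, spec$w_inhib_to_output, gamma = spec$gamma_inhib,
            v_rp = spec$v_rp_inhib, delay_ms = spec$delay_inhib_ms,
            step_ms = cell_params$step_ms),
    synapse(3, 4, spec$w_mid_to_output, gamma = spec$gamma_mid, v_rp = 0,
            delay_ms = spec$delay_mid_ms, step_ms = cell_params$step_ms))
  prm <- list(cell_params, cell_params,
              map_params(alpha = cell_params$alpha, mu = spec$mu_exc_mid,
                         sigma = cell_params$sigma,
                         beta_input = cell_params$beta_input,
                         sigma_input = cell_params$sigma_input,
                         step_ms = cell_params$step_ms),
              map_params(alpha = cell_params$alpha, mu = spec$mu_out,
                         sigma = cell_params$sigma,
                         beta_input = cell_params$beta_input,
                         sigma_input = cell_params$sigma_input,
                         step_ms = cell_params$step_ms))
  network(c("input", "inhibitory", "excitatory_mid", "output"), syn,
          params = prm,
          meta = list(circuit = "duration", spec = spec))
}

#' Families of circuit variants along one tuning knob
#'
#' Convenience builders for ensembles of detector units tuned along one
#' parameter axis, as used in the heat-chart scans: `sideband_family()`
#' varies the mean input-to-inhibitory weight (rate threshold),
#' `facilitation_family()` varies the slow delay (preferred rate), and
#' `duration_family()` varies the weak integrative weight (preferred
#' duration).
#'
#' @param mean_grid,asymmetry Sideband: grid of mean inhibitory-input
#'   weights and a common asymmetry coefficient.
#' @param base_spec Spec whose other fields are shared by all variants.
#' @param cell_params Shared cell parameters.
#' @return A named list of [network()] objects (one per variant).
#' @export
sideband_family <- function(mean_grid = seq(0.18, 0.55, length.out = 10),
                            asymmetry = 0, base_spec = sideband_spec(),
                            cell_params = circuit_cell_params()) {
  nets <- lapply(mean_grid, function(m) {
    sp <- base_spec
    pos <- seq_len(sp$n_inputs)
    centre <- (sp$n_inputs + 1) / 2
    sp$w_input_to_inhib <- m * (1 + asymmetry * (pos - centre) / 2)
    build_sideband(sp, cell_params)
  })
  names(nets) <- sprintf("mean_inhib=%.3g", mean_grid)
  nets
}

#' @rdname sideband_family
#' @param delay_slow_grid Facilitation: grid of slow delays (ms).
#' @export
facilitation_family <- function(delay_slow_grid = seq(3, 19, by = 2),
                                base_spec = facilitation_spec(),
                                cell_params = circuit_cell_params()) {
  nets <- lapply(delay_slow_grid, function(d) {
    sp <- base_spec
    sp$delay_slow_ms <- d
    build_facilitation(sp, cell_params)
  })
  names(nets) <- sprintf("delay_slow=%.3g", delay_slow_grid)
  nets
}

#' @rdname sideband_family
#' @param w_weak_grid Duration: grid of weak integrative weights.
#' @export
duration_family <- function(w_weak_grid = seq(0.10, 0.16, length.out = 10),
                            base_spec = duration_spec(),
                            cell_params = circuit_cell_params()) {
  nets <- lapply(w_weak_grid, function(w) {
    sp <- base_spec
    sp$w_weak <- w
    build_duration(sp, cell_params)
  })
  names(nets) <- sprintf("w_weak=%.3g", w_weak_grid)
  nets
}
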