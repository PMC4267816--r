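#' Parameters of the reduced map neuron
#'
#' The neuron model is a two-variable difference equation (a "map") iterated
#' at a fixed step: a fast membrane-voltage variable `V` driven through a
#' piecewise nonlinearity, and a slow adaptation variable `I` that mimics the
#' effect of slow conductances. One iteration corresponds to `step_ms`
#' milliseconds (0.5 ms by default). The fast subsystem is
#'
#' \deqn{V_{n+1} = \alpha/(1 - V_n) + I_n + \beta_{inp} i_n \quad (V_n \le 0)}
#'
#' with a spike branch that carries `V` to its peak value \eqn{\alpha + u}
#' once `V` becomes positive and then resets it to \eqn{-1}. The slow
#' variable relaxes as
#'
#' \deqn{I_{n+1} = I_n - \mu (V_n + 1) + \mu (\sigma + \sigma_{inp} i_n)}
#'
#' where \eqn{i_n} is the external (synaptic or injected) current.
#' `sigma` sets the resting potential of the neuron and therefore its
#' distance from spiking threshold; `mu` must be small so that `I` evolves
#' slowly relative to `V`.
#'
#' The default constants are the standard values used for cortical cells in
#' the map-neuron literature (`alpha = 3.65`, `mu = 0.0005`,
#' `beta_input = 0.133`, `sigma_input = 1`), with `sigma = -0.05` placing the
#' resting state just below the excitation threshold so that the cell is
#' silent without input but can be driven by realistic synaptic currents.
#'
#' @param alpha Gain of the fast map nonlinearity (dimensionless).
#' @param mu Rate of the slow variable; must satisfy `0 < mu << 1`.
#' @param sigma Resting-state bias (dimensionless); the resting voltage is
#'   `sigma - 1`.
#' @param beta_input Coupling of external current into the fast update.
#' @param sigma_input Coupling of external current into the slow update.
#' @param step_ms Duration of one map iteration in milliseconds.
#' @param spike_threshold Voltage whose upward crossing is registered as a
#'   spike. The default 0 separates the subthreshold branch (`V <= 0`) from
#'   the spike branch of the map.
#'
#' @return An object of class `map_params`.
#' @seealso [map_rest_state()], [map_step()], [find_rheobase()]
#' @export
#' @examples
#' p <- map_params()
#' s <- map_rest_state(p)
#' s2 <- map_step(s, p, input_current = 0)
#' abs(s2$V - s$V) < 1e-9
map_params <- function(alpha = 3.65, mu = 5e-4, sigma = -0.05,
                       beta_input = 0.133, sigma_input = 1,
                       step_ms = 0.5, spike_threshold = 0) {
  stopifnot(is.numeric(alpha), is.numeric(mu), is.numeric(sigma))
  if (!(mu > 0 && mu < 0.1))
    stop("`mu` must satisfy 0 < mu << 1 (slow variable)", call. = FALSE)
  if (!(step_ms > 0)) stop("`step_ms` must be positive", call. = FALSE)
  structure(list(alpha = alpha, mu = mu, sigma = sigma,
                 beta_input = beta_input, sigma_input = sigma_input,
                 step_ms = step_ms, spike_threshold = spike_threshold),
            class = "map_params")
}

#' Resting state of the map neuron
#'
#' Returns the fixed point of the map with zero external current:
#' `V_rest = sigma - 1` (from the slow-variable balance) and
#' `I_rest = V_rest - alpha / (1 - V_rest)`.
#'
#' @param params A [map_params()] object.
#' @return A `map_state` list with elements `V`, `I`, `spiked_last_step`.
#' @export
map_rest_state <- function(params) {
  v <- params$sigma - 1
  i <- v - params$alpha / (1 - v)
  structure(list(V = v, I = i, spiked_last_step = FALSE, peaked = FALSE),
            class = "map_state")
}

#' Advance the map neuron by one step
#'
#' Pure function of `(state, params, input_current)`: applies one iteration
#' of the fast-slow map. A spike is registered (`spiked_last_step = TRUE` in
#' the returned state) when `V` crosses `params$spike_threshold` from below.
#'
#' @param state A `map_state` as returned by [map_rest_state()] or a previous
#'   call to `map_step()`.
#' @param params A [map_params()] object.
#' @param input_current External current (dimensionless), e.g. total synaptic
#'   current.
#' @return The next `map_state`.
#' @export
map_step <- function(state, params, input_current = 0) {
  if (!is.finite(state$V) || !is.finite(state$I) || !is.finite(input_current))
    stop("non-finite neuron state or input (numerical blow-up)", call. = FALSE)
  u <- state$I + params$beta_input * input_current
  peaked <- isTRUE(state$peaked)
  if (peaked) {
    v_new <- -1
    pk <- FALSE
  } else if (state$V <= 0) {
    v_new <- params$alpha / (1 - state$V) + u
    pk <- FALSE
  } else if (state$V < params$alpha + u) {
    v_new <- params$alpha + u
    pk <- TRUE
  } else {
    v_new <- -1
    pk <- FALSE
  }
  i_new <- state$I - params$mu * (state$V + 1) +
    params$mu * (params$sigma + params$sigma_input * input_current)
  spiked <- (v_new > params$spike_threshold) && (state$V <= params$spike_threshold)
  structure(list(V = v_new, I = i_new, spiked_last_step = spiked, peaked = pk),
            class = "map_state")
}

#' Convert dimensionless map voltage to millivolts
#'
#' Applies the affine conversion `V_ph = V * 50 - 15` mV used to express the
#' dimensionless map voltage on a physiological scale.
#'
#' @param V Dimensionless voltage (vectorised).
#' @return Membrane potential in mV.
#' @export
#' @examples
#' to_physiological(0)   # -15 mV
#' to_physiological(1)   #  35 mV
to_physiological <- function(V) {
  stopifnot(all(is.finite(V)))
  V * 50 - 15
}

#' Iterate a single neuron under a constant current
#'
#' Convenience driver used for calibration: iterates the map from rest for
#' `n_steps` with a constant external current and returns the spike count and
#' the voltage trace.
#'
#' @param params A [map_params()] object.
#' @param input_current Constant external current.
#' @param n_steps Number of iterations.
#' @return A list with `spikes` (spike step indices), `V` (trace) and the
#'   final `state`.
#' @export
iterate_constant <- function(params, input_current, n_steps) {
  s <- map_rest_state(params)
  v <- numeric(n_steps)
  spikes <- integer(0)
  for (n in seq_len(n_steps)) {
    s <- map_step(s, params, input_current)
    v[n] <- s$V
    if (s$spiked_last_step) spikes <- c(spikes, n)
  }
  list(spikes = spikes, V = v, state = s)
}

#' Smallest constant current that elicits a spike
#'
#' Finds, by bisection, the minimal constant external current that makes the
#' neuron fire at least one spike within `horizon_ms`. Circuit builders use
#' this to express synaptic weights as "subthreshold" or "suprathreshold"
#' relative to the cell's own excitability.
#'
#' @param params A [map_params()] object.
#' @param horizon_ms Simulation horizon for the spike search.
#' @param upper Upper bound of the search interval.
#' @param tol Absolute tolerance on the returned current.
#' @return The rheobase current (dimensionless).
#' @export
find_rheobase <- function(params, horizon_ms = 200, upper = 5, tol = 1e-4) {
  n_steps <- round(horizon_ms / params$step_ms)
  spikes_at <- function(amp) length(iterate_constant(params, amp, n_steps)$spikes) > 0
  if (!spikes_at(upper))
    stop(sprintf("no spike within %g ms even at input %g; raise `upper`",
                 horizon_ms, upper), call. = FALSE)
  lo <- 0
  hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}
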