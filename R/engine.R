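#' Assemble a network of map neurons
#'
#' A network is a set of cells, each with a role and a parameter set, plus a
#' table of synapses. Roles follow the circuit templates of the package:
#' `"input"` cells are the tonotopic layer that receives stimulus current,
#' `"inhibitory"` and `"excitatory_mid"` are middle-layer cells, and
#' `"output"` cells carry the circuit readout. Stimulus events index input
#' cells by their tonotopic position (1-based within the input layer), so
#' stimuli are independent of the network's internal cell numbering.
#'
#' @param roles Character vector, one role per cell, each of `"input"`,
#'   `"inhibitory"`, `"excitatory_mid"`, `"output"`.
#' @param synapses A `data.frame` of [synapse()] rows (may be empty).
#' @param params A single [map_params()] shared by all cells, or a list with
#'   one `map_params` per cell.
#' @param meta Free-form metadata (circuit type and spec), kept with the
#'   network.
#' @return An object of class `map_network`.
#' @export
network <- function(roles, synapses, params = map_params(), meta = list()) {
  valid <- c("input", "inhibitory", "excitatory_mid", "output")
  if (!all(roles %in% valid))
    stop("cell roles must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  n <- length(roles)
  if (inherits(params, "map_params")) params <- rep(list(params), n)
  if (length(params) != n)
    stop("`params` must be one map_params or one per cell", call. = FALSE)
  if (is.null(synapses) || nrow(synapses) == 0) {
    synapses <- synapse(1, 2, 0)[0, ]
  }
  if (any(synapses$pre < 1 | synapses$pre > n |
          synapses$post < 1 | synapses$post > n))
    stop("synapse endpoints must reference existing cells", call. = FALSE)
  if (any(synapses$pre == synapses$post))
    stop("self-synapses are not allowed", call. = FALSE)
  step_ms <- params[[1]]$step_ms
  structure(list(roles = roles, params = params, synapses = synapses,
                 n_cells = n, step_ms = step_ms,
                 input_cells = which(roles == "input"),
                 output_cells = which(roles == "output"),
                 meta = meta),
            class = "map_network")
}

#' @export
print.map_network <- function(x, ...) {
  cat(sprintf("<map_network: %d cells (%s), %d synapses>\n",
              x$n_cells, paste(x$roles, collapse = ","), nrow(x$synapses)))
  invisible(x)
}

#' Simulate a network under a stimulus
#'
#' Deterministic fixed-step simulation. Each step uses only previous-step
#' states (synchronous, Jacobi-style updates), so results are independent of
#' cell and synapse ordering. Stimulus events are delivered as brief
#' suprathreshold current injections to input cells: an input-cell spike
#' stands for a tone onset at that cell's frequency.
#'
#' Cells listed in `spike_block` have their fast subsystem clamped to the
#' subthreshold branch: depolarization accumulates but the spike/reset
#' branch never triggers. The unclamped depolarization candidate is recorded
#' in `max_V`, which is the "maximum excitation" readout used by the
#' rate-scan figures.
#'
#' @param net A [network()].
#' @param events A `data.frame` of stimulus events with columns `cell`
#'   (tonotopic input index) and `time_ms`, e.g. from [sweep_events()] or
#'   [tone_events()]. May be `NULL` or empty.
#' @param horizon_ms Simulated duration in ms.
#' @param record_traces If `TRUE`, keep the full voltage matrix.
#' @param spike_block Integer ids of cells whose spikes are blocked.
#' @param stim_amp,stim_width_steps Amplitude and width (in steps) of the
#'   injection pulse delivered per stimulus event. The default (10 for one
#'   0.5 ms step) reliably elicits exactly one input-cell spike per event.
#' @return A `sim_result` list: `spikes` (data.frame `cell`, `step`,
#'   `time_ms`), `max_V` (per-cell maximum depolarization, dimensionless),
#'   `traces` (matrix steps x cells, or `NULL`), `n_steps`, `step_ms`.
#' @export
simulate_network <- function(net, events = NULL, horizon_ms = 200,
                             record_traces = FALSE, spike_block = integer(0),
                             stim_amp = 10, stim_width_steps = 1) {
  stopifnot(inherits(net, "map_network"))
  step_ms <- net$step_ms
  n_steps <- as.integer(round(horizon_ms / step_ms))
  n <- net$n_cells
  syn <- net$synapses
  n_syn <- nrow(syn)

  # per-cell parameter vectors
  pget <- function(f) vapply(net$params, `[[`, numeric(1), f)
  alpha_v <- pget("alpha"); mu_v <- pget("mu"); sigma_v <- pget("sigma")
  beta_v <- pget("beta_input"); sigin_v <- pget("sigma_input")
  thr_v <- pget("spike_threshold")

  # stimulus injection matrix
  inj <- matrix(0, nrow = n, ncol = n_steps)
  if (!is.null(events) && nrow(events) > 0) {
    if (any(events$cell < 1 | events$cell > length(net$input_cells)))
      stop("stimulus events reference input cells outside the input layer",
           call. = FALSE)
    for (k in seq_len(nrow(events))) {
      s0 <- as.integer(round(events$time_ms[k] / step_ms)) + 1L
      s1 <- min(s0 + stim_width_steps - 1L, n_steps)
      if (s0 > n_steps)
        stop("stimulus event outside the simulation horizon", call. = FALSE)
      cid <- net$input_cells[events$cell[k]]
      inj[cid, s0:s1] <- inj[cid, s0:s1] + stim_amp
    }
  }

  blocked <- rep(FALSE, n)
  blocked[spike_block] <- TRUE

  # initial conditions: every cell at its own resting fixed point
  V <- sigma_v - 1
  I <- V - alpha_v / (1 - V)
  peaked <- rep(FALSE, n)
  max_V <- V
  spike_hist <- matrix(FALSE, nrow = n, ncol = n_steps)
  g <- numeric(n_syn)
  traces <- if (record_traces) matrix(NA_real_, n_steps, n) else NULL

  pre_idx <- syn$pre; post_idx <- syn$post
  gam <- syn$gamma; gs <- syn$g_syn; vrp <- syn$v_rp
  dly <- syn$delay_steps; add_mode <- syn$mode == "add"

  for (nstep in seq_len(n_steps)) {
    # synaptic conductances: decay, then apply delayed presynaptic spikes
    if (n_syn > 0) {
      g <- gam * g
      m <- nstep - dly
      ok <- m >= 1L
      arrived <- ok
      if (any(ok))
        arrived[ok] <- spike_hist[cbind(pre_idx[ok], m[ok])]
      if (any(arrived)) {
        jp <- arrived & !add_mode
        ad <- arrived & add_mode
        g[jp] <- gs[jp]
        g[ad] <- g[ad] + gs[ad]
      }
    }
    # total external current per cell
    inp <- inj[, nstep]
    if (n_syn > 0) {
      cur <- -g * (V[post_idx] - vrp)
      for (s in seq_len(n_syn)) inp[post_idx[s]] <- inp[post_idx[s]] + cur[s]
    }
    # neuron updates (previous-step states only)
    u <- I + beta_v * inp
    v_new <- rep(-1, n)
    pk_new <- rep(FALSE, n)
    b1 <- !peaked & V <= 0 & !blocked
    b2 <- !peaked & V > 0 & V < alpha_v + u & !blocked
    v_new[b1] <- alpha_v[b1] / (1 - V[b1]) + u[b1]
    v_new[b2] <- alpha_v[b2] + u[b2]
    pk_new[b2] <- TRUE
    if (any(blocked)) {
      cand <- alpha_v[blocked] / (1 - pmin(V[blocked], 0)) + u[blocked]
      v_new[blocked] <- pmin(cand, 0)
      max_V[blocked] <- pmax(max_V[blocked], cand)
    }
    i_new <- I - mu_v * (V + 1) + mu_v * (sigma_v + sigin_v * inp)
    if (any(!is.finite(v_new)) || any(!is.finite(i_new))) {
      bad <- which(!is.finite(v_new) | !is.finite(i_new))[1]
      stop(sprintf("numerical blow-up at step %d, cell %d", nstep, bad),
           call. = FALSE)
    }
    crossed <- (v_new > thr_v) & (V <= thr_v) & !blocked
    spike_hist[, nstep] <- crossed
    max_V[!blocked] <- pmax(max_V[!blocked], v_new[!blocked])
    V <- v_new; I <- i_new; peaked <- pk_new
    if (record_traces) traces[nstep, ] <- V
  }

  idx <- which(spike_hist, arr.ind = TRUE)
  spikes <- data.frame(cell = as.integer(idx[, 1]),
                       step = as.integer(idx[, 2]))
  spikes <- spikes[order(spikes$step, spikes$cell), , drop = FALSE]
  rownames(spikes) <- NULL
  spikes$time_ms <- spikes$step * step_ms
  structure(list(spikes = spikes, max_V = max_V, traces = traces,
                 n_steps = n_steps, step_ms = step_ms,
                 horizon_ms = horizon_ms),
            class = "sim_result")
}

#' Spike times of one cell
#'
#' @param sim A result of [simulate_network()].
#' @param cell Cell id.
#' @return Numeric vector of spike times in ms.
#' @export
spike_times <- function(sim, cell) {
  sim$spikes$time_ms[sim$spikes$cell == cell]
}
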