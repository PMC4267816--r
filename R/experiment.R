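#' @keywords internal
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export a spike raster or voltage traces as delimited text
#'
#' @param sim A [simulate_network()] result.
#' @param path Output file path (tab-separated).
#' @return The path, invisibly.
#' @export
export_spikes <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  invisible(.write_tsv(sim$spikes[, c("cell", "time_ms")], path))
}

#' @rdname export_spikes
#' @export
export_traces <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(sim$traces))
    stop("simulation was run without `record_traces = TRUE`", call. = FALSE)
  n <- ncol(sim$traces)
  df <- data.frame(step = rep(seq_len(sim$n_steps), n),
                   time_ms = rep(seq_len(sim$n_steps) * sim$step_ms, n),
                   cell = rep(seq_len(n), each = sim$n_steps),
                   V = as.vector(sim$traces))
  df$V_ph <- to_physiological(df$V)
  invisible(.write_tsv(df, path))
}

.check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown config field%s in `%s`: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

.build_from_config <- function(circ) {
  .check_keys(circ, c("type", "n_inputs", "w_input_to_output", "mean_inhib",
                      "asymmetry", "w_input_to_inhib", "w_inhib_to_output",
                      "v_rp_inhib", "delay_exc_ms", "delay_inhib_in_ms",
                      "delay_inhib_out_ms", "gamma_exc", "gamma_inhib",
                      "plastic", "delay_fast_ms", "delay_slow_ms", "w_each",
                      "gamma", "regime", "w_strong", "w_weak",
                      "w_mid_to_output", "w_inhib_to_output", "mu_out",
                      "mu_exc_mid", "inter_spike_ms"), "circuit")
  type <- circ$type
  if (is.null(type))
    stop("config field `circuit.type` is required", call. = FALSE)
  args <- circ[setdiff(names(circ), "type")]
  switch(type,
    sideband = build_sideband(do.call(sideband_spec, args)),
    facilitation = build_facilitation(do.call(facilitation_spec, args)),
    duration = build_duration(do.call(duration_spec, args)),
    stop("unknown circuit type: ", type, call. = FALSE))
}

.family_from_config <- function(circ, fam) {
  .check_keys(fam, c("knob", "values"), "scan.family")
  base <- .build_from_config(circ)
  vals <- unlist(fam$values)
  switch(fam$knob,
    mean_inhib = sideband_family(vals, base_spec = base$meta$spec),
    delay_slow = facilitation_family(vals, base_spec = base$meta$spec),
    w_weak = duration_family(vals, base_spec = base$meta$spec),
    stop("unknown family knob: ", fam$knob, call. = FALSE))
}

#' Run a declarative experiment configuration
#'
#' Reads a YAML (or list) configuration describing a circuit plus any of a
#' single-stimulus simulation, a rate or duration scan (optionally over a
#' family of variants along one knob), and an STDP training run, and
#' writes the resulting rasters, scan tables and training trajectories as
#' tab-separated text to the output directory together with a
#' `manifest.json` recording the configuration hash and package version.
#' All outputs are deterministic: re-running an unchanged configuration
#' reproduces byte-identical data files.
#'
#' Config blocks (all keys validated; unknown keys rejected):
#' * `circuit`: `type` (`sideband`, `facilitation`, `duration`) plus the
#'   fields of the corresponding spec constructor.
#' * `stimulus`: `kind` (`sweep`/`tone`) with `rate`, `n_cells`,
#'   `onset_ms` or `n_spikes`, `inter_spike_ms` — writes `raster.tsv`.
#' * `scan`: `mode`, `tail_ms`, optional `rates` or `counts`, optional
#'   `family` (`knob`, `values`) — writes `scan.tsv`.
#' * `training`: `n_trials`, `rate`, `record_dsi_every`, `normalize` —
#'   writes `trajectory.tsv` and `trained_weights.tsv`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param outdir Output directory (created if missing); defaults to
#'   `config$output$dir` or the current directory.
#' @return Invisibly, the list of files written.
#' @export
run_experiment <- function(config, outdir = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  } else cfg_path <- NULL
  .check_keys(config, c("circuit", "stimulus", "scan", "training", "output",
                        "step_ms"), "top level")
  if (is.null(config$circuit))
    stop("config field `circuit` is required", call. = FALSE)
  # validate the circuit block eagerly, even when no action block uses it
  base_net <- .build_from_config(config$circuit)
  if (is.null(outdir))
    outdir <- if (!is.null(config$output$dir)) config$output$dir else "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  if (!is.null(config$stimulus)) {
    st <- config$stimulus
    .check_keys(st, c("kind", "rate", "n_cells", "onset_ms", "n_spikes",
                      "inter_spike_ms", "tail_ms"), "stimulus")
    net <- base_net
    onset <- if (is.null(st$onset_ms)) 5 else st$onset_ms
    tail <- if (is.null(st$tail_ms)) 50 else st$tail_ms
    ev <- switch(st$kind,
      sweep = sweep_events(sweep_stimulus(st$rate,
        if (is.null(st$n_cells)) length(net$input_cells) else st$n_cells,
        onset_ms = onset)),
      tone = tone_events(tone_train(1, st$n_spikes,
        inter_spike_ms = if (is.null(st$inter_spike_ms)) 5 else st$inter_spike_ms,
        onset_ms = onset)),
      stop("unknown stimulus kind: ", st$kind, call. = FALSE))
    sim <- simulate_network(net, ev, horizon_ms = max(ev$time_ms) + tail)
    written <- c(written, .write_tsv(ev, file.path(outdir, "events.tsv")),
                 export_spikes(sim, file.path(outdir, "raster.tsv")))
  }

  if (!is.null(config$scan)) {
    sc <- config$scan
    .check_keys(sc, c("mode", "rates", "counts", "tail_ms", "family"), "scan")
    mode <- if (is.null(sc$mode)) "spikes" else sc$mode
    nets <- if (!is.null(sc$family))
      .family_from_config(config$circuit, sc$family)
    else base_net
    if (!is.null(sc$counts)) {
      curve <- duration_curve(nets, counts = unlist(sc$counts), mode = mode)
      written <- c(written, .write_tsv(curve, file.path(outdir, "scan.tsv")))
    } else {
      rates <- if (is.null(sc$rates)) default_rate_grid() else unlist(sc$rates)
      tail <- if (is.null(sc$tail_ms)) 50 else sc$tail_ms
      scan <- rate_scan(nets, rates = rates, mode = mode, tail_ms = tail)
      written <- c(written, .write_tsv(scan, file.path(outdir, "scan.tsv")))
    }
  }

  if (!is.null(config$training)) {
    tr <- config$training
    .check_keys(tr, c("n_trials", "rate", "record_dsi_every", "normalize",
                      "k_pre_before_post", "k_post_before_pre", "tc_ms"),
                "training")
    net <- base_net
    if (!any(net$synapses$plastic))
      stop("training requires `circuit.plastic: true`", call. = FALSE)
    rule <- stdp_rule(
      k_pre_before_post = if (is.null(tr$k_pre_before_post)) 0.025
                          else tr$k_pre_before_post,
      k_post_before_pre = if (is.null(tr$k_post_before_pre)) -0.025
                          else tr$k_post_before_pre,
      tc_ms = if (is.null(tr$tc_ms)) 10 else tr$tc_ms)
    sw <- sweep_stimulus(if (is.null(tr$rate)) 320 else tr$rate,
                         length(net$input_cells), onset_ms = 5)
    fit <- train_direction(net, sw,
      n_trials = if (is.null(tr$n_trials)) 200 else tr$n_trials,
      rule = rule,
      record_dsi_every = if (is.null(tr$record_dsi_every)) 25
                         else tr$record_dsi_every,
      normalize = if (is.null(tr$normalize)) "per_trial" else tr$normalize)
    tj <- cbind(fit$trajectory,
                as.data.frame(fit$weights,
                              col.names = sprintf("w%d", seq_len(ncol(fit$weights)))))
    written <- c(written,
                 .write_tsv(tj, file.path(outdir, "trajectory.tsv")),
                 .write_tsv(fit$network$synapses,
                            file.path(outdir, "trained_weights.tsv")))
  }

  manifest <- list(package = "fmnet",
                   version = as.character(utils::packageVersion("fmnet")),
                   config_md5 = if (!is.null(cfg_path))
                     unname(tools::md5sum(cfg_path)) else NA,
                   files = basename(written))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, mpath))
}

#' Heat-chart plot of a scan table
#'
#' Renders a rate or duration scan (as written by [run_experiment()] or
#' returned by [rate_scan()] / [duration_curve()]) as a variant-by-rate
#' heat map of maximum excitation, with spiking entries saturated, in the
#' style of the maximum-excitation figures. Requires ggplot2.
#'
#' @param scan A `rate_scan`/`duration_curve` data.frame (or a path to a
#'   `scan.tsv`).
#' @param path Optional PNG output path; when `NULL` the ggplot object is
#'   returned.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_scan <- function(scan, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_scan() requires the ggplot2 package", call. = FALSE)
  if (is.character(scan))
    scan <- utils::read.delim(scan)
  xvar <- if ("rate" %in% names(scan)) "rate" else "n_spikes"
  p <- ggplot2::ggplot(scan,
         ggplot2::aes(x = factor(.data[[xvar]], levels = sort(unique(.data[[xvar]]))),
                      y = .data$variant, fill = .data$max_mV)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = c("navy", "skyblue", "yellow",
                                              "red", "darkred"),
                                  name = "max V (mV)") +
    ggplot2::labs(x = if (xvar == "rate") "sweep rate (cells/s)"
                      else "tone duration (input spikes)",
                  y = "circuit variant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 150)
  invisible(p)
}
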