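---
title: "Map-neuron circuit models of FM sweep selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-neuron circuit models of FM sweep selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmnet)
```

## The problem

Auditory neurons across species are selective for the rate and direction of
frequency-modulated (FM) sweeps — sounds whose frequency moves across the
tonotopic axis, as in echolocation calls, rodent vocalizations, and human
speech. fmnet implements three minimal spiking circuits that each produce
such selectivity from a different synaptic mechanism, plus a
spike-timing-dependent plasticity (STDP) rule under which one of them can
*learn* a direction preference from experience:

* **Sideband inhibition** — tonotopic inputs excite an output cell directly
  and an inhibitory interneuron di-synaptically; the latency race between
  the two paths makes the output a *fast-pass* rate filter, and asymmetry
  of the inhibitory input weights makes it direction selective.
* **Facilitation (coincidence detection)** — two subthreshold inputs with
  different axonal/dendritic delays converge on one cell; only the sweep
  rate and direction whose inter-tone interval offsets the delay
  difference produces coincident EPSPs, giving *band-pass* tuning.
* **Duration tuning** — onset-locked inhibition lasting the tone plus
  delayed integrative excitation make the output respond to a narrow
  interval of tone durations; with subthreshold delayed excitation the
  response additionally requires coincidence with the rebound from
  inhibition (offset-locked), with suprathreshold excitation it is vetoed
  by overlapping inhibition (onset-locked, "anti-coincidence").

Throughout, a sweep is abstracted to its tonotopic footprint: the signed
rate, in *input cells per second*, at which consecutive frequency-selective
input cells are activated. An infinite rate activates all inputs
simultaneously; negative rates reverse the order. No audio-frequency axis
is modelled — frequency identity *is* the input-cell index.

## The neuron and synapse models

Cells are reduced difference-equation ("map") neurons iterated at a fixed
0.5 ms step: a fast voltage `V` updated through the piecewise nonlinearity

$$V_{n+1} = \frac{\alpha}{1 - V_n} + I_n + \beta\, i_n \qquad (V_n \le 0),$$

with a spike branch that carries `V` to its peak and resets it to −1, and a
slow variable

$$I_{n+1} = I_n - \mu (V_n + 1) + \mu(\sigma + \sigma_{inp}\, i_n),$$

where $i_n$ is the external (synaptic) current. This is the standard
fast–slow map formulation used for large cortical network models; its
advantage here is that the model *is* the integration scheme — simulations
are exactly reproducible, bit for bit, with no solver tolerances. The
dimensionless voltage maps to millivolts as $V_{ph} = 50V - 15$, putting
the default resting state ($V = \sigma - 1 = -1.05$) at −67.5 mV.

Default constants are `alpha = 3.65`, `mu = 5e-4`, `beta_input = 0.133`,
`sigma_input = 1`, the standard values for cortical cells in the map-neuron
literature, with `sigma = -0.05` chosen so the cell is silent at rest but
within reach of realistic synaptic drive. A spike is registered when `V`
crosses 0 from below (the boundary between the subthreshold and spike
branches); the spiking threshold in current terms is found by bisection
(`find_rheobase()`, and `epsp_threshold()` for a single synaptic event),
which is how circuit builders check that weights declared "subthreshold"
really are.

**Phasic circuit cells.** Circuit builders use `circuit_cell_params()`,
which sets `sigma_input = 0`. With the generic `sigma_input = 1`, sustained
synaptic drive charges the slow variable and cells continue firing for tens
of milliseconds after their input ends; that behaviour is desirable for
modelling slow cortical rhythms but destroys the timing relations these
circuits depend on (the inhibitory middle cell must stop when the tone
stops, and STDP pairings must reflect the stimulus, not afterdischarge).
This is a deliberate calibration choice of the package, exposed as an
ordinary parameter.

Synapses are first-order kinetic conductances on the same step grid:
geometric decay `g -> gamma * g` each step, reset to the peak value
`g_syn` when a presynaptic spike (deferred by an integer-step delay,
0.5–20 ms) arrives. The current is the driving-force form
`-g (V_post - V_rp)`; `V_rp = 0` gives an excitatory synapse, `V_rp` below
rest an inhibitory one. The integrative input of the duration circuit uses
the additive mode (`mode = "add"`), in which arrivals accumulate instead of
resetting — that is what lets a weak synapse count input spikes.

## Circuit calibration

The circuit weight values are calibrated, once, so that each circuit
reproduces its qualitative selectivity profile; they are expressed in
units of the single-EPSP firing threshold (≈ 0.366 for the default phasic
cell, `gamma = 0.9`, 1 ms delay) and exposed in the spec constructors:

* **Sideband** (`sideband_spec()`): direct excitation 0.183 per input
  (half-threshold: no single tone fires the output; three near-coincident
  inputs do), mean inhibitory-path input 0.274, feed-forward inhibition
  2.0 with reversal −1.1, delays 1/1/2 ms. The inhibitory-path mean is the
  rate-threshold knob (stronger drive → earlier inhibition → fewer
  responded rates); the asymmetry coefficient tilts the profile linearly
  around the central input cell.
* **Facilitation** (`facilitation_spec()`): two equal weights of 0.2
  (subthreshold alone, suprathreshold when coincident), fast/slow delays
  1/11 ms, so the preferred inter-input interval is 10 ms ≙ 100 cells/s.
* **Duration** (`duration_spec()`): strong input→inhibitory synapse 0.73
  (the inhibitory cell fires roughly one spike per input spike at the
  5 ms train spacing), weak integrative input 0.10 (threshold after ~6
  spikes; stronger values shorten the preferred duration), middle→output
  excitation delayed 15 ms. The two regimes differ only in that
  connection and the inhibition: *anti* uses suprathreshold excitation
  (0.6) against inhibition 2.0 at reversal −1.1; *coincidence* uses
  subthreshold excitation (0.3), weaker inhibition (1.0) at a deeper
  reversal (−1.5) and a larger output-cell `mu` (5e-3), which together
  produce a usable rebound at tone offset. We verified that in the
  coincidence regime the rebound alone (excitation weight 0) never fires
  the output — the response genuinely requires the overlap.

The tone-train spike rate, which the duration circuit's calibration
references, is set to 200 spikes/s (5 ms spacing).

## Selectivity metrics

`rate_scan()` drives a circuit (or a family of variants along one knob)
across a grid of signed sweep rates — by default 10 log-spaced points from
10 to 1000 cells/s per direction plus ±Inf — and records output spike
counts and maximum depolarization. A variant *responds* to a rate if its
output fires at least once between stimulus onset and 50 ms after the last
input activation (the response window is a package convention; it is ample
for every latency the circuits produce). The direction selectivity index is

$$DSI = \frac{n_{up} - n_{down}}{n_{up} + n_{down}}$$

counted on the scan grid, so DSI values are comparable only within a grid.
The asymmetry of the inhibitory input profile is summarized by the
distance-weighted side difference

$$ASY = \frac{\sum_d d\,S_{c-d} - \sum_d d\,S_{c+d}}{\sum_d d},$$

with linear distance weights and per-side normalization by the sum of
distances — the minimal reading of a distance-weighted average; the weight
law is exposed as an argument, and only the sign and monotonicity of ASY
are meaningful across conventions. Positive ASY (stronger low-frequency
flank) predicts a downward preference: the network is *less* sensitive to
sweeps that enter from the strong side, because those fire the inhibitory
cell earliest.

In `blocked_depolarization` mode the output cells are clamped to the
subthreshold branch of the map (the reset never triggers) and the readout
is the unclamped depolarization candidate, which shows graded excitation
below threshold and saturates above it — the heat-chart view of circuit
tuning. One consequence is that near-preferred stimuli form a plateau at
the saturated level, so "the tuning curve peaks at the preferred interval"
is tested as: the peak region is contiguous, contains the delay
difference, and the curve is unimodal up to a small tolerance.

## STDP training

Plasticity acts on the input→inhibitory synapses of the sideband circuit.
Each adjacent pre/post spike pairing creates one event — a post spike
directly following a pre spike is a *pre-before-post* event, further post
spikes before the next pre spike create none, and symmetrically — valued
at $k\,S\,e^{-\Delta t / T_c}$ with $k = \pm 0.025$ and $T_c = 10$ ms. The
exponential kernel with multiplicative strength dependence is the standard
form for this constant set. Simultaneous pre and post spikes create no
event (strict ordering). After every trial, weights are floored at zero
and the total incoming plastic weight of the inhibitory cell is rescaled
to its initial value (conservation holds to 1e-12 across arbitrary runs);
a per-event normalization schedule is available as an option
(`normalize = "per_event"`), since the constraint itself does not dictate
the schedule.

Training with repeated upward sweeps at 320 cells/s from a symmetric
network (`mean_inhib = 0.183`) places the inhibitory spike a few
milliseconds *after* the last input cell: all inputs potentiate, the late
(high-frequency) inputs most strongly, so weight concentrates on the
high-frequency flank, |ASY| grows, and the network becomes selective for
the trained direction (DSI > 0). Starting from a stronger symmetric
network (`mean_inhib = 0.219`) the inhibitory cell spikes *before* the
last input cell; the pairing order for that synapse is then reversed, its
weight is depressed, and asymmetry growth is reduced relative to the
lagging regime.

**Known limitation.** In this calibration the lagging regime does not
spontaneously cross into the leading regime during a single training run:
under weight conservation the inhibitory spike converges to just after the
last input spike that drives it and cannot causally precede it. The full
non-monotone asymmetry trajectory (growth, then reduction after the
crossing) is therefore demonstrated by comparing the two regimes rather
than observed within one run. The ceiling effect on DSI (coarse, grid-
counted, saturating while ASY still moves) is reproduced.

## Numerical and design choices

* Fixed 0.5 ms step everywhere; delays and time constants are converted to
  integer step counts (off-grid values round with a warning).
* Synchronous (Jacobi) updates: every step uses only previous-step states,
  so results are independent of cell and synapse ordering — tested by
  permuting the synapse table.
* Stimulus events are brief suprathreshold current injections (amplitude
  10 for one step) that elicit exactly one input-cell spike per event.
* Non-finite states abort the simulation with the step and cell index.
* The model is entirely deterministic — there is no noise source — so
  reproducibility is bit-exact and tested as identity.
* Problem sizes: circuits have 3–7 cells; scans use 12–22 rates and
  simulate 50–250 ms per stimulus; training demonstrations use 30–200
  trials. These sizes fully exercise every mechanism; nothing in the
  package's claims depends on larger networks.

## What the synthetic stimuli do and do not show

The stimulus generator produces idealized tonotopic footprints: exactly
one spike per input cell per sweep, perfectly regular tone trains, no
amplitude, bandwidth, or spectral-splatter structure, and no background
activity. Passing tests therefore show that the three synaptic mechanisms
produce the claimed selectivity classes (fast-pass, band-pass,
duration-interval) and that STDP with synaptic competition can sculpt
direction preference — they do not show robustness to jittered spike
timing, overlapping sweeps, or realistic cochlear front-ends, all of which
are outside the model's scope, nor do they reproduce any specific
species' tuning quantitatively.
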