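---
title: "Modelling calcium-triggered vesicular release at a CA3-CA1 bouton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium-triggered vesicular release at a CA3-CA1 bouton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bouton)
```

## The model

`bouton` simulates the chain of events between an action potential arriving
at a small hippocampal presynaptic terminal and the release of
neurotransmitter-filled vesicles. The terminal is a 0.5 x 0.5 x 4 µm box of
axon with a single active zone of seven docked vesicles on one membrane
face. Four interacting pieces are modelled explicitly:

1. **Voltage-dependent calcium channels (P/Q type).** A cluster of
   channels (1-208; 48 in the reference configuration, in a disc of up to
   66 nm radius) at a co-localization distance $l_c$ (10-400 nm) from the
   active zone. Each channel is a five-state Markov chain
   C1⇌C2⇌C3⇌C4⇌O with voltage-dependent rates
   $a_i(v) = a_{i0} e^{v/v_i}$, $b_i(v) = b_{i0} e^{-v/v_i}$; only O
   conducts. Channels are immobile.
2. **Buffered calcium diffusion.** Free Ca²⁺ diffuses at 220 µm²/s and is
   chased by the mobile buffer calbindin-D28k (45 µM, 28 µm²/s, two
   high-affinity and two medium-affinity sites per molecule) and by
   plasma-membrane calcium ATPase (PMCA) pumps (180 /µm²) that, together
   with a compensating leak, hold the resting level at 100 nM. The free
   calcium concentration is clamped at 100 nM in 20 nm slabs at both ends
   of the axon segment.
3. **A dual calcium-sensor release machinery** on each docked vesicle:
   a synchronous sensor with five binding sites that fuses at
   $\gamma = 2000\,s^{-1}$ when saturated, and an asynchronous sensor with
   two sites and a 40-fold slower fusion rate $a\gamma$ ($a = 0.025$).
   Unbinding is slowed per bound site by the cooperativity factor
   $b = 0.25$. A small spontaneous rate $\delta$ acts from the unbound
   state. The readily-releasable pool holds 7 vesicles and is decremented
   by each release.
4. **Refractory coupling.** Any release disables fusion zone-wide and the
   machinery is re-enabled with time constant $\varepsilon = 6.34$ ms
   (exponentially distributed closure; a deterministic 6 ms dead time is a
   config option). Calcium binding continues while the gate is shut.

Two engines drive the sensor chain. The **spatial engine** is a
particle-based Monte Carlo of every free ion, buffer molecule and pump in
the box. The **hybrid engine** replaces the local calcium field at the
active zone by a parameterised transient calibrated against the spatial
engine, and is used for large trial ensembles (thousands of trials in
seconds instead of CPU-hours).

## Stochastic simulation details

The sensor chain and the channel chain are simulated exactly (no tau
leaping): within each interval of the piecewise-constant input the next
event time is exponential in the total rate, and the gate re-opening time
is drawn when the gate closes. Event times are continuous random reals, so
ties have probability zero. Every trial uses its own counter-seeded
xoshiro256++ stream derived from the master seed, which makes ensembles
reproducible and lets paired protocol comparisons share common random
numbers.

The spatial engine advances free calcium with isotropic Gaussian steps
(per-axis variance $2 D \Delta t$, reflecting walls), and all other
species on a slower clock. Bimolecular binding uses a cell-local
mass-action probability: an ion in a grid cell (62.5 nm) binds in
$\Delta t$ with probability $1 - \exp(-k_{on} [S]_{cell} \Delta t)$ where
$[S]_{cell}$ is the concentration of free buffer sites in that cell. This
recovers the macroscopic on-rate exactly in a well-mixed volume and
resolves nanodomain gradients at the cell scale. Ion bookkeeping is
integer-exact; a conservation identity (influx = binding + extrusion +
boundary exchange + free pool change) is asserted in the tests.

The printed reference time steps are 0.1 µs for calcium and 1 µs for other
molecules. The package default configuration keeps these values; the
desk-scale analyses in the tests and the acceptance script run at 1 µs /
10-20 µs, where the simulated local calcium peak changes by less than the
across-trial spread (convergence is covered by a test). Long runs coarsen
both steps tenfold after the stimulus transient has passed.

## Calibrated quantities and their anchors

Three ingredients of the model are not fixed by printed constants and are
calibrated once, then frozen:

* **The action-potential waveform.** Only its qualitative role is known
  (it depolarises the bouton; the downstream release latency is about
  3 ms, and the superfast release component tracks the local calcium
  pulse, with a time constant near 0.65 ms). We use a biexponential spike
  from -70 mV to +34 mV whose rise/fall constants are chosen so that the
  channel-gating response reproduces that latency and pulse width.
* **The single-channel flux.** The calcium current of one open channel is
  treated as a scalar (ions/ms while open), fixed by bisection so that the
  mean across-trial peak of the measured local calcium transient at the
  reference configuration (48 channels, $l_c$ = 250 nm) equals 12 µM, then
  frozen for all other experiments. `calibrate_channel_flux()` implements
  the procedure.
* **The probe sampling volume.** Local concentration is an ion count in a
  small sphere 10 nm from the active zone. The reference dispersion of the
  measured peak (±4.8 µM about 12 µM, a CV of 0.4) is strongly
  volume-dependent; a 25 nm sampling radius reproduces that
  trial-to-trial spread, while 50 nm would give a CV near 0.12. The probe
  radius is config-exposed; sensitivity: halving the radius roughly
  doubles the Poisson noise of a single-trial trace while leaving the
  across-trial mean unchanged.

The hybrid template is then extracted from spatial-engine runs at the
calibrated flux: the across-trial mean probe trace is decomposed into a
spike, an intermediate shoulder and a slow residual (each a normalised
biexponential bump), and per-trial amplitude variability is a
gamma-distributed factor with the measured CV. The calibration record
(component amplitudes and time constants) ships as the defaults of
`hybrid_template()`.

## What the synthetic-data generator does and does not emulate

The fixture generator (`generate_fixture()`) produces event streams from
known multi-exponential rate profiles and noisy template transients; it is
used to verify that the analysis layer recovers generating parameters.
It emulates the Poisson statistics of binned release counts, but not
refractory correlations between releases, pool depletion, or pathway
labels. Passing the recovery tests therefore demonstrates correctness of
the estimators, not realism of the release model — that is what the
simulation engines and their acceptance checks are for.

## Analysis choices

* **Histograms** use the reference error rule: the standard deviation of a
  bin with $r$ events is $\sqrt r$.
* **Decay fits** start 3 ms after the stimulus (the release latency) and
  extend to 400 ms. The fitted function is the reference form
  $a_0 e^{-t/\tau_{fast}} + a_1 e^{-t/\tau_{slow}} + a_2$ (and the
  three-exponential analogue for 1 ms bins), but each exponential is
  integrated over the bin rather than evaluated at the bin centre — with
  $\tau_{fast}$ of the order of the 10 ms bin width, centre evaluation
  biases the fast constant noticeably. Weights are inverse expected
  counts, iterated from the fit (weights taken from observed counts
  correlate with the noise and bias the slow component downward; the
  recovery tests document both effects). Because weak components create
  local minima, the optimiser restarts from a small grid of time-constant
  seeds and keeps the solution with the lowest Poisson deviance of the
  binned counts. The constant term is the base-level release rate; the
  bundled analyses pin it to the measured late-window (300-400 ms) rate,
  which removes its ill-conditioned trade-off against the slow
  exponential at realistic event counts. Even so the slow constant is the
  least determined quantity of the analysis (roughly a factor-two spread
  across seeds at 10^4 trials).
* **Component fractions** are the integrals of each fitted component over
  the fit window divided by the integral of the total fit.
* **Facilitation** for an n-stimulus train is computed from total release
  in consecutive 100 ms windows; the summary number is the maximum percent
  increase over the first window.
* **Dose-response cooperativity** fits
  $R = R_{max}\,(c/(c+K))^n$ with $n$ and $K$ free to the mean number of
  vesicles released in the first 20 ms as the channel flux is scaled
  0.25x-2x (extracellular calcium enters the model only through the
  single-channel flux, linearly; saturation is carried by the fitted
  form).
* **Effective diffusion** is the slope of a mean-squared-displacement fit
  $MSD(t) = 6 D_{eff} t$ for tagged ions over a 3 ms window. The window
  matters and is part of the measurement definition: tagged ions start
  free, are captured by the buffer within ~0.3 ms, and thereafter move at
  the buffer's diffusivity, so short windows read closer to the free
  constant and very long windows approach the bound constant.

## Design decisions on open points

* The five-state channel scheme (four rate pairs) is the standard
  linear-chain P/Q model; only the terminal state conducts.
* Calbindin stoichiometry is two high- plus two medium-affinity
  independent sites per molecule (config-exposed).
* The PMCA cycle is bind (kpm1) / release-back (kpm2) / extrude (kpm3) /
  reset (kpm4) with a per-pump counter-leak. The printed nominal leak of
  12.5 /s per pump exceeds the cycle's possible extrusion flux at 100 nM
  (about 0.75 /s per pump with the printed cycle rates), so by default the
  engine balances the leak to the resting extrusion flux; the rest-state
  test verifies a stable 100 nM baseline. The printed value remains
  available via `pump_params(balance_leak = FALSE)`.
* The cooperativity factor b applies to unbinding on both pathways (a
  single b is printed). The alternative (synchronous only) is a switch;
  the steady-state spontaneous rate — the quantity most sensitive to this
  choice — stays inside the reference band either way (1.31 vs
  0.99 x 10⁻⁴ /ms against 1.2 ± 0.2 x 10⁻⁴ /ms).
* Spontaneous fusion δ fires from the fully unbound state only
  (`delta_any` switches to any-state).
* The refractory closure is exponentially distributed with mean ε,
  matching the "time constant" phrasing; a deterministic dead time is a
  config option.
* In spatial mode the sensors are driven by the local concentration
  measured in a sampling sphere at each vesicle (0.1 ms resolution)
  feeding the same exact-jump sensor chain used in hybrid mode, rather
  than by per-collision binding. At that resolution the two couplings
  agree in distribution, and a single code path keeps the engines
  comparable.

## Problem sizes

The bundled analyses use desk-scale ensembles: 2000-8000 hybrid trials
for probabilities and facilitation, 2x10^4 trials where decay constants
are fitted (the slow/constant separation is count-hungry; the reference
studies use 10^4), about 100 spatial trials for the local-peak
measurement, and about 1200 tagged ions tracked over a 3 ms window for
the effective-diffusion fit. All are configurable upward; quantities
inherit counting noise that scales as $\sqrt r$.

## Known limitations

* No ER or mitochondrial calcium stores, no immobile endogenous buffer,
  no glutamate diffusion in the cleft, no postsynaptic response.
* No vesicle replenishment: protocols longer than a few hundred ms at
  high release probability deplete the pool.
* The hybrid engine assumes all vesicles see the same transient (their
  spatial spread of 35 nm is small against $l_c$ = 250 nm); spatial mode
  lifts this.
* The phenomenological single-gate variant keeps its calcium occupancy
  after a release; only the refractory gate separates consecutive
  releases. In this implementation the single gate reduces, but does not
  fully eliminate, the early asynchronous release that appears when the
  per-vesicle model is forced to equal fusion rates on both pathways.
* The simulated time course reproduces the reference operating point
  (release probability ~0.2 with 48 channels at 250 nm, the spontaneous
  rate, the ~3 ms latency and the fast/superfast constants) but carries a
  smaller phasic share of total release and a less cleanly exponential
  slow tail: residual calcium here is sustained by slow unloading of the
  high-affinity calbindin sites and decays over several hundred ms.

## A worked example

```{r example, eval = FALSE}
library(bouton)

spec <- experiment_spec(preset = "pr02", n_trials = 2000, seed = 1)
ens <- run_ensemble(spec)
compute_pr(ens) # ~0.2: one in five action potentials releases a vesicle

h <- release_histogram(ens, t_b = 10, window = c(0, 400))
fit <- fit_release_decay(h, "2exp", constant = spontaneous_release_rate())
glance(fit)     # tau_fast (ms), tau_slow (ms)
autoplot(fit)
```
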