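---
title: "Modeling DBS desynchronization of bursting neural lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling DBS desynchronization of bursting neural lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dbsnet` simulates pathologically synchronized populations of bursting
neurons — a computational caricature of parkinsonian basal ganglia — and
the desynchronizing action of charge-balanced high-frequency Deep Brain
Stimulation (DBS). This vignette is the package's account of the science:
the model equations and their assumptions, every tunable that matters, the
numerical scheme, the design decisions taken where the problem was
genuinely open, and the limits of what the simulations show.

## The two neuron backends

**Morris-Lecar with delayed slow feedback** (`ml_params()`). The reference
neuron is the dimensionless Morris-Lecar spike generator in its canonical
hyperbolic form,

$$C\dot v = -g_{Ca} m_\infty(v)(v - v_{Ca}) - g_K w (v - v_K)
           - g_L (v - v_L) + I^{slow} + I^{syn} + I^{noise}
           + s_1 X_1 I^{stim},$$
$$\dot w = \phi\,\frac{w_\infty(v) - w}{\tau_w(v)},$$

with $m_\infty, w_\infty$ the usual $\tfrac12(1+\tanh)$ sigmoids and
$\tau_w = 1/\cosh$. Bursting comes from a slow current that integrates the
*delayed* membrane potential,

$$\dot I^{slow} = \epsilon_j\,(v^* - v(t-\tau_j) - \alpha I^{slow}),$$

an abstraction of the inhibitory loop through the external globus
pallidus: while the neuron rests below the set point $v^*$ the current
charges, pushes the fast subsystem over its spiking threshold (a saddle
node at $I \approx 0.08$ for the default parameters), and discharges while
the neuron spikes. At the defaults this produces 8-spike bursts; each
neuron draws its own rate $\epsilon_j \sim N(2\times10^{-3},
2\times10^{-5})$, so natural burst frequencies differ by about 1 %. One
dimensionless time unit is interpreted as 1 ms (`time_unit_ms`), which
places the burst rate at ≈5.5 Hz, inside the 3–10 Hz tremor band; the
constant is exposed because it is a modeling convention, not a derived
quantity.

**Izhikevich chattering neuron** (`izh_params()`). The reduced-order
backend is the quadratic integrate-and-fire-with-adaptation model
($v$ in mV, $t$ in ms),

$$\dot v = 0.04 v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with reset $v \to c$, $u \to u + d$ at the +30 mV apex. With $a = 0.02$,
$b = 0.2$, $c = -50$, $d = 0.7$ the model bursts only for a tonic drive in
a narrow window, roughly $I \in [4.5, 6.5]$: below it is silent, above it
spikes tonically. The default `drive = 5` sits mid-window and yields
9 spikes per burst at ≈8.8 Hz, matching the Morris-Lecar backend's burst
structure at two orders of magnitude less arithmetic. Each neuron draws
its drive from $N(5, 0.05)$ (`drive_sd`, 1 % relative — deliberately the
same relative heterogeneity as $\epsilon_j$); without some dispersion a
population of literally identical deterministic oscillators freezes at
whatever phases it starts with, which would make "does it synchronize?"
an ill-posed question.

Two sign/regime corrections to the reference constants were forced by the dynamics and are worth
recording. A *positive* after-spike reset ($c = +50$) cannot chatter, so
the canonical $-50$ is used. And a tonic drive of 22 lies deep in the
tonic-spiking regime at every step size we tried, so the bursting-window
value 5 replaces it; the parameter is exposed for users who want the tonic
regime.

## Network, noise, stimulation

**Lattice and coupling** (`build_lattice()`, `coupling_params()`).
Neurons occupy a square lattice (spacing 0.1; 10×10 for Morris-Lecar,
15×15 for Izhikevich). The "random lattice" variant adds independent
$N(0, 0.1)$ jitter to each pairwise *distance* (not the positions),
clamped at zero — the jittered matrix is deliberately asymmetric. Synapses
are excitatory and conductance-like, gated by a first-order variable $s$
that opens during spikes (`gate_params()`), weighted by a Gaussian kernel
$w(d) = e^{-d^2/2\sigma_g^2}$, $\sigma_g = 0.5$:

$$I^{syn}_j = \frac{\bar g_s}{c_n\,\bar n}\sum_{k\neq j} w(d_{jk})\,
  s_k\,(v_s - v_j), \qquad \bar n = \overline{\textstyle\sum_k w(d_{jk})}.$$

Two design decisions live here. First, the population normalization uses
the mean kernel-weighted in-degree $\bar n$ (57.6 for the 10×10 lattice,
83.9 for 15×15) rather than the raw population size: it is the effective
number of inputs per neuron, it makes the summed synaptic drive invariant
to lattice size and kernel width, and with the reference constants the raw-N
alternative leaves the coupling too weak to lock the lattice at all.
Second, the Morris-Lecar synaptic reversal defaults to $+0.85$: the
coupling is glutamatergic (excitatory), which requires a reversal above
the operating range $[-0.3, 0.14]$; with $-0.85$ the identical formula is
hyperpolarizing and the lattice desynchronizes instead of locking. The
Izhikevich reversal $-0.8$ mV lies above rest and needs no correction.

**Background noise** (`noise_params()`, `ou_noise_trace()`). Each neuron
receives an independent Ornstein-Uhlenbeck current,
$\dot I = -I/\tau + D\,\xi(t)$, with $D = 10^{-5}$, $\tau = 5$:
autocorrelation $e^{-\Delta/\tau}$, stationary s.d. $D\sqrt{\tau/2}$. The
amplitude convention (is $D$ inside or outside a square root?) matters
only as a scale; this package fixes it by the burst statistics — the
alternative reading gives a noise s.d. comparable to the coupling currents
and smears the stereotyped 6–10-spike bursts into 2–14-spike ones. The
integrator uses the exact exponential update (stationary initial draw), so
variance and autocorrelation are independent of the step size; the same
update streams inside the compiled steppers and backs the standalone
"offline" trace generator.

**Stimulation** (`pulse_train()`, `electrode_layout()`,
`stim_protocol()`). The waveform is the clinical charge-balanced biphasic
pulse: 0.2 ms positive, 3.0 ms negative, repeated at 130 Hz, with the
negative amplitude derived so each period integrates to exactly zero
charge. Electrodes sit at the lattice centroid (`"center"`) or the four
quadrant centroids (`"quad"`); each neuron receives the train scaled by
$\frac{c_s}{c_n^{stim}}\sum_k e^{-d_{jk}/\lambda}$, where $c_n^{stim}$ is
the ratio of summed spatial activation between the layout and the single
central electrode, so the *total* delivered stimulation is independent of
the electrode count.

Two protocol parameters are not fixed by any reference value and were
calibrated once, openly:

* `decay_len` $\lambda$ (default 0.15 lattice units). At the synaptic
  scale $\sigma_g = 0.5$ the one- and four-electrode fields are nearly
  interchangeable and four electrodes buy almost nothing. The defining
  qualitative feature of the multi-electrode protocol — more electrodes,
  deeper desynchronization — requires a profile short enough that one
  central electrode cannot cover the sheet while four quadrant electrodes
  can. 0.15 lattice units (1.5 lattice spacings) achieves that for both
  lattice sizes.
* `amp_pos`, the pulse amplitude (reference protocols: 10 for
  Morris-Lecar, 150 for Izhikevich; `pulse_train()` itself defaults to a
  normalized 1). This is the stimulation-efficacy knob. The reference
  values put near-field neurons into the 130 Hz entrainment regime — each
  positive phase forces a spike, functionally lesioning the covered
  region — while the far field keeps bursting; this is the regime in which
  desynchronization saturates and the electrode-count ordering is robust.
  Sensible ranges are roughly 5–20 (ML) and 75–200 (Izh); the two scales
  differ because the backends' voltage scales do, which is also why the
  Izhikevich stimulation weight is 50 against the Morris-Lecar 1.

**Synchrony metric** (`detect_burst_onsets()`, `order_parameter()`,
`compute_sync()`). Burst onsets are upward threshold crossings
($-0.05$ dimensionless / 0 mV) preceded by quiescence of at least
`min_gap`; the automatic gap is 3× the median inter-crossing interval,
which for a bursting train is dominated by the fast intra-burst interval.
Phases interpolate linearly between onsets ($2\pi$ per burst); samples
before a neuron's first or after its last onset are excluded from $R$
rather than extrapolated, because extrapolation biases $R$ at the window
edges. $R(t)$ is sampled on a 1 ms grid regardless of the integration
step. For the Izhikevich backend the integrator's exact reset times are
used instead of voltage crossings.

**LFP and spectrogram** (`simulated_lfp()`, `spectrogram_db()`). The
recording electrode sits at the lattice centroid with a distance floor of
half the lattice spacing; the LFP is the $1/r$-weighted sum of each
neuron's total *non-stimulation* current (for the Izhikevich backend,
which has no explicit ionic currents, $\dot v$ minus the stimulation
term plays that role, an extension documented here). Spectrograms use a
1 s Hann window with 75 % overlap (1 Hz resolution — enough to resolve
the 5–20 Hz band), reported in dB.

## Numerical scheme

Morris-Lecar: classical fixed-step RK4 (default $dt = 0.025$ units) on
the full coupled system, with the delayed membrane potential read from a
per-neuron ring buffer by linear interpolation at the stage times and a
constant-history initialization before $t = 0$ (the standard convention
for delay equations). Izhikevich: forward Euler (default $dt = 0.1$ ms)
with the post-step reset — Euler is part of this model's definition, as
its bursting regimes are conventionally characterized under it. Noise is
held constant within a step and updated with the exact OU map afterwards.
Both steppers abort with the step and neuron index if the state leaves the
finite range (the symptom of an oversized step). Halving either default
step changes mean $R$ of the reference scenarios by well under 0.05 (this
is a tested invariant). Traces are recorded at 1 ms by default;
`record_dt` exposes full resolution.

Initial conditions: membrane potentials uniform over the operating range
($[-0.3, 0.14]$ / $[-65, -50]$ mV), gates closed, Morris-Lecar slow
current at zero, and the Izhikevich adaptation variable uniform over
the mid-quiescent stretch of its burst cycle
($u_0 \sim U(\mathrm{drive}-13, \mathrm{drive}-11)$; the quiescent branch
exists above $\mathrm{drive}-15.6$ and bursts end near
$\mathrm{drive}-10$). That choice makes the initial order parameter
start high, as expected of random initial data for a relaxation-oscillator
ensemble observed through burst phases, while the per-neuron frequency
dispersion supplies the long-run phase spread; seeding the adaptation
variable across the whole cycle mainly lengthens the locking transient
without changing any steady state.

All randomness flows through three named seeds per scenario (`lattice`,
`init`, `noise`), and identical configurations reproduce bit-identical
traces.

## The two-population experiment

`simulate_two_populations()` couples a pacemaker lattice to a driven
lattice of the same size through feedforward synapses with Gaussian-random
weights whose mean equals the mean intra-pacemaker kernel weight (the
"strong driving" condition); the weight spread is 25 % relative, clamped
at zero to stay excitatory. The driven population keeps a weak
intra-coupling, 1 % of the pacemaker conductance — the value is set by the
requirement that an isolated driven population must *not* synchronize over
the simulated horizon (with identical oscillators any appreciable coupling
eventually locks, so the constraint, not a preset number, fixes the
fraction). Stimulating the pacemaker flattens its aggregate synaptic
output; the driven population, no longer entrained by a coherent rhythm,
disperses under its own frequency heterogeneity — which is why the
heterogeneity above is not optional.

## What the synthetic fixtures do and do not show

`make_burst_population()` builds burst trains on a periodic grid with
Gaussian per-onset jitter, for which the order parameter sampled at the
grid instants has the closed form $R = \exp(-\tfrac12(2\pi f\sigma)^2)$;
`make_voltage_with_bursts()` paints stereotyped clipped-sinusoid bursts
(the shape is irrelevant to onset detection by design) onto a noisy
baseline. These fixtures validate the whole metrics stack — detection,
phase reconstruction, $R$ — independently of the simulator. Two caveats
are documented in the function help: between onsets the interpolated phase
mixes two independent jitters, so the *time-averaged* $R(t)$ sits slightly
above the grid-sampled value (≈$e^{-\sigma_\phi^2/3}$ rather than
$e^{-\sigma_\phi^2/2}$), and the interval-ratio estimator carries a
positive bias of order $\sigma_\phi^2 \sigma/P$. Passing fixture tests
therefore certifies the metrics' arithmetic, not the realism of any
simulated trace; conversely they say nothing about burst detection on real
electrophysiology, whose noise is neither white nor stationary.

## Problem sizes and runtime

The reference scenarios are the study conditions themselves: 100
Morris-Lecar neurons for 9 s (stimulation window [4.5, 9] s) and 225
Izhikevich neurons for 7 s (window [3, 6.5] s), five independent seed sets
per condition. A single Morris-Lecar run takes on the order of 15 s on one
CPU and an Izhikevich run about 2 s; the full acceptance recomputation is
a few minutes. Unit tests use miniature lattices (9–25 neurons, 1–4.5 s)
chosen as the smallest systems that still exhibit the property under test.

## Known limitations

* The model is a caricature: two-variable point neurons, a single
  abstracted GPe delay loop, excitatory-only lattices with open
  boundaries, no plasticity, no volume conduction. Conclusions are about
  synchronization dynamics, not anatomy.
* The stimulation spatial profile (exponential, $\lambda = 0.15$) and
  pulse amplitude are calibrated conventions, not measurements; the
  electrode-count ordering is robust around the defaults but the absolute
  desynchronization depths move with both knobs.
* The inhibitory afferent-fibre pathway (stimulation rectified into the
  slow current) is out of scope; only direct excitatory somatic action is
  modeled.
* Burst-phase $R$ treats 130 Hz-entrained (tonically spiking) neurons as
  phase-invalid rather than as a synchronized subpopulation at the
  stimulation frequency — the desynchronization the metric reports is loss
  of *burst* synchrony, which is the clinically relevant band.
* The Izhikevich drive heterogeneity (1 %) and the feedforward weight
  spread (25 %) are modeling choices; populations of truly identical
  neurons would freeze rather than desynchronize, and nothing in the
  reference parameter sets constrains these spreads.
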