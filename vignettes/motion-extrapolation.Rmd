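---
title: "Motion-based prediction in a spiking network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based prediction in a spiking network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbpnet)
```

## The problem

A moving object is often briefly invisible — occluded, or lost during a
blink — yet observers (and neurons in higher visual areas) keep a running
estimate of where it is and where it is going. `mbpnet` implements a spiking
network that tests one candidate mechanism for this *motion extrapolation*:
lateral connectivity that is *anisotropic* with respect to each neuron's
motion tuning, so that activity is handed forward along plausible
trajectories with delays matching the implied travel times. The package lets
you wire the same population three ways — isotropically (distance only),
motion-based (position *and* velocity selective, with trajectory latencies
as delays), and direction-based (angle selective, speed-free) — drive all
three with literally identical input, and compare how well the target's
trajectory can be decoded while the input is blanked.

## Model components

### Retinotopic tuning on a torus

Each neuron carries four tuning properties \((x_i, y_i, u_i, v_i)\): a
receptive-field center on the unit square and a preferred velocity. The
square's opposite edges are identified (a torus), so there are no boundary
effects; all distances and displacements use the minimal periodic image
(`torus_distance()`, `torus_displacement()`). Receptive-field centers sit on
a hexagonal (offset) grid — by default 100 cells for the excitatory
population — and each cell hosts the full velocity lattice: 10 speeds,
log-spaced between `v_min = 0.1` and `v_max = 4.0` space-units/s (equal
neuron counts per log-spaced speed give a density favoring slow motion, a
Weber-law speed scale), crossed with 10 uniformly spaced directions. The
lattice is replicated round-robin onto the target population size (13000
excitatory, 2520 inhibitory at full scale) and dispersed with Gaussian
jitter to emulate natural variability.

Choices the construction leaves open, fixed here once:

* **Hex layout.** Rows spaced \(1/\mathrm{rows}\), columns
  \(1/\mathrm{cols}\), odd rows shifted half a column. The slight hexagon
  distortion is the price of tiling the torus exactly.
* **Dispersal magnitudes.** No established value exists; defaults are
  `jitter_x = 0.01` (a tenth of the full-scale grid spacing) and a velocity
  jitter of 5% of each neuron's speed — small enough to keep the lattice
  recognizable, large enough that replicated neurons are not clones.
* **Replication versus coverage.** 13000 neurons do not divide evenly into
  10000 tuning combinations; combinations are reused round-robin (each
  replicate independently jittered). The inhibitory population (coarser 6x6
  grid) may have *fewer* neurons than combinations; combinations are then
  consumed in cell-fastest order so spatial coverage stays even — only
  inhibitory positions matter to the default wiring anyway.

### Stimulus encoding

A dot moves with constant velocity (default \((0.5, 0)\) from
\((0.1, 0.5)\)). Each excitatory neuron's input is an inhomogeneous Poisson
train whose envelope is a Gaussian tuning curve in torus position (width
`beta_x = 0.15`) times a Gaussian in velocity (width `beta_v = 0.15`),
peaking at `f_max = 5` kHz for a perfect match. Spikes are generated by
per-step Bernoulli thinning at `dt = 0.1` ms (per-step probability at most
0.5); this matches the stepwise envelope definition, and the deviation from
exact Poisson thinning is absorbed by the rate-versus-envelope regression
test. During **blank** phases the dot keeps moving invisibly and the
envelope vector is *permuted uniformly across the population at every
step*: the multiset of rates (hence the summed input) is preserved exactly
while all selectivity is destroyed. The default schedule is blank 0–200 ms,
stimulus 200–600 ms, blank 600–800 ms, stimulus 800–1000 ms.

Background drive is a 2 kHz homogeneous Poisson train per neuron and
polarity at 4 nS. Noise events carry continuous times (discretized only at
delivery); this keeps their inter-spike-interval statistics exactly
exponential, which the distributional test checks.

### Connectivity rules

All pathways other than E→E are wired isotropically. For a source at
distance \(d\):

\[p_{ij} = p_{\max} \exp\!\big(-d_{ij}^2 / 2\sigma_X^2\big)\]

with \(p_{\max}\) solved (exactly, by a chunked mean over all pairs) so the
mean pairwise probability equals the pathway's overall probability
(\(p_{EE} = 0.5\%\), \(p_{EI} = 2\%\), \(p_{IE} = 2\%\),
\(p_{II} = 1\%\)). Weights are normal with CV 0.2, truncated at zero, with
mean set so the *expected* incoming sum per target equals the pathway
target (\(w_{EE} = 0.3\), \(w_{EI} = 1.8\), \(w_{IE} = 0.8\),
\(w_{II} = 0.15\) µS); delays are Normal(3, 1) ms. A completely *random*
scheme is the \(\sigma_X \to \infty\) limit (`sigma_x = 10`). The isotropic
\(\sigma_X\) has no canonical value; the default 0.2 keeps diffusion local.

The **motion-based** E→E rule scores a source \(i\) against a target \(j\)
by where the source predicts the stimulus to be after the trajectory
latency \(\tau_{ij} = d_{ij}/\lVert \vec v_i \rVert\):

\[p_{ij} \propto
  \exp\!\big(-\lVert \vec x^*_{ij} - \vec x_j \rVert^2 / 2\sigma_X^2\big)
  \exp\!\big(-\lVert \vec v_i - \vec v_j \rVert^2 / 2\sigma_V^2\big),
  \qquad \vec x^*_{ij} = \vec x_i + \vec v_i\,\tau_{ij}.\]

Velocities are unbounded real vectors, so their difference is plain
Euclidean. Each target keeps the top 0.5% of sources (exact in-degree,
ties broken by ascending source index for reproducibility), the selected
probabilities are rescaled so incoming weights sum exactly to
\(w_{EE} = 0.20\) µS, and the *latency itself becomes the delay*
(\(1000\,\tau_{ij}\) ms, clipped to [dt, 400 ms] — slow cells otherwise
imply arbitrarily long delays). Because selection and normalization are
deterministic, the anisotropic table is bit-identical across runs.

The **direction-based** rule drops all speed and distance dependence in the
score and uses von Mises kernels on two angles — displacement versus the
source's preferred direction, and the two preferred directions:

\[p_{ij} \propto \exp\!\big(\cos\angle(\vec x_j - \vec x_i, \vec v_i) /
  \sigma_X^2\big)\,
  \exp\!\big(\cos\angle(\vec v_i, \vec v_j) / \sigma_V^2\big).\]

Pairs are admitted when they lie within `r_conn = 0.10` of the source *or*
the trajectory latency is at most 100 ms (an inclusive-or: fast cells may
reach further); coincident positions have no defined displacement angle and
are excluded. Delays are again trajectory latencies, clipped to
[dt, 100 ms], and \(w_{EE} = 0.25\) µS.

The selectivity widths are exposed as configuration; the defaults are
\(\sigma_X = \sigma_V = 1.0\) for the motion-based rule and 0.5 for the
direction-based rule. Only the *relative order* of probabilities matters to
top-k selection and proportional weights, so \(p_{\max} = 1\) for the
anisotropic rules.

A scalar **anisotropy statistic** summarizes any E→E table: the mean (over
sources) of the mean outgoing torus displacement projected on the source's
preferred direction. It is ≈ 0 for isotropic tables and positive when
wiring points "downstream".

### Neuron model and integration

Neurons are conductance-based leaky integrate-and-fire units:

\[C_m \frac{dV}{dt} = g_l (E_l - V) + g_E (E_E - V) + g_I (E_I - V)\]

with exponentially decaying summed conductances (\(\tau_E = 5\) ms,
\(\tau_I = 10\) ms — one summed conductance per polarity is mathematically
identical to per-synapse exponentials), \(C_m = 1\) nF, \(g_l = 0.1\) µS
(so \(\tau_m = 10\) ms), \(E_l = E_I = -70\) mV, \(E_E = 0\) mV, threshold
−50 mV, reset −70 mV, refractory 1 ms. Initial potentials are
Normal(−65, 10) mV with draws above threshold redrawn (avoiding spurious
spikes at \(t = 0\)).

Numerical choices:

* **Exponential update with frozen conductances** per `dt = 0.1` ms step —
  exact for piecewise-constant conductances and unconditionally stable; the
  update is a convex combination of the reversal potentials, so \(V\) can
  never diverge. Tests compare a single EPSP against an independent
  integration at `dt/100` (agreement within 1%) and check that halving `dt`
  under a fixed drive changes the network spike count by less than 5%.
* **Spike timestamps at the end of the crossing step**; no sub-step
  interpolation.
* **Delays discretized** to the nearest step, minimum one step, via a ring
  buffer of future conductance increments (units: mV·µS = nA, nA/nF =
  mV/ms, all internally consistent).
* During the refractory period the membrane is clamped at the reset value
  while conductances continue to evolve.

The stepping core is compiled (Rcpp); everything around it is plain R.

### Decoding

Excitatory spikes are counted in 50 ms bins and normalized per bin into
confidence weights \(p_i = n_i / \sum_i n_i\) — each neuron's share of the
population's belief. Position is read out as the activity-weighted
*circular* mean of receptive-field centers (coordinates mapped to angles,
mean vector computed, angle mapped back). Two conventions differ by an
additive constant; the default (`mode = "centered"`) is the one under which
a single active neuron decodes exactly to its own tuning center, and a
strict `"literal"` mode (additive full unit) is kept for comparison.
Velocity components are decoded the same way via the angle
\(\pi v / v_\mathrm{scale}\); the printed convention
\(v_\mathrm{scale} = 1\) wraps at \(|v| = 1\) although preferred speeds
reach 4.0 — the default reproduces it, and `v_scale = v_max` gives an
unambiguous alternative. Bins without any spike are flagged invalid and
carry no estimate (nothing is carried forward: persistence the network did
not produce should not be fabricated). Prediction error is the squared
minimal-image distance between the decoded and true dot position at each
bin center, averaged per protocol phase; the headline comparison uses the
*second* blank (600–800 ms), after the network has locked onto the target.

## The experiment driver

`run_experiment()` chains tuning → wiring → stimulus → integration →
decoding → scoring under child seeds derived from one master seed, and
persists every intermediate table as CSV with a JSON manifest when an
output directory is set. `compare_schemes()` holds the tuning tables, the
stimulus and noise realizations, the shared isotropic pathways and the
initial potentials fixed and swaps only the E→E table, so scheme
differences are attributable to wiring alone.

`make_fixture_config(scale_factor)` shrinks the model for fast runs:
neuron counts, grid cells and in-degrees scale with `scale_factor`, while
per-neuron operating points are preserved (incoming-weight sums, input and
noise rates unchanged). The test suite exercises end-to-end behavior at
scales 0.05–0.25 (the scheme comparison runs at 0.25 with three seeds);
`scripts/acceptance.R` runs the full-size network (13000/2520) over three
seeds, which takes a few minutes per seed on one CPU.

## What the synthetic stimulus does and does not emulate

The generator reproduces the *structure* of the tracking task: a rigid
translating target encoded through joint position–velocity tuning curves,
Poisson spiking, uninformative blanks with a preserved rate budget, and
stationary background noise. It does not emulate natural-scene statistics,
multiple or looming targets, curved trajectories, adaptation, or any
structured (oscillatory, correlated) background activity. Passing tests
therefore show that the wiring rules transport and decode trajectory
information under the stated encoding model — not that they would do so for
arbitrary real inputs.

## Known limitations

* At reduced scale the direction-based network's blank-phase activity is
  fragile: with few, strongly concentrated incoming weights per target the
  propagating wave sometimes dies out during the blank, and its decode then
  collapses onto the noise baseline (the motion-based network is robust at
  the same scale). Related: because proportional weight mapping divides a
  fixed incoming sum among few sources at small scale, single synapses can
  become very strong; a weight cap is a documented non-goal.
* Population-average firing levels are sensitive to the connection-weight
  targets \(w_{kl}\) and to the selectivity widths, for which several
  plausible values exist; with the defaults, the full-scale blank-phase
  excitatory average computed by `scripts/acceptance.R` is below 1 Hz. The
  *qualitative* contrast between schemes — the headline result — is
  insensitive to this level.
* Velocity readout with the printed `v_scale = 1` is ambiguous for speeds
  above 1; position decoding is unaffected.
* Anisotropic wiring is applied to E→E only; anisotropic E→I/I→E/I→I
  variants, learning of tuning or wiring, and slow synaptic currents are
  out of scope.
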