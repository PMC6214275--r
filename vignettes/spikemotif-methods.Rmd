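---
title: "Methods: simulating, reconstructing and censusing spiking-network topology"
author: "spikemotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, reconstructing and censusing spiking-network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`spikemotif` asks a structural question about functional connectivity
inference: when a directed functional network is reconstructed from the
spike trains of a simulated neuronal microcircuit, which features of the
underlying synaptic graph survive, and where do the inevitable false
positives (FP) and false negatives (FN) land?  The package covers the
whole chain:

1. **Structural networks** — a 2-D lattice with distance-based undirected
   connections, Watts–Strogatz rewiring, controlled reduction of
   recurrent (reciprocal) connections, 80/20 excitatory/inhibitory types
   and Gaussian synaptic amplitudes.
2. **Spiking simulation** — Izhikevich regular-spiking and fast-spiking
   neurons, delayed synaptic events, external Poisson drive; 1-ms binned
   binary spike trains.
3. **Functional reconstruction** — higher-order transfer entropy (TE) on
   spike patterns and delayed Pearson correlation of Gaussian-convolved
   firing rates (CC), each maximized over a conduction-delay grid, then
   thresholded per neuron at `mu + kappa * sigma`.
4. **Multiplex census** — the structural and functional layers share one
   vertex set; every unordered pair and triple is classified in both
   layers (3 dyad classes, 16 triad classes), giving 10 dyadic and 256
   triadic structural-to-functional transformation classes.
5. **Null models and Z-scores** — a degree-preserving randomization of
   the structural layer and a placement randomization of the observed
   FP/FN counts; transformation counts are scored as
   `Z = (observed - mu_null) / sigma_null`.

# The structural generator

`build_structural_network()` chains four stages.  The lattice places
`rows * cols` neurons on an integer grid and connects pairs within
Euclidean distance `sqrt(2)` (no periodic boundaries); a 10 × 10 grid
has exactly 342 undirected edges.  Rewiring moves each undirected edge
with probability `p_rw` to a uniformly random partner of one (uniformly
kept) endpoint, rejecting self-loops and duplicates, so the undirected
edge count is conserved.  Recurrence reduction selects an exact count
`round(p_r * E)` of undirected edges without replacement and deletes one
direction of each — the canonical (low-index to high-index) direction
with probability `p_d`, the reverse otherwise.  Two consequences we rely
on: with `p_r = 0.4` on the 342-edge lattice, 205/342 ≈ 60 % of
connected pairs stay recurrent exactly, not merely in expectation; and
with `p_r = 1` and `p_d` at 0 or 1 every surviving edge points the same
way along the canonical order, so the digraph is acyclic.  Types are
assigned uniformly at random (`round(0.2 n)` inhibitory); each directed
synapse from an excitatory neuron draws an independent amplitude from
Gaussian(3.1, 0.1) mV, and every inhibitory synapse is −1.5 mV.

All stages use R's global random number generator: one `set.seed()`
reproduces a network bit for bit, which is also how the pipeline derives
per-trial seeds.

# The neuron models and the coupling decision

Excitatory cells follow the regular-spiking form

$$100\,\dot v = 0.7 (v+60)(v+40) - u + I_E,\qquad
\dot u = 0.03(-2(v+60)) - u,$$

with reset $v \ge 35 \Rightarrow v \leftarrow -50,\ u \leftarrow u+100$;
inhibitory cells follow the fast-spiking form

$$20\,\dot v = (v+55)(v+40) - u + I_I,\qquad
\dot u = 0.2\,(U(v) - u),$$

with $U(v) = 0.025 (v - v_b)^3$ above $v_b = -55$ mV and 0 below, and
reset $v \ge 25 \Rightarrow v \leftarrow -45$.  Both rest states,
(−60, 0) and (−55, 0), are exact fixed points of the discretized update,
which the test suite checks over 10^5 steps.  Integration is forward
Euler at `dt = 0.1` ms (configurable); halving `dt` changes seeded spike
counts by under 5 %.

Synapses are exponential-decay events: amplitude `v_X` (the Gaussian
weight for excitatory sources, −1.5 mV for inhibitory), onset delay
`t_X` (5 ms excitatory, 1 ms inhibitory) after the presynaptic spike,
decay constant `tau = 3` ms.  `synaptic_contribution()` evaluates this
waveform, gated to zero before onset.

**How events couple into the neuron is a genuine modelling choice.**
The amplitudes are described in millivolts — "the maximum voltage
increase delivered to the postsynaptic cell" — yet the model equations
accept input through the current-like slot `I`, which is divided by the
capacitance-like factors 100 (20).  Summing a 3.1-unit waveform into `I`
deflects the membrane by ~0.2 mV at steady state: such a network never
fires and the voltage description of the amplitude is violated.  We
therefore default to `input_mode = "voltage"`: each arriving event
increments `v` by its amplitude at onset time, which realizes the
"maximum voltage increase" reading exactly (the decay back to rest is
then governed by the membrane, whose linearized time constant near rest,
~7 ms for the excitatory cell, is of the same order as `tau`).  The
literal current-summation route is retained as `input_mode = "current"`
for completeness.

# The external drive and its calibration

The drive is a per-neuron Poisson process of excitatory events with
Gaussian amplitude.  Its rate and amplitude jointly set the operating
regime, and only the regime — not any downstream statistic — was used to
fix the defaults.  Two regimes exist:

* **Suprathreshold kicks** (e.g. ~20 mV events at 10 Hz): every event
  fires the cell from rest.  Firing is then almost entirely externally
  caused, single 3.1-mV EPSPs are rarely decisive, and reconstruction
  precision is poor (pilot runs: ~46 % of synaptic connections recovered
  at `kappa = 0.2`).
* **Fluctuation-driven** (many sub-threshold compound events): the
  membrane hovers below threshold with fluctuations comparable to an
  EPSP, so recurrent input frequently tips the balance — the standard
  picture of cortical irregular firing.

A pilot grid over rate × amplitude (20-s and 60-s trains, scored by
population firing rate and by the fraction of true synapses among the
top-|E| TE values against the known structure) selected **80 Hz events
of Gaussian(8, 0.8) mV for both populations**: mean firing ≈ 22 Hz
(excitatory ≈ 27 Hz, inhibitory sparser), and ~78 % of synaptic
connections recovered at `kappa = 0.2` — consistent with the ~80 %
benchmark reported for transfer-entropy reconstruction of comparable
simulated networks.  These values were frozen before the acceptance
properties were evaluated and are not revisited.  The fast-spiking
cells' much leakier subthreshold dynamics make them fire well below the
excitatory rate under equal drive; their −1.5 mV synapses are
correspondingly harder to infer, a known asymmetry of this setting.

# Reconstruction measures

**Transfer entropy.** `transfer_entropy()` is the plug-in estimator on
1-ms binary words: target history order `k = 5`, source order `l = 5`,
source word taken at delay `d`, probabilities as raw empirical
frequencies with the `0 log 0 = 0` convention.  `hote_max()` and the
TE branch of `correlation_matrix()` maximize over `d = 0..30` ms
(ties to the smallest delay).  The estimator is validated against a
brute-force word-count oracle to 1e-12 and against the analytic 1-bit
value of a Bernoulli(1/2) copy channel.  Plug-in TE is positively
biased at finite length (order `#states / 2N ln 2`); the per-neuron
`mu + kappa sigma` thresholds absorb the common component of that bias,
and no explicit bias correction is applied (deliberately out of scope).

**Gaussian-convolution correlation.** Each binned train is convolved
with a zero-mean Gaussian kernel, truncated at ±4σ, normalized to unit
sum, "same" alignment.  The kernel width is printed as σ = 0.2 without
units in the source description; we read it as **0.2 s** on the 1-ms
axis, since 0.2 ms would be sub-bin and inert, and a coarse firing-rate
kernel is consistent with CC's characteristically higher false-positive
rate.  The delayed Pearson coefficient is evaluated on the truncated
overlap for `d = 1..30` ms and maximized; zero-variance overlaps yield
an undefined marker that is excluded from the maximum and, if an entry
stays undefined, treated as 0 at thresholding (with a logged count).

# Thresholding

For neuron `j`, the outward statistics are the mean and **population**
standard deviation (denominator `n − 1`, the number of values) of its
`n − 1` outgoing correlation values, the inward statistics likewise over
incoming values; `gamma = mu + kappa * sigma` on each side, and an edge
`j -> i` survives iff its value is `>=` both `gamma_out(j)` and
`gamma_in(i)`.  The non-strict inequality makes the degenerate
`sigma = 0` case (all values equal) retain all edges, and implies
nesting: the `kappa = 0.8` edge set is contained in the 0.5 set, which
is contained in the 0.2 set.  Whether the per-neuron statistics should
include all pairwise values or only suprathreshold ones is ambiguous in
the source description; we use all `n − 1` off-diagonal values.

# Census conventions

Adjacency is `A[i, j] = 1` iff `j -> i` everywhere.  The multiplex view
stores both layers and exposes the `2n × 2n` supra-adjacency with
identity off-diagonal blocks.  Dyad states on an unordered pair reduce,
under the simultaneous swap of both layers, to 10 transformation
classes; `2->2` preserves the direction, `2->2*` reverses it.  Triads
are classified by canonical form (minimum 6-bit encoding over the six
vertex permutations) into the 16 standard directed-triad classes —
class 4 the out-hub, 5 the in-star, 6 the chain, 10 the cyclic triple,
16 the complete triad — the same ordering as the classical directed
triad census, which lets `igraph::triad_census()` serve as an
independent oracle in the tests.  Excitatory and inhibitory neurons are
treated identically in all censuses.  Census totals are conserved by
construction: `choose(n, 2)` pairs and `choose(n, 3)` triples.

# Null models

**Null model one** (is the reconstruction shaped by the structure?):
the structural layer is randomized by a uniform vertex permutation
followed by 100 double-edge-swap attempts; an attempt draws two edges
from the pool of recurrent units and unidirectional edges, requires both
of the same kind and vertex-disjoint, swaps sources while preserving
source/sink roles, and is discarded if it would create a self-loop,
duplicate, or an accidental recurrent pair.  In-, out- and
recurrent-degree sequences are preserved exactly (tested on every
sample).  Each ensemble member re-permutes independently.  The
permutation alone already destroys the structural-functional alignment
while fixing the full isomorphism class; the swaps additionally decouple
the degree-preserving fine structure.  "100 iterations" is read as 100
attempts (failed draws are discarded and counted), and the count is
configurable.

**Null model two** (do FP/FN locations depend on local circuitry?): the
functional layer is replaced by a copy of the structural layer with the
observed number of FNs deleted from uniformly chosen structural edges
and the observed number of FPs added on uniformly chosen absent ordered
pairs.  The structural layer of the pairing is untouched.

Z-scores use the ensemble mean and N-sample population standard
deviation (N = 100 in the full design, 20 in the reduced profile).
Cells with `sigma = 0` are reported as undefined (never infinite)
unless the observed count equals the null mean, which scores 0;
undefined cells are excluded from cross-trial averages and the
denominator of defined trials is reported alongside.

# Experiment profiles and problem sizes

`experiment_config("paper")` is the full design: 10 × 10 grid,
`p_rw = 0.4`, `p_r = 0.4`, `p_d = 0.5`, ten-minute trains, 10 trials,
N = 100 randomizations, `kappa` in {0.2, 0.5, 0.8}, both methods.
`experiment_config("reduced")` — the profile used by the test suite and
the acceptance script — keeps the network, drive, methods and `kappa`
grid but uses 60-s trains, 3 trials and N = 20.  These sizes were chosen
so that a complete reduced experiment, including the TE sweep over all
9 900 ordered pairs × 31 delays, runs in minutes on a single core while
every qualitative contrast of interest (preservation transformations
overrepresented, FP/FN conversions underrepresented, direction-reversal
transformations near random, CC's FP excess over TE) is already stable.
Shorter trains do inflate the TE plug-in bias and shrink |Z| relative to
the ten-minute design, so reduced-profile Z magnitudes are not
comparable to full-profile ones — only their signs and ordering are.

The 1024-neuron configuration is expressible (`rows = 32, cols = 32`)
but is not exercised by the tests; the census and null-model code are
vectorized per pair/triple and scale as `n^2`/`n^3`.

# What the generator does and does not emulate

The synthetic stage emulates irregular, fluctuation-driven spiking on a
known synaptic graph with conduction delays and signed synapses.  It
does not emulate synaptic plasticity, conductance-based synapses,
axonal-delay heterogeneity beyond the two fixed onset delays,
subsampling of a larger circuit (electrode arrays), or non-stationary
drive.  Passing tests therefore demonstrate correctness of the
inference-and-census machinery under the stated model, and qualitative
robustness of the transformation statistics at reduced scale — not that
the measures would achieve the same operating point on biological
recordings.

# Numerical choices and degenerate inputs

* Exact-count semantics for `p_r` (selection without replacement), so
  recurrence percentages are deterministic given E.
* Rewiring redraws on forbidden targets rather than skipping, so the
  undirected edge count is invariant.
* TE ties across delays resolve to the smallest delay; CC likewise.
* TE values are clipped at 0 against floating-point dust; CC is bounded
  in [−1, 1] by construction.
* Thresholding with `sigma = 0` retains ties (non-strict `>=`).
* `Z` with `sigma = 0` is 0 when the observation matches the null mean,
  undefined otherwise; undefined cells carry an explicit flag through
  aggregation.
* The simulator aborts with a diagnostic if |v| exceeds 1000 mV or goes
  non-finite; the excitatory adaptation variable follows the printed
  form `du/dt = 0.03(-2(v+60)) - u` (see the package sources for the
  discussion of this reading).

# Known limitations

* Plug-in HOTE at order 5 on 60-s trains is bias-dominated for weakly
  coupled pairs; the per-neuron thresholds compensate only the shared
  component.  A related short-train effect touches direction
  discrimination itself: because the source word extends the target's
  own 5-bin history, a connected pair leaks reverse-direction
  information, so on 60-s trains the direction-reversal transformations
  (`2->2*`, `2->3`) should not be expected to sit at Z ≈ 0 the way the
  full ten-minute design places them; the reduced-profile checks in the
  test suite report exactly this deviation.
* The wide CC kernel (σ = 0.2 s) makes the delayed correlation nearly
  symmetric in practice, so CC functional edges are predominantly
  mutual; dyadic cells that require unidirectional functional edges
  (`2->2`, `2->2*`, `3->2`) carry very low CC counts and their Z-scores
  are correspondingly noisy.
* Inhibitory synapses (−1.5 mV against 8-mV drive fluctuations) are
  recovered far less reliably than excitatory ones; the census treats
  both identically, so FN statistics mix the two populations.
* The double-edge-swap null uses a fixed attempt budget, not a mixing
  diagnostic; with the initial permutation this is adequate for
  100-neuron graphs but has not been audited for much larger ones.
* CSV/GraphML/YAML are the only exchange formats; no binary container
  is provided.
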