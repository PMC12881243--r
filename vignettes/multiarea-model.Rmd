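---
title: "A brain-constrained multi-area spiking network for word learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A brain-constrained multi-area spiking network for word learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebbnet)
```

## The model

`hebbnet` simulates a network of twelve cortical areas involved in
learning spoken words for actions and objects.  Six areas are
language-proximal (perisylvian): an auditory stream A1 → AB → PB and an
articulatory stream PFi → PMi → M1i.  Six provide semantic grounding
(extrasylvian): a visual stream V1 → TO → AT and a dorsolateral motor
stream PFL → PML → M1L.  PB, PFi, AT and PFL are multimodal connector
hubs linked to one another by long-distance connections.

Each area is a 25×25 toroidal grid of excitatory spiking neurons, a
matching grid of graded (mean-field) inhibitory neurons, and one
area-wide global-inhibition unit.  Every unit obeys first-order leaky
dynamics

$$\tau \, \dot V = -V + k_1\,(I + k_2\,\eta),$$

where $\eta$ is uniform white noise on $[-0.5, 0.5]$ (excitatory units
only, $k_2 = 0.005$, $k_1 = 0.01$; inhibitory and global units use
$k_1 = 1$, $k_2 = 0$).  An excitatory unit emits a binary spike when
$V - \psi\,\alpha\,\omega > \mathrm{thresh}$, with threshold 0.18,
$\psi = 0.872$, and $\omega$ a leaky average of the unit's own spikes
(adaptation, time constant 10 excitatory steps).  A slower leaky average
$\omega_E$ (time constant 30) estimates the firing rate used by the
learning rule.  The global unit of each area integrates the area's total
spike count (time constant 12) and feeds back uniform inhibition with
gain $k_G = 65$, producing area-wide competition (winner-take-all) that
stabilises retrieved activity patterns.

The adaptation gain $\alpha$ is not fixed by the model tables; it enters
only through the product $\psi\alpha$ and defaults to 1, exposed as a
configuration parameter.

### Connectivity

Within an area, excitatory-to-excitatory synapses are wired by pairwise
Bernoulli trials with an isotropic Gaussian probability over a 19×19
window ($\sigma = 3.2$, amplitude 0.15), giving an expected
out-degree of 9.45 (autapses excluded; 9.60 if included — the published
figure of 9.5 lies between the two conventions, and the autapse flag is
exposed).  Each excitatory neuron contacts its 5×5 inhibitory
neighbourhood deterministically with Gaussian weights ($\sigma = 1.42$,
amplitude 0.295); each inhibitory unit feeds back to its own excitatory
partner (strength 1500).  All 625 excitatory cells drive the area's
global unit and receive its feedback.  Between areas, only excitatory
projections exist, with the same Gaussian form at $\sigma = 9$ —
amplitude 0.13 within a functional system (expected out-degree 33.3 per
projection) and 0.065 across systems (16.6).  Excitatory weights start
uniform on $[0, 0.1]$; class strengths are 500 (E–E), 1500 (I–E), 65
(global-to-E) and 1 elsewhere.

The area-to-area link table is pictorial in its source; the package
encodes it as editable plain data (`default_link_table()`), flagged as
interpretive: next-neighbour chains and a primary-to-hub jumping link in
each system, jumping links between the adjacent systems' secondary and
hub areas, and all six hub-hub pairs.  This yields 22 reciprocal links
(44 directed projections).

### The ABS learning rule

All (and only) excitatory-to-excitatory synapses are plastic, following
a discretised Artola–Bröcher–Singer scheme.  With presynaptic rate
estimate $\omega_E$ and postsynaptic potential $V$:

* $+\Delta$ (LTP) if $\omega_E \ge \theta_{pre}$ and $V \ge \theta_+$;
* $-\Delta$ (homosynaptic LTD) if $\omega_E \ge \theta_{pre}$ and
  $\theta_- \le V < \theta_+$;
* $-\Delta$ (heterosynaptic LTD) if $\omega_E < \theta_{pre}$ and
  $V \ge \theta_+$;
* no change otherwise.

All comparisons are inclusive; at $V = \theta_+$ the printed conditions
of the first two branches overlap, and the package resolves the tie in
favour of LTP (branches evaluated in their printed order).  Weights are
clipped to $[0, 0.225]$.  Two parameter columns are shipped:
`felix` ($\theta_- = 0.14$, $\Delta = 8\times10^{-4}$) and `nest`
($\theta_- = 0.11$, $\Delta = 2\times10^{-4}$); both share
$\theta_{pre} = 0.05$ and $\theta_+ = 0.15$.  Plasticity is applied once
per excitatory step, after the state update, using the same-step rate
estimates and pre-reset membrane potentials; it is frozen during
evaluation trials so that mapping cannot alter the trained network.

### Two numerical backends

The `felix` backend updates synchronously with forward Euler at
resolution 1 step: inhibitory and global units integrate the excitatory
spikes of the previous step, and excitatory units then use that
same-step inhibition.  The `delay` backend works on a half-step grid
with explicit synaptic delays (excitatory-to-excitatory 1 step, all
other classes 0.5 step) and exact integration, holding inputs constant
over each update.  Because the 0.5-step classes place the inhibitory and
global units on half-integer ticks and the excitatory units on integer
ticks, each unit advances exactly once per excitatory step and the
cumulative E→I→E loop delay is one step — the same schedule as the
synchronous backend, reached through explicit delays rather than a
same-step convention.  The two backends therefore differ only in their
decay factors ($1 - dt/\tau$ versus $e^{-dt/\tau}$).
`matched_parameters()` computes delay-backend time constants whose exact
decay equals the Euler decay, making the two backends algebraically
identical maps; the backend-equivalence tests verify spike-for-spike and
state-for-state agreement under matched constants, on the single
excitatory–inhibitory pair testbench and on a two-area network.

A consequence of the staggered grid is that excitatory spikes are
evaluated on the 1-step excitatory clock; the finer 0.5-step resolution
exists to express the inhibitory loop delays.  We chose this over
re-evaluating the excitatory threshold every half step because it
preserves the defining property that both backends implement the same
effective loop timing, which is what makes their comparison meaningful.

### Interpretive choices

Several details are not fixed by the model definition; the package's
choices are:

* **Post-spike reset.**  The threshold function defines no reset, but the
  reference traces show sharp resets at spike events; `spike_reset`
  defaults to `TRUE` ($V \to 0$ on spiking) and is exposed as a flag.
* **Inhibitory output.**  Graded inhibitory units need an output
  function; the package uses the rectified potential
  $\max(V_i, 0)$.
* **Global inhibition timing.**  The global unit is updated with the
  same schedule as local inhibition (from previous-step spikes, used by
  the same-step excitatory update).
* **Autapses** are excluded from local wiring by default (flag
  `exclude_self`).
* **Checkpoints** use R's native serialisation, capturing all state
  arrays, weights and the random-number-generator state, so a restored
  run is bit-identical to an uninterrupted one.

## Protocols

### Word learning

Twelve stimulus triplets (six object, six action words) each select 20
random cells (3.2%) in three of the four primary areas: A1 and M1i
always, plus V1 for object words or M1L for action words.  A learning
trial drives the triplet's cells for 16 steps while the unused primary
area receives uncorrelated input — a fresh 20-cell subset resampled
every trial at the same amplitude — and all areas receive noise.  Trials
follow a randomised interleaved schedule with each word appearing
equally often.  After stimulation, the stimulus-to-stimulus interval
(STSI) runs noise-only steps until global inhibition in the hub areas PB
and PFi falls below `stsi_epsilon` (default 0.5; capped at 100 steps
with a logged warning).

Two protocol amplitudes are calibration choices rather than model
constants.  The **drive amplitude** (default 5000) guarantees that a
driven cell fires within two steps even against full adaptation and the
strongest global inhibition observed in operation (global states of
order 40 correspond to inhibitory currents of order 2600).  The **noise
amplitude** (default 10) keeps spontaneous membrane fluctuations clearly
below threshold: baseline spiking is essentially absent, matching the
minimal spontaneous activity the protocol assumes during baseline
periods.  Raising the noise into the spiking regime is possible but
makes the network settle into a self-organised baseline of several
spikes per step and area, which contaminates the activity-based
cell-assembly criterion below; we therefore keep the subthreshold
default.

### Cell-assembly mapping

Evaluation trials run with plasticity frozen: 5 baseline steps, 2 steps
driving one port area (A1, simulating comprehension, or M1i, simulating
articulation) with a word's cells, then 60 free propagation steps, noise
throughout.  A neuron is *active* in a trial if it spikes at least once
during that trial; it belongs to the word's cell assembly if it is
active in at least 4 of the 6 trials (3 per port).  The phrase "spiked
at least four times across the six trials" is read as
active-in-at-least-4-trials, consistent with the explicit definition of
"active"; a literal total-spike-count criterion is also implemented
(`criterion = "spikes"`).

### Statistics

`rm_anova()` computes the two-way repeated-measures ANOVA (factors
WordType and Area, subjects = networks) on the per-network mean CA
counts, using the standard within-subject sums-of-squares decomposition
with each effect tested against its own effect-by-subject interaction;
no sphericity correction is applied, matching the reported degrees of
freedom ((1, 11) and (11, 121) for 12 networks).  With only two
word-type levels the per-area Tukey contrast degenerates to a paired
comparison; `posthoc_wordtype_by_area()` therefore runs paired t tests
per area with Bonferroni correction over the 12 areas (critical level
$0.05/12 \approx 0.0042$) and is labelled as such.  The implementation
is validated against `stats::aov` error-strata output and a brute-force
sums-of-squares oracle, and its type-I error is checked by simulation.

## Scaled study conditions

The published experiment trains 12 independently wired networks for
2000 trials per word (288,000 trials in total) on cluster hardware.  The
package's test suite reproduces the design at desk scale: three
independently seeded networks, the full 6 + 6 word set, and 300 trials
per word, which completes in minutes on one CPU with the compiled
stepping kernels.  At this scale the category effect is robust — action
words recruit more M1L than V1 cells and object words the reverse — and
connector hubs hold at least as many CA cells as secondary areas.

One finite-training artifact is worth stating plainly: with 300 trials
per word, many between-area synapses still carry their virgin initial
weights, and a strong assembly ignition can therefore recruit a
one-spike "halo" in the port primary areas (A1 and especially M1i)
through those untrained edges whenever global inhibition is fully
relaxed.  This inflates primary-area CA counts relative to the
stabilised published regime, where heterosynaptic depression has pruned
such edges (stabilisation is reported after about 1000 exposures per
word).  The halo shrinks steadily with both the number of words and the
number of trials in our runs, but removing it entirely is outside desk
scale; consequences for the acceptance checks are noted in the test
suite.

What the synthetic protocol does *not* emulate: real acoustic or motor
feature structure (patterns are uniform random cell subsets),
correlations between words, attention or lesion manipulations, and
distance-dependent inter-area delays.  Passing tests therefore show that
the mechanism — Hebbian binding of co-active sensorimotor patterns into
distributed, topographically graded assemblies — operates as specified,
not that the model generalises to natural stimuli.

## Numerical details

* State arrays are checked for non-finite values every 100 steps; an
  error names the first offending area.
* Weight comparisons in tests use exact equality where the arithmetic is
  exact (backend equivalence under matched constants) and 1e-8 .. 1e-6
  tolerances elsewhere.
* All randomness flows through R's generator: one master seed derives
  per-projection wiring seeds, and protocol functions accept explicit
  seeds.  Identical seeds give bit-identical trajectories, rasters and
  weights.
* The edge store is compressed sparse column by presynaptic unit; the
  two per-step hot loops (spike-input accumulation and the ABS update)
  are implemented in C++ and mutate the weight store in place.
  Accessors (`network_weights()`) return detached copies.

## A worked example

```{r example, eval = FALSE}
net <- build_network(model_parameters("felix"), seed = 1)
pats <- generate_patterns(n_object = 2, n_action = 2, seed = 2)
log <- train_network(net, pats,
                     training_config(trials_per_word = 300, seed = 3))
tab <- evaluate_network(net, pats, network_id = 1)
aggregate(ca_count ~ category + area, tab, mean)
```

See the README for a complete run with its printed output.
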