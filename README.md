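# hebbnet

Simulation of Hebbian cell-assembly formation in a brain-constrained,
twelve-area cortical network of spiking neurons — the kind of model used
to study how words for actions and objects acquire their meaning through
sensorimotor grounding.

## The model in brief

Twelve cortical areas (auditory A1–AB–PB, articulatory PFi–PMi–M1i,
visual V1–TO–AT, dorsolateral motor PFL–PML–M1L; PB, PFi, AT, PFL are
multimodal connector hubs) are each modelled as a 25×25 toroidal grid of
excitatory spiking neurons, a matching grid of graded inhibitory
neurons, and one area-wide global-inhibition unit.  All units follow
leaky first-order dynamics
τ·dV/dt = −V + k₁(I + k₂η); excitatory units spike when
V − ψαω > thresh (thresh = 0.18, ψ = 0.872) with spike-rate adaptation
ω, and the global unit integrates the area's spike count and feeds back
uniform inhibition (gain 65), producing winner-take-all competition.

Connectivity is wired by pairwise Bernoulli trials under an isotropic
Gaussian kernel p(dx,dy) = k_C·exp(−(dx²+dy²)/2σ²) truncated to a 19×19
window (σ = 3.2, k_C = 0.15 locally; σ = 9 between areas with
k_C = 0.13 within and 0.065 across functional systems).  All — and only
— excitatory-to-excitatory synapses are plastic under a discretised
Artola–Bröcher–Singer rule with a presynaptic rate threshold
(θ_pre = 0.05) and two postsynaptic potential thresholds (θ₊ = 0.15,
θ₋ = 0.14 or 0.11 depending on preset) separating LTP from homo- and
heterosynaptic LTD in steps of ±Δ, clipped to [0, 0.225].

Two numerical backends are provided: synchronous forward-Euler updating
with same-step inhibition (`felix` preset) and exact integration on a
half-step grid with explicit synaptic delays (`nest` preset).  With
mode-matched time constants (`matched_parameters()`) the two are
algebraically identical, which the test suite verifies spike-for-spike.

Word learning presents stimulus triplets — 20 random cells in A1, M1i
and either V1 (object words) or M1L (action words) — for 16-step trials
with uncorrelated input to the unused primary area, followed by a
relaxation interval until hub inhibition returns to baseline.  Cell
assemblies are then mapped by probing each word through the auditory
and articulatory ports and counting neurons active in ≥ 4 of 6 trials.
A two-way repeated-measures ANOVA (WordType × Area, networks as
subjects) with Bonferroni-corrected per-area post-hocs
(critical p = 0.05/12 ≈ 0.0042) quantifies the semantic topography.

See `vignettes/multiarea-model.Rmd` for the full account, including the
interpretive choices and the scaled-down study conditions.

## Worked example

Train one network on two object and two action words and map the cell
assemblies:

```r
library(hebbnet)
set.seed(11)
net  <- build_network(model_parameters("felix"), seed = 11)
pats <- generate_patterns(n_object = 2, n_action = 2, seed = 12)
log  <- train_network(net, pats,
                      training_config(trials_per_word = 300, seed = 13))
tab  <- evaluate_network(net, pats, network_id = 1)
aggregate(ca_count ~ category + area, tab, mean)
```

Output from this exact run (counts of cell-assembly neurons per area,
averaged over the two words of each category):

```
   category area ca_count
1    action   A1    121.0
2    object   A1     26.5
...
9    action  M1L      3.5
10   object  M1L      0.0
...
13   action  PFi     82.0
14   object  PFi     56.5
...
23   action   V1      0.0
24   object   V1      9.5
```

The signature result is the last four rows: action words recruit
lateral-motor (M1L) but no visual (V1) cells, object words the reverse —
the network has grounded the two word categories in the correct
sensorimotor systems, with assemblies also spanning the shared
perisylvian (auditory/articulatory) areas.  At this reduced scale
(4 words, 300 trials instead of 12 words, 2000 trials) the port primary
areas A1/M1i carry an additional one-spike ignition halo through
still-untrained synapses; it shrinks as words and trials approach the
published scale (see the vignette).

A thin command-line front end is included
(`inst/cli/hebbnet`; subcommands `build`, `train`, `evaluate`,
`analyze`, `testbench`), e.g.

```sh
Rscript inst/cli/hebbnet train --seed 1 --words 4 --trials 300 --out runs/demo
Rscript inst/cli/hebbnet testbench --mode felix --mode delay --current 50 --out runs/tb
```

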