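---
title: "Attractor-network modelling of free recall: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor-network modelling of free recall: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallnet)
```

## The model

`recallnet` implements a Hopfield-style rate network that retrieves items
from long-term memory the way people do in free recall: sequentially,
stochastically, and incompletely. Each of P = 16 items is stored as a
random sparse binary pattern $\eta^\mu \in \{0,1\}^N$ with coding level
$f = 0.1$ (each of the $N = 10^5$ neurons joins each item's ensemble
independently with probability $f$). The synaptic matrix is the Hebbian
covariance rule

$$J_{ij} = \frac{\kappa}{N}\Big(\sum_{\mu=1}^{P}
  (\eta_i^\mu - f)(\eta_j^\mu - f) - \phi\Big),$$

with excitation strength $\kappa$ and a relative feedback-inhibition
strength $\phi$ subtracted once per weight. Neuron currents follow
$\tau \dot c_i = -c_i + \sum_j J_{ij}\, r_j + \xi_i$ with the sublinear
threshold gain $r = g(c) = (c + \theta)^\gamma_+$. Optional
temporal-contiguity couplings $J_+$ and $J_-$ chain each item's ensemble to
the ensembles of its list neighbours (presentation order, open boundaries),
modelling the tendency to recall neighbouring list items together.

Retrieval is driven by two ingredients:

* $\phi(t)$ oscillates sinusoidally between $\phi^{min} = 0.7$ and
  $\phi^{max} = 1.06$ with period $\tau_o = 1 \gg \tau$, starting at the
  trough;
* Gaussian white noise perturbs the dynamics.

At the trough, single-memory attractors exist and the currently cued item
is stably active. As inhibition rises past the single-memory existence
boundary the active ensemble can no longer sustain itself and the state
contracts onto the *intersection* between the active item's ensemble and
the ensemble of some other item — the neurons encoding both. When
inhibition falls again, the intersection state expands into one of its two
parent items. Each oscillation cycle is therefore a chance to move to a new
item, with the competition between candidate intersections decided by their
sizes and by noise. A memory counts as *recalled* whenever the mean firing
rate of its ensemble exceeds $r_{thresh} = 15$.

## Mean-field theory

With overlaps $m^\mu = \frac1N \sum_i (\eta_i^\mu - f) r_i$ and mean
activity $m^0 = \frac1N \sum_i r_i$, the fixed points satisfy a closed
$(P{+}1)$-dimensional system obtained by grouping neurons into
*populations*: all neurons sharing the same membership vector
$v \in \{0,1\}^P$ behave identically, and in the $N \to \infty$ limit the
population weights are $S_v = f^{|v|}(1-f)^{P-|v|}$
(`fixed_point_residual()` evaluates the self-consistency map by exact
enumeration over all $2^P$ vectors).

For a state in which Q items are co-active with a common overlap, only the
populations inside all Q active ensembles fire, all at the same rate, and
the system collapses to one scalar equation. Writing
$\Delta = Q(1-f)^2 - \phi$, for $\gamma = 1/2$:

$$m^0 = \tfrac12\Big(f^{2Q}\kappa\Delta +
  \sqrt{f^{4Q}\kappa^2\Delta^2 + 4 f^{2Q}\theta}\Big),\qquad
  m^{active} = (1-f)\,m^0 .$$

For $\theta = 0$ the solution exists iff $\phi < Q(1-f)^2$ — 0.81 for
single memories, 1.62 for pairs at $f = 0.1$ — so the reference oscillation
range $[0.7, 1.06]$ deliberately straddles the single-memory boundary: that
is the transition mechanism. We derived this form directly from the
population equations and verify it in the tests by substituting it into the
exact $2^P$ enumeration (residual at round-off). Note that a literal
transcription of the published closed form carries an extra factor of the
excitation strength; the form above is the one that is an exact fixed point
of the published self-consistency system, and the active/total ratio
$(1-f)$ is unaffected.

Existence is necessary but not sufficient: `verify_ansatz()` additionally
checks the sign conditions on the currents of every population class
(inside all Q active items: above threshold; any other: below). The pair
state formally exists at $\phi = 0.7$ but violates its ansatz there —
populations belonging to exactly one active item would be suprathreshold —
which is why pairs only become available as inhibition rises
($\phi > (1-f)(1-2f) = 0.72$). `phase_diagram_scan()` combines both checks
into $(\kappa, \phi)$ phase labels; at $\theta = 0$ the boundaries are
$\kappa$-independent. For the simulation's $\gamma = 2/5$ the same ansatz
gives $r_{active} = (\kappa f^Q \Delta)^{\gamma/(1-\gamma)}$ (at
$\theta = 0$), i.e. an attractor rate of $\approx 27.3$ for a single memory
at the trough, comfortably above $r_{thresh} = 15$, while an active pair
intersection leaves each parent item's *mean* rate at
$\approx f \cdot 17.4 \approx 1.7$, far below threshold — the threshold
cleanly separates full recalls from stepping-stone states. Stability is
probed by simulation (zero-noise persistence/collapse runs in the test
suite); no analytic stability spectra are attempted.

## Exact dimensionality reduction

Simulating $N = 10^5$ neurons directly is wasteful: neurons with identical
membership vectors receive identical input. `partition_populations()`
groups them (V ≈ 1800 populations at $N = 2\times10^4$, ≈ 3800 at
$N = 10^5$, rather than the ≈1000 sometimes quoted — the partition is
exact, we simply report the measured count), and `simulate_reduced()`
integrates one unit per population with weights given by the empirical
fractions. This is an exact rewriting, not an approximation: the test suite
checks that full and reduced trajectories of population-mean currents agree
to round-off (≤ 1e−6 demanded, ~1e−10 observed) and that the
Euler integrator converges at first order in `dt`.

The reduced drive is evaluated through its low-rank structure — overlaps
first, then population currents — so a step costs O(VP) rather than
O(V²). The equivalence of this path with the explicit population coupling
matrix `reduced_coupling()` is itself a test invariant. One convention
matters: the published population-coupling expression absorbs the 1/N of
the synaptic rule into the population fractions (we therefore use $\kappa$,
not $\kappa/N$, in the reduced matrix), and the contiguity couplings enter
the reduced matrix with their raw values. The equivalent full-network
contiguity is then $J_\pm/N$ per synapse; `full_connectivity()` offers both
normalisations (`contiguity_norm`), using the per-pair form by default and
the per-neuron form in `simulate_full()` so the two simulators describe the
same system. Under the row-receives convention the printed forward term
makes an active item excite its *predecessor*; since relabelling the list
in reverse maps this onto the successor convention, every reported
statistic is invariant to the choice, and we implement the printed form.

## Noise: the one genuinely open choice

The published description of the population noise term is ambiguous (its
printed amplitude, read literally as an SD, grows with population size
in a way that makes the dynamics diverge, while the phrase "variance"
suggests other readings). We resolved it empirically, once, by measuring
which rule reproduces the model's described phenomenology at the reference
amplitude $\xi_0 = 65$, and then froze the choice:

* *central-limit averaging* $\xi_0/\sqrt{S_vN}$ (available as
  `clt_noise_scaling`): transitions become nearly deterministic — ~90% of
  them land on the largest intersection and only 2–4 items are ever
  recalled; no amplitude rescues this before recall collapses;
* *literal variance reading* $\mathrm{SD} = \sqrt{\xi_0 S_v N}$: at any
  amplitude that randomises transitions, recall becomes nearly perfect
  (13–16 of 16) and the similarity effects disappear;
* *uniform population amplitude* $\mathrm{SD} = \xi_0$ (the default,
  `uniform_noise_scaling`): working recall (~7 items per 100 cycles at
  $N = 2\times10^4$), a monotonically decaying transition-rank
  distribution, faster transitions for larger intersections, and an
  interior optimum of performance in $\xi_0$.

The uniform rule keeps the single-unit noise amplitude on each population
unit instead of averaging it away; mechanistically this is what lets noise
compete with the finite-size spread of intersection sizes (≈7% at
$N = 2\times10^4$, ≈3% at $N = 10^5$) during the selection of the next
item. Selection sharpness is therefore *not* scale-invariant: at the
reference $N = 10^5$ we measure a most-similar-transition fraction of
≈0.21 (consistent with the published 0.30 within Monte-Carlo error),
while at the desk scale $N = 2\times10^4$ the larger heterogeneity
sharpens selection to ≈0.40. We report the measured values rather than
forcing them. Euler–Maruyama
discretisation adds $\mathrm{SD}\cdot\sqrt{dt}/\tau$ Gaussian increments
per step, using a fast dedicated generator seeded from R's RNG stream so
`set.seed()` fully determines trajectories.

## Recall analysis

`detect_recalls()` turns memory-rate traces into event logs (upward
threshold crossings, linearly interpolated, merged within a cycle;
simultaneous suprathreshold memories raise an error since the threshold is
chosen to preclude them). On top of the logs:

* `accumulation_curve()` — mean distinct items recalled versus time;
* `irt_statistics()` — inter-retrieval times between successive *new*
  items, pooled and conditioned on the trial's final recall total
  (one curve per total, transition index on the x-axis);
* `recall_probability_by_size()` — equal-count size bins (the published
  binning is unspecified; quantile bins keep per-bin error comparable);
* `transition_ranks()` / `transition_rank_distribution()` — transitions
  are, by default, successive *newly* recalled items: since an
  already-recalled item is not reported again, the reported protocol is
  the sequence of first retrievals. (The event-level alternative —
  consecutive distinct suprathreshold items — is available via
  `convention = "distinct_events"`, but under it almost every transition
  takes one oscillation cycle, which erases the IRT–similarity relation
  by construction.) The pair's similarity is ranked ascending among the
  first item's 15 partners (rank 15 = most similar), ties sharing their
  mass via fractional ranks;
* `irt_vs_similarity()` — mean IRT binned on raw similarity values
  (the published x-axis could be sizes or ranks; raw sizes are
  implemented, with configurable breaks).

All of these accept any recall-log table plus any symmetric similarity
matrix (or one per trial), so externally collected recall data with, e.g.,
corpus-derived similarity scores can be analysed identically; computing
such scores is out of scope.

## Experiments, scales and seeds

`experiment_config()` carries the reference parameters; `scaled_config()`
is the desk-scale profile used by the packaged experiments, tests and the
acceptance script: $N = 2\times10^4$, 50 trials, $T = 100$ oscillation
cycles, $dt = 2\times10^{-3}$ (= $\tau/5$, the stability limit we enforce;
the reference profile uses $10^{-3}$). These sizes keep a full ensemble
within a few minutes on one CPU while leaving Monte-Carlo errors well below
the effect sizes probed. Each trial draws a fresh pattern set (a fresh
word list), with per-trial seeds derived from one master seed;
`run_experiment()` writes tidy tables plus a manifest with the resolved
configuration and seeds, and reruns are byte-identical. The recall window
equals the configured total time; the manifest records both.

Three experiments switch the contiguity couplings off (`size_effects`,
`transition_stats`, `noise_sweep`): with the reference $J_+ = 1500$,
transitions are dominated by presentation-order chaining and the
representation-driven effects they probe are masked — the published
discussion makes the same point about temporal-association effects masking
long-term-representation effects. (For the noise sweep specifically, very
strong noise with contiguity on reactivates chain transitions and
performance rises again at the high end; the characteristic interior
optimum of noise belongs to the representation-driven regime. The sweep's
upper end stops where coherent recall has collapsed: far beyond it, rate
fluctuations alone push ensemble means across the recall threshold and
crossing counts stop measuring recall.) The
contiguity sweep and time-course keep the full reference configuration.
For the strong-contiguity limit ($J_+ = 2500$) the ensemble assigns
initial items by blocked random permutations ("stratified"): marginally
uniform, as specified, but removing the between-start variance of the
chain-length count (a pure variance-reduction device; the estimand is
unchanged). In that limit recall proceeds as a chain from the random
starting position toward the list end reached by the coupling direction,
then halts, so the ideal mean is $(P+1)/2 = 8.5$; noise occasionally
breaks chains early, and we measure ≈ 7.2 at desk scale.

## Known limitations

* Pattern statistics are i.i.d. Bernoulli; correlated or semantically
  structured codes are not modelled.
* Memory load is low ($P \ll N$); capacity effects are out of scope.
* Inhibition is a single scalar feedback term; no interneuron populations.
* The noise convention is a documented interpretation (above). The
  transition-rank statistics match the published value only at the
  reference network size; at desk scale the most-similar fraction is
  inflated by finite-size heterogeneity (≈0.40 versus 0.30), and the
  separation of conditional IRT curves at the first transition is below
  Monte-Carlo resolution at either scale in this implementation. Both
  deviations are reported, not hidden.
* Passing tests on synthetic ensembles show internal consistency of the
  model and analysis code, not agreement with behavioural data beyond the
  qualitative signatures listed.
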