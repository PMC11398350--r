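---
title: "Modeling established and enabled biome affinities on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling established and enabled biome affinities on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfbs)
```

## The model

Where a species lives is not the same as where it could live. `rfbs` models
both on a time-calibrated phylogeny: for each of $B$ biomes a species holds a
**non-affinity** (code 0), an **enabled affinity** (code 1: the biome lies in
the species' fundamental niche but is unoccupied), or an **established
affinity** (code 2: the biome is occupied, the realized-niche analogue).
A species state is the length-$B$ vector of codes; because a species must
persist somewhere, at least one biome is established, giving $3^B - 2^B$
valid states (5 for two biomes, 19 for three). States are written with an
uppercase biome initial for established, lowercase for enabled, and nothing
for a non-affinity, so with biomes (T, W, C) the vector 210 is "Tw".

**Anagenesis.** Along branches, single-biome events occur with exponential
waiting times: step-wise gains $g_{0\to1}$ (niche expansion) and
$g_{1\to2}$ (establishment of a pre-enabled biome), a lock-step double gain
$g_{0\to2}$ (adaptation and establishment in one rapid episode),
established loss $l_{2\to1}$, and enabled loss $l_{1\to0}$. Double losses
$2\to0$ are forbidden, as is losing the last established affinity. These
rules fill a sparse generator $Q$ over the state space; finite-time
transition probabilities are $e^{Qt}$.

**Cladogenesis.** At a speciation node the established set is inherited
under three scenarios with probabilities $p_e + p_s + p_b = 1$:

* *equal*: both daughters inherit the full state (1 outcome);
* *subset*: one daughter inherits the full established set, the other a
  proper non-empty subset ($2^{n+2}-8$ outcomes for $n \ge 2$ established
  biomes);
* *split*: the established set is divided into two non-empty parts
  ($2^{n+1}-4$ outcomes).

Within a scenario, outcomes are equally likely. In subset and split events
the established biomes a daughter does not inherit all reduce the same way —
either to enabled (divergence unrelated to the niche, e.g. geographic
isolation) or to non-affinity (ecological divergence); this single global
reduction mode per event is the only reading under which the outcome counts
above hold, which is why the package adopts it. Enabled-only biomes (code 1)
pass unchanged to both daughters. A parent with one established biome always
inherits identically. These rules fill the sparse three-dimensional tensor
$P(i; j, k)$, normalized per parent and symmetric under daughter exchange.

**Likelihood.** Felsenstein pruning with a cladogenetic combine: tip
partials are 0/1 ambiguity masks, branch updates multiply by $e^{Qt}$, and
at each internal node (and the root, treated as the earliest cladogenesis)
the two daughter partials are combined through $P$. Root state frequencies
default to uniform over the valid states; the source model description does
not state its root convention, so the choice is explicit and overridable.
Partials are rescaled at every node with accumulated log scalers, which
changes nothing mathematically (verified to $10^{-10}$ against the unscaled
computation) but prevents underflow on large trees.

## Coding tip data

Established affinities are observable; unestablished ones are ambiguous
between enabled and non-affinity. The package codes each tip as the set of
states compatible with the observation, all receiving equal likelihood:

* worst case: established biomes fixed at 2, every unestablished biome
  ambiguous over $\{0, 1\}$ — a species established in one of three biomes
  (true state 211, say) is coded as the four states {211, 210, 201, 200};
* *includes* (e.g. survival in a non-native botanical garden) force an
  unestablished biome to exactly code 1 — the evidence demonstrates
  suitability, not occupancy, so code 2 is not admitted;
* *excludes* (e.g. failed germination without prolonged cold) force code 0;
* the *climatic adjacency* rule: for biomes ordered along a thermal
  gradient, states in which two flanking biomes are established while an
  intermediate biome has no affinity are dropped. By default the rule fires
  only when both flanks are established (the documented empirical usage);
  an optional mode extends it to enabled flanks. The rule constrains tip
  coding only — the model's state space and $Q$ are untouched, since
  restricting the global space would change the evolutionary process.

Contradictory constraints (an emptied ambiguity set, or excluding an
established biome) are errors naming the species.

## Inference

Parameters get the priors used throughout the validation experiments: the
five rates are Exponential($\beta$) with $\beta$ in units of events per unit
tree height ($\beta = 0.5$–$2$ in the experiments; trees can be rescaled to
unit height with `rescale_tree_height()`), and $p_s, p_b \sim$ Uniform(0,1)
with $p_e = 1 - p_s - p_b$, proposals outside the simplex rejected through
the zero prior. Each free parameter is updated once per iteration, in a
fixed order, by the multiplier proposal $x' = x e^{\lambda u}$,
$u \sim \mathrm{Unif}(-0.5, 0.5)$, with Hastings correction $\log(x'/x)$;
tunings default to $\lambda = 1.5$ for rates and $\lambda = 0.2$ for the
cladogenetic probabilities. Chains are initialized from prior draws for
rates and $p_s = p_b = 1/3$; burn-in defaults to 10% (the retained trace
records everything). Ancestral histories are drawn jointly — root from
$\pi_i D_i$, corner pairs from $P(i;j,k) F_L(j) F_R(k)$, node states from
$e^{Qt}_{jk} D_k$ — at a configurable post-burn-in cadence, and marginalized
into per-node/per-corner, per-biome probabilities of the three affinity
types.

`hpd_interval()` is the shortest contiguous sample window holding the
requested mass; `effective_sample_size()` uses the initial-positive-sequence
truncation (consecutive autocorrelation pairs are summed until the first
non-positive pair), capped at the sample size.

A practical note on mixing: under the $\lambda = 0.2$ tuning the
cladogenetic probabilities move in ~5% multiplicative steps, so their
autocorrelation time is two orders of magnitude longer than the rates'.
Chains of a few hundred thousand iterations reach ESS $\ge 200$ for all
seven parameters; the rates get there a hundred times sooner. The package
keeps these tunings as defaults because they define the validated operating
point, and reports per-parameter acceptance rates and ESS so short
exploratory chains are not over-read.

## The simulator and the validation experiments

`simulate_tree()` draws a pure-birth (Yule) topology — two lineages from the
root, Exponential($k$) waiting times with $k$ lineages, a final
Exponential($n$) stretch to the present — rescaled to unit root height to
match the rate units. The tree process itself is a package choice (any
user-supplied newick works everywhere); results that depend on it are
treated as properties, not numeric reproductions. `simulate_history()`
realizes the process forward: uniform root state by default, Gillespie
events along branches, tensor draws at nodes. `mask_tips()` applies the
ambiguity treatments: for a chosen fraction of tips it removes
$\lceil f \cdot m \rceil$ of the $m$ non-true states from the worst-case
compatible set ($f = 1/3$ or $2/3$ in the partial treatments; $f = 1$ is the
entirely-confirmed coding; the true state is never removed).
`recode_dec()` collapses affinities to presence/absence (2 vs {0, 1}) for
the baseline model.

The baseline itself (`build_dec_space()`, `dec_model()`) is a
presence/absence analogue over the $2^B - 1$ non-empty occupancy sets with
one gain and one loss rate and the same three cladogenetic scenarios on
occupancy sets (single reduction mode: non-inherited biomes become absent).
Its published counterpart is named only generically, so the comparison is
structural — same machinery, no enabled tier — and property-based rather
than a numeric reproduction of published panels.

Validation, all runnable through `run_experiment()` and exercised by the
test suite and `scripts/acceptance.R`:

* **Worked-example equivalence**: the built two-biome $Q$ and the tensor
  slices for parents Hc and HC match the worked matrices entry by entry,
  with subset/split divisors confirmed by brute-force outcome enumeration.
* **Likelihood oracle**: pruning agrees to $10^{-8}$ relative with an
  exhaustive sum over all node and corner state assignments on every 3- and
  4-tip topology.
* **Prior recovery**: with fully ambiguous tips the posterior equals the
  prior (means within 3 Monte-Carlo standard errors).
* **HPD calibration**: generating parameters drawn from the prior fall in
  the 95% HPD at the nominal binomial rate. The package's test runs 20
  replicates of 50-tip, two-biome datasets with 100 000-iteration chains
  (the full published design — 100 replicates, up to 500 tips, 500 000
  iterations — is hours of CPU; the reduced run checks the same binomial
  property with a correspondingly widened bound). Chains are retained when
  the rate parameters reach ESS $\ge 200$; at this reduced length the
  cladogenetic probabilities reach ESS $\approx 70$, so the pooled
  seven-parameter coverage uses the widened bound while the rate-only
  coverage is held to the nominal one.
* **Ancestral accuracy and the baseline comparison**: 20 replicates
  (150-tip trees, two biomes, prior scale 1.0, 3 000-iteration chains with
  histories sampled every 25 post-burn-in iterations) fitted under
  entirely-confirmed, partial, and entirely-ambiguous codings, paired
  across treatments. Scored on the cell-pooled mean posterior probability
  assigned to true ancestral affinities and on per-type accuracies against
  the pooled chance baselines; both the full model and the
  presence/absence baseline must beat their respective chance levels on
  established-affinity reconstruction, the baseline's chance level being
  higher (one of two types rather than one of three). Per-type accuracy is
  structurally capped by corner cells just after subset/split events,
  where the two reduction modes (to enabled vs to non-affinity) are nearly
  unidentifiable until later events accrue — visible as lower enabled and
  non-affinity accuracy, a property of the process, not the sampler.
* **Masking sensitivity**: a separate 20-replicate battery on 40-tip,
  three-biome trees (the partial treatments need the 4-state worst-case
  ambiguity sets of a 3-biome system to have room to act; with two biomes a
  tip has at most one unestablished biome and 66% resolution already
  confirms it). Enabled-tier rate error ($g_{0\to1}, g_{0\to2},
  l_{1\to0}$) must grow monotonically from entirely-confirmed through
  partial (66% resolution on 75% of tips) to entirely-ambiguous coding,
  and in the fully ambiguous coding those posteriors revert to the prior
  (their replicate-averaged posterior means match the prior mean, the
  calibration identity for truths drawn from the prior).

## What the simulator does and does not emulate

Simulated data are generated by the model itself on clean Yule trees with
exact binary tips and no detection error, so passing tests demonstrate
internal correctness and calibration — that the machinery recovers what it
assumes — not robustness to model misspecification, phylogenetic error,
biased sampling of biomes, or rate heterogeneity across clades and time.
Empirical settings also differ in having informative (non-uniform) root
states and constraint data of heterogeneous quality.

## Numerical choices and degenerate inputs

* Transition matrices: eigendecomposition of $Q$ with a reconstruction
  check, falling back to scaling-and-squaring for near-defective
  generators; at the R level, `Matrix::expm`. Negative round-off entries
  are clamped to zero.
* Row sums of $Q$ and tensor normalization are enforced to $10^{-10}$ and
  $10^{-9}$ respectively; zero-length branches use the identity matrix
  (continuity of $e^{Qt}$ at $t = 0$).
* Zero-probability data return $-\infty$ with the offending node named;
  empty tip masks are rejected before a chain starts.
* Ties in the HPD window are broken by the lowest start; the ESS estimator
  never exceeds $n$ nor drops below 1; a constant series is a degenerate
  input error.
* All randomness flows through R's RNG, so a single seed makes every
  simulation, chain, and sampled history bit-reproducible.

## Known limitations

State-space size grows as $3^B - 2^B$: dense exponentials are comfortable
to $B \approx 5$ (229 states) and beyond that data-augmentation approaches
would be needed. Extinction is not modelled, so a species cannot occupy a
biome without an enabled affinity even transiently; diversification is
independent of state (no state-dependent speciation/extinction); tip
ambiguity is a hard 0/1 mask (no probabilistic soft priors); and the
cladogenetic scenario probabilities are global, not biome-specific.
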