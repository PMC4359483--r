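---
title: "Joint clone identification and intra-tumor phylogeny reconstruction"
author: "cloneTree package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint clone identification and intra-tumor phylogeny reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneTree)
```

## The problem

A tumor is a mixture of subclones: groups of cells sharing the same pattern
of somatic change. Binary marker profiles — CpG methylation patterns read
from bisulfite sequencing, or single-cell SNV genotypes — sample this
mixture. Reconstructing the tumor's life history means solving two coupled
problems at once: grouping the observed sequences into clones, and
arranging the clones in a phylogeny in which clones may sit at *inner*
nodes as well as leaves (an ancestral clone can still be alive when its
descendant clones are sampled). Classical phylogenetics places every
observation at a leaf and cannot express this; clustering alone discards
the genealogy. `cloneTree` fits both jointly in one Bayesian model.

## The model

**Tree prior.** Clone sizes follow a tree-structured stick-breaking process
(TSSB). Every node $\epsilon$ of an infinite tree draws a depth-wise stick
$\nu_\epsilon \sim \mathrm{Beta}(1, \lambda^{|\epsilon|}\alpha_0)$, keeping
a fraction of the mass that reaches it, and breadth-wise sticks
$\psi \sim \mathrm{Beta}(1, \gamma)$ that split the remainder among its
children: the $i$-th child's share is $\phi_i = \psi_i \prod_{j<i}
(1-\psi_j)$. The node weight is
$\pi_\epsilon = \nu_\epsilon \phi_\epsilon \prod_{\epsilon'}
\phi_{\epsilon'}(1-\nu_{\epsilon'})$ over the ancestors $\epsilon'$, with
$\pi_\emptyset = \nu_\emptyset$ at the root. Observations draw their clone
from $\mathrm{Discrete}(\pi)$. The hyperparameters are fixed at
$\lambda = 2$, $\alpha_0 = 0.3$, $\gamma = 0.1$ and are exposed in
`mcmcConfig()`; $\lambda$ is implemented exactly as written, as the base of
the depth-dependent second Beta shape (larger depth, stochastically smaller
$\nu$), even though stick-breaking constructions elsewhere often restrict
the analogous decay to $(0,1]$ — the direction of this convention is a
genuinely open choice and we keep the printed one.

**Observation model.** Each clone carries a real parameter
$\theta_{i,\epsilon}$ per site; a sequence from the clone shows a 1 at site
$i$ with probability $\sigma(\theta_{i,\epsilon})$ (logistic sigmoid),
independently across sites. Missing entries (allele dropout averages above
half the sites per cell in single-cell SNV data) are ignored site-wise,
which is exact under missingness completely at random.

**Evolution kernel.** Parent and child parameters are linked through a
two-component Laplace mixture with modes at $\pm\mu$ and scale $\Lambda$:
the weight of the $+\mu$ mode at site $i$ is the probability that the child
is in the methylated/mutated state given the parent's state, read from the
transition matrix $P(t) = \exp(At)$ of a two-state CTMC run for the branch
length $t$. States are called by thresholding $\theta \ge \eta$ with
$\eta = 1$ (a conservative call). The methylation generator allows both
gains and losses and is scaled so the average event rate is one
($2\beta_u\beta_m\rho = 1$); the SNV generator has a zero loss rate
(irreversible mutations) and scale $\beta_m(1-\beta_m)\rho = 1$. The
equilibrium frequencies $\beta_m, \beta_u$ are estimated from the data as
the mean marker frequency. The root prior is an independent Laplace at
$-\mu$ per site, favouring an unmethylated / wild-type root clone. We treat
$\Lambda$ as the Laplace *scale* (the standard second parameter); the
alternative rate reading would only rescale one hyperparameter.

## Inference

The sampler is a Gibbs/Metropolis scheme over assignments, clone
parameters, branch lengths, sticks and the kernel hyperparameters
$(\mu, \Lambda)$:

* **Assignments.** The instantiated tree is extended by size-biased lazy
  instantiation — vacant sticks receiving the most mass are instantiated
  first, drawing $\nu$, $\psi$, $t$ and $\theta$ from their priors — until
  the un-instantiated mass falls below `massTol` ($10^{-3}$) or a per-sweep
  candidate budget (40 nodes) is spent. Assignments are then resampled from
  their exact multinomial full conditionals, collapsed over identical data
  rows (rows with the same values and missingness pattern are exchangeable,
  so per-pattern multinomial counts followed by a random allocation are
  distributionally identical to per-observation draws, at a fraction of the
  cost). Candidates that attract no observations are culled within the
  sweep. The assignment-and-stick pair is scanned `assignScans = 3` times
  per sweep: a new clone is born when a fresh candidate captures
  observations and its sticks are immediately promoted by the conjugate
  Beta update, and several scans per sweep give this birth process several
  chances per sweep. Each scan is a valid Gibbs kernel, so the target is
  unchanged; with a single scan, chains at reduced schedules visibly stall
  in states where a small clone stays merged with a dominant neighbour.
* **Clone parameters.** Per-node, per-site Metropolis with a symmetric
  proposal mixture $0.7\,N(\theta, 0.5^2) + 0.3\,N(-\theta, 0.5^2)$. The
  reflected component lets a site hop between the $\pm\mu$ modes of the
  Laplace mixture; a pure random walk of step 0.5 essentially never crosses
  the $2\mu \approx 8$ gap. The mixture is symmetric, so the plain
  Metropolis ratio applies.
* **Branch lengths.** No prior is dictated by the model beyond positivity;
  we use independent Exponential(mean 1) priors — natural on the CTMC time
  scale where one unit is one expected event — with a log-scale random
  walk.
* **Hyperparameters.** $\mu \sim$ Gamma(shape 8, scale 0.5) (mean 4,
  standard deviation about 1.4) and $\Lambda \sim$ Gamma(shape 2,
  scale 0.5) (mean 1), updated by Metropolis steps. These priors are
  deliberately informative about the mode separation: with a diffuse prior
  on $\mu$ the chain can collapse the separation (small $\mu$, inflated
  $\Lambda$) to accommodate a blurred merged clone, which in turn makes
  further clone merging almost free — a degenerate feedback loop we
  observed directly in merged-mode chains ($\mu \approx 2.3$,
  $\Lambda \approx 2.2$). Keeping $\mu$ concentrated near 4 (so
  $\sigma(\mu) \approx 0.98$, i.e. conservative state calls consistent
  with $\eta = 1$) blocks the collapse without fixing the values.
* **Sticks.** $\nu$ and $\psi$ have conjugate Beta full conditionals given
  own-node and subtree observation counts. Draws are clamped to
  $[10^{-12}, 1-10^{-12}]$ because the Beta$(1, b<1)$ stick priors are
  unbounded at 1 and an exact boundary draw would break later Metropolis
  ratios.
* **Swap-clone move.** Once per sweep, the parameters and assigned data of
  two uniformly chosen nodes are proposed for exchange, with both nodes'
  depth sticks re-proposed from their Beta full conditionals under the
  exchanged allocation (the proposal densities enter the
  Metropolis-Hastings ratio, so the move is exact); afterwards all sticks
  are resampled. Exchanging the raw stick values instead leaves them
  mismatched with the new subtree counts and the ratio then rejects almost
  every swap between nodes of unequal mass — observable as inverted trees
  in which the tumor clone sits at the root. States with an empty root are
  invalid: the assignment step already samples the truncated
  (root-occupied) conditional by rejection, and a bounded sequence of
  root swaps repairs the rare remaining cases.
* **Split-merge move.** Five times per sweep, a collective
  Metropolis-Hastings move proposes either splitting an occupied node on a
  marker site — all observations carrying the chosen state at the chosen
  site move into a brand-new last child, whose parameters are proposed
  around the moved group's empirical logit frequencies, whose sticks (and
  the parent's sticks and parameters) are re-proposed from their full
  conditionals under the new allocation — or the exact reverse merge of a
  childless single-split child into its parent. All proposal factors,
  including the multiplicity of (site, direction) choices inducing the
  same partition, are explicit, so the acceptance ratio is exact and the
  target is unchanged. The move exists because per-observation updates
  cross between merged and separated clone configurations only through
  vanishing-probability intermediate states: a fresh candidate must
  capture observations one at a time while its stick mass is negligible,
  and once a node's subtree empties, its depth stick is driven towards
  one, strangling later births. Acceptance instrumentation of stalled
  chains showed exactly this bottleneck.

The complete-data log-likelihood (assignments marginalised against $\pi$)
is recorded per retained sample, along with the big-node count: the number
of clones with $\pi_\epsilon > 0.01$ (strictly more than 1% of the tumor
mass).

**Summaries.** The posterior similarity matrix holds pairwise co-clustering
frequencies across retained samples. The summary partition maximises the
posterior expected adjusted Rand index (PEAR) over candidate partitions
obtained by cutting an average-linkage clustering of one minus the
similarity matrix at $k = 1, \dots, \min(N, 20)$; exact maximisation over
all partitions is infeasible, and tests verify the candidate construction
recovers the exact optimum at enumerable sizes. The MAP tree groups
retained samples by their big-node number, takes the most frequent group
(ties broken towards fewer big nodes — parsimony) and reports that group's
highest-likelihood snapshot.

## The benchmark simulator

`makeFixture()` builds five ground-truth trees spanning the classic modes
of tumor evolution, with eight marker sites and deterministic genotypes
(per-edge site toggles):

* `monoclonal` — an all-zero healthy root (frequency 0.1) and one tumor
  clone (0.9) four sites away.
* `polyclonal_low` — six clones in three layers with a dominant mid-layer
  clone and minor siblings.
* `polyclonal_medium` — the same tree plus a fourth level of five small
  clones at frequencies 0.03, 0.03, 0.03, 0.02, 0.02 (existing frequencies
  rescaled); each added clone differs from its parent in exactly one site.
* `polyclonal_high` — extended to 18 clones, the additions at roughly 0.02
  and renormalised.
* `mutator` — a star: root plus twelve low-frequency leaf clones, most one
  site from the root.

The full study design samples 2,000 observations per tree and flips every
site independently with error probability 0, 0.01, 0.02 or 0.05
(`sampleObservations()`, `addFlipNoise()`). The generator emulates i.i.d.
sampling from a fixed clone mixture with independent site errors; it does
not emulate spatial structure, read-depth variation, or site-dependent
error, so passing benchmarks here demonstrates correct inference under the
model's own assumptions, not robustness to those real-data artefacts.

The single-site differences between small clones and their parents, with
highly asymmetric sizes, are what make the noise-free benchmark
deliberately imperfect for the Bayesian method: merging a small
one-site-different clone into its large parent costs little likelihood, so
the posterior concentrates on slightly coarser clusterings and the
v-measure plateaus near 0.9 instead of 1. The distance-based baselines,
having no model complexity penalty, separate these clones perfectly on
noise-free data — and collapse much faster when noise is added.

## Scaled problem sizes

The package's test-suite benchmarks run the chains at burn-in 2,000, 3,000
kept sweeps, thinning 5 (600 retained samples), with n = 200 (monoclonal)
or n = 500 (polyclonal) observations; the full study schedule (burn-in
30,000, 50,000 kept, thinning 5, n = 2,000) is the `mcmcConfig()` default.
These reduced sizes were chosen so a complete benchmark cycle runs in
minutes on a single core while preserving most qualitative results:
perfect monoclonal recovery, the polyclonal v-measure plateau, and the
Bayesian method's advantage in tree distance under noise.

One result does not survive the down-scaling, and it is worth being
explicit about why. At the full design size (n = 2,000) the
MPEAR-summarised clustering beats both distance-based baselines on
polyclonal data at 5% flip noise (we measure 0.68 against 0.52 and 0.63
with the reduced chain schedule). At n = 500, however, the low-frequency
clones carry only 10–15 observations each; the posterior's
partition-entropy cost of separating them then outweighs their likelihood
contribution, the Bayesian summary settles on genuinely coarser
clusterings (v-measure about 0.56–0.60), while the silhouette baselines overfit
to about twenty clusters — which the v-measure penalises only through
completeness — and score 0.54–0.66. The under-segmentation is the
posterior's honest answer at that sample size, not a sampler failure:
the corresponding benchmark check in the test suite is therefore expected
to fail at the reduced size, and the n = 2,000 behaviour is the one that
reflects the method's design conditions.

## Numerical and degenerate-input choices

* Sigmoid probabilities are clamped to $[10^{-15}, 1-10^{-15}]$ before
  taking logarithms.
* With the printed depth-decay convention ($\lambda = 2 > 1$) the depth
  sticks shrink geometrically with depth, so the prior places a small but
  positive mass on infinitely deep chains: roughly one lazy prior draw in
  a thousand would descend without bound. Prior-tree sampling therefore
  caps the descent (default depth 50, configurable) and assigns such
  draws at the cap; the sampler's instantiated trees are bounded by node
  and depth caps anyway.
* The un-instantiated-mass tolerance during assignment ($10^{-3}$) sits far
  below the 0.01 big-clone threshold; `expandTree()` accepts stricter
  tolerances for analyses of the prior itself.
* All-missing matrices, constant matrices ($\beta_m \in \{0,1\}$) and
  Jaccard distances between two all-zero rows (defined as 0) are handled
  explicitly; baselines refuse matrices with missing entries.
* Silhouette model selection on data whose distances are all zero returns
  a single cluster with a warning.
* Minimum spanning trees are built with `igraph`; root ties in the
  spanning-tree pipeline break towards the lexicographically smallest
  pattern, and methyltype mean-threshold ties (exactly 0.5) call the
  unmethylated state.
* In the tree distance, "markers shared by the trees" are the node-level
  marker patterns, mapped (when duplicated within one tree) to the
  highest-mass node carrying them, and path lengths are hop counts;
  branch-length-weighted paths are available behind the `weighted` flag.

## Limitations

Sites are modelled as independent, which a well-chosen molecular clock
locus approximates but correlated CpG neighbourhoods violate. The sampler
is exact but local: at heavily reduced schedules, whether a borderline
small clone is separated can vary between seeds (the swap move and
repeated assignment scans mitigate, but do not eliminate, this). Real
bisulfite or single-cell studies should use the full default schedule and
inspect the big-node-number trace and complete-data log-likelihood for
stability before interpreting the MAP tree.
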