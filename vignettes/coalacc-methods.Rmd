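---
title: "Detecting lineage-specific rate shifts under gene-tree discordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific rate shifts under gene-tree discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalacc)
```

## The problem

Comparative genomics screens ask whether a locus — typically a conserved
noncoding element — has evolved at an accelerated substitution rate on
particular branches of a species phylogeny.  Standard approaches fit a
substitution model directly on the species tree.  When effective
population sizes are large relative to internode times, however,
individual loci have genealogies ("gene trees") that differ from the
species tree through incomplete lineage sorting (ILS).  A discordant
genealogy mapped onto the species tree mimics rate variation: terminal
branches look too long, internal branches too short, and spurious
"accelerations" appear.  `coalacc` removes this artifact by treating the
gene tree of every locus as a latent variable with a multispecies
coalescent (MSC) prior, and estimating rate shifts conditional on it.

## Model

**Species tree.**  A rooted bifurcating tree $T$ with $N = 2S-1$ nodes
whose branch lengths are expected neutral substitutions per site.  Each
branch $s$ carries a population-size parameter $\theta_s = 4N_e\mu$
(dimensionless).  Extant species have $\theta = 0$ (one sampled allele);
the root inherits the mean of the internal-branch estimates.  Node
heights are computed bottom-up from the branch lengths; the MSC
embedding treats these heights as the shared time scale, so the pairwise
coalescence rate within branch $s$ is $2/\theta_s$ per unit of expected
neutral substitution.

**Conservation states.**  Each species branch is in a latent state
$Z_s \in \{0, 1, 2\}$: background (rate multiplier $r_0 = 1$), conserved
($r_1 < 1$), or accelerated ($r_2 > r_1$).  States evolve root-to-tips
as a Markov chain with transition matrix
$\Phi(\alpha, \beta)$: background gains conservation with probability
$\alpha$, conservation is lost to acceleration with probability
$\beta$, and under Dollo irreversibility the accelerated state is
absorbing.  The root state is fixed to background by default
(`chain_config(root_state = )`), matching the view of loci becoming
conserved from a neutral background; a non-Dollo option adds a
reversion probability with a uniform prior and a conjugate update.

**Gene tree and likelihood.**  The locus genealogy $G$ has one lineage
per species and receives the standard MSC density: within each ancestral
branch, exponential waiting times with rate $k(k-1)/\theta_s$ between
coalescences and a survival term for lineages that leave the branch; the
root branch absorbs all remaining lineages.  Sequences evolve along $G$
under a strand-symmetric GTR model: $\pi_A = \pi_T$, $\pi_C = \pi_G$,
leaving one free composition parameter $\pi_A$ with prior
$2\pi_A \sim \mathrm{Beta}(\gamma, \gamma)$ ($\gamma = 10$ by default,
matching the simulator).  Crucially, the *rate* applied to a gene-tree
branch segment is determined by the species branch the segment passes
through, so one gene-tree branch can evolve at several rates.  The
package implements this by cutting every gene-tree edge at each
speciation time it crosses (the "augmented" tree of
`map_gene_tree()`); Felsenstein pruning with per-segment transition
matrices then yields the likelihood with all ancestral bases summed out.

**Models and evidence.**  Three nested models restrict where
acceleration may occur: M0 (nowhere), M1 (only on branches leading
exclusively to the declared target taxa), M2 (anywhere outside the
outgroup; outgroup branches never accelerate under any model).  Loci are
classified by log Bayes factors
$\log \mathrm{BF}_1 = \log P(Y\mid M_1) - \log P(Y \mid M_0)$,
$\log \mathrm{BF}_2 = \log P(Y\mid M_1) - \log P(Y \mid M_2)$, and
$\log \mathrm{BF}_3 = \log \mathrm{BF}_1 - \log \mathrm{BF}_2$ when no
targets are given.  Branch-level calls use the posterior
$P(Z_s = 2 \mid Y) \ge 0.5$ under the selected alternative model, with
independent events counted as maximal accelerated subtrees.

## Inference

`run_chain()` is a collapsed Gibbs sampler.  Each sweep:

1. imputes ancestral bases $H$ at every coalescent node *and* every
   speciation-crossing point (exact conditional draw via pruning and a
   root-to-tips backward pass);
2. samples $Z$ by forward–backward on the species tree from per-branch
   emissions assembled from the imputed segments;
3. updates $r_1, r_2$ by multiplicative random-walk MH against their
   Gamma priors (shape–scale Gamma(5, 0.04) and Gamma(10, 0.2), means
   0.2 and 2), rejecting proposals that violate $r_1 < 1$ or
   $r_2 > r_1$;
4. updates $\pi_A$ by reflected Gaussian MH on $(0, 1/2)$, refreshing
   the rate-matrix eigendecomposition on acceptance;
5. proposes `k_spr` guided subtree-prune-regraft moves and local
   node-height moves on $G$;
6. draws $\alpha, \beta$ from their conjugate Beta conditionals.

**A note on the guided SPR move.**  The regraft position is chosen with
probability proportional to the transition probability of the moving
subtree's imputed sequence from each candidate's imputed sequence — the
proposal *uses* $H$.  A proposal that depends on $H$ cannot be paired
with an acceptance ratio in which $H$ has been marginalized out: the
imputed sequences are correlated with the current gene tree, and the
resulting marginal chain is measurably biased (we verified this
directly on the three-taxon topology law).  The package therefore
accepts gene-tree moves against the joint target of $(G, H)$ at gene
nodes, with the bases at speciation-crossing points marginalized
analytically as ordered products of segment transition matrices (their
number varies with $G$, so they are treated as per-sweep auxiliary
variables).  Gene-node identities persist across moves, making the
complete-data ratio well defined.  With this pairing the data-free
sampler reproduces the closed-form MSC topology frequencies to Monte
Carlo accuracy (see `test-sampler.R` and the acceptance suite).

Other conventions of the gene-tree moves: the candidate weight uses the
neutral rate over a representative gap equal to the height difference
between candidate and subtree root; regrafts above the remaining root
draw the new height from an exponential with the root branch's
coalescent rate (a proposal choice, corrected by Hastings ratios);
node-height windows are truncated to the legal interval — above the
children and the species MRCA of the clade, below the parent — with the
truncation correction included.  Proposal scales for $r$ and $\pi_A$
adapt toward ~0.3 acceptance during burn-in only.

**Species-tree mode.**  `method = "st"` runs the same state machinery
with the species tree itself as the (fixed) genealogy — the classical
single-tree model.  It is nested in the gene-tree mode as
$\theta \to 0$ and is used both for routing cheap loci and as the
comparison baseline.

## Marginal likelihoods

`marginal_likelihood_wl()` partitions the alignment into blocks of
`block_size` sites (default 50) and bridges from the prior to the full
posterior one block at a time.  Step $i$ runs a two-component mixture
chain — surrogate: posterior given blocks $1..i-1$; target: posterior
given blocks $1..i$ — with an adaptive log-weight $w$ tuned so both
components are occupied equally; at balance $w$ estimates
$\log P(Y_{1:i})/P(Y_{1:i-1})$, and the steps sum to $\log P(Y)$.
Numerical choices: the weight is initialized from the block
log-likelihood of a posterior-conditioned sweep (removing a long
random-walk transient; the fixed point is unchanged); the update is
Rao-Blackwellized, moving $w$ by $\delta(2p_1 - 1)$ where $p_1$ is the
conditional probability of the target component, which removes binary
occupancy noise; flatness is judged on a sliding window of `wl_check`
iterations at tolerance `wl_flat`, halving $\delta$ from `wl_step0`
until `wl_step_min`.  The reported estimate averages the late-stage
weights, and the standard error is the spread of the last few
stage-end weights (inflated when the histogram never flattened).  The
estimator was validated against a prior-sampling Monte Carlo oracle and
an independent stepping-stone implementation on small loci (see
`test-evidence.R`).

## Preprocessing and routing

`estimate_theta()` implements $\hat\theta = 2 l_1 / l_2$ from a
substitution-unit tree and a topologically identical coalescent-unit
tree, with tips set to 0 and the root set to the internal mean.
`site_cf()` computes per-locus site concordance factors: for each
internal branch, up to `n_quartets` quartets (one taxon per surrounding
subtree) are sampled with a fixed seed; a site is decisive if its four
bases are unambiguous and form a 2+2 two-state split, concordant if the
split follows the branch.  Branches with no decisive sites are
undefined and excluded from locus means; a locus with no defined branch
routes to the cheaper species-tree method.  `route_loci()` applies
either the mean-sCF rule or the fraction-below-threshold rule.

## The simulator

`simulate_locus()` is the generative counterpart of the model: a gene
tree from the MSC, a root sequence i.i.d. from the stationary
distribution with $2\pi_A \sim \mathrm{Beta}(10,10)$, segment-by-segment
CTMC evolution at the enclosing species branch's rate, and only extant
sequences emitted.  Conserved and accelerated rates are drawn from
Gamma(5, 0.04) and Gamma(10, 0.2) (means 0.2 and 2).
`build_benchmark()` assembles null loci (conserved on every lineage,
background root) plus loci accelerated in one, two, or three
monophyletic clades, 100 bp each by default, with optional
multiplicative scaling of all internal $\theta$ values.  The bundled
20-taxon `surrogate_tree()` (three outgroups, height 0.36
substitutions/site, internal $\theta = 0.02$) is a synthetic stand-in
with realistic magnitudes for examples and property tests; it is not an
empirical phylogeny.

What the simulator does *not* emulate: alignment error, indels,
introgression, selection on base composition, or rate variation among
sites.  Passing benchmarks therefore demonstrate correctness of the
inferential machinery under the model's own assumptions, not robustness
to real-data artifacts.

## Numerical choices

* Transition matrices come from the eigendecomposition of the
  symmetrized generator $\pi^{1/2} Q \pi^{-1/2}$ (real spectrum for the
  reversible model); batched construction computes all segment matrices
  in one multiply.  Entries below $-10^{-12}$ raise an error; smaller
  negatives are clipped to 0.
* Pruning rescales partial likelihoods per site only when underflow
  threatens (periodic guard), keeping log-likelihoods finite for loci of
  thousands of sites.
* $\theta = 0$ branches coalesce instantly in the simulator (the
  zero-ILS limit); the MSC density reports an error instead of
  $-\infty$ when multiple lineages meet a zero-$\theta$ branch.
* Trees with up to 30 tips use integer bitmask tip sets for the
  gene-tree-to-species-tree mapping; larger trees fall back to list
  arithmetic.
* All randomness flows from one seed per chain or per locus; reruns are
  bit-reproducible.

## Study conditions for the bundled checks

The test suite and `scripts/acceptance.R` exercise the full pipeline at
desk scale: a 9-taxon clock-like tree (7 ingroup, 2 outgroup, internal
$\theta = 0.02$), 100-bp loci, 10 conserved + 10 target-accelerated + 6
off-target-accelerated loci, Wang-Landau schedules of at most 700
mixture iterations per block, and posterior chains of a few hundred
sweeps.  These sizes were chosen as the smallest at which the
detection-quality claims (precision-recall of $\log\mathrm{BF}_1$,
target specificity of $\log\mathrm{BF}_2$, branch-level false-positive
control under M2, robustness to doubled $\theta$, and the inflation of
species-tree-mode Bayes factors) remain measurable with Monte Carlo
error well below the effect sizes; larger designs scale linearly in
loci and sweeps.

## Limitations

* One allele per extant species; no migration or introgression in the
  MSC prior.
* Three rate classes shared across branches; independent accelerations
  share one $r_2$.
* $\Theta$ is a fixed input, not estimated per locus; mis-specification
  biases rate estimates (over-estimated $\theta$ shrinks them) though
  model selection is comparatively robust.
* The Wang-Landau schedule constants trade accuracy for time and are
  deliberately config-exposed; very short schedules report inflated
  standard errors rather than failing.
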