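---
title: "Model-adequacy-driven data selection for partitioned phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-adequacy-driven data selection for partitioned phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phybpa)
library(ape)
```

## The problem

Model-based phylogenetic inference (ML and Bayesian) conditions everything
on the substitution model. Standard model *selection* — picking the best
GTR-family model per partition by AIC/BIC — guarantees only that the chosen
model is the least bad of the candidates, not that it describes the data
adequately. When a partition evolved under processes the model cannot
express (lineage-specific base composition, covarion-like on/off switching
of sites, mixtures of site classes), inference from that partition can be
biased, and no amount of model selection within the GTR+Γ family will flag
the problem.

`phybpa` implements the complementary step: per-partition *model adequacy*
testing by Bayesian posterior prediction, and the data-selection cascade
built on top of it. The intended workflow mirrors how large multi-gene
supermatrices (hundreds of taxa, ~5–6 kb over ~8 gene regions, ~40% missing
cells from incomplete sequencing) are actually processed:

1. annotate sites (gene, codon position, rDNA stem/loop, protein domain)
   and cut the supermatrix into *a priori* data blocks;
2. build nested dataset variants:
   **ALL** (third codon positions of saturation-prone genes such as COI
   removed), **G20** (sites with gaps in more than 20% of sequences also
   removed), **DT3** (partitions that fail the adequacy test also removed);
3. search for a partitioning scheme by greedy BIC merging;
4. compare the trees inferred from the variants (shared-clade percentages,
   clade presence/absence, ASDSF).

## The adequacy test

For a partition with alignment $X$ (gap columns removed), the test
statistic is the unconstrained multinomial log-likelihood of the observed
site-pattern frequencies,

$$T(X) \;=\; \sum_{p} N_p \,\ln\!\frac{N_p}{N},$$

where $N_p$ counts the columns showing pattern $p$ (the tuple of states
across taxa) and $N$ is the number of sites. $T \le 0$, with $T = 0$ iff
all columns are identical; it measures how concentrated the pattern
distribution is. Given a posterior sample
$\{(\theta^{(s)}, \tau^{(s)})\}$ of GTR+Γ parameters and trees for the
partition, the package simulates one replicate alignment of identical
dimensions per (evenly thinned) draw, computes $T^{(s)}_{\mathrm{rep}}$,
and reports the lower-tail rank p-value with add-one correction

$$p \;=\; \frac{1 + \#\{T^{(s)}_{\mathrm{rep}} \le T_{\mathrm{obs}}\}}
               {1 + S},$$

which can never be exactly 0 or 1. The decision rule is two-tailed by
default (inadequate iff $p < \alpha/2$ or $p > 1 - \alpha/2$, $\alpha =
0.05$): both an excess and a deficit of pattern duplication relative to
the fitted model are failures. A lower-tail-only rule is available
(`tail = "lower"`), since reports of this workflow describe the excluded
partitions as the low-p ones while the accompanying figure describes a 95%
two-tailed band; both conventions are exposed and the default follows the
two-tailed band.

Two posterior sources are supported: the internal sampler below, and
externally produced MrBayes-style `.p` traces via `readParamTrace()` +
`traceToPosterior()`. An external trace carries no trees, so a
user-supplied fixed tree stands in for every draw; this is documented
behaviour, chosen because the replicate dimension (same taxa, same sites)
and the parameter draws dominate the predictive distribution at this
scale.

## The sampler

`mcmcSample()` is a deliberately compact Metropolis–Hastings sampler over
GTR exchangeabilities (Dirichlet proposal on the rate simplex), base
frequencies (Dirichlet), gamma shape (multiplier), branch lengths (random
single-branch multipliers plus a whole-tree rescaling), and optionally
topology (NNI). One *generation* is a full sweep of these moves, so chains
mix in hundreds-to-thousands of generations at desk scale rather than the
millions familiar from single-move-per-generation samplers. Proposal
step sizes are auto-tuned toward ~15–45% acceptance during burn-in only
(the post-burn-in kernel is fixed, preserving detailed balance).
Metropolis coupling is available with the usual heat schedule
$1/(1 + \lambda i)$, $\lambda = 0.2$.

Two branch-length prior regimes are implemented, because they matter for
partitioned data: i.i.d. exponential (rate 10 by default), and the
compound Dirichlet — a Gamma(1, 1) prior on total tree length with a flat
Dirichlet over branch proportions — which avoids the well-known
tree-length inflation of i.i.d. exponential priors on partitioned
analyses. A directional unit test verifies that on prior-sensitive data
the compound Dirichlet posterior tree length is at least as close to the
truth. Adequacy-style runs use the default (exponential) priors; both
regimes are first-class.

The gamma shape prior is Exponential(1); four equal-probability gamma
categories are used by default, each represented by its category mean (so
the mean relative rate is exactly 1). No proportion-invariant term is
offered: combining +I with +Γ is deliberately unsupported because the two
parameters are poorly identifiable jointly, and the discrete gamma absorbs
the invariant-site signal.

## Likelihood and simulation internals

The pruning likelihood runs over compressed site patterns in C++, with the
transition matrices obtained from the eigendecomposition of the
symmetrized GTR matrix ($B = \Pi^{1/2} Q \Pi^{-1/2}$ is symmetric, so the
decomposition is numerically stable; near-zero frequencies are floored at
$10^{-8}$ and renormalized). Gaps, `?` and `N` enter as all-ones partial
likelihood vectors (IUPAC codes as the corresponding 0/1 masks), so an
all-missing column contributes exactly zero log-likelihood. Underflow is
handled by per-pattern rescaling, triggered only when a partial falls
below $10^{-80}$ and accumulated in log space — on trees of tens of taxa
this branch is essentially never taken, which keeps the hot loop
vectorizable. The simulator shares the same transition-matrix machinery
and draws from R's RNG, so every simulation is reproducible from
`set.seed()`/`seed` arguments.

Correctness is pinned by oracles in the test suite: exhaustive
enumeration over all internal-state assignments on 4-leaf trees, the JC69
closed form on pairs, the Chapman–Kolmogorov identity, stationarity and
detailed balance of the rate matrix, quadrature values for the discrete
gamma means, and a 2-taxon grid-integration posterior that the sampler
must match (KL < 0.01 on equal-probability bins).

## What the synthetic generator emulates — and what it does not

`simulateStudy()` generates study-shaped data with known truth: a Yule
topology with i.i.d. exponential branch lengths (mean 0.03
substitutions/site, giving mean pairwise distances around 0.2 — typical
intra-family divergence; the original pilot value of 0.08 made almost
every site pattern unique, a regime where the multinomial statistic is
nearly degenerate), eight gene regions (four rDNA with alternating
stem/loop tracts, four protein-coding with codon structure, two of them
with multiple domains — 32 candidate blocks, mergeable to a 28-block *a
priori* layout), per-block GTR+Γ models drawn once from realistic ranges
(transition bias, Dirichlet(20) compositions, α in 0.3–2), whole
gene-by-taxon blanking to a 40% missing-cell target (missingness from
incomplete sequencing is amplicon-shaped, not random cells; every taxon
keeps at least one gene), and gap injection confined to rDNA loop columns.

It does **not** emulate: indel evolution (gaps are injected, not evolved),
alignment error, secondary-structure-aware substitution (stem pairing),
codon-level selection, or rogue-taxon effects. Passing tests on these data
therefore validate the pipeline's logic and statistics, not robustness to
alignment artefacts.

Three violation processes are available for `simulateViolation()`:
nonstationary composition (one or more designated clades switch to
composition-shifted models, optionally with rate acceleration — in real
data composition shifts accrue along accelerated lineages),
covarion switching (an exact 8-state chain over base × on/off; slow
switching freezes whole subtrees per site), and partition mixtures (sites
drawn from two models or two trees, e.g. a frozen plus a fast component —
the classic invariant-site excess that a discrete gamma cannot absorb).

## Calibration and power: what to expect

Two properties of the posterior predictive multinomial test deserve
honest statement, both quantified by `calibrateAdequacy()` and the
acceptance script:

* **Conservatism.** When the generating parameters are known exactly (a
  point-mass "posterior"), the rank p-value is uniform — the test suite
  checks this. Under a genuine posterior, replicate statistics mix over
  the parameter posterior, which widens the predictive distribution of
  $T$ relative to its sampling distribution at the true parameters; the
  p-values concentrate toward 0.5 (observed SD ≈ 0.19–0.20 versus 0.289
  for uniform at 30 taxa × 500 sites) and the realized two-tailed
  rejection rate under the generating model falls well below the nominal
  5%. This is the documented behaviour of posterior predictive checks
  with data-only discrepancy statistics, not an implementation artefact;
  it makes the test conservative (few false exclusions), at a cost in
  power.

* **Differential power.** The statistic responds to mismatches in
  site-pattern duplication that the fitted GTR+Γ cannot absorb. Covarion
  switching and frozen/fast mixtures are detected reliably at 30 taxa ×
  750 sites with 200 replicates; pure compositional nonstationarity is
  weakly visible because fitted branch lengths and shape soak up most of
  its signal — a single-clade GC 0.3→0.7 shift is usually *not* flagged.
  The 10-partition power benchmark (`simulatePowerBenchmark()`) therefore
  carries one extreme composition violator, two covarion violators and
  three mixture violators; compositional inadequacy is better pursued
  with composition-specific statistics, listed as an extension point.

## Numerical and design choices

* Site coordinates are 1-based inclusive everywhere in R, and emitted
  1-based inclusive in all file formats (RAxML/NEXUS convention), with
  `\3` stride notation for codon blocks.
* `?` and `N` are fully missing; `-` is kept distinct because the
  gap-fraction filter ("more than 20% gaps", strict inequality, gaps only
  by default) and the pre-test gap stripping are defined on gaps.
* Gap fractions are computed over the taxon set of the dataset being
  filtered, i.e. after any taxon-completeness filtering.
* The audit table attributes every dropped site to exactly one provenance
  label (first applicable mask in order, then excluded partitions), so
  category counts plus retained length always equal the original length.
* BIC parameter counts in the scheme search: 9 free substitution
  parameters per subset (5 exchangeabilities, 3 frequencies, 1 shape)
  plus branch lengths counted once (linked lengths with per-subset
  proportional scalers). Greedy merge ties break lexicographically; the
  full merge log is returned so schemes can be replayed and manually
  refined — coarser hand-made schemes can genuinely beat the greedy
  result, which is why the log is a first-class output.
* Shared-clade percentage uses the average-of-counts denominator
  $100\,|S_a \cap S_b| / ((|S_a|+|S_b|)/2)$ because compared trees can
  differ in resolution; `min` and `reference` denominators are flags.
  Splits are canonical (smaller side, lexicographic tie-break), so all
  clade logic is unrooted and re-rooting invariant.
* ASDSF uses sample SD (n−1) over splits reaching 10% in at least one
  sample, matching the conventions of the MCMC software this diagnostic
  comes from; below 0.05 is read as acceptable convergence.
* Problem sizes in the test suite and acceptance script: calibration at
  30 taxa × 500 sites × 200 repeats × 200 replicates; power at 10
  partitions × 750 sites; recovery at 4 taxa × 2000 sites; scheme search
  at 8 taxa × 3 × 1000 sites. These are the package's validation
  conditions, chosen to be study-shaped at desk scale.

## Orchestration

`runFull()` drives the cascade from a single validated YAML config
(unknown keys rejected): data (or a simulated study), blocks, ALL → G20 →
adequacy → DT3, optional scheme search and tree comparison. One master
seed fans out to per-stage seeds through a fixed `sample.int()` counter,
every artifact is stamped with the config hash and seed, the log records
counts at each filter stage, and reruns with the same config and seed are
byte-identical. The package is a library: `runFull()` plus the exported
module functions are the command surface.

```{r, eval = FALSE}
res <- runFull(list(
  seed = 1,
  outdir = "run1",
  data = list(simulate = TRUE),
  adequacy = list(enabled = TRUE, reps = 200, ngen = 1500)))
res$datasets$DT3$audit
```

## Known limitations

* The sampler is desk-scale: fixed-topology (or NNI-only) chains on tens
  of taxa. It is not a replacement for MrBayes/ExaBayes on hundreds of
  taxa; external traces plug in where cluster-scale sampling is needed.
* Posterior predictive p-values are conservative (above); calibration
  against Uniform(0,1) fails by construction for this class of test, and
  the package reports the realized distribution rather than pretending
  otherwise.
* Compositional violations are weak targets for the multinomial
  statistic; additional discrepancy statistics (composition χ²,
  Goldman–Cox) are extension points, not implemented.
* Gaps are treated as missing data in the likelihood and stripped before
  adequacy testing; no indel model is provided.
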