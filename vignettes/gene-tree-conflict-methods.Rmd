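---
title: "Methods: dissecting gene-tree/species-tree conflict in a small species complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting gene-tree/species-tree conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phyloconflict implements a complete analysis chain for a recurring
situation in shallow phylogenomics: a handful of closely related taxa,
hundreds of gene alignments whose trees disagree, and the question of
whether that disagreement reflects incomplete lineage sorting (ILS),
introgression, or hybrid origin. The package grew around a four-taxon
ingroup (labelled `att`, `dai`, `lgk`, `mus`, with outgroup `ela` and a
fifth sampled variety `lcn` merged into `mus`), but every component is
generic.

This vignette records the models, the defaults, and the design decisions a
maintainer would want to know; it states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Topology space and likelihood kernel

Candidate topologies are enumerated exhaustively: for n free labels there
are (2n−3)!! rooted binary trees, so a four-taxon ingroup gives exactly 15
candidate hypotheses; with a fixed outgroup the enumeration runs over the
ingroup and the outgroup is attached at the root. Monophyly constraints
(for conspecific samples) are implemented by enumerating over
"super-leaves" crossed with within-group arrangements. Topology identity
is decided by a label-sorted canonical Newick string, which makes
enumeration order deterministic and ties impossible.

Per-site log-likelihoods use Felsenstein pruning over an eigendecomposed
reversible rate matrix (JC69, K80, HKY85, GTR; optional discrete-Gamma
with k = 4 mean-category rates, the field convention). IUPAC ambiguity
codes contribute partial likelihood 1 for every compatible state; gaps are
fully missing. Branch lengths are optimized coordinate-wise with bounded
Brent search on [1e−8, 10] substitutions/site, swept until the relative
log-likelihood change is below 1e−6. At 4–6 taxa the surface is unimodal
in practice, so no multistart is used. The kernel and optimizer are in
C++; the test suite checks them against an exhaustive
internal-state-summation oracle and the pulley principle (re-rooting
invariance).

Model families per gene can be compared by BIC
(`select_substitution_model()`), counting branch lengths and free model
parameters; base frequencies for HKY85/GTR are empirical. The supported
family set is a pragmatic subset of what per-gene model selection tools
offer.

## 2. Gene genealogy interrogation and the AU test

Each gene is scored against every candidate: branch lengths optimized,
per-site log-likelihoods kept, ΔL = logL(best) − logL(candidate), and the
best fit is the candidate with ΔL = 0 (ties broken deterministically by
candidate index and flagged). The approximately unbiased (AU) test is run
from a RELL multiscale bootstrap: site columns are resampled at 10 scales
r ∈ {0.5, …, 1.4} (the standard grid; the replicate count of 10,000 is
read as 10,000 total, split 1,000 per scale, with more per scale
available), bootstrap proportions BP_r are the fraction of replicates in
which the candidate attains the maximum resampled log-likelihood, and the
model Φ⁻¹(1 − BP_r) = d·√r + c/√r is fitted by weighted least squares
(weights from the delta-method binomial variance). The AU p-value is
1 − Φ(d − c). BP values are clamped to [0.5/B, 1 − 0.5/B]; if fewer than
three scales are interior the fit is degenerate and p is reported as 0 or
1 with a flag.

Summaries count, per candidate, the genes selecting it by lowest ΔL and
the genes unable to reject it at α (default 0.05, configurable — the
"unable to reject" total can legitimately exceed the gene count because a
gene may fail to reject several topologies; the summary notes this).
Both summaries are emitted because the two counting rules answer different
questions.

**Calibration regime.** The acceptance suite checks type-I calibration by
simulating 500 genes on a known generating tree and testing the true
topology's p-values. Two facts shape the design:

* if the generating tree is well resolved, the truth lies in the interior
  of the null region and the AU test is *conservative by construction* —
  rejection far below α and p-values pushed upward. That regime verifies
  nothing about calibration.
* exact uniformity of p is an asymptotic property at a *smooth* boundary.
  With 15 candidates and two free internal branches the least-favorable
  configuration (both branches zero) is a corner, where the signed
  distance/curvature approximation is known to degrade (we measure
  over-rejection there).

The calibration experiment therefore uses the hardest *identified*
configuration: ingroup internal branches carrying one expected
substitution per gene (b = 1/n_sites, with 500 sites), terminal branches
0.05 and an outgroup at 0.1 substitutions/site under JC69. The rejection
band [0.02, 0.09] is met in this regime. The Kolmogorov–Smirnov uniformity
check is additionally run on a one-dimensional half-space problem — the
smooth case the AU construction is exact for — where the implementation
passes; residual non-uniformity in the 15-topology corner geometry is a
property of the AU approximation itself, not of this implementation.

## 3. Multispecies coalescent simulator

`demographic_scenario()` declares populations with constant diploid sizes
N (pairwise coalescence rate 1/(2N) per generation — stated explicitly
because simulator parameterizations differ), backward-in-time merge
events, and pulse admixture (each recipient lineage jumps to the donor
with probability γ). The structured coalescent runs in C++ on R's RNG, so
`set.seed()` governs everything. Simulated gene trees are ultrametric in
generations; multiplying by a per-site per-generation rate μ converts to
substitution units, and sequences evolve site-independently from
stationary root states.

Microsatellites follow the strict stepwise mutation model: per locus an
independent gene tree, Poisson(μ_SSR × branch) mutations, each ±1 repeat
with probability ½. Strict SMM is the simplest model consistent with
integer repeat data; multi-step extensions are deliberately out of scope.
Closed-form checks used in the tests: two-lineage E[TMRCA] = 2N; triplet
discordance (1/3)e^(−T) for an internal branch of T coalescent units; SMM
equilibrium heterozygosity 1 − 1/√(1+2θ).

**Scenario registry.** Nine templates a–i encode four hypothesis classes
for the study system: H1 (a, b) a hybrid origin of `mus` from `att` ×
`dai` (pulse admixture at t_h followed by absorption of the remaining
lineages into `dai`, with the two plausible backbone arrangements of the
other taxa); H2 (c) the species tree (((att,lgk),mus),dai); H3 (d, e, f)
`dai` sister to `mus` in its three arrangements; H4 (g, h, i) a
(dai,lgk) clade in its three arrangements. Only the class-defining feature
is fixed; within-class variants enumerate the remaining free arrangements,
because the source material defines the classes but not every internal
arrangement. Default parameters are the study-scale point estimates:
divergence times 8,800 / 18,600 / 93,100 generations at a one-year
generation time, a shared diploid size of 10,000 (a typical herbaceous
perennial scale; the source does not state one), μ = 5e−9 per site per
generation (0.005/site/Myr, the angiosperm silent-site average), and
μ_SSR = 5e−4 per locus per generation (mid-range for plant
microsatellites).

## 4. Triplet classification: ILS vs ILS + introgression

For every 3-subset of the ingroup, each gene tree (rooted on the outgroup,
conspecific samples collapsed to the alphabetically first — a
deterministic, disclosed rule) contributes the displayed topology and the
internal branch length t between the two coalescences. Under pure ILS the
discordant-topology internal branches are approximately exponential; a
delayed second component captures introgression. We fit:

* ILS-only: t ~ Exp(λ), λ̂ = 1/mean(t), k = 1;
* ILS + introgression: t ~ π·Exp(λ) + (1−π)·(δ + Exp(λ)), shared λ,
  k = 3, fitted by EM over (π, λ) with the shift δ profiled over a
  deterministic grid of 10 quantiles of t plus a local refinement. EM
  log-likelihood monotonicity is asserted at every iteration; nesting
  guarantees the mixture never scores below the single exponential.

The decision rule is ΔBIC = BIC_mixture − BIC_single < −10; in the
significant case genes are assigned to components by posterior
responsibility, and both the mixture weight and the posterior-assignment
fraction are reported (published tables are ambiguous about which
proportion they print, so we emit both). This is an exponential /
shifted-exponential *approximation* to the published coalescent-density
mixture: acceptance is parameter recovery on its own generative model plus
the ΔBIC decision semantics, not numeric equality with the original tool.
Classification is invariant to rescaling t (λ scales inversely, δ
proportionally, ΔBIC unchanged), so substitution-unit branch lengths can
be used directly.

## 5. Rejection ABC over demographic scenarios

The summary-statistic vector (the published statistic list is not printed;
this set is an informed, configurable reconstruction): per population the
mean allele count K̄, Nei's unbiased expected heterozygosity H̄, and the
mean allele-size SD; per pair the Weir–Cockerham FST (variance components
summed over alleles and loci) and Goldstein's (δμ)²; plus the global mean
allele count. Statistics with pairwise Pearson |r| > 0.8 over the pooled
simulation table are pruned by a single deterministic greedy pass in
declaration order (the source does not say which member of a correlated
pair was dropped; greedy-in-order is reproducible).

Model choice and estimation use plain rejection: statistics standardized
by their median absolute deviation over the pooled table (robust and
conventional; zero-MAD columns pass through unscaled), Euclidean
distances, the 5,000 nearest simulations for model posteriors (share of
each model among retained) and the 2,000 nearest rows of the winning model
for parameters, log-transformed, summarized by median and 2.5/97.5
percentiles, and back-transformed. No local-linear regression adjustment
is applied — the source names retention counts but no adjustment method,
and plain rejection is the minimal defensible reading.

Priors: log-uniform divergence times and sizes on [1e2, 1e6] (three time
draws sorted; hybrid templates draw t_h below t1), γ ~ U(0,1). The
acceptance experiment is deliberately scaled down (3 templates × 20,000
simulations, panels of 12 loci × 15 diploids per population) from the
study-scale 10⁶ × 9; study-scale runs are a flag away but take hours, and
a desk-scale recovery experiment (does the generating template win? is the
true recent divergence time covered?) is what a green test can honestly
certify.

## 6. Phylogenetic signal

Blomberg's K compares the observed ratio of tip variance around the GLS
phylogenetic mean to the phylogenetically corrected variance against its
Brownian expectation on the same tree; K = 1 under Brownian motion, K > 1
for stronger-than-Brownian conservatism. The randomization test's null is
ambiguous in the source ("Brownian model as the null … randomization
test"), so both nulls are implemented: tip permutation (the default,
standard for K) and Brownian simulation on the tree; reports name the null
used. The p-value uses the add-one permutation correction, so n_perm = 0
gives p = 1. K is unstable below 10 tips and the package warns there —
a deliberate honesty about species-tree-scale (5-taxon) analyses.

## 7. Synthetic study bundles

`make_fixture()` writes a miniature, fully self-described study: gene
alignments simulated under a chosen scenario template (default c, the
species tree) for one sample per ingroup taxon plus the outgroup joining
at 1e6 generations; the true gene trees; an SSR panel; a 21-trait table
with exactly one conserved trait; and a JSON manifest with every seed,
parameter and the true ingroup topology tally. Identical seeds produce
byte-identical bundles. Defaults (100 genes × 300 sites, 8 loci × 10
diploids per population) run every stage in minutes.

One deliberate departure from strict realism: at the angiosperm
silent-site clock (5e−9/site/generation) and the system's shallow
divergence times, a 300-site gene is almost invariant and every
topological test ties. The fixture therefore evolves its sequences at
`seq_mu = 2e-7` by default — an inflation of roughly 40× that keeps the
coalescent process (and hence the ILS structure) untouched while putting
desk-scale genes in the informative regime. The manifest records the rate
used; pass `seq_mu = 5e-9` for clock-realistic alignments.

The conserved trait is Brownian motion simulated on a copy of the species
tree whose terminal branches are shrunk to 10% (plus 5% tip noise).
Straight Brownian motion has E[K] ≈ 1 and produces K > 1 only about half
the time; concentrating variance on internal branches is what actually
generates the K > 1, low-p signature of a phylogenetically conservative
trait that the fixture is meant to emulate. The remaining traits are
tip-shuffled Brownian draws (no signal). What a green trait test
establishes is power/size on this generative model — not that any real
trait is conserved.

What the generator does *not* emulate: sequencing error, alignment error,
orthology mistakes, within-locus recombination, continuous migration, and
rate variation among lineages. Green pipeline tests certify the analysis
chain, not robustness to those violations.

## Known limitations

* The AU p-value inherits the corner-geometry inaccuracy of the
  signed-distance/curvature approximation when several candidate
  topologies are simultaneously near-tied (see §2).
* The triplet mixture is an approximation sharing one rate across
  components; heavily unbalanced coalescent rates across triplets are
  better served by the original coalescent-density formulation.
* Rejection ABC with ~10 retained statistics and wide log-uniform priors
  yields honest but wide credible intervals; point medians shrink toward
  prior mass at desk scale, and the most recent divergence time is the
  weakest-identified parameter — its nominal 95% interval can slightly
  under-cover (the acceptance suite measures exactly this).
* Constant population sizes; no migration; strict ±1 SMM.
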