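# phyloconflict

Tools for dissecting gene-tree/species-tree conflict in small, recently
diverged species complexes — the situation where hundreds of gene trees
disagree and the question is *why*: incomplete lineage sorting (ILS),
introgression, or hybrid origin.

The package implements, end to end:

* **Constrained topology enumeration** — all (2n−3)!! rooted binary
  candidate topologies (15 for a four-taxon ingroup), with monophyly
  constraints for conspecific samples and a fixed outgroup.
* **A phylogenetic likelihood kernel** — Felsenstein pruning with per-site
  log-likelihoods under JC69/K80/HKY85/GTR (+Γ), branch-length
  optimization by bounded Brent search (C++ core).
* **Gene genealogy interrogation (GGI)** — each gene scored against every
  candidate topology; best fit by lowest ΔL; the approximately unbiased
  (AU) topology test from a RELL multiscale bootstrap,
  `p_AU = 1 − Φ(d − c)` from the fit `Φ⁻¹(1 − BP_r) = d√r + c/√r`.
* **A multispecies-coalescent simulator** — structured coalescent with
  population merges and pulse admixture; gene trees, sequence alignments,
  and stepwise-mutation-model (SMM) microsatellite panels; nine shipped
  demographic scenario templates (`a`–`i`) in four hypothesis classes
  (hybrid origin / species tree / dai–mus resemblance / dai–lgk
  monophyly).
* **Triplet classification of discordance** — internal branch lengths per
  (triplet, topology) category modelled as Exp(λ) (ILS only) versus
  π·Exp(λ) + (1−π)·(δ + Exp(λ)) (ILS + a delayed component), decided by
  ΔBIC < −10.
* **Rejection ABC** — microsatellite summary statistics (allele counts,
  Nei's unbiased H, allele-size SD, Weir–Cockerham FST, (δμ)²),
  |r| > 0.8 correlation pruning, model choice from the 5,000 nearest
  simulations and log-scale parameter estimation from the 2,000 nearest.
* **Blomberg's K** — phylogenetic-signal statistic with permutation and
  Brownian-simulation randomization tests.
* **Synthetic study bundles** — `make_fixture()` writes a complete
  miniature data set (alignments, true gene trees, SSR panel, trait
  table, manifest) with known ground truth, byte-reproducible from a
  seed.

## Worked example

Generate a 30-gene bundle under the species-tree scenario (template `c`,
divergence times 8,800 / 18,600 / 93,100 generations, N = 10,000), then
interrogate every gene against all 15 candidate topologies:

```r
library(phyloconflict)
fx <- make_fixture(file.path(tempdir(), "demo"), template = "c",
                   n_genes = 30, n_sites = 300, seed = 7)
cands <- enumerate_topologies(c("att", "dai", "lgk", "mus", "ela"),
                              outgroup = "ela")
model <- substitution_model("HKY85", base_freq = c(0.3, 0.2, 0.2, 0.3),
                            kappa = 2)
recs <- run_ggi(fx$alignments, cands, model, n_boot = 1000, seed = 1)
summarize_ggi(recs, alpha = 0.05,
              topology_names = vapply(cands, canonical_topology, ""))
#> GGI summary over 30 genes (alpha = 0.05 )
#>                      topology n_best n_not_rejected
#>  ((((att,dai),lgk),mus),ela);      2             13
#>  ...
#>  ((((att,lgk),mus),dai),ela);     16             29
#>  ...
#>  ((((lgk,mus),att),dai),ela);      8             22
#>  ...
#> note: sum of not-rejected gene counts (209) exceeds the gene count (30):
#> genes can fail to reject several topologies
```

The generating topology `(((att,lgk),mus),dai)` collects the most best
fits (16/30) and the most failures-to-reject (29/30); because the taxa are
so recently diverged, most genes cannot reject many topologies — the
not-rejected column legitimately sums past the gene count, exactly the
counting semantics used for this kind of study. The remaining best fits
land on ILS-typical neighbours such as `((lgk,mus),att)`.

Classify triplet discordance on the true gene trees:

```r
obs <- extract_triplet_observations(fx$gene_trees,
                                    c("att", "dai", "lgk", "mus"), "ela")
classify_triplets(obs, min_n = 10)[, c("topology", "prop_ils",
                                       "delta_bic", "n_genes", "n_intro")]
#>          topology prop_ils delta_bic n_genes n_intro
#> 1 ((att,lgk),dai)   0.0747     -47.2      30      28
#> 2 ((att,lgk),mus)   1.0000      -5.5      18       0
#> 3 ((att,mus),dai)   0.2465     -33.6      30      23
#> 4 ((lgk,mus),dai)   0.1403     -47.8      30      26
```

Read this the way the method intends: for *concordant* categories (rows
matching the species tree, e.g. `((att,lgk),dai)`) the delayed component
absorbs the speciation offset, so a strongly negative ΔBIC there means
"lineage-sorted, not pure ILS" — not introgression. The *discordant*
category `((att,lgk),mus)` (n = 18) stays ILS-only (ΔBIC −5.5 ≥ −10,
Prop_ILS = 1), the correct call for data simulated without gene flow.

Phylogenetic signal, on a tree large enough for Blomberg's K to be stable
(the package warns below 10 tips):

```r
tr16 <- ape::stree(16, "balanced")
tr16$edge.length <- rep(1, nrow(tr16$edge))
tt <- make_trait_table(tr16, n_traits = 3, conserved_index = 1, seed = 5)
phylo_signal_table(tr16, tt, n_perm = 1000, seed = 6)
#>     trait     K     p
#> 1 trait01 1.630 0.002
#> 2 trait02 0.373 0.891
#> 3 trait03 0.412 0.752
```

The planted conserved trait shows K > 1 with a small permutation p; the
signal-free traits do not.

## Documentation

The methods vignette
(`vignettes/gene-tree-conflict-methods.Rmd`) documents the models, every
tunable default with units and rationale, what the synthetic-data
generator does and does not emulate, and known limitations (notably the
corner-geometry behaviour of AU p-values when many candidates are
near-tied).
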