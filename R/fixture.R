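#' Simulate a trait table with one phylogenetically conserved trait
#'
#' Emulates a morphological trait panel in which exactly one trait tracks
#' the phylogeny (like a conserved diagnostic trait) while the rest carry
#' no signal. The conserved trait is Brownian motion simulated on a copy
#' of the tree whose terminal branches are shrunk by `tip_scale`
#' (concentrating variance on the internal branches produces
#' stronger-than-Brownian conservatism, K > 1), plus a small independent
#' tip noise. The remaining traits are Brownian draws on the original
#' tree whose values are then shuffled across tips, which destroys the
#' signal (K at or below 1).
#'
#' @param tree Rooted ultrametric `phylo`.
#' @param n_traits Number of traits (>= 1).
#' @param conserved_index Which trait column is the conserved one.
#' @param tip_scale Terminal-branch multiplier for the conserved trait's
#'   generating tree (default 0.1).
#' @param noise_frac Tip-noise standard deviation as a fraction of the
#'   conserved trait's standard deviation (default 0.05).
#' @param seed Optional integer seed.
#' @return Data frame (tips x traits), row names = tip labels, with
#'   attribute `conserved` naming the conserved column.
#' @export
make_trait_table <- function(tree, n_traits = 21L, conserved_index = 1L,
                             tip_scale = 0.1, noise_frac = 0.05,
                             seed = NULL) {
  stopifnot(n_traits >= 1L, conserved_index >= 1L,
            conserved_index <= n_traits)
  set_seed_if(seed)
  n <- length(tree$tip.label)
  bm_draw <- function(tr) {
    C <- suppressWarnings(brownian_vcv(tr))
    L <- t(chol(C + diag(1e-12 * max(diag(C)), n)))
    as.numeric(L %*% stats::rnorm(n))
  }
  shrunk <- tree
  term <- shrunk$edge[, 2] <= n
  shrunk$edge.length[term] <- shrunk$edge.length[term] * tip_scale
  out <- matrix(NA_real_, n, n_traits,
                dimnames = list(tree$tip.label,
                                sprintf("trait%02d", seq_len(n_traits))))
  for (j in seq_len(n_traits)) {
    if (j == conserved_index) {
      x <- bm_draw(shrunk)
      x <- x + stats::rnorm(n, sd = noise_frac * stats::sd(x))
    } else {
      x <- sample(bm_draw(tree))
    }
    out[, j] <- x
  }
  out <- as.data.frame(out)
  attr(out, "conserved") <- colnames(out)[conserved_index]
  out
}

#' Default 5-taxon species tree of the study system
#'
#' Ultrametric tree over att, dai, lgk, mus, lcn with node heights (in
#' generations) taken from the default template-c divergence times and a
#' recent mus/lcn split.
#'
#' @param t1,t2,t3 Divergence times in generations (att-lgk, +mus, +dai).
#' @param t_lcn mus-lcn split time.
#' @return A `phylo`.
#' @export
study_species_tree <- function(t1 = 8800, t2 = 18600, t3 = 93100,
                               t_lcn = 4000) {
  read_newick(sprintf(
    "(((att:%g,lgk:%g):%g,(mus:%g,lcn:%g):%g):%g,dai:%g);",
    t1, t1, t2 - t1, t_lcn, t_lcn, t2 - t_lcn, t3 - t2, t3))
}

#' Generate a complete miniature study bundle
#'
#' Writes a self-contained synthetic data set with known ground truth so
#' every pipeline stage runs without downloads: per-gene FASTA
#' alignments simulated under a demographic scenario (4 ingroup taxa +
#' outgroup `ela`), the true gene trees (substitution units, one Newick
#' per line), an SSR genotype panel, a trait table with one conserved
#' trait, and a JSON manifest holding every seed and parameter plus the
#' true ingroup gene-tree topology tally.
#'
#' @param dir Output directory (created; must not already contain a
#'   manifest unless `overwrite`).
#' @param template Scenario template (`"a"`..`"i"`).
#' @param n_genes,n_sites Alignment count and length.
#' @param ssr_loci,ssr_diploids SSR panel shape (loci; diploids per
#'   population).
#' @param n_traits,conserved_index Trait table shape.
#' @param params Optional scenario parameter overrides (see
#'   [get_scenario()]).
#' @param seq_mu Per-site per-generation substitution rate used for the
#'   bundled sequences. The default (2e-7) is deliberately ~40x the
#'   angiosperm silent-site clock so that 300-site desk-scale genes carry
#'   usable signal at the study's shallow divergence times; pass 5e-9 for
#'   strictly clock-realistic (mostly invariant) alignments.
#' @param outgroup_time Outgroup (`ela`) join time in generations.
#' @param seed Integer seed; the bundle is a deterministic function of it.
#' @param overwrite Allow writing into an existing bundle directory.
#' @return Invisibly, a list with the in-memory objects (`scenario`,
#'   `gene_trees`, `alignments`, `ssr`, `traits`, `manifest`).
#' @export
make_fixture <- function(dir, template = "c", n_genes = 100L,
                         n_sites = 300L, ssr_loci = 8L, ssr_diploids = 10L,
                         n_traits = 21L, conserved_index = 1L,
                         params = list(), seq_mu = 2e-7,
                         outgroup_time = 1e6, seed = 1L,
                         overwrite = FALSE) {
  stopifnot(n_genes >= 1L)
  if (file.exists(file.path(dir, "manifest.json")) && !overwrite)
    stop("bundle already exists at ", dir, " (use overwrite = TRUE)")
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  scenario <- get_scenario(template, params = params,
                           outgroup_time = outgroup_time)
  set.seed(as.integer(seed))
  samples <- stats::setNames(rep(1L, 5),
                             c("att", "dai", "lgk", "mus", "ela"))
  gene_trees <- simulate_gene_trees(scenario, samples, n = n_genes)
  gene_trees <- lapply(gene_trees, in_substitution_units, mu = seq_mu)
  names(gene_trees) <- sprintf("gene%04d", seq_len(n_genes))
  model <- substitution_model("HKY85", base_freq = c(0.3, 0.2, 0.2, 0.3),
                              kappa = 2)
  alignments <- lapply(gene_trees, simulate_alignment, model = model,
                       n_sites = n_sites)
  for (g in names(alignments))
    write_alignment(alignments[[g]],
                    file.path(dir, "alignments", paste0(g, ".fasta")))
  write_trees(gene_trees, file.path(dir, "genetrees.nwk"))
  tally <- table(vapply(gene_trees, function(tr)
    canonical_topology(ape::drop.tip(tr, "ela")), character(1)))
  ssr <- simulate_ssr(scenario,
                      stats::setNames(rep(ssr_diploids, 4),
                                      c("att", "dai", "lgk", "mus")),
                      n_loci = ssr_loci)
  utils::write.table(ssr, file.path(dir, "ssr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp_tree <- study_species_tree()
  traits <- make_trait_table(sp_tree, n_traits = n_traits,
                             conserved_index = conserved_index)
  utils::write.table(cbind(tip = rownames(traits), traits),
                     file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    template = template, seed = as.integer(seed), n_genes = n_genes,
    n_sites = n_sites, ssr_loci = ssr_loci, ssr_diploids = ssr_diploids,
    n_traits = n_traits, conserved_trait = attr(traits, "conserved"),
    outgroup_time = outgroup_time,
    scenario_params = attr(scenario, "params"),
    mu = scenario$mu, seq_mu = seq_mu, mu_ssr = scenario$mu_ssr,
    substitution_model = list(family = model$family,
                              base_freq = model$base_freq, kappa = 2),
    true_topology_tally = as.list(tally))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scenario = scenario, gene_trees = gene_trees,
                 alignments = alignments, ssr = ssr, traits = traits,
                 species_tree = sp_tree, manifest = manifest))
}
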