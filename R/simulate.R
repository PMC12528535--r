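set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# (parent, time) arrays from the coalescent engine -> ape phylo.
# Engine numbering: tips 1..n in sampling order, internal nodes n+1..2n-1
# in coalescence order (root last). ape wants the root at n+1.
parent_time_to_phylo <- function(parent, time, labels) {
  nn <- length(parent)
  n <- (nn + 1L) / 2L
  newid <- integer(nn)
  newid[seq_len(n)] <- seq_len(n)
  internal <- (n + 1L):nn
  newid[nn] <- n + 1L                        # root (created last)
  if (nn > n + 1L) newid[internal[-length(internal)]] <- (n + 2L):nn
  child <- which(parent > 0L)
  edge <- cbind(newid[parent[child]], newid[child])
  len <- time[parent[child]] - time[child]
  tr <- structure(list(edge = edge, edge.length = len, tip.label = labels,
                       Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate gene trees under a demographic scenario
#'
#' Structured coalescent: within a population of diploid size N each pair
#' of lineages coalesces at rate 1/(2N) per generation; at a merge event
#' all lineages of the absorbed population move to the ancestor; at an
#' admixture pulse each lineage of the recipient jumps to the donor with
#' probability gamma. Trees are ultrametric with branch lengths in
#' generations; node times in coalescent units of the reference size
#' (2 x the size of the final ancestral population) are attached as
#' attribute `depth_coal_units` (tree depth).
#'
#' @param scenario A [demographic_scenario()].
#' @param samples Named integer vector: haploid lineages sampled per
#'   population (missing populations mean 0).
#' @param n Number of independent gene trees.
#' @param seed Optional integer seed.
#' @return A list of `phylo` trees (length `n`). Tip labels are
#'   `<pop>_<i>`, or just `<pop>` for single-lineage populations.
#' @examples
#' sc <- get_scenario("c")
#' trees <- simulate_gene_trees(sc, c(att = 1, dai = 1, lgk = 1, mus = 1),
#'                              n = 3, seed = 1)
#' @export
simulate_gene_trees <- function(scenario, samples, n = 1, seed = NULL) {
  stopifnot(inherits(scenario, "demographic_scenario"))
  set_seed_if(seed)
  counts <- integer(length(scenario$populations))
  names(counts) <- scenario$populations
  if (is.null(names(samples))) stop("samples must be a named vector")
  bad <- setdiff(names(samples), scenario$populations)
  if (length(bad)) stop("samples name unknown population(s): ",
                        paste(bad, collapse = ", "))
  counts[names(samples)] <- as.integer(samples)
  if (any(counts < 0) || sum(counts) < 2)
    stop("need at least two sampled lineages in total")
  labels <- unlist(lapply(scenario$populations, function(p) {
    k <- counts[[p]]
    if (k == 0) character(0) else if (k == 1) p else paste0(p, "_", seq_len(k))
  }))
  ev <- scenario_event_matrix(scenario)
  ref_2N <- 2 * scenario$sizes[[length(scenario$sizes)]]
  lapply(seq_len(n), function(i) {
    sim <- cpp_coalescent_tree(counts, unname(scenario$sizes), ev)
    tr <- parent_time_to_phylo(sim$parent, sim$time, labels)
    attr(tr, "depth_coal_units") <- max(sim$time) / ref_2N
    attr(tr, "time_units") <- "generations"
    tr
  })
}

#' Convert a gene tree from generations to substitution units
#'
#' @param tree `phylo` with branch lengths in generations.
#' @param mu Per-site per-generation substitution rate (>= 0).
#' @return The tree with every branch multiplied by `mu`.
#' @export
in_substitution_units <- function(tree, mu) {
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0)
    stop("mu must be a single non-negative number")
  tree$edge.length <- tree$edge.length * mu
  attr(tree, "time_units") <- "substitutions/site"
  tree
}

#' Simulate a nucleotide alignment on a gene tree
#'
#' Root states are drawn from the model's stationary frequencies and
#' evolved independently per site along each branch using the model's
#' transition probabilities.
#'
#' @param tree Rooted `phylo` with branch lengths in expected
#'   substitutions per site.
#' @param model A [substitution_model()]. Gamma rate heterogeneity, if
#'   present, draws one relative rate per site from the discrete
#'   categories.
#' @param n_sites Number of sites (positive integer).
#' @param seed Optional integer seed.
#' @return Character matrix (tips x sites) with tip labels as row names.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(n_sites >= 1)
  set_seed_if(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  states <- matrix(0L, nn, n_sites)
  site_rate <- if (length(model$cat_rates) > 1)
    sample(model$cat_rates, n_sites, replace = TRUE) else rep(1, n_sites)
  root <- n + 1L
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE,
                               prob = model$base_freq)
  rate_groups <- split(seq_len(n_sites), site_rate)
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    for (g in names(rate_groups)) {
      idx <- rate_groups[[g]]
      P <- transition_matrix(model, tree$edge.length[e] * as.numeric(g))
      cum <- t(apply(P, 1, cumsum))
      u <- stats::runif(length(idx))
      from <- states[pa, idx]
      states[ch, idx] <- 1L + rowSums(u > cum[from, , drop = FALSE])
    }
  }
  aln <- matrix(NUC[states[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(aln) <- tree$tip.label
  aln
}

#' Simulate a microsatellite genotype panel
#'
#' Per locus an independent gene tree is drawn under the scenario for
#' 2 x (diploid individuals) lineages, mutations are placed as
#' Poisson(mu_ssr x branch length) events, and each mutation shifts the
#' repeat score by +1 or -1 with equal probability (strict stepwise
#' mutation model). Consecutive lineage pairs form individuals.
#'
#' @param scenario A [demographic_scenario()] (uses its `mu_ssr` unless
#'   overridden).
#' @param diploids Named integer vector: diploid individuals per
#'   population.
#' @param n_loci Number of independent loci (>= 1).
#' @param mu_ssr Optional override of the scenario's SSR mutation rate.
#' @param root_size Repeat score of the root allele (default 100).
#' @param seed Optional integer seed.
#' @return Data frame: `individual`, `population`, then two integer
#'   columns per locus (`L<k>.a1`, `L<k>.a2`).
#' @export
simulate_ssr <- function(scenario, diploids, n_loci, mu_ssr = NULL,
                         root_size = 100L, seed = NULL) {
  stopifnot(inherits(scenario, "demographic_scenario"), n_loci >= 1)
  set_seed_if(seed)
  if (is.null(mu_ssr)) mu_ssr <- scenario$mu_ssr
  counts <- integer(length(scenario$populations))
  names(counts) <- scenario$populations
  counts[names(diploids)] <- as.integer(diploids)
  al <- cpp_ssr_panel(2L * counts, unname(scenario$sizes),
                      scenario_event_matrix(scenario), as.integer(n_loci),
                      mu_ssr) + root_size
  ssr_matrix_to_table(al, rep(scenario$populations, counts))
}

# allele matrix (2 x n_ind rows, consecutive pairs = individuals) -> table
ssr_matrix_to_table <- function(alleles, pop_per_individual) {
  n_ind <- nrow(alleles) / 2
  a1 <- alleles[2 * seq_len(n_ind) - 1, , drop = FALSE]
  a2 <- alleles[2 * seq_len(n_ind), , drop = FALSE]
  out <- data.frame(individual = paste0(pop_per_individual, "_",
                                        stats::ave(seq_len(n_ind),
                                                   pop_per_individual,
                                                   FUN = seq_along)),
                    population = pop_per_individual,
                    stringsAsFactors = FALSE)
  for (l in seq_len(ncol(alleles))) {
    out[[paste0("L", l, ".a1")]] <- a1[, l]
    out[[paste0("L", l, ".a2")]] <- a2[, l]
  }
  out
}

# inverse helper used by the summary-statistic code
ssr_table_to_matrix <- function(ssr) {
  locus_cols <- grep("^L\\d+\\.a[12]$", names(ssr), value = TRUE)
  loci <- unique(sub("\\.a[12]$", "", locus_cols))
  n_ind <- nrow(ssr)
  al <- matrix(0L, 2 * n_ind, length(loci))
  for (k in seq_along(loci)) {
    al[2 * seq_len(n_ind) - 1, k] <- ssr[[paste0(loci[k], ".a1")]]
    al[2 * seq_len(n_ind), k] <- ssr[[paste0(loci[k], ".a2")]]
  }
  list(alleles = al, pop = rep(ssr$population, each = 2))
}
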