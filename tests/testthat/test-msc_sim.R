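test_that("scenario validation catches malformed inputs", {
  expect_error(demographic_scenario("A", c(A = -5), empty_events()),
               "positive")
  expect_error(demographic_scenario(c("A", "B"), c(A = 10, B = 10),
    data.frame(time = -1, type = "merge", from = "B", to = "A")),
    "strictly positive")
  expect_error(demographic_scenario(c("A", "B"), c(A = 10, B = 10),
    data.frame(time = 1, type = "admixture", from = "B", to = "A",
               gamma = 1.5)), "gamma")
  # stranded population: no merge for C
  expect_error(demographic_scenario(c("A", "B", "C"),
    c(A = 10, B = 10, C = 10),
    data.frame(time = 5, type = "merge", from = "B", to = "A")),
    "unabsorbed")
  # event referencing an absorbed population
  expect_error(demographic_scenario(c("A", "B", "C"),
    c(A = 10, B = 10, C = 10),
    data.frame(time = c(5, 9), type = "merge", from = c("B", "C"),
               to = c("A", "B"))), "absorbed")
})

test_that("scenario registry exposes nine templates in four classes", {
  reg <- scenario_registry()
  expect_equal(nrow(reg), 9L)
  expect_equal(reg$template, letters[1:9])
  expect_equal(as.vector(table(reg$class)[c("H1", "H2", "H3", "H4")]),
               c(2L, 1L, 3L, 3L))
  expect_error(get_scenario("z"), "available")
  for (tmpl in letters[1:9]) {
    sc <- get_scenario(tmpl)
    expect_s3_class(sc, "demographic_scenario")
    expect_setequal(sc$populations, c("att", "dai", "lgk", "mus"))
  }
})

test_that("gene trees are ultrametric with the expected TMRCA scale", {
  sc <- one_pop_scenario(N = 1000)
  trees <- simulate_gene_trees(sc, c(A = 4), n = 400, seed = 21)
  for (tr in trees[1:20]) {
    depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    expect_lt(diff(range(depths)), 1e-9)
  }
  # 2-lineage mean TMRCA ~ 2N (Exp rate 1/(2N))
  trees2 <- simulate_gene_trees(sc, c(A = 2), n = 3000, seed = 22)
  tm <- vapply(trees2, function(t) max(ape::node.depth.edgelength(t)), 0)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("triplet discordance tracks (1/3)exp(-T) and shrinks with T", {
  N <- 5000
  frac_minor <- function(T_cu, n) {
    sc <- demographic_scenario(c("A", "B", "C"), c(A = N, B = N, C = N),
      data.frame(time = c(500, 500 + 2 * N * T_cu), type = "merge",
                 from = c("B", "C"), to = c("A", "A")))
    trees <- simulate_gene_trees(sc, c(A = 1, B = 1, C = 1), n = n,
                                 seed = round(100 * T_cu))
    tops <- vapply(trees, canonical_topology, character(1))
    mean(tops != "((A,B),C);")
  }
  n <- 3000
  f1 <- frac_minor(1, n)
  expected <- 2 / 3 * exp(-1)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(f1 - expected), 3 * se)
  expect_gt(frac_minor(0.2, 1500), frac_minor(2, 1500))  # monotonicity
})

test_that("admixture with gamma = 1 reroutes all recipient lineages", {
  N <- 2000
  # B is a total hybrid from C at t=100; B then "merges" into A much later,
  # but carries no lineages by then: topology must match B-sister-to-C
  sc <- demographic_scenario(c("A", "B", "C"), c(A = N, B = N, C = N),
    data.frame(time = c(100, 30000, 60000),
               type = c("admixture", "merge", "merge"),
               from = c("B", "B", "C"), to = c("C", "A", "A"),
               gamma = c(1, NA, NA)))
  trees <- simulate_gene_trees(sc, c(A = 1, B = 1, C = 1), n = 400,
                               seed = 23)
  tops <- table(vapply(trees, canonical_topology, character(1)))
  # (B,C) cherry must dominate heavily (B coalesces within C's deep branch)
  expect_gt(tops[["((B,C),A);"]] / 400, 0.9)
})

test_that("unit conversion scales linearly and validates mu", {
  sc <- one_pop_scenario()
  tr <- simulate_gene_trees(sc, c(A = 4), n = 1, seed = 24)[[1]]
  expect_error(in_substitution_units(tr, -1), "non-negative")
  z <- in_substitution_units(tr, 0)
  expect_true(all(z$edge.length == 0))
  expect_equal(in_substitution_units(tr, 1e-8)$edge.length,
               tr$edge.length * 1e-8)
  for (mu in c(1e-9, 3e-8, 2e-7))
    expect_equal(sum(in_substitution_units(tr, mu)$edge.length),
                 mu * sum(tr$edge.length), tolerance = 1e-12)
})

test_that("sequence simulation honors the model", {
  m <- jc_model()
  tr0 <- read_newick("((a:0,b:0):0,c:0);")
  aln0 <- simulate_alignment(tr0, m, 50, seed = 25)
  expect_true(all(aln0["a", ] == aln0["b", ]))
  expect_true(all(aln0["a", ] == aln0["c", ]))
  # JC expected mismatch fraction at t = 0.3
  t <- 0.3
  tr <- read_newick(sprintf("(a:%g,b:%g);", t / 2, t / 2))
  aln <- simulate_alignment(tr, m, 10000, seed = 26)
  p_exp <- 0.75 * (1 - exp(-4 * t / 3))
  p_obs <- mean(aln["a", ] != aln["b", ])
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
  # stationary base composition
  mh <- substitution_model("HKY85", base_freq = c(0.4, 0.1, 0.2, 0.3),
                           kappa = 4)
  alnh <- simulate_alignment(read_newick("(a:1.5,b:1.5);"), mh, 20000,
                             seed = 27)
  freq <- table(factor(alnh, levels = c("A", "C", "G", "T"))) / length(alnh)
  for (i in 1:4)
    expect_lt(abs(freq[i] - mh$base_freq[i]),
              3 * sqrt(mh$base_freq[i] * (1 - mh$base_freq[i]) / 40000) + 0.01)
})

test_that("SSR simulation: monomorphic at mu 0, SMM heterozygosity, FST limits", {
  sc0 <- one_pop_scenario(N = 500, mu_ssr = 0)
  ssr0 <- simulate_ssr(sc0, c(A = 10), n_loci = 5, seed = 28)
  al0 <- phyloconflict:::ssr_table_to_matrix(ssr0)$alleles
  expect_true(all(apply(al0, 2, function(x) length(unique(x))) == 1))
  # theta = 2: E[H] = 1 - 1/sqrt(5)
  theta <- 2; N <- 1000
  scH <- one_pop_scenario(N = N, mu_ssr = theta / (4 * N))
  ssrH <- simulate_ssr(scH, c(A = 20), n_loci = 200, seed = 29)
  mH <- phyloconflict:::ssr_table_to_matrix(ssrH)
  h <- vapply(seq_len(200), function(l) {
    f <- table(mH$alleles[, l]) / 40
    40 / 39 * (1 - sum(f^2))
  }, 0)
  target <- 1 - 1 / sqrt(1 + 2 * theta)
  expect_lt(abs(mean(h) - target), 3 * stats::sd(h) / sqrt(200))
  # two populations: tau = 0 split -> FST ~ 0; deep split -> large FST
  mk2 <- function(tau) demographic_scenario(c("A", "B"),
    c(A = 1000, B = 1000),
    data.frame(time = tau, type = "merge", from = "B", to = "A"),
    mu_ssr = 5e-4)
  s_near <- ssr_sumstats(simulate_ssr(mk2(1e-9), c(A = 15, B = 15),
                                      n_loci = 40, seed = 30))
  s_far <- ssr_sumstats(simulate_ssr(mk2(2e5), c(A = 15, B = 15),
                                     n_loci = 40, seed = 31))
  expect_lt(abs(s_near[["fst_A_B"]]), 0.05)
  # size homoplasy under the SMM caps identity-based FST well below 1
  expect_gt(s_far[["fst_A_B"]], 0.25)
  expect_gt(s_far[["fst_A_B"]], s_near[["fst_A_B"]] + 0.2)
})
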