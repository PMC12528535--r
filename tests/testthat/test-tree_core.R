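test_that("Newick parsing validates structure and reports offsets", {
  tr <- read_newick("(A:1,B:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))

  cat4 <- read_newick("(((att,lgk),mus),dai);")
  expect_equal(length(cat4$tip.label), 4L)
  expect_equal(canonical_topology(cat4), "(((att,lgk),mus),dai);")

  expect_error(read_newick("((A,B);"), "unclosed")
  expect_error(read_newick("(A,B))C;"), "offset 6")
  expect_error(read_newick("(A,B)"), "missing terminal")
  expect_error(read_newick("(A,A);"), "duplicate leaf")
  expect_error(read_newick("(A:-1,B:1);"), "negative branch")
  # polytomies parse but are flagged
  expect_false(attr(read_newick("(A,B,C);"), "binary"))
})

test_that("Newick round-trip preserves topology and lengths", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:16, 1)
    s <- random_newick(n)
    tr <- read_newick(s)
    tr2 <- read_newick(write_newick(tr))
    expect_identical(canonical_topology(tr), canonical_topology(tr2))
    d1 <- ape::cophenetic.phylo(tr)
    expect_equal(d1, ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)],
                 tolerance = 1e-12)
  }
})

test_that("topology enumeration matches (2n-3)!! and the insertion oracle", {
  for (n in 2:6) {
    tops <- enumerate_topologies(paste0("x", 1:n))
    expect_equal(length(tops), count_rooted_insertion(n))
    canon <- vapply(tops, canonical_topology, character(1))
    expect_false(anyDuplicated(canon) > 0)
    expect_identical(canon, sort(canon))  # deterministic canonical order
  }
})

test_that("enumeration honors constraints", {
  # monophyly group of size g: (2(n-g+1)-3)!! x (2g-3)!!
  n <- 6; g <- 3
  tops <- enumerate_topologies(paste0("x", 1:n),
                               groups = list(paste0("x", 1:g)))
  expect_equal(length(tops),
               count_rooted_insertion(n - g + 1) * count_rooted_insertion(g))
  for (tr in tops[c(1, length(tops))]) {
    mrca <- ape::getMRCA(tr, paste0("x", 1:g))
    clade <- ape::extract.clade(tr, mrca)
    expect_setequal(clade$tip.label, paste0("x", 1:g))
  }
  # fixed outgroup: enumeration over the ingroup, outgroup at the root
  tops <- enumerate_topologies(c("att", "dai", "lgk", "mus", "ela"),
                               outgroup = "ela")
  expect_equal(length(tops), 15L)
  for (tr in tops) {
    root_children <- tr$edge[tr$edge[, 1] == length(tr$tip.label) + 1L, 2]
    expect_true(match("ela", tr$tip.label) %in% root_children)
  }
  expect_error(enumerate_topologies(letters[1:5],
                                    groups = list(c("a", "b"), c("b", "c"))),
               "overlap")
})

test_that("site log-likelihoods match closed forms for two taxa", {
  m <- jc_model()
  # identical sequences, zero branch lengths: logL = log(1/4) per site
  tr0 <- read_newick("(A:0,B:0);")
  aln <- rbind(A = c("A", "C", "G", "T"), B = c("A", "C", "G", "T"))
  expect_equal(site_loglik(tr0, aln, m), rep(log(0.25), 4), tolerance = 1e-10)
  # JC closed form at total branch t
  t <- 0.37
  tr <- read_newick(sprintf("(A:%g,B:%g);", t / 2, t / 2))
  aln <- rbind(A = c("A", "A"), B = c("A", "G"))
  expected <- c(log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))),
                log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3))))
  expect_equal(site_loglik(tr, aln, m), expected, tolerance = 1e-10)
})

test_that("pruning equals exhaustive state summation; ambiguity = missing", {
  set.seed(11)
  m <- substitution_model("HKY85", base_freq = c(0.35, 0.15, 0.2, 0.3),
                          kappa = 3)
  tr <- read_newick("(((a:0.1,b:0.3):0.15,c:0.2):0.05,d:0.4);")
  aln <- matrix(sample(c("A", "C", "G", "T"), 4 * 20, replace = TRUE), 4,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_equal(sum(site_loglik(tr, aln, m)),
               sum(brute_force_loglik(tr, aln, m)), tolerance = 1e-8)
  # a fully ambiguous residue behaves like a removed observation
  aln2 <- aln
  aln2["a", 1] <- "N"
  tr_drop <- ape::drop.tip(tr, "a")
  sl_full <- site_loglik(tr, aln2, m)
  sl_drop <- site_loglik(tr_drop, aln2[-1, , drop = FALSE], m)
  expect_equal(sl_full[1], sl_drop[1], tolerance = 1e-10)
  # partial ambiguity: R = {A, G}
  aln3 <- aln
  aln3["a", 1] <- "R"
  manual <- sum(exp(brute_force_loglik(tr, `[<-`(aln, "a", 1, "A"), m))[1],
                exp(brute_force_loglik(tr, `[<-`(aln, "a", 1, "G"), m))[1])
  expect_equal(exp(site_loglik(tr, aln3, m)[1]), manual, tolerance = 1e-10)
})

test_that("total logL is invariant to re-rooting (pulley principle)", {
  set.seed(12)
  for (fam in c("JC69", "GTR")) {
    m <- if (fam == "GTR")
      substitution_model("GTR", base_freq = c(0.4, 0.1, 0.25, 0.25),
                         rates = c(1, 4, 0.7, 1.3, 5, 1)) else jc_model()
    tr <- read_newick("(((a:0.1,b:0.3):0.15,c:0.2):0.05,d:0.4);")
    aln <- matrix(sample(c("A", "C", "G", "T"), 4 * 30, replace = TRUE), 4,
                  dimnames = list(c("a", "b", "c", "d"), NULL))
    base <- sum(site_loglik(tr, aln, m))
    for (og in c("a", "c", "d")) {
      rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                            resolve.root = TRUE)
      expect_equal(sum(site_loglik(rerooted, aln, m)), base,
                   tolerance = 1e-8)
    }
  }
})

test_that("gamma rate heterogeneity averages discrete category rates", {
  m <- substitution_model("JC69", gamma_shape = 0.5, n_cat = 4)
  expect_equal(mean(m$cat_rates), 1, tolerance = 1e-12)
  tr <- read_newick("(A:0.2,B:0.2);")
  aln <- rbind(A = "A", B = "G")
  # per-site likelihood = mean over category-rescaled branch lengths
  manual <- mean(vapply(m$cat_rates, function(r) {
    0.25 * (0.25 - 0.25 * exp(-4 * 0.4 * r / 3))
  }, 0))
  expect_equal(exp(site_loglik(tr, aln, m)[1]), manual, tolerance = 1e-10)
})

test_that("branch-length optimization recovers the analytic JC distance", {
  set.seed(13)
  m <- jc_model()
  true_tr <- read_newick("(A:0.15,B:0.15);")
  aln <- simulate_alignment(true_tr, m, 4000, seed = 14)
  p <- mean(aln["A", ] != aln["B", ])
  fit <- optimize_branch_lengths(read_newick("(A:0.1,B:0.1);"), aln, m)
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * p / 3),
               tolerance = 1e-3)
})

test_that("optimized logL beats random length assignments and is stable", {
  set.seed(15)
  m <- jc_model()
  gen <- read_newick("(((a:0.4,b:0.5):0.3,c:0.6):0.2,d:0.7);")
  aln <- simulate_alignment(gen, m, 300, seed = 16)
  topo <- read_newick("(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:0.1);")
  fit <- optimize_branch_lengths(topo, aln, m)
  for (i in 1:50) {
    rnd <- topo
    rnd$edge.length <- stats::runif(nrow(topo$edge), 1e-6, 2)
    expect_gte(fit$loglik, sum(site_loglik(rnd, aln, m)) - 1e-9)
  }
  # stability under a different edge visit order (tree stored differently)
  topo2 <- read_newick("(d:0.1,(c:0.1,(b:0.1,a:0.1):0.1):0.1);")
  fit2 <- optimize_branch_lengths(topo2, aln, m)
  expect_lt(abs(fit$loglik - fit2$loglik), 1e-4)
  # returned logL never below the starting point
  start_ll <- sum(site_loglik(topo, aln, m))
  expect_gte(fit$loglik, start_ll)
})

test_that("non-binary topologies are rejected by the optimizer", {
  m <- jc_model()
  poly <- read_newick("(a:1,b:1,c:1);")
  aln <- matrix("A", 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(optimize_branch_lengths(poly, aln, m), "binary")
})

test_that("alignment/tree label mismatches list the offenders", {
  m <- jc_model()
  tr <- read_newick("((a:1,b:1):1,c:1);")
  aln <- matrix("A", 3, 5, dimnames = list(c("a", "b", "x"), NULL))
  expect_error(site_loglik(tr, aln, m), "x")
  expect_error(site_loglik(tr, aln, m), "c")
  good <- matrix("A", 3, 0, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(site_loglik(tr, good, m), "zero-length")
})

test_that("BIC model selection identifies a strong transition bias", {
  set.seed(17)
  gen_m <- substitution_model("K80", kappa = 8)
  tr <- read_newick("(((a:0.2,b:0.2):0.1,c:0.3):0.1,d:0.3);")
  aln <- simulate_alignment(tr, gen_m, 1500, seed = 18)
  sel <- select_substitution_model(tr, aln, families = c("JC69", "K80"))
  expect_equal(sel$best$family, "K80")
  expect_gt(sel$best$kappa, 3)
})
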