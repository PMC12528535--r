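test_that("RELL bootstrap proportions behave on constructed inputs", {
  set.seed(41)
  n <- 120
  # candidate 1 dominates every site
  L <- rbind(rep(-1, n), rep(-1.5, n), rep(-2, n))
  bp <- rell_bootstrap(L, n_boot = 200, seed = 1)
  expect_true(all(bp[, 1] == 1))
  expect_true(all(bp[, -1] == 0))
  expect_true(all(abs(rowSums(bp) - 1) < 1e-12))
  # two equal-likelihood candidates, tiny symmetric perturbation
  x <- rnorm(n)
  eps <- rnorm(n, sd = 1e-3)
  eps <- eps - mean(eps)  # so resampled sums are centred at 0
  L2 <- rbind(x + eps, x - eps)
  bp2 <- rell_bootstrap(L2, n_boot = 2000, seed = 2)
  se <- sqrt(0.25 / 2000)
  expect_true(all(abs(bp2[, 1] - 0.5) < 4 * se))
  expect_error(rell_bootstrap(L[, 1:5]), ">= 10 sites")
  expect_error(rell_bootstrap(matrix(1, 1, 50)), ">= 2 candidate")
})

test_that("BP at scale 1 agrees with a naive full-bootstrap oracle", {
  set.seed(42)
  n <- 200
  L <- matrix(rnorm(4 * n, sd = 0.5), 4, n)
  L[1, ] <- L[1, ] + 0.05
  bp <- rell_bootstrap(L, scales = 1, n_boot = 4000, seed = 3)
  # independent oracle: explicit index resampling
  wins <- integer(4)
  for (b in 1:4000) {
    idx <- sample.int(n, n, replace = TRUE)
    tot <- rowSums(L[, idx])
    wins[which.max(tot)] <- wins[which.max(tot)] + 1L
  }
  bp_oracle <- wins / 4000
  for (k in 1:4) {
    se <- sqrt(bp_oracle[k] * (1 - bp_oracle[k]) / 4000 + 1e-8)
    expect_lt(abs(bp[1, k] - bp_oracle[k]), 3 * sqrt(2) * se + 0.005)
  }
})

test_that("AU p-values reflect dominance and symmetry", {
  # dominant candidate: BP -> 1 at all scales
  scales <- seq(0.5, 1.4, by = 0.1)
  bp_hi <- 1 - pnorm(2.5 * sqrt(scales) - 0.1 / sqrt(scales))
  fit_hi <- au_pvalue(1 - bp_hi, scales = scales, n_boot = 10000)
  expect_gt(fit_hi$p_au, 0.95)
  # symmetric: BP = 0.5 everywhere -> p = 0.5
  fit_sym <- au_pvalue(rep(0.5, 10), scales = scales, n_boot = 1000)
  expect_equal(fit_sym$p_au, 0.5, tolerance = 1e-9)
  # all-at-bound inputs are degenerate with decisive p
  expect_true(au_pvalue(rep(0, 10), scales = scales, n_boot = 1000)$degenerate)
  expect_equal(au_pvalue(rep(0, 10), scales = scales, n_boot = 1000)$p_au, 0)
  expect_equal(au_pvalue(rep(1, 10), scales = scales, n_boot = 1000)$p_au, 1)
})

test_that("interrogate_gene recovers a strongly supported topology", {
  set.seed(44)
  cands <- enumerate_topologies(c("a", "b", "c", "d", "o"), outgroup = "o")
  m <- jc_model()
  gen <- read_newick(
    "((((a:0.05,b:0.05):0.08,c:0.05):0.08,d:0.05):0.1,o:0.05);")
  target <- canonical_topology(read_newick("((((a,b),c),d),o);"))
  idx <- which(vapply(cands, canonical_topology, character(1)) == target)
  hits <- 0L
  for (rep in 1:10) {
    aln <- simulate_alignment(gen, m, 600)
    rec <- interrogate_gene(aln, cands, m, n_boot = 500, seed = 500 + rep)
    if (rec$best == idx && rec$p_au[idx] > 0.05) hits <- hits + 1L
    expect_equal(rec$delta[rec$best], 0)
    expect_true(all(rec$delta >= 0))
    expect_true(all(rec$p_au >= 0 & rec$p_au <= 1))
    expect_length(rec$p_au, 15L)
  }
  expect_gte(hits, 9L)
})

test_that("zero-variation alignments give all-zero deltas and degenerate p", {
  cands <- enumerate_topologies(c("a", "b", "c", "d"))
  m <- jc_model()
  aln <- matrix("A", 4, 60, dimnames = list(c("a", "b", "c", "d"), NULL))
  rec <- interrogate_gene(aln, cands, m, n_boot = 200, seed = 7)
  expect_true(all(rec$delta < 1e-9))
  expect_true(rec$tie)
  expect_true(all(rec$degenerate))
})

test_that("p_AU is invariant to candidate order at fixed resample indices", {
  set.seed(45)
  n <- 150
  L <- matrix(rnorm(5 * n), 5, n)
  scales <- seq(0.5, 1.4, by = 0.1)
  W <- lapply(scales, function(r)
    stats::rmultinom(400, ceiling(r * n), rep(1 / n, n)))
  bp <- rell_bootstrap(L, scales, n_boot = 400, resample_weights = W)
  perm <- c(3, 1, 5, 2, 4)
  bp_p <- rell_bootstrap(L[perm, ], scales, n_boot = 400,
                         resample_weights = W)
  for (k in 1:5) {
    p1 <- au_pvalue(bp[, k], scales, 400)$p_au
    p2 <- au_pvalue(bp_p[, match(k, perm)], scales, 400)$p_au
    expect_lt(abs(p1 - p2), 1e-9)
  }
  # site order: permute columns and resample weights consistently
  sp <- sample(n)
  W2 <- lapply(W, function(w) w[sp, ])
  bp_s <- rell_bootstrap(L[, sp], scales, n_boot = 400,
                         resample_weights = W2)
  expect_equal(bp, bp_s, tolerance = 1e-12)
})

test_that("GGI summary implements the study counting semantics", {
  mkrec <- function(best, p) structure(
    list(gene = "g", loglik = -p, delta = as.numeric(seq_along(p) != best),
         p_au = p, best = best, tie = FALSE,
         degenerate = rep(FALSE, length(p))), class = "ggi_record")
  # 10 genes all best-fitting topology 1 and rejecting others
  recs <- replicate(10, mkrec(1, c(0.9, 0.01, 0.01)), simplify = FALSE)
  s <- summarize_ggi(recs, alpha = 0.05)
  expect_equal(s$table$n_best, c(10L, 0L, 0L))
  expect_equal(sum(s$table$n_not_rejected), 10L)
  expect_true(is.na(s$note))
  # one gene failing to reject two topologies counts twice
  recs2 <- list(mkrec(1, c(0.8, 0.4, 0.01)), mkrec(2, c(0.03, 0.9, 0.2)))
  s2 <- summarize_ggi(recs2, alpha = 0.05)
  expect_equal(sum(s2$table$n_not_rejected), 4L)
  expect_match(s2$note, "exceeds")
  expect_equal(sum(s2$table$n_best), 2L)
})

test_that("a synthetic majority mixture is recovered by n_best", {
  set.seed(46)
  m <- jc_model()
  cands <- enumerate_topologies(c("a", "b", "c"))
  genA <- read_newick("((a:0.08,b:0.08):0.1,c:0.08);")
  genB <- read_newick("((a:0.08,c:0.08):0.1,b:0.08);")
  canon <- vapply(cands, canonical_topology, character(1))
  iA <- which(canon == canonical_topology(genA))
  iB <- which(canon == canonical_topology(genB))
  recs <- lapply(1:40, function(g) {
    gen <- if (g <= 24) genA else genB
    interrogate_gene(simulate_alignment(gen, m, 300), cands, m,
                     n_boot = 200, seed = 600 + g)
  })
  s <- summarize_ggi(recs)
  expect_gt(s$table$n_best[iA], s$table$n_best[iB])
  expect_equal(sum(s$table$n_best) + 0L, 40L)
})
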