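test_that("summary statistics on degenerate panels", {
  # every individual identical: K = 1, H = 0, sd = 0
  al <- matrix(7L, 20, 4)
  tab <- phyloconflict:::ssr_matrix_to_table(al, rep(c("A", "B"), each = 5))
  expect_warning(s <- ssr_sumstats(tab), "monomorphic")
  expect_equal(unname(s[c("K_A", "K_B")]), c(1, 1))
  expect_equal(unname(s[c("H_A", "H_B")]), c(0, 0))
  expect_equal(unname(s[["fst_A_B"]]), 0)
  expect_error(ssr_sumstats(tab[c(1, 6), ]), ">= 2 individuals")
})

test_that("duplicated populations show no differentiation", {
  set.seed(61)
  block <- matrix(sample(95:105, 30 * 8, replace = TRUE), 30, 8)
  tab <- phyloconflict:::ssr_matrix_to_table(rbind(block, block),
                                             rep(c("A", "B"), each = 15))
  s <- ssr_sumstats(tab)
  # Weir-Cockerham theta is unbiased, so a duplicated population gives a
  # small (often negative) estimate near zero, not exactly zero
  expect_lt(abs(s[["fst_A_B"]]), 0.1)
  expect_equal(s[["dmu2_A_B"]], 0)
  expect_equal(s[["H_A"]], s[["H_B"]])
})

test_that("Weir-Cockerham FST matches the independent ANOVA oracle", {
  set.seed(62)
  for (rep in 1:5) {
    al <- matrix(sample(98:104, 48 * 6, replace = TRUE,
                        prob = c(1, 2, 4, 6, 4, 2, 1)), 48, 6)
    al[1:24, ] <- al[1:24, ] + sample(0:2, 24 * 6, replace = TRUE)
    pop <- rep(c("A", "B"), each = 24)
    expect_equal(wc_fst(al, pop, c("A", "B")),
                 anova_wc_fst(al, pop, c("A", "B")), tolerance = 1e-10)
    # and the C++ sumstat path agrees with the R implementation
    s <- phyloconflict:::sumstats_from_matrix(al, pop, c("A", "B"))
    expect_equal(unname(s[["fst_A_B"]]), wc_fst(al, pop, c("A", "B")),
                 tolerance = 1e-10)
  }
})

test_that("correlation filter is greedy, deterministic and null-safe", {
  set.seed(63)
  n <- 5000
  # duplicated column: exactly one survivor
  x <- rnorm(n)
  m <- cbind(s1 = x, s2 = x, s3 = rnorm(n))
  expect_equal(filter_correlated_stats(m), c("s1", "s3"))
  # independent columns: all retained
  m2 <- matrix(rnorm(n * 8), n, 8,
               dimnames = list(NULL, paste0("u", 1:8)))
  expect_length(filter_correlated_stats(m2), 8L)
  # chain A~B~C with r(A,B) = r(B,C) = 0.85 > threshold, r(A,C) = 0.5:
  # the greedy pass keeps {A, C}
  S <- matrix(c(1, 0.85, 0.5, 0.85, 1, 0.85, 0.5, 0.85, 1), 3, 3)
  L <- chol(S)
  m3 <- matrix(rnorm(n * 3), n, 3) %*% L
  colnames(m3) <- c("A", "B", "C")
  expect_equal(filter_correlated_stats(m3), c("A", "C"))
  # zero-variance column dropped with warning
  m4 <- cbind(const = rep(1, n), ok = rnorm(n))
  expect_warning(keep <- filter_correlated_stats(m4), "zero-variance")
  expect_equal(keep, "ok")
})

test_that("model selection posterior behaves on constructed tables", {
  set.seed(64)
  n <- 400
  tab <- data.frame(model = rep("c", n), N = runif(n), t1 = runif(n),
                    s1 = rnorm(n), s2 = rnorm(n))
  attr(tab, "stat_names") <- c("s1", "s2")
  attr(tab, "param_names") <- c("N", "t1")
  obs <- c(s1 = 0, s2 = 0)
  post <- abc_select_model(obs, tab, n_retain = 50)
  expect_equal(unname(post$posterior), 1)
  expect_error(abc_select_model(obs, tab, n_retain = 1000), "exceeds")
  # affine rescaling of a stat column leaves the posterior unchanged
  tab2 <- rbind(tab, transform(tab, model = "d", s1 = s1 + 0.5))
  attr(tab2, "stat_names") <- c("s1", "s2")
  post2 <- abc_select_model(obs, tab2, n_retain = 100)
  tab3 <- tab2
  tab3$s1 <- tab3$s1 * 250 - 13
  obs3 <- c(s1 = 0 * 250 - 13, s2 = 0)
  post3 <- abc_select_model(obs3, tab3, n_retain = 100)
  expect_equal(post2$posterior, post3$posterior)
  # duplicating every row leaves the posterior unchanged
  tab4 <- rbind(tab2, tab2)
  attr(tab4, "stat_names") <- c("s1", "s2")
  post4 <- abc_select_model(obs, tab4, n_retain = 200)
  expect_equal(post4$posterior, post2$posterior, tolerance = 0.02)
})

test_that("parameter estimation summarizes retained draws on log scale", {
  n <- 300
  tab <- data.frame(model = "c", N = rep(1234, n), t1 = exp(rnorm(n, 7)),
                    s1 = rnorm(n), s2 = rnorm(n))
  attr(tab, "stat_names") <- c("s1", "s2")
  attr(tab, "param_names") <- c("N", "t1")
  est <- abc_estimate_parameters(c(s1 = 0, s2 = 0), tab, "c", n_retain = 100)
  sN <- est$summary[est$summary$parameter == "N", ]
  expect_equal(sN$median, 1234)
  expect_equal(sN$upper - sN$lower, 0)
  expect_error(abc_estimate_parameters(c(s1 = 0, s2 = 0), tab, "c",
                                       n_retain = 1000), "n_retain")
  tab$t1[1] <- -5
  expect_error(abc_estimate_parameters(c(s1 = 0, s2 = 0), tab, "c",
                                       n_retain = 100), "t1")
})

test_that("reference-table simulation produces complete, provenanced rows", {
  tab <- simulate_reference_table(c("c", "g"), 30,
                                  diploids = c(att = 5, dai = 5, lgk = 5,
                                               mus = 5),
                                  n_loci = 4, seed = 65)
  expect_equal(nrow(tab), 60L)
  expect_equal(sort(unique(tab$model)), c("c", "g"))
  sn <- attr(tab, "stat_names")
  expect_length(sn, 3 * 4 + 2 * 6 + 1)
  expect_false(anyNA(tab[, sn]))
  expect_true(all(tab$t1 < tab$t2))
})

test_that("a scaled-down ABC round trip recovers the generating template", {
  tab <- simulate_reference_table(c("c", "d"), 800,
                                  diploids = c(att = 8, dai = 8, lgk = 8,
                                               mus = 8),
                                  n_loci = 8, seed = 66)
  keep <- filter_correlated_stats(as.matrix(tab[, attr(tab, "stat_names")]))
  sc <- get_scenario("c")
  wins <- 0L
  set.seed(67)
  for (r in 1:5) {
    obs <- ssr_sumstats(simulate_ssr(sc, c(att = 8, dai = 8, lgk = 8,
                                           mus = 8), n_loci = 8))
    post <- abc_select_model(obs, tab, n_retain = 150, stats = keep)
    if (names(which.max(post$posterior)) == "c") wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
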