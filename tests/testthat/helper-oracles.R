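# Independent oracles used across test files. These deliberately do NOT
# share code with the package implementations they check.

# random rooted binary tree with random lengths, as a Newick string
random_newick <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- sample(paste0("t", seq_len(n)))
  nodes <- as.list(labs)
  lens <- function() round(stats::runif(1, 0.01, 2), 6)
  while (length(nodes) > 1) {
    i <- sample(length(nodes), 2)
    merged <- sprintf("(%s:%s,%s:%s)", nodes[[i[1]]], lens(),
                      nodes[[i[2]]], lens())
    nodes[[i[1]]] <- merged
    nodes[[i[2]]] <- NULL
  }
  paste0(nodes[[1]], ";")
}

# rooted-topology count by independent recursion T(n) = (2n-3) * T(n-1)
count_rooted_insertion <- function(n) {
  if (n <= 2) return(1)
  (2 * n - 3) * count_rooted_insertion(n - 1)
}

# brute-force tree log-likelihood: sum over every internal-state assignment
brute_force_loglik <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  aln <- aln[tree$tip.label, , drop = FALSE]
  nuc <- c("A", "C", "G", "T")
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(model, tree$edge.length[e]))
  internal <- (n + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  sapply(seq_len(ncol(aln)), function(s) {
    tipstate <- match(aln[, s], nuc)  # NA for ambiguity: not used here
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      state <- integer(nn)
      state[seq_len(n)] <- tipstate
      state[internal] <- grid[g, ]
      pr <- model$base_freq[state[n + 1]]
      for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pr <- pr * Ps[[e]][state[pa], state[ch]]
      }
      tot <- tot + pr
    }
    log(tot)
  })
}

# textbook Weir-Cockerham theta via the ANOVA (mean squares) route,
# two populations, multiple alleles and loci
anova_wc_fst <- function(alleles, pop, pair) {
  keep <- pop %in% pair
  al <- alleles[keep, , drop = FALSE]
  gp <- pop[keep]
  num <- den <- 0
  for (l in seq_len(ncol(al))) {
    for (allele in unique(al[, l])) {
      y <- as.numeric(al[, l] == allele)
      ind <- rep(seq_len(length(y) / 2), each = 2)
      popf <- gp
      n_i <- tapply(y, popf, length) / 2        # individuals per pop
      r <- 2
      nbar <- mean(n_i)
      nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
      ybar_pop <- tapply(y, popf, mean)
      ybar <- mean(y)
      ybar_ind <- tapply(y, ind, mean)
      pop_of_ind <- tapply(popf, ind, `[`, 1)
      MSP <- sum(2 * n_i * (ybar_pop[names(n_i)] - ybar)^2) / (r - 1)
      MSI <- sum(2 * (ybar_ind - ybar_pop[pop_of_ind])^2) / (sum(n_i) - r)
      MSG <- sum((y - ybar_ind[as.character(ind)])^2) / sum(n_i)
      a <- (MSP - MSI) / (2 * nc)
      b <- (MSI - MSG) / 2
      cc <- MSG
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# brute-force Brownian covariance: shared root path by node-path intersection
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(tip) {
    p <- tip
    repeat {
      pa <- tree$edge[tree$edge[, 2] == p[1], 1]
      if (!length(pa)) break
      p <- c(pa, p)
    }
    p
  })
  elen <- function(node) tree$edge.length[tree$edge[, 2] == node]
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    shared <- setdiff(shared, n + 1L)  # drop root
    C[i, j] <- sum(vapply(shared, function(nd) elen(nd), 0))
  }
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

jc_model <- function() substitution_model("JC69")

empty_events <- function()
  data.frame(time = numeric(0), type = character(0), from = character(0),
             to = character(0))

one_pop_scenario <- function(N = 1000, mu_ssr = 5e-4)
  demographic_scenario("A", c(A = N), empty_events(), mu_ssr = mu_ssr)
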