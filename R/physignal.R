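#' Brownian-motion tip covariance matrix
#'
#' C\[i, j\] is the shared root-to-MRCA path length of tips i and j; the
#' diagonal is each tip's root-to-tip depth (equal on an ultrametric
#' tree). Non-ultrametric input triggers a warning (K remains computable)
#' and sets attribute `ultrametric = FALSE`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
brownian_vcv <- function(tree, tol = 1e-8) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  if (diff(range(depth[seq_len(n)])) > tol * max(depth) + 1e-12)
    warning("tree is not ultrametric; Brownian covariance still computed")
  mrca <- ape::mrca(tree)
  C <- matrix(depth[mrca], n, n, dimnames = list(tree$tip.label,
                                                 tree$tip.label))
  diag(C) <- depth[seq_len(n)]
  attr(C, "ultrametric") <- diff(range(depth[seq_len(n)])) <=
    tol * max(depth) + 1e-12
  C
}

#' Blomberg's K phylogenetic-signal statistic
#'
#' K compares the observed ratio of the trait's tip variance around the
#' GLS phylogenetic mean (MSE0) to its phylogenetically corrected
#' variance (MSE) against the ratio expected under Brownian motion on the
#' tree:
#' `K = (MSE0/MSE)_obs / [ (tr(C) - n/sum(Cinv)) / (n - 1) ]`,
#' with the phylogenetic mean `a = (1'Cinv 1)^-1 (1'Cinv x)`. K = 1 is
#' the Brownian expectation; K > 1 indicates stronger-than-Brownian
#' conservatism. Trees with fewer than 10 tips give notoriously unstable
#' K and trigger a warning.
#'
#' @param tree Rooted `phylo` with branch lengths (>= 4 tips).
#' @param trait Named numeric vector matching the tip labels one-to-one.
#' @return K (numeric scalar).
#' @export
blomberg_k <- function(tree, trait) {
  n <- length(tree$tip.label)
  if (n < 4) stop("need >= 4 tips")
  if (n < 10)
    warning("Blomberg's K is unstable below 10 tips (n = ", n, ")")
  x <- align_trait(tree, trait)
  if (stats::var(x) == 0) stop("constant trait: K undefined")
  k_kernel(k_precompute(tree), x)
}

# covariance pieces shared across the permutations of a randomization test
k_precompute <- function(tree) {
  C <- brownian_vcv(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular Brownian covariance matrix"))
  n <- nrow(C)
  list(C = C, Cinv = Cinv, n = n,
       expected = (sum(diag(C)) - n / sum(Cinv)) / (n - 1))
}

k_kernel <- function(pre, x) {
  a <- sum(pre$Cinv %*% x) / sum(pre$Cinv)
  dev <- x - a
  mse0 <- sum(dev^2) / (pre$n - 1)
  mse <- as.numeric(t(dev) %*% pre$Cinv %*% dev) / (pre$n - 1)
  (mse0 / mse) / pre$expected
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  if (!setequal(names(trait), tree$tip.label))
    stop("trait labels must match the tree's tips one-to-one; offending: ",
         paste(c(setdiff(names(trait), tree$tip.label),
                 setdiff(tree$tip.label, names(trait))), collapse = ", "))
  x <- as.numeric(trait[tree$tip.label])
  if (any(!is.finite(x))) stop("trait values must be finite")
  x
}

#' Randomization test for phylogenetic signal
#'
#' Computes Blomberg's K and a p-value against a null distribution
#' obtained either by shuffling trait values across tips (default,
#' standard practice for K) or by simulating Brownian motion on the tree
#' with rate matched to the trait's phylogenetic variance. The p-value
#' uses the add-one correction
#' `p = (1 + #(K_null >= K_obs)) / (1 + n_perm)`.
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of randomizations (default 10000).
#' @param null `"permutation"` or `"brownian"`.
#' @param seed Optional integer seed.
#' @return List of class `physignal_result`: `K`, `p_value`, `n_perm`,
#'   `null`, `null_K` (the null sample).
#' @export
phylo_signal_test <- function(tree, trait, n_perm = 10000L,
                              null = c("permutation", "brownian"),
                              seed = NULL) {
  null <- match.arg(null)
  set_seed_if(seed)
  K_obs <- blomberg_k(tree, trait)
  x <- align_trait(tree, trait)
  pre <- suppressWarnings(k_precompute(tree))
  null_K <- numeric(n_perm)
  if (n_perm > 0) {
    if (null == "permutation") {
      null_K <- vapply(seq_len(n_perm), function(i)
        k_kernel(pre, sample(x)), 0)
    } else {
      L <- t(chol(pre$C + diag(1e-12 * max(diag(pre$C)), pre$n)))
      null_K <- vapply(seq_len(n_perm), function(i)
        k_kernel(pre, as.numeric(L %*% stats::rnorm(length(x)))), 0)
    }
  }
  p <- (1 + sum(null_K >= K_obs)) / (1 + n_perm)
  structure(list(K = K_obs, p_value = p, n_perm = n_perm, null = null,
                 null_K = null_K), class = "physignal_result")
}

#' @export
print.physignal_result <- function(x, ...) {
  cat("Blomberg's K =", signif(x$K, 4), " p =", signif(x$p_value, 4),
      " (", x$n_perm, x$null, "randomizations )\n")
  invisible(x)
}

#' Signal tests for every trait in a table
#'
#' @param tree Rooted `phylo`.
#' @param traits Data frame or matrix, one column per trait, row names =
#'   tip labels.
#' @inheritParams phylo_signal_test
#' @return Data frame: trait, K, p (one row per trait).
#' @export
phylo_signal_table <- function(tree, traits, n_perm = 10000L,
                               null = c("permutation", "brownian"),
                               seed = NULL) {
  null <- match.arg(null)
  set_seed_if(seed)
  traits <- as.data.frame(traits)
  do.call(rbind, lapply(names(traits), function(tn) {
    tv <- stats::setNames(traits[[tn]], rownames(traits))
    res <- suppressWarnings(
      phylo_signal_test(tree, tv, n_perm = n_perm, null = null))
    data.frame(trait = tn, K = res$K, p = res$p_value,
               stringsAsFactors = FALSE)
  }))
}
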