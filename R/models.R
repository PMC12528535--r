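IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), "-" = c("A", "C", "G", "T"),
  "?" = c("A", "C", "G", "T")
)
NUC <- c("A", "C", "G", "T")

#' Construct a nucleotide substitution model
#'
#' Builds a time-reversible rate matrix for one of the JC69, K80, HKY85 or
#' GTR families, normalized so the expected number of substitutions per
#' unit branch length is 1, with optional discrete-Gamma rate
#' heterogeneity (k mean-category rates).
#'
#' @param family One of `"JC69"`, `"K80"`, `"HKY85"`, `"GTR"`.
#' @param base_freq Stationary frequencies in A,C,G,T order (must sum to 1,
#'   strictly positive). Forced to 1/4 for JC69/K80.
#' @param kappa Transition/transversion rate ratio (K80, HKY85).
#' @param rates Six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT
#'   (positive; scale is arbitrary).
#' @param gamma_shape Optional Gamma shape alpha > 0 for among-site rate
#'   variation.
#' @param n_cat Number of discrete Gamma categories (default 4, the field
#'   convention).
#' @return An object of class `subst_model` holding the rate matrix `Q`,
#'   its eigendecomposition, stationary frequencies and category rates.
#' @examples
#' m <- substitution_model("HKY85", base_freq = c(.3, .2, .2, .3), kappa = 4)
#' @export
substitution_model <- function(family = c("JC69", "K80", "HKY85", "GTR"),
                               base_freq = rep(0.25, 4), kappa = 2,
                               rates = rep(1, 6), gamma_shape = NULL,
                               n_cat = 4L) {
  family <- match.arg(family)
  if (family %in% c("JC69", "K80")) base_freq <- rep(0.25, 4)
  stopifnot(length(base_freq) == 4, all(base_freq > 0),
            abs(sum(base_freq) - 1) < 1e-8)
  base_freq <- base_freq / sum(base_freq)
  ex <- switch(family,
    JC69 = rep(1, 6),
    K80 = c(1, kappa, 1, 1, kappa, 1),
    HKY85 = c(1, kappa, 1, 1, kappa, 1),
    GTR = rates)
  if (any(ex <= 0)) stop("exchangeability parameters must be positive")
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- ex[k] * base_freq[j]
    Q[j, i] <- ex[k] * base_freq[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(base_freq * diag(Q))
  Q <- Q / scale
  # reversible Q diagonalized via the symmetric similarity transform
  sq <- sqrt(base_freq)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- diag(1 / sq) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sq)
  cat_rates <- 1
  if (!is.null(gamma_shape)) {
    stopifnot(gamma_shape > 0, n_cat >= 2)
    q <- stats::qgamma((0:n_cat) / n_cat, shape = gamma_shape, rate = gamma_shape)
    p <- stats::pgamma(q, shape = gamma_shape + 1, rate = gamma_shape)
    cat_rates <- n_cat * diff(p)
    cat_rates <- cat_rates / mean(cat_rates)
  }
  structure(list(family = family, Q = Q, base_freq = base_freq,
                 kappa = if (family %in% c("K80", "HKY85")) kappa else NA_real_,
                 rates = ex, gamma_shape = gamma_shape,
                 V = V, Vinv = Vinv, lambda = eig$values,
                 cat_rates = as.numeric(cat_rates)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Substitution model:", x$family)
  if (!is.null(x$gamma_shape))
    cat(" + Gamma(", x$gamma_shape, ") x", length(x$cat_rates))
  cat("\n  base frequencies:", signif(x$base_freq, 4), "\n")
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site).
#' @return 4x4 matrix of transition probabilities (rows = from, A,C,G,T).
#' @export
transition_matrix <- function(model, t) {
  P <- model$V %*% diag(exp(model$lambda * t)) %*% model$Vinv
  P[P < 0] <- 0
  dimnames(P) <- list(NUC, NUC)
  P / rowSums(P)
}

# tip partial-likelihood array (4 x npattern x ntip) + pattern weights
encode_alignment <- function(aln, tip_labels) {
  if (is.null(rownames(aln))) stop("alignment must have row names")
  miss_tree <- setdiff(rownames(aln), tip_labels)
  miss_aln <- setdiff(tip_labels, rownames(aln))
  if (length(miss_tree) || length(miss_aln))
    stop("alignment/tree label mismatch; in alignment only: [",
         paste(miss_tree, collapse = ","), "]; in tree only: [",
         paste(miss_aln, collapse = ","), "]")
  if (ncol(aln) == 0L) stop("zero-length alignment")
  aln <- aln[tip_labels, , drop = FALSE]
  key <- apply(aln, 2, paste, collapse = "\r")
  upat <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[upat])))
  pat <- aln[, upat, drop = FALSE]
  ntip <- length(tip_labels)
  npat <- ncol(pat)
  arr <- array(0, c(4, npat, ntip))
  for (i in seq_len(ntip)) {
    for (s in seq_len(npat)) {
      states <- IUPAC[[pat[i, s]]]
      if (is.null(states))
        stop("unknown residue '", pat[i, s], "' in sequence ", tip_labels[i])
      arr[match(states, NUC), s, i] <- 1
    }
  }
  list(partials = arr, weights = weights, npat = npat,
       pattern_index = match(key, key[upat]))
}

#' Per-site log-likelihoods by Felsenstein pruning
#'
#' Computes the log-likelihood of every alignment column on a rooted tree
#' with branch lengths under a reversible nucleotide model. Gaps and IUPAC
#' ambiguity codes are treated as (partially) missing data: all compatible
#' states get partial likelihood 1.
#'
#' @param tree Rooted binary `phylo` with branch lengths in expected
#'   substitutions per site.
#' @param aln Character matrix (taxa x sites); row names must match the
#'   tree's tip labels exactly (as a set).
#' @param model A [substitution_model()].
#' @return Numeric vector of per-site log-likelihoods; `sum()` of it is the
#'   tree log-likelihood.
#' @export
site_loglik <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  enc <- encode_alignment(aln, tree$tip.label)
  ll <- cpp_site_loglik(tree$edge, length(tree$tip.label), tree$Nnode,
                        as.numeric(enc$partials), enc$npat,
                        tree$edge.length, model$V, model$Vinv, model$lambda,
                        model$base_freq, model$cat_rates,
                        rep(1, enc$npat))
  ll[enc$pattern_index]
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise bounded Brent optimization of every branch length,
#' swept until the relative log-likelihood improvement falls below `tol`.
#' Small trees make the problem effectively unimodal, so no multistart is
#' used.
#'
#' @inheritParams site_loglik
#' @param tree Rooted binary `phylo`; existing branch lengths are used as
#'   the starting point, otherwise all start at 0.1.
#' @param bounds Length-2 numeric, allowed branch-length range.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_sweeps Cap on optimization sweeps (warning if reached).
#' @return List with `tree` (fitted lengths), `loglik`, and `converged`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, bounds = c(1e-8, 10),
                                    tol = 1e-6, max_sweeps = 50L) {
  if (!is_binary_rooted(tree)) stop("topology must be binary")
  tree <- ape::reorder.phylo(tree, "postorder")
  start <- tree$edge.length
  if (is.null(start)) start <- rep(0.1, nrow(tree$edge))
  enc <- encode_alignment(aln, tree$tip.label)
  fit <- cpp_optimize_edges(tree$edge, length(tree$tip.label), tree$Nnode,
                            as.numeric(enc$partials), enc$npat, start,
                            model$V, model$Vinv, model$lambda,
                            model$base_freq, model$cat_rates, enc$weights,
                            bounds[1], bounds[2], tol, max_sweeps)
  if (!fit$converged)
    warning("branch-length optimization hit the sweep cap; best-found returned")
  tree$edge.length <- fit$edge_len
  list(tree = tree, loglik = fit$loglik, converged = fit$converged)
}

#' Select a substitution-model family by BIC
#'
#' Fits JC69, K80, HKY85 and GTR (optionally +Gamma) on a fixed topology,
#' optimizing branch lengths and the family's free parameters, and ranks
#' them by BIC (parameter count includes branch lengths). Base frequencies
#' for HKY85/GTR are empirical.
#'
#' @inheritParams site_loglik
#' @param families Character vector of families to compare.
#' @param gamma If `TRUE` also estimate a Gamma shape (adds 1 parameter).
#' @return List with `best` (a `subst_model`), and `table` (data.frame of
#'   family, loglik, k, BIC).
#' @export
select_substitution_model <- function(tree, aln, families = c("JC69", "K80",
                                      "HKY85", "GTR"), gamma = FALSE) {
  n <- ncol(aln)
  counts <- table(factor(aln[aln %in% NUC], levels = NUC))
  emp <- as.numeric(counts) / sum(counts)
  emp[emp <= 0] <- 1e-6
  emp <- emp / sum(emp)
  res <- list()
  for (fam in families) {
    make <- function(par) {
      kappa <- 2; ex <- rep(1, 6); shape <- NULL
      i <- 0
      if (fam %in% c("K80", "HKY85")) { kappa <- exp(par[i + 1]); i <- i + 1 }
      if (fam == "GTR") { ex <- c(exp(par[i + (1:5)]), 1); i <- i + 5 }
      if (gamma) shape <- exp(par[i + 1])
      substitution_model(fam, base_freq = if (fam %in% c("JC69", "K80"))
                         rep(0.25, 4) else emp,
                         kappa = kappa, rates = ex, gamma_shape = shape)
    }
    npar <- (fam %in% c("K80", "HKY85")) + 5 * (fam == "GTR") + gamma
    par <- rep(0, npar)
    fit <- optimize_branch_lengths(tree, aln, make(par))
    if (npar > 0) {
      for (round in 1:2) {
        obj <- function(p) -sum(site_loglik(fit$tree, aln, make(p)))
        opt <- if (npar == 1)
          stats::optim(par, obj, method = "Brent", lower = -5, upper = 5)
        else stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(maxit = 200))
        par <- opt$par
        fit <- optimize_branch_lengths(fit$tree, aln, make(par))
      }
    }
    k_model <- npar + 3 * (fam %in% c("HKY85", "GTR"))  # + free base freqs
    k <- k_model + nrow(tree$edge)
    res[[fam]] <- list(model = make(par), loglik = fit$loglik, k = k,
                       bic = k * log(n) - 2 * fit$loglik)
  }
  tab <- data.frame(family = names(res),
                    loglik = vapply(res, `[[`, 0, "loglik"),
                    k = vapply(res, `[[`, 0, "k"),
                    BIC = vapply(res, `[[`, 0, "bic"), row.names = NULL)
  best <- res[[which.min(tab$BIC)]]$model
  list(best = best, table = tab[order(tab$BIC), ])
}
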