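#' Enumerate (triplet, topology) category labels
#'
#' For k ingroup taxa there are choose(k, 3) triplets x 3 rooted
#' resolutions each (12 categories for 4 taxa). Labels follow the
#' convention `((A,B),C)` where C is the outlier taxon.
#'
#' @param taxa Character vector of >= 3 ingroup taxa.
#' @return Character vector of category labels in deterministic order.
#' @export
triplet_topology_labels <- function(taxa) {
  stopifnot(length(taxa) >= 3L)
  taxa <- sort(taxa)
  trips <- utils::combn(taxa, 3, simplify = FALSE)
  unlist(lapply(trips, function(tr)
    vapply(1:3, function(i)
      sprintf("((%s,%s),%s)", sort(tr[-i])[1], sort(tr[-i])[2], tr[i]),
      character(1))))
}

triplet_label <- function(pair, outlier)
  sprintf("((%s,%s),%s)", sort(pair)[1], sort(pair)[2], outlier)

#' Extract triplet observations from gene trees
#'
#' For every gene tree and every 3-subset of the ingroup taxa: the tree
#' is rooted on the outgroup, pruned to the triplet, and the displayed
#' topology (which taxon is the outlier) plus the internal branch length
#' between the two coalescences is recorded. Species with several samples
#' are reduced to the alphabetically first sample. Gene trees missing the
#' outgroup or a triplet taxon are skipped with a log entry.
#'
#' @param gene_trees List of rooted `phylo` gene trees with branch
#'   lengths (typically substitutions/site).
#' @param ingroup Character vector of >= 3 ingroup taxon labels.
#' @param outgroup Single outgroup label used to root each gene tree.
#' @param species_map Optional named character vector sample -> species;
#'   when given, tip labels are first collapsed to one sample per species.
#' @return Data frame (`triplet_observations`): `gene`, `triplet`,
#'   `topology` (category label), `outlier`, `t` (internal branch
#'   length); attribute `skipped` lists skipped genes.
#' @export
extract_triplet_observations <- function(gene_trees, ingroup, outgroup,
                                         species_map = NULL) {
  stopifnot(length(ingroup) >= 3L, length(outgroup) == 1L)
  ids <- names(gene_trees)
  if (is.null(ids)) ids <- sprintf("gene%04d", seq_along(gene_trees))
  trips <- utils::combn(sort(ingroup), 3, simplify = FALSE)
  skipped <- character(0)
  rows <- vector("list", length(gene_trees))
  for (g in seq_along(gene_trees)) {
    tr <- gene_trees[[g]]
    if (!is.null(species_map)) {
      keep_samples <- vapply(split(names(species_map), species_map),
                             function(s) sort(s)[1], character(1))
      drop <- setdiff(intersect(tr$tip.label, names(species_map)),
                      keep_samples)
      if (length(drop)) tr <- ape::drop.tip(tr, drop)
      m <- match(tr$tip.label, keep_samples)
      tr$tip.label[!is.na(m)] <- names(keep_samples)[m[!is.na(m)]]
    }
    if (!outgroup %in% tr$tip.label) {
      skipped <- c(skipped, sprintf("%s: missing outgroup '%s'", ids[g], outgroup))
      next
    }
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    out_rows <- list()
    for (trip in trips) {
      if (!all(trip %in% tr$tip.label)) {
        skipped <- c(skipped, sprintf("%s: missing taxa for triplet %s",
                                      ids[g], paste(trip, collapse = ",")))
        next
      }
      sub <- ape::keep.tip(tr, c(trip, outgroup))
      sub <- ape::drop.tip(ape::root(sub, outgroup = outgroup,
                                     resolve.root = TRUE), outgroup)
      # rooted 3-taxon tree: the non-root internal node subtends the pair
      n <- length(sub$tip.label)
      inner <- sub$edge[sub$edge[, 2] > n, 2]
      if (length(inner) != 1L) next  # unresolved triplet
      pair_tips <- sub$tip.label[sub$edge[sub$edge[, 1] == inner, 2]]
      outlier <- setdiff(trip, pair_tips)
      tlen <- sub$edge.length[sub$edge[, 2] == inner]
      out_rows[[length(out_rows) + 1L]] <-
        data.frame(gene = ids[g], triplet = paste(trip, collapse = ","),
                   topology = triplet_label(pair_tips, outlier),
                   outlier = outlier, t = tlen, stringsAsFactors = FALSE)
    }
    rows[[g]] <- if (length(out_rows)) do.call(rbind, out_rows) else NULL
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene = character(0), triplet = character(0),
                      topology = character(0), outlier = character(0),
                      t = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("triplet_observations", "data.frame")
  out
}

#' Fit an exponential or exponential-mixture model to internal branch
#' lengths
#'
#' The ILS-only model is a single exponential with rate lambda (closed
#' form MLE `1/mean(t)`, k = 1 parameter). The ILS+introgression model is
#' a two-component mixture of an exponential and a delta-shifted
#' exponential sharing lambda, with mixing weight `pi_ils` (k = 3),
#' fitted by EM. The shift delta is profiled over a deterministic grid of
#' 10 quantiles of `t` (EM over `pi_ils` and lambda at each, followed by
#' a local refinement of delta), and the best fit by log-likelihood is
#' returned. The mixture log-likelihood can never fall below the
#' ILS-only one since the models are nested at delta = 0, pi = 1.
#'
#' @param t Non-negative branch lengths (>= 5 observations).
#' @param model `"ils"` or `"ils_intro"`.
#' @param tol Relative EM convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @return A `mixture_fit`: `model`, `pi_ils`, `lambda`, `delta`,
#'   `loglik`, `k`, `n`, `bic` (`k*log(n) - 2*loglik`), `responsibility`
#'   (posterior P(ILS component) per observation), `degenerate`.
#' @export
fit_branch_mixture <- function(t, model = c("ils", "ils_intro"),
                               tol = 1e-8, max_iter = 2000L) {
  model <- match.arg(model)
  t_raw <- as.numeric(t)
  if (any(!is.finite(t_raw)) || any(t_raw < 0))
    stop("t must be finite and >= 0")
  n <- length(t_raw)
  if (n < 5L) stop("need >= 5 observations, got ", n)
  # fit on mean-standardized data so results are exactly scale-equivariant
  # (lambda scales inversely, delta proportionally, Delta-BIC unchanged);
  # the log-likelihood is mapped back by -n*log(scale)
  scale_t <- mean(t_raw)
  degenerate <- stats::var(t_raw) < 1e-24 * max(scale_t, 1)^2 ||
    scale_t <= 0
  t <- if (scale_t > 0) t_raw / scale_t else t_raw
  lambda_hat <- if (mean(t) > 0) 1 / mean(t) else 1e12
  lambda_hat <- min(lambda_hat, 1e12)
  ll_ils <- n * log(lambda_hat) - lambda_hat * sum(t)
  unscale <- function(lambda, delta, loglik) {
    if (scale_t > 0)
      list(lambda = lambda / scale_t, delta = delta * scale_t,
           loglik = loglik - n * log(scale_t))
    else list(lambda = lambda, delta = delta, loglik = loglik)
  }
  if (model == "ils" || degenerate) {
    u <- unscale(lambda_hat, 0, ll_ils)
    k <- if (model == "ils") 1L else 3L
    fit <- list(model = model, pi_ils = 1, lambda = u$lambda, delta = 0,
                loglik = u$loglik, k = k,
                n = n, bic = k * log(n) - 2 * u$loglik,
                responsibility = rep(1, n), degenerate = degenerate)
    return(structure(fit, class = "mixture_fit"))
  }
  em_at_delta <- function(delta) {
    pi1 <- 0.7
    lambda <- lambda_hat
    ll_old <- -Inf
    r1 <- rep(1, n)
    for (it in seq_len(max_iter)) {
      f1 <- stats::dexp(t, lambda)
      f2 <- ifelse(t >= delta, lambda * exp(-lambda * (t - delta)), 0)
      mix <- pi1 * f1 + (1 - pi1) * f2
      mix[mix <= 0] <- 1e-300
      ll <- sum(log(mix))
      if (ll < ll_old - 1e-8 * (abs(ll_old) + 1))
        stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) break
      ll_old <- ll
      r1 <- pi1 * f1 / mix
      pi1 <- mean(r1)
      pi1 <- min(max(pi1, 1e-8), 1 - 1e-8)
      denom <- sum(r1 * t) + sum((1 - r1) * pmax(t - delta, 0))
      lambda <- n / max(denom, 1e-300)
      lambda <- min(lambda, 1e12)
    }
    list(pi_ils = pi1, lambda = lambda, delta = delta, loglik = ll_old,
         responsibility = r1)
  }
  deltas <- unique(stats::quantile(t, probs = seq(0, 0.9, by = 0.1),
                                   names = FALSE))
  fits <- lapply(deltas, em_at_delta)
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(lls)]]
  # local refinement of delta around the best grid point
  prof <- function(d) em_at_delta(d)$loglik
  dbest <- best$delta
  span <- diff(range(t)) / 10
  opt <- stats::optimize(prof, lower = max(0, dbest - span),
                         upper = dbest + span, maximum = TRUE, tol = 1e-6)
  if (opt$objective > best$loglik) best <- em_at_delta(opt$maximum)
  if (best$loglik < ll_ils) {  # nested safeguard: fall back to ILS solution
    best <- list(pi_ils = 1 - 1e-8, lambda = lambda_hat, delta = 0,
                 loglik = ll_ils, responsibility = rep(1, n))
  }
  u <- unscale(best$lambda, best$delta, best$loglik)
  structure(list(model = "ils_intro", pi_ils = best$pi_ils,
                 lambda = u$lambda, delta = u$delta,
                 loglik = u$loglik, k = 3L, n = n,
                 bic = 3 * log(n) - 2 * u$loglik,
                 responsibility = best$responsibility,
                 degenerate = FALSE), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Branch-length mixture [", x$model, "]: pi_ils =",
      signif(x$pi_ils, 4), " lambda =", signif(x$lambda, 5),
      " delta =", signif(x$delta, 5), "\n  logL =", signif(x$loglik, 8),
      " BIC =", signif(x$bic, 8),
      if (x$degenerate) " [degenerate]" else "", "\n")
  invisible(x)
}

#' Classify one (triplet, topology) category as ILS-only vs
#' ILS+introgression
#'
#' Fits both models to the category's internal branch lengths and applies
#' the decision rule `Delta-BIC = BIC_ILS+intro - BIC_ILS-only < -10`. In
#' the significant case each gene is assigned to the component with the
#' higher posterior responsibility and the reported proportions are the
#' mixture weights; otherwise Prop_ILS = 1 and no introgression genes are
#' counted.
#'
#' @param t Internal branch lengths for one category.
#' @param topology Category label carried through to the output.
#' @param threshold Delta-BIC significance threshold (default -10).
#' @return One-row data frame: topology, prop_ils, prop_non_ils,
#'   bic_ils_intro, bic_ils_only, delta_bic, n_genes, n_ils, n_intro,
#'   significant, plus attribute `fits` and `prop_ils_assigned` (the
#'   posterior-assignment fraction, reported alongside the mixture
#'   weight).
#' @export
classify_triplet_topology <- function(t, topology = "triplet",
                                      threshold = -10) {
  fit1 <- fit_branch_mixture(t, "ils")
  fit2 <- fit_branch_mixture(t, "ils_intro")
  delta_bic <- fit2$bic - fit1$bic
  significant <- is.finite(delta_bic) && delta_bic < threshold
  n <- length(t)
  if (significant) {
    assign_ils <- fit2$responsibility >= 0.5
    prop_ils <- fit2$pi_ils
    n_ils <- sum(assign_ils)
    n_intro <- n - n_ils
  } else {
    prop_ils <- 1
    n_ils <- n
    n_intro <- 0L
  }
  out <- data.frame(topology = topology, prop_ils = prop_ils,
                    prop_non_ils = 1 - prop_ils,
                    bic_ils_intro = fit2$bic, bic_ils_only = fit1$bic,
                    delta_bic = delta_bic, n_genes = n, n_ils = n_ils,
                    n_intro = n_intro, significant = significant,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- list(ils = fit1, ils_intro = fit2)
  attr(out, "prop_ils_assigned") <- if (significant)
    mean(fit2$responsibility >= 0.5) else 1
  out
}

#' Classify every (triplet, topology) category in an observation table
#'
#' @param obs Output of [extract_triplet_observations()].
#' @param min_n Categories with fewer observations are skipped (the
#'   mixture fit needs >= 5).
#' @param threshold Delta-BIC significance threshold.
#' @return Data frame with one row per category, shaped like the
#'   study-style summary table (topology, proportions, both BICs,
#'   Delta-BIC, gene counts).
#' @export
classify_triplets <- function(obs, min_n = 5L, threshold = -10) {
  stopifnot(nrow(obs) > 0)
  split_obs <- split(obs$t, obs$topology)
  keep <- names(split_obs)[lengths(split_obs) >= max(min_n, 5L)]
  out <- do.call(rbind, lapply(keep, function(top)
    classify_triplet_topology(split_obs[[top]], topology = top,
                              threshold = threshold)))
  rownames(out) <- NULL
  out
}
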