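#' RELL multiscale bootstrap proportions
#'
#' Resampling of estimated log-likelihoods: at each scale r,
#' `ceiling(r * n_sites)` site columns are drawn with replacement `n_boot`
#' times, and BP(candidate) is the fraction of replicates in which that
#' candidate attains the maximum resampled total log-likelihood (ties go
#' to the lowest candidate index, counted once, so BP sums to 1 per
#' scale).
#'
#' @param loglik Numeric matrix of per-site log-likelihoods, candidates x
#'   sites (>= 2 candidates, >= 10 sites).
#' @param scales Relative resample sizes r (default the standard 10-scale
#'   grid 0.5..1.4).
#' @param n_boot Replicates per scale.
#' @param seed Optional integer seed.
#' @param resample_weights Optional list (one `n_sites x n_boot` integer
#'   matrix of multinomial site counts per scale) to reuse fixed resample
#'   indices; mainly for invariance testing.
#' @return Matrix of bootstrap proportions, `length(scales)` x
#'   `n_candidates`, with attributes `scales` and `n_boot`.
#' @export
rell_bootstrap <- function(loglik, scales = seq(0.5, 1.4, by = 0.1),
                           n_boot = 1000L, seed = NULL,
                           resample_weights = NULL) {
  if (!is.matrix(loglik) || nrow(loglik) < 2L)
    stop("need a matrix with >= 2 candidate rows")
  n <- ncol(loglik)
  if (n < 10L) stop("need >= 10 sites")
  stopifnot(all(scales > 0))
  set_seed_if(seed)
  bp <- matrix(0, length(scales), nrow(loglik))
  colnames(bp) <- rownames(loglik)
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * n)
    W <- if (is.null(resample_weights)) {
      stats::rmultinom(n_boot, m, rep(1 / n, n))
    } else resample_weights[[si]]
    totals <- loglik %*% W
    winners <- max.col(t(totals), ties.method = "first")
    bp[si, ] <- tabulate(winners, nrow(loglik)) / ncol(W)
  }
  structure(bp, scales = scales, n_boot = n_boot)
}

#' Approximately unbiased p-value from multiscale bootstrap proportions
#'
#' Fits the multiscale bootstrap model
#' `qnorm(1 - BP_r) = d * sqrt(r) + c / sqrt(r)` by weighted least squares
#' (weights from the binomial variance of BP via the delta method) and
#' returns `p_AU = 1 - pnorm(d - c)`. BP values are clamped to
#' `[0.5/n_boot, 1 - 0.5/n_boot]` before the probit transform; if fewer
#' than 3 scales remain strictly inside the clamp bounds the fit is
#' degenerate and p is 0 or 1 according to which bound dominates.
#'
#' @param bp Numeric vector of bootstrap proportions, one per scale (a
#'   single candidate's column of [rell_bootstrap()] output).
#' @param scales Scales r matching `bp` (taken from the attribute when
#'   `bp` comes straight from `rell_bootstrap`).
#' @param n_boot Bootstrap replicates per scale.
#' @return List of class `au_fit`: `p_au`, `d`, `c`, `bp`, `scales`,
#'   `residuals` (weighted), `degenerate`.
#' @export
au_pvalue <- function(bp, scales = attr(bp, "scales"),
                      n_boot = attr(bp, "n_boot")) {
  if (is.null(scales)) scales <- seq(0.5, 1.4, by = 0.1)
  if (is.null(n_boot)) n_boot <- 1000L
  bp <- as.numeric(bp)
  stopifnot(length(bp) == length(scales), all(scales > 0), n_boot >= 1)
  lo <- 0.5 / n_boot
  hi <- 1 - lo
  clamped <- pmin(pmax(bp, lo), hi)
  interior <- bp > lo & bp < hi
  if (sum(interior) < 3L) {
    p <- if (mean(clamped) >= 0.5) 1 else 0
    return(structure(list(p_au = p, d = NA_real_, c = NA_real_, bp = bp,
                          scales = scales, residuals = NULL,
                          degenerate = TRUE), class = "au_fit"))
  }
  z <- stats::qnorm(1 - clamped)
  w <- n_boot * stats::dnorm(z)^2 / (clamped * (1 - clamped))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(X, z, w)
  d <- fit$coefficients[1]
  cc <- fit$coefficients[2]
  structure(list(p_au = unname(1 - stats::pnorm(d - cc)), d = unname(d),
                 c = unname(cc), bp = bp, scales = scales,
                 residuals = sqrt(w) * fit$residuals, degenerate = FALSE),
            class = "au_fit")
}

#' @export
print.au_fit <- function(x, ...) {
  cat("AU fit: p =", signif(x$p_au, 4), " d =", signif(x$d, 4),
      " c =", signif(x$c, 4),
      if (x$degenerate) " [degenerate]" else "", "\n")
  invisible(x)
}

#' Interrogate one gene against a set of candidate topologies
#'
#' Gene genealogy interrogation for a single alignment: each candidate
#' topology gets its branch lengths optimized, per-site log-likelihoods
#' are computed, Delta-L is the drop from the best candidate's total
#' log-likelihood (so the best fit has Delta-L = 0), and AU p-values come
#' from a joint RELL multiscale bootstrap across candidates.
#'
#' @param aln Character alignment matrix (see [read_alignment()]).
#' @param candidates List of rooted binary `phylo` topologies spanning
#'   the alignment's taxa (species-level topologies are expanded with
#'   `species_map` when samples outnumber species).
#' @param model A [substitution_model()].
#' @param species_map Optional named character vector mapping sample
#'   labels to species (see [expand_topology()]).
#' @param scales,n_boot,seed Passed to [rell_bootstrap()]. The default
#'   splits 10,000 total resamplings evenly over the 10 scales.
#' @param gene_id Identifier attached to the record (and to error
#'   messages).
#' @return A `ggi_record`: list with `gene`, `loglik`, `delta`, `p_au`,
#'   `best` (index), `tie`, `degenerate` (logical per candidate).
#' @export
interrogate_gene <- function(aln, candidates, model, species_map = NULL,
                             scales = seq(0.5, 1.4, by = 0.1),
                             n_boot = 1000L, seed = NULL, gene_id = "gene") {
  set_seed_if(seed)
  ncand <- length(candidates)
  stopifnot(ncand >= 2L)
  sitell <- NULL
  loglik <- numeric(ncand)
  for (i in seq_len(ncand)) {
    topo <- candidates[[i]]
    if (!is.null(species_map)) topo <- expand_topology(topo, species_map)
    fit <- tryCatch(optimize_branch_lengths(topo, aln, model),
                    error = function(e)
                      stop("gene '", gene_id, "', candidate ", i, ": ",
                           conditionMessage(e)))
    sl <- site_loglik(fit$tree, aln, model)
    if (is.null(sitell)) sitell <- matrix(0, ncand, length(sl))
    sitell[i, ] <- sl
    loglik[i] <- sum(sl)
  }
  delta <- max(loglik) - loglik
  best <- which.min(delta)
  tie <- sum(delta < 1e-9) > 1L
  bp <- rell_bootstrap(sitell, scales = scales, n_boot = n_boot)
  fits <- lapply(seq_len(ncand), function(i) au_pvalue(bp[, i], scales, n_boot))
  structure(list(gene = gene_id, loglik = loglik, delta = delta,
                 p_au = vapply(fits, `[[`, 0, "p_au"), best = best,
                 tie = tie,
                 degenerate = vapply(fits, `[[`, TRUE, "degenerate"),
                 au_fits = fits),
            class = "ggi_record")
}

#' Run gene genealogy interrogation over many genes
#'
#' @param alignments Named list of alignment matrices, or a directory of
#'   FASTA files (`*.fa`, `*.fasta`).
#' @inheritParams interrogate_gene
#' @param seed Integer seed; gene g uses `seed + g - 1` so runs are
#'   reproducible and order-independent per gene.
#' @return List of `ggi_record`s (class `ggi_records`).
#' @export
run_ggi <- function(alignments, candidates, model, species_map = NULL,
                    scales = seq(0.5, 1.4, by = 0.1), n_boot = 1000L,
                    seed = 1L) {
  if (is.character(alignments) && length(alignments) == 1L) {
    files <- sort(list.files(alignments, pattern = "\\.(fa|fasta)$",
                             full.names = TRUE))
    if (!length(files)) stop("no FASTA files found in ", alignments)
    alignments <- stats::setNames(lapply(files, read_alignment),
                                  sub("\\.(fa|fasta)$", "", basename(files)))
  }
  ids <- names(alignments)
  if (is.null(ids)) ids <- sprintf("gene%04d", seq_along(alignments))
  recs <- lapply(seq_along(alignments), function(g)
    interrogate_gene(alignments[[g]], candidates, model,
                     species_map = species_map, scales = scales,
                     n_boot = n_boot, seed = seed + g - 1L,
                     gene_id = ids[g]))
  structure(recs, class = "ggi_records")
}

#' Summarize GGI records per candidate topology
#'
#' Counts, per candidate: `n_best` (genes whose lowest Delta-L selects
#' it; ties go to the lowest index and are tallied separately) and
#' `n_not_rejected` (genes with AU p >= alpha). A single gene can fail to
#' reject several topologies, so `sum(n_not_rejected)` may exceed the
#' number of genes; the summary notes when it does.
#'
#' @param records List of `ggi_record`s.
#' @param alpha Rejection threshold for "unable to reject" (default 0.05).
#' @param topology_names Optional labels for the candidates.
#' @return A `ggi_summary`: data frame `table` plus `alpha`, `n_genes`,
#'   `n_ties`, `note`.
#' @export
summarize_ggi <- function(records, alpha = 0.05, topology_names = NULL) {
  stopifnot(length(records) >= 1L)
  ncand <- length(records[[1]]$delta)
  if (is.null(topology_names))
    topology_names <- sprintf("T%02d", seq_len(ncand))
  n_best <- integer(ncand)
  n_not_rejected <- integer(ncand)
  n_ties <- 0L
  for (r in records) {
    n_best[r$best] <- n_best[r$best] + 1L
    if (r$tie) n_ties <- n_ties + 1L
    keep <- r$p_au >= alpha
    n_not_rejected[keep] <- n_not_rejected[keep] + 1L
  }
  tab <- data.frame(topology = topology_names, n_best = n_best,
                    n_not_rejected = n_not_rejected,
                    stringsAsFactors = FALSE)
  note <- if (sum(n_not_rejected) > length(records))
    sprintf("sum of not-rejected gene counts (%d) exceeds the gene count (%d): genes can fail to reject several topologies",
            sum(n_not_rejected), length(records)) else NA_character_
  structure(list(table = tab, alpha = alpha, n_genes = length(records),
                 n_ties = n_ties, note = note), class = "ggi_summary")
}

#' @export
print.ggi_summary <- function(x, ...) {
  cat("GGI summary over", x$n_genes, "genes (alpha =", x$alpha, ")\n")
  print(x$table, row.names = FALSE)
  if (x$n_ties) cat(x$n_ties, "gene(s) had tied best fits\n")
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Write per-gene GGI records as a tidy table
#'
#' @param records `ggi_records` list.
#' @param topology_names Optional candidate labels.
#' @return Data frame: gene, topology, loglik, delta, p_au, best.
#' @export
ggi_table <- function(records, topology_names = NULL) {
  ncand <- length(records[[1]]$delta)
  if (is.null(topology_names))
    topology_names <- sprintf("T%02d", seq_len(ncand))
  do.call(rbind, lapply(records, function(r)
    data.frame(gene = r$gene, topology = topology_names,
               loglik = r$loglik, delta = r$delta, p_au = r$p_au,
               best = seq_len(ncand) == r$best,
               stringsAsFactors = FALSE)))
}
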