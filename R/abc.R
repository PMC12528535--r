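#' Microsatellite summary statistics
#'
#' Computes the ABC statistic set from a genotype table: per population
#' the mean number of alleles per locus (K), the mean unbiased expected
#' heterozygosity (Nei's H with sample-size correction) and the mean
#' allele-size standard deviation; per population pair the
#' Weir-Cockerham FST (multi-locus ratio of variance-component sums) and
#' Goldstein's mean squared allele-size difference (delta-mu)^2; plus the
#' global total allele count.
#'
#' @param ssr Genotype data frame from [simulate_ssr()] (columns
#'   `individual`, `population`, `L<k>.a1/.a2`).
#' @param populations Optional population ordering (default: sorted
#'   unique labels).
#' @return Named numeric vector (a summary-statistic vector). Monomorphic
#'   pairs get FST 0 with a warning.
#' @export
ssr_sumstats <- function(ssr, populations = NULL) {
  m <- ssr_table_to_matrix(ssr)
  if (is.null(populations)) populations <- sort(unique(ssr$population))
  counts <- table(ssr$population)[populations]
  if (any(is.na(counts)) || any(counts < 2))
    stop("need >= 2 individuals per population")
  sumstats_from_matrix(m$alleles, m$pop, populations)
}

# alleles: (2*n_ind) x n_loci integer matrix; pop: per-lineage labels.
# Heavy lifting is in C++ (cpp_ssr_sumstats); names and the monomorphic-FST
# convention (NA -> 0 with warning) are applied here.
sumstats_from_matrix <- function(alleles, pop, populations) {
  pop_idx <- match(pop, populations) - 1L
  if (any(is.na(pop_idx))) stop("population labels not in 'populations'")
  raw <- cpp_ssr_sumstats(alleles, pop_idx, length(populations))
  nms <- unlist(lapply(populations, function(p) paste0(c("K_", "H_", "sd_"), p)))
  if (length(populations) >= 2) {
    prs <- utils::combn(populations, 2)
    nms <- c(nms, as.vector(rbind(paste0("fst_", prs[1, ], "_", prs[2, ]),
                                  paste0("dmu2_", prs[1, ], "_", prs[2, ]))))
  }
  nms <- c(nms, "K_total")
  out <- stats::setNames(raw, nms)
  bad <- is.na(out) & startsWith(nms, "fst_")
  if (any(bad)) {
    warning("FST undefined (monomorphic) for pair(s) ",
            paste(sub("^fst_", "", nms[bad]), collapse = ", "),
            "; set to 0", call. = FALSE)
    out[bad] <- 0
  }
  out
}

#' Weir-Cockerham FST for a pair of populations
#'
#' Multi-allele, multi-locus theta of Weir & Cockerham (1984): variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals) are summed over alleles and
#' loci, with theta = sum(a) / sum(a + b + c). Individuals are
#' consecutive lineage pairs.
#'
#' @param alleles (2 x n_ind) x n_loci matrix of allele sizes.
#' @param pop Per-lineage population labels.
#' @param pair Length-2 character vector of population labels.
#' @return FST, or `NA` when every locus is monomorphic across the pair.
#' @export
wc_fst <- function(alleles, pop, pair) {
  keep <- pop %in% pair
  al <- alleles[keep, , drop = FALSE]
  gpop <- pop[keep]
  A <- B <- C <- 0
  r <- 2
  for (l in seq_len(ncol(al))) {
    sizes <- al[, l]
    uall <- unique(sizes)
    if (length(uall) < 2) next
    n_i <- c(sum(gpop == pair[1]) / 2, sum(gpop == pair[2]) / 2)
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (allele in uall) {
      p_i <- h_i <- numeric(2)
      for (k in 1:2) {
        rows <- which(gpop == pair[k])
        g1 <- sizes[rows[c(TRUE, FALSE)]]
        g2 <- sizes[rows[c(FALSE, TRUE)]]
        p_i[k] <- mean(c(g1, g2) == allele)
        h_i[k] <- mean((g1 == allele) != (g2 == allele))
      }
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                               hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  if (A + B + C == 0) return(NA_real_)
  A / (A + B + C)
}

#' Greedy correlation filter for summary statistics
#'
#' Single deterministic pass in column order: a statistic is kept iff its
#' absolute Pearson correlation with every previously kept statistic is
#' <= `threshold`. Zero-variance columns are dropped with a warning.
#'
#' @param stat_matrix Numeric matrix (simulations x statistics) with
#'   column names; >= 10 rows, >= 2 columns.
#' @param threshold Absolute-correlation cutoff (default 0.8).
#' @return Character vector of retained statistic names.
#' @export
filter_correlated_stats <- function(stat_matrix, threshold = 0.8) {
  stopifnot(is.matrix(stat_matrix), ncol(stat_matrix) >= 2,
            nrow(stat_matrix) >= 10)
  nms <- colnames(stat_matrix)
  if (is.null(nms)) nms <- paste0("S", seq_len(ncol(stat_matrix)))
  sds <- apply(stat_matrix, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance statistic(s): ",
            paste(nms[sds == 0], collapse = ", "))
  }
  kept <- character(0)
  kept_idx <- integer(0)
  for (j in seq_len(ncol(stat_matrix))) {
    if (sds[j] == 0) next
    ok <- TRUE
    for (i in kept_idx) {
      if (abs(stats::cor(stat_matrix[, i], stat_matrix[, j])) > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      kept <- c(kept, nms[j])
      kept_idx <- c(kept_idx, j)
    }
  }
  kept
}

#' Simulate an ABC reference table of microsatellite summary statistics
#'
#' For each listed template, `n_per_model` parameter draws from the
#' priors ([draw_scenario_params()]) are each turned into one simulated
#' SSR panel and its summary-statistic vector.
#'
#' @param templates Character vector of scenario templates (`"a"`..`"i"`).
#' @param n_per_model Simulations per template.
#' @param diploids Named integer vector of diploid individuals per
#'   population (default 15 each for att, dai, lgk, mus).
#' @param n_loci Number of SSR loci (default 12).
#' @param mu_ssr SSR mutation rate per locus per generation.
#' @param seed Optional integer seed.
#' @return A `sim_table`: data frame with `model`, the drawn parameters,
#'   and one column per summary statistic; attributes `stat_names`,
#'   `param_names`, `seed`, `panel`.
#' @export
simulate_reference_table <- function(templates, n_per_model,
                                     diploids = c(att = 15, dai = 15,
                                                  lgk = 15, mus = 15),
                                     n_loci = 12, mu_ssr = 5e-4,
                                     seed = NULL) {
  set_seed_if(seed)
  param_names <- c("N", "t1", "t2", "t3", "t_h", "gamma")
  blocks <- lapply(templates, function(tmpl) {
    pars <- draw_scenario_params(tmpl, n_per_model)
    pops <- names(diploids)
    samples <- 2L * as.integer(diploids)
    stat_rows <- vector("list", n_per_model)
    for (i in seq_len(n_per_model)) {
      sc <- get_scenario(tmpl, params = as.list(pars[i, param_names]),
                        mu_ssr = mu_ssr)
      counts <- integer(length(sc$populations))
      names(counts) <- sc$populations
      counts[pops] <- samples
      al <- cpp_ssr_panel(counts, unname(sc$sizes),
                          scenario_event_matrix(sc), as.integer(n_loci),
                          mu_ssr)
      stat_rows[[i]] <- sumstats_from_matrix(
        al, rep(sc$populations, counts), sort(pops))
    }
    cbind(data.frame(model = tmpl, stringsAsFactors = FALSE), pars,
          do.call(rbind, stat_rows))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "stat_names") <- setdiff(names(out), c("model", param_names))
  attr(out, "param_names") <- param_names
  attr(out, "panel") <- list(diploids = diploids, n_loci = n_loci,
                             mu_ssr = mu_ssr)
  class(out) <- c("sim_table", "data.frame")
  out
}

# median-absolute-deviation standardization shared by selection/estimation
abc_distances <- function(observed, table, stats) {
  X <- as.matrix(table[, stats, drop = FALSE])
  obs <- observed[stats]
  if (any(is.na(obs))) stop("observed vector lacks statistic(s): ",
                            paste(stats[is.na(obs)], collapse = ", "))
  mads <- apply(X, 2, stats::mad)
  mads[mads == 0] <- 1
  Xs <- sweep(X, 2, mads, "/")
  obs_s <- obs / mads
  sqrt(colSums((t(Xs) - obs_s)^2))
}

#' Rejection-ABC model selection
#'
#' Statistics are standardized by their median absolute deviation over
#' the pooled table; the `n_retain` simulations nearest to the observed
#' vector in Euclidean distance are retained, and each model's posterior
#' probability is its share among them.
#'
#' @param observed Named numeric summary-statistic vector
#'   ([ssr_sumstats()]).
#' @param table A `sim_table` from [simulate_reference_table()].
#' @param n_retain Number of retained simulations (default 5000).
#' @param stats Statistic names to use (default: the table's full set,
#'   typically pre-filtered with [filter_correlated_stats()]).
#' @return List of class `abc_model_posterior`: `posterior` (named,
#'   sums to 1), `n_retain`, `distance_quantile`, `retained` (row
#'   indices).
#' @export
abc_select_model <- function(observed, table, n_retain = 5000,
                             stats = attr(table, "stat_names")) {
  if (n_retain > nrow(table))
    stop("n_retain (", n_retain, ") exceeds table rows (", nrow(table), ")")
  d <- abc_distances(observed, table, stats)
  keep <- order(d)[seq_len(n_retain)]
  models <- sort(unique(table$model))
  post <- table(factor(table$model[keep], levels = models)) / n_retain
  structure(list(posterior = stats::setNames(as.numeric(post), models),
                 n_retain = n_retain,
                 distance_quantile = n_retain / nrow(table),
                 retained = keep),
            class = "abc_model_posterior")
}

#' @export
print.abc_model_posterior <- function(x, ...) {
  cat("ABC model posterior (", x$n_retain, "retained,",
      signif(100 * x$distance_quantile, 3), "% ):\n")
  print(round(x$posterior, 4))
  invisible(x)
}

#' Rejection-ABC parameter estimation for one model
#'
#' The `n_retain` simulations of `model` nearest to the observed vector
#' are retained; each parameter is log-transformed, summarized by its
#' median and 2.5/97.5 percentiles, and back-transformed.
#'
#' @inheritParams abc_select_model
#' @param model Template id whose rows to use.
#' @param n_retain Retained simulations (default 2000).
#' @param log_transform Log-transform parameters before summarizing
#'   (default `TRUE`; errors on non-positive values, naming the
#'   parameter).
#' @return List of class `abc_parameter_posterior`: `summary` (data frame
#'   parameter/median/lower/upper), `samples` (retained, back-transformed),
#'   `n_retain`.
#' @export
abc_estimate_parameters <- function(observed, table, model,
                                    n_retain = 2000,
                                    stats = attr(table, "stat_names"),
                                    log_transform = TRUE) {
  rows <- table[table$model == model, , drop = FALSE]
  if (nrow(rows) < n_retain)
    stop("model '", model, "' has ", nrow(rows), " rows < n_retain = ",
         n_retain)
  d <- abc_distances(observed, rows, stats)
  keep <- order(d)[seq_len(n_retain)]
  pnames <- attr(table, "param_names")
  if (is.null(pnames))
    pnames <- setdiff(names(rows), c("model", stats))
  samples <- rows[keep, pnames, drop = FALSE]
  samples <- samples[, colSums(!is.na(samples)) > 0, drop = FALSE]
  summ <- lapply(names(samples), function(p) {
    x <- samples[[p]]
    if (log_transform) {
      if (any(x <= 0)) stop("parameter '", p,
                            "' has non-positive values; cannot log-transform")
      q <- exp(stats::quantile(log(x), c(0.5, 0.025, 0.975), names = FALSE))
    } else {
      q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
    }
    data.frame(parameter = p, median = q[1], lower = q[2], upper = q[3])
  })
  structure(list(summary = do.call(rbind, summ), samples = samples,
                 n_retain = n_retain, log_transform = log_transform),
            class = "abc_parameter_posterior")
}

#' @export
print.abc_parameter_posterior <- function(x, ...) {
  cat("ABC parameter posterior (", x$n_retain, "retained",
      if (x$log_transform) ", log scale" else "", "):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
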