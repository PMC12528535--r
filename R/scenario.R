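#' Define a demographic scenario
#'
#' A scenario is a set of populations with constant diploid effective
#' sizes, plus a backward-in-time event schedule: population merges
#' (divergences, viewed backward) and pulse admixture events (each lineage
#' in the recipient jumps to the donor with probability `gamma`).
#' Validation checks that event times are positive and ordered, that every
#' event references populations still alive at its time, and that exactly
#' one population survives after the final merge.
#'
#' @param populations Character vector of population labels.
#' @param sizes Named numeric vector of diploid effective sizes N (one per
#'   population; pairwise coalescence rate within a population is 1/(2N)
#'   per generation).
#' @param events Data frame with columns `time` (generations, > 0), `type`
#'   (`"merge"` or `"admixture"`), `from`, `to` (population labels) and
#'   `gamma` (admixture proportion in \[0, 1\]; ignored for merges).
#' @param mu Per-site per-generation substitution rate for sequence
#'   simulation.
#' @param mu_ssr Per-locus per-generation microsatellite mutation rate.
#' @param generation_time Years per generation (used only to report times
#'   in years).
#' @return An object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(populations, sizes, events,
                                 mu = 5e-9, mu_ssr = 5e-4,
                                 generation_time = 1) {
  stopifnot(is.character(populations), length(populations) >= 1,
            !anyDuplicated(populations))
  if (is.null(names(sizes)) || !setequal(names(sizes), populations))
    stop("sizes must be named for every population")
  if (any(sizes <= 0)) stop("population sizes must be positive")
  if (mu < 0) stop("mu must be non-negative")
  if (mu_ssr < 0) stop("mu_ssr must be non-negative")
  stopifnot(is.data.frame(events),
            all(c("time", "type", "from", "to") %in% names(events)))
  if (is.null(events$gamma)) events$gamma <- rep(NA_real_, nrow(events))
  if (nrow(events)) {
    if (any(events$time <= 0)) stop("event times must be strictly positive")
    if (!all(events$type %in% c("merge", "admixture")))
      stop("event type must be 'merge' or 'admixture'")
    bad <- setdiff(c(events$from, events$to), populations)
    if (length(bad)) stop("event references unknown population(s): ",
                          paste(bad, collapse = ", "))
    adm <- events$type == "admixture"
    if (any(adm & (is.na(events$gamma) | events$gamma < 0 | events$gamma > 1)))
      stop("admixture gamma must lie in [0, 1]")
    events <- events[order(events$time), , drop = FALSE]
  }
  # liveness check: merges absorb 'from'; later events must not use it
  alive <- populations
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!(ev$from %in% alive) || !(ev$to %in% alive))
      stop("event at time ", ev$time, " references absorbed population ",
           setdiff(c(ev$from, ev$to), alive)[1])
    if (ev$from == ev$to) stop("event cannot reference a single population twice")
    if (ev$type == "merge") alive <- setdiff(alive, ev$from)
  }
  if (length(alive) != 1L)
    stop(length(alive), " populations remain unabsorbed at the oldest time (",
         paste(alive, collapse = ", "), "); exactly one must remain")
  structure(list(populations = populations, sizes = sizes[populations],
                 events = events, mu = mu, mu_ssr = mu_ssr,
                 generation_time = generation_time),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("Demographic scenario:", length(x$populations), "populations (",
      paste(x$populations, collapse = ", "), ")\n")
  if (nrow(x$events)) {
    cat("events (backward in time):\n")
    print(x$events, row.names = FALSE)
  }
  cat("mu =", x$mu, " mu_ssr =", x$mu_ssr,
      " generation time =", x$generation_time, "yr\n")
  invisible(x)
}

# 0-based event matrix for the C++ engine
scenario_event_matrix <- function(scenario) {
  ev <- scenario$events
  if (!nrow(ev)) return(matrix(0, 0, 5))
  cbind(ev$time, ifelse(ev$type == "merge", 0, 1),
        match(ev$from, scenario$populations) - 1L,
        match(ev$to, scenario$populations) - 1L,
        ifelse(is.na(ev$gamma), 0, ev$gamma))
}

#' Registry of the nine demographic scenario templates
#'
#' Nine templates (`a`-`i`) for four ingroup taxa (att, dai, lgk, mus)
#' grouped in four hypothesis classes:
#' H1 hybrid origin of mus from att and dai (`a`, `b`); H2 the species
#' tree (((att,lgk),mus),dai) (`c`); H3 dai sister to mus (`d`, `e`, `f`);
#' H4 a (dai,lgk) clade (`g`, `h`, `i`). The class-defining feature of
#' each template is fixed; within-class variants enumerate the remaining
#' arrangements of the other taxa.
#'
#' @return A data frame with columns `template`, `class`, `description`.
#' @export
scenario_registry <- function() {
  data.frame(
    template = letters[1:9],
    class = c("H1", "H1", "H2", "H3", "H3", "H3", "H4", "H4", "H4"),
    description = c(
      "mus = hybrid(att, dai); backbone ((att,lgk),dai)",
      "mus = hybrid(att, dai); backbone ((att,dai),lgk)",
      "species tree (((att,lgk),mus),dai)",
      "(((dai,mus),att),lgk)",
      "(((dai,mus),lgk),att)",
      "((dai,mus),(att,lgk))",
      "(((dai,lgk),att),mus)",
      "(((dai,lgk),mus),att)",
      "((dai,lgk),(att,mus))"),
    stringsAsFactors = FALSE)
}

#' Instantiate a scenario template
#'
#' Builds a [demographic_scenario()] from one of the nine registry
#' templates. Defaults follow the study system's scale: divergence times
#' `t1 < t2 < t3` of 8800, 18600 and 93100 generations (the best-model
#' point estimates at a one-year generation time), a shared diploid size
#' of 10000, hybridization time `t_h = t1/2` and admixture proportion 0.5
#' for the hybrid templates. An outgroup population (`ela`) joining at
#' `outgroup_time` can be added for sequence work.
#'
#' @param template One of `"a"`..`"i"`.
#' @param params Optional named list overriding `N`, `t1`, `t2`, `t3`,
#'   `t_h`, `gamma`.
#' @param outgroup_time If non-`NULL`, add population `ela` merging into
#'   the final ancestor at this time (generations).
#' @param mu,mu_ssr,generation_time Passed to [demographic_scenario()].
#' @return A `demographic_scenario` with attribute `template`.
#' @export
get_scenario <- function(template, params = list(), outgroup_time = NULL,
                         mu = 5e-9, mu_ssr = 5e-4, generation_time = 1) {
  reg <- scenario_registry()
  if (!template %in% reg$template)
    stop("unknown template '", template, "'; available: ",
         paste(reg$template, collapse = ", "))
  p <- utils::modifyList(list(N = 1e4, t1 = 8800, t2 = 18600, t3 = 93100,
                              t_h = NA_real_, gamma = 0.5), params)
  if (is.na(p$t_h)) p$t_h <- p$t1 / 2
  if (template %in% c("a", "b")) {
    if (!(p$t_h < p$t1 && p$t1 < p$t2))
      stop("hybrid templates need t_h < t1 < t2")
  } else if (!(p$t1 < p$t2 && p$t2 < p$t3)) stop("need t1 < t2 < t3")
  mg <- function(time, from, to)
    data.frame(time = time, type = "merge", from = from, to = to,
               gamma = NA_real_)
  ad <- function(time, from, to, gamma)
    data.frame(time = time, type = "admixture", from = from, to = to,
               gamma = gamma)
  hyb <- function(backbone) rbind(
    ad(p$t_h, "mus", "att", p$gamma), mg(p$t_h * (1 + 1e-12), "mus", "dai"),
    backbone)
  ev <- switch(template,
    a = hyb(rbind(mg(p$t1, "lgk", "att"), mg(p$t2, "dai", "att"))),
    b = hyb(rbind(mg(p$t1, "dai", "att"), mg(p$t2, "lgk", "att"))),
    c = rbind(mg(p$t1, "lgk", "att"), mg(p$t2, "mus", "att"),
              mg(p$t3, "dai", "att")),
    d = rbind(mg(p$t1, "mus", "dai"), mg(p$t2, "att", "dai"),
              mg(p$t3, "lgk", "dai")),
    e = rbind(mg(p$t1, "mus", "dai"), mg(p$t2, "lgk", "dai"),
              mg(p$t3, "att", "dai")),
    f = rbind(mg(p$t1, "mus", "dai"), mg(p$t2, "lgk", "att"),
              mg(p$t3, "att", "dai")),
    g = rbind(mg(p$t1, "lgk", "dai"), mg(p$t2, "att", "dai"),
              mg(p$t3, "mus", "dai")),
    h = rbind(mg(p$t1, "lgk", "dai"), mg(p$t2, "mus", "dai"),
              mg(p$t3, "att", "dai")),
    i = rbind(mg(p$t1, "lgk", "dai"), mg(p$t2, "mus", "att"),
              mg(p$t3, "att", "dai")))
  pops <- c("att", "dai", "lgk", "mus")
  # the population surviving the last merge receives the outgroup
  alive <- pops
  for (k in seq_len(nrow(ev))) if (ev$type[k] == "merge")
    alive <- setdiff(alive, ev$from[k])
  final <- alive
  if (!is.null(outgroup_time)) {
    if (outgroup_time <= p$t3) stop("outgroup_time must exceed t3")
    pops <- c(pops, "ela")
    ev <- rbind(ev, mg(outgroup_time, final, "ela"))
  }
  sizes <- stats::setNames(rep(p$N, length(pops)), pops)
  sc <- demographic_scenario(pops, sizes, ev, mu = mu, mu_ssr = mu_ssr,
                             generation_time = generation_time)
  attr(sc, "template") <- template
  attr(sc, "params") <- p
  sc
}

#' Prior specification for a scenario template's free parameters
#'
#' ABC priors: log-uniform divergence/hybridization times on
#' \[1e2, 1e6\] generations (three draws sorted into `t1 < t2 < t3`;
#' hybrid templates use `t_h` uniform-in-log below `t1`), a shared
#' log-uniform diploid size N on \[1e2, 1e6\], and gamma uniform on (0, 1)
#' for hybrid templates.
#'
#' @param template One of `"a"`..`"i"`.
#' @param n Number of parameter draws.
#' @return Data frame of parameter draws (columns `N`, `t1`, `t2`, `t3`,
#'   `t_h`, `gamma`; unused ones `NA`).
#' @export
draw_scenario_params <- function(template, n) {
  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  if (template %in% c("a", "b")) {
    times <- matrix(runif_log(2 * n, 1e2, 1e6), ncol = 2)
    times <- t(apply(times, 1, sort))
    out <- data.frame(N = runif_log(n, 1e2, 1e6),
                      t1 = times[, 1], t2 = times[, 2], t3 = NA_real_,
                      t_h = NA_real_, gamma = stats::runif(n))
    out$t_h <- exp(stats::runif(n, log(1e2), log(pmax(out$t1, 1e2 + 1))))
    out$t_h <- pmin(out$t_h, out$t1 * 0.999)
  } else {
    times <- matrix(runif_log(3 * n, 1e2, 1e6), ncol = 3)
    times <- t(apply(times, 1, sort))
    out <- data.frame(N = runif_log(n, 1e2, 1e6),
                      t1 = times[, 1], t2 = times[, 2], t3 = times[, 3],
                      t_h = NA_real_, gamma = NA_real_)
  }
  out
}
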