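#' Enumerate rooted binary leaf-labelled topologies
#'
#' Generates every distinct rooted binary topology on `labels` by recursive
#' leaf insertion (a tree on k leaves offers 2k-1 attachment points for the
#' next leaf, giving the classical (2n-3)!! count). Constraints:
#'
#' * `groups` (monophyly): each group's labels must form a clade. The
#'   enumeration then runs over "super-leaves" (one per group) crossed with
#'   every within-group arrangement, so a single group of size g on n labels
#'   yields (2(n-g+1)-3)!! x (2g-3)!! trees.
#' * `outgroup`: one label fixed as sister to all others; enumeration runs
#'   over the remaining labels and the outgroup is attached at the root.
#'
#' Results are returned in deterministic canonical order (sorted canonical
#' Newick; see [canonical_topology()]).
#'
#' @param labels Character vector of leaf labels (>= 2, unique).
#' @param groups Optional list of character vectors, pairwise disjoint
#'   subsets of `labels`, each of size >= 2, to be constrained monophyletic.
#' @param outgroup Optional single label fixed as sister to everything else.
#' @return List of `phylo` topologies (no branch lengths); each carries a
#'   `canonical` attribute.
#' @examples
#' length(enumerate_topologies(c("att", "dai", "lgk", "mus")))  # 15
#' @export
enumerate_topologies <- function(labels, groups = NULL, outgroup = NULL) {
  stopifnot(is.character(labels), length(labels) >= 2L)
  if (anyDuplicated(labels)) stop("leaf labels must be unique")
  if (!is.null(outgroup)) {
    if (length(outgroup) != 1L || !outgroup %in% labels)
      stop("outgroup must be a single label among 'labels'")
    labels <- setdiff(labels, outgroup)
    if (length(labels) < 2L) stop("need >= 2 ingroup labels with an outgroup")
  }
  if (!is.null(groups)) {
    groups <- lapply(groups, as.character)
    all_g <- unlist(groups)
    if (anyDuplicated(all_g))
      stop("contradictory constraints: monophyly groups overlap")
    if (!all(all_g %in% labels))
      stop("constraint group references unknown label(s): ",
           paste(setdiff(all_g, labels), collapse = ", "))
  }
  newicks <- enumerate_strings(labels, groups)
  if (!is.null(outgroup))
    newicks <- paste0("(", newicks, ",", outgroup, ")")
  newicks <- sort(unique(newicks))
  out <- lapply(paste0(newicks, ";"), read_newick)
  for (i in seq_along(out)) attr(out[[i]], "canonical") <- paste0(newicks[i], ";")
  out
}

# all rooted binary shapes over labels with optional monophyly groups,
# as canonical (sorted-clade) Newick strings without semicolon
enumerate_strings <- function(labels, groups = NULL) {
  if (is.null(groups) || !length(groups)) return(enumerate_free(labels))
  placeholders <- sprintf(".grp%d.", seq_along(groups))
  free <- setdiff(labels, unlist(groups))
  backbone <- enumerate_free(c(placeholders, free))
  inner <- lapply(groups, enumerate_free)
  combos <- expand.grid(lapply(inner, seq_along), KEEP.OUT.ATTRS = FALSE)
  out <- character(0)
  for (bb in backbone) {
    for (r in seq_len(nrow(combos))) {
      s <- bb
      for (g in seq_along(groups)) {
        s <- sub(placeholders[g], inner[[g]][[combos[r, g]]], s, fixed = TRUE)
      }
      out <- c(out, s)
    }
  }
  # re-canonicalize: substitution can break sibling sort order
  vapply(out, function(s) canon_string(parse_nested(s)), character(1),
         USE.NAMES = FALSE)
}

enumerate_free <- function(labels) {
  labels <- sort(labels)
  if (length(labels) == 1L) return(labels)
  trees <- list(list(labels[1], labels[2]))
  for (lab in labels[-(1:2)]) {
    trees <- unlist(lapply(trees, insert_leaf, leaf = lab), recursive = FALSE)
  }
  sort(vapply(trees, canon_string, character(1)))
}

# attach `leaf` as sister to every node of the nested-list tree
insert_leaf <- function(tree, leaf) {
  res <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (r in insert_leaf(tree[[1]], leaf)) res <- c(res, list(list(r, tree[[2]])))
    for (r in insert_leaf(tree[[2]], leaf)) res <- c(res, list(list(tree[[1]], r)))
  }
  res
}

canon_string <- function(tree) {
  if (!is.list(tree)) return(tree)
  subs <- sort(c(canon_string(tree[[1]]), canon_string(tree[[2]])))
  paste0("(", paste(subs, collapse = ","), ")")
}

# minimal nested-list parser for topology-only Newick fragments
parse_nested <- function(s) {
  pos <- 1L
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  parse_node <- function() {
    if (chars[pos] == "(") {
      pos <<- pos + 1L
      kids <- list(parse_node())
      while (chars[pos] == ",") {
        pos <<- pos + 1L
        kids <- c(kids, list(parse_node()))
      }
      stopifnot(chars[pos] == ")")
      pos <<- pos + 1L
      if (length(kids) == 1L) return(kids[[1]])
      node <- kids[[1]]
      for (k in kids[-1]) node <- list(node, k)
      return(node)
    }
    start <- pos
    while (pos <= length(chars) && !chars[pos] %in% c(",", ")", "(")) pos <<- pos + 1L
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parse_node()
}

#' Expand a species-level topology to sample level
#'
#' Replaces each tip named for a species by a clade containing that
#' species' samples (a ladder in alphabetical order; the within-species
#' arrangement is arbitrary for constrained scoring and is fixed for
#' determinism). Species with a single sample keep a single tip renamed to
#' the sample. This realizes the "samples of the same species form a clade"
#' constraint when scoring genes with several conspecific samples.
#'
#' @param tree Species-level `phylo` topology.
#' @param species_map Named character vector: names are sample labels,
#'   values the species each belongs to.
#' @return Sample-level `phylo` topology.
#' @export
expand_topology <- function(tree, species_map) {
  stopifnot(!is.null(names(species_map)))
  nested <- parse_nested(sub(";$", "", write_newick(tree)))
  expand <- function(node) {
    if (is.list(node)) return(list(expand(node[[1]]), expand(node[[2]])))
    samples <- sort(names(species_map)[species_map == node])
    if (!length(samples)) stop("no samples mapped to species '", node, "'")
    sub <- samples[1]
    for (s in samples[-1]) sub <- list(sub, s)
    sub
  }
  to_str <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", to_str(node[[1]]), ",", to_str(node[[2]]), ")")
  }
  read_newick(paste0(to_str(expand(nested)), ";"))
}
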