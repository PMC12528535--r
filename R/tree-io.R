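#' Parse a Newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Beyond parsing, it
#' checks bracket balance (reporting the character offset of the first
#' violation), requires a terminal semicolon, rejects duplicate leaf labels
#' and negative or non-finite branch lengths, and flags polytomies.
#'
#' @param text A Newick string (exactly one tree).
#' @return An object of class `phylo`. Non-binary trees carry
#'   `attr(, "binary") = FALSE`.
#' @examples
#' tr <- read_newick("(((att,lgk),mus),dai);")
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unmatched ')' at character offset ", i)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' (string ends at offset ",
         length(chars), ")")
  if (!endsWith(text, ";"))
    stop("malformed Newick: missing terminal ';' at character offset ",
         length(chars) + 1L)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length)) {
    if (any(!is.finite(tr$edge.length)))
      stop("non-finite branch length")
    if (any(tr$edge.length < 0))
      stop("negative branch length")
  }
  attr(tr, "binary") <- is_binary_rooted(tr)
  tr
}

# rooted reading of binarity: every internal node has exactly two children
is_binary_rooted <- function(tr) {
  all(tabulate(tr$edge[, 1], nbins = length(tr$tip.label) + tr$Nnode) %in%
        c(0L, 2L))
}

#' Write a tree as a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string with terminal semicolon.
#' @export
write_newick <- function(tree, digits = 15) {
  ape::write.tree(tree, digits = digits)
}

#' Canonical topology string of a rooted tree
#'
#' Produces a label-sorted, branch-length-free Newick string that is
#' identical for isomorphic rooted topologies: at every internal node the
#' child subtree strings are sorted lexicographically. Used as the identity
#' key for candidate topologies throughout the package.
#'
#' @param tree A `phylo` object (polytomies allowed).
#' @return A character scalar ending in ";".
#' @export
canonical_topology <- function(tree) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    subs <- sort(vapply(children[[as.character(node)]], rec, character(1)))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}

#' Read a nucleotide alignment from FASTA
#'
#' Reads an aligned FASTA file (via [ape::read.FASTA()]) into the character
#' matrix representation used by the likelihood kernel: one row per
#' sequence, upper-case IUPAC characters, columns are sites.
#'
#' @param file Path to an aligned FASTA file.
#' @return A character matrix with sequence names as row names.
#' @export
read_alignment <- function(file) {
  dna <- ape::read.FASTA(file)
  len <- lengths(dna)
  if (length(unique(len)) != 1L)
    stop("sequences are not aligned: lengths ", paste(unique(len), collapse = ", "))
  m <- toupper(as.character(as.matrix(dna)))
  rownames(m) <- names(dna)
  m
}

#' Write a nucleotide alignment to FASTA
#'
#' @param aln Character matrix (taxa x sites) with row names.
#' @param file Output path.
#' @export
write_alignment <- function(aln, file) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1, paste, collapse = "")
  writeLines(lines, file)
}

#' Read / write multi-tree Newick files
#'
#' One tree per line; used for candidate topology sets and simulated
#' gene-tree banks.
#'
#' @param file Path.
#' @return `read_trees()`: a list of `phylo` objects.
#' @export
read_trees <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lapply(lines[nzchar(trimws(lines))], read_newick)
}

#' @rdname read_trees
#' @param trees List of `phylo` objects.
#' @export
write_trees <- function(trees, file) {
  writeLines(vapply(trees, write_newick, character(1)), file)
}
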