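## Newick serialisation of the UPGMA tree ---------------------------------
##
## The writer is its own small serialiser (rather than ape::write.tree) so
## that leaf labels containing whitespace or Newick metacharacters can be
## single-quoted per the Newick standard; round-trip tests reparse its
## output with ape as the independent parser.

.newick_quote <- function(label) {
  if (grepl("[][ \t(),:;']", label)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Write a tree in Newick format
#'
#' Accepts either a [upgma] result or an `ape::phylo` object; branch
#' lengths are always written and the string is terminated by ";". Leaf
#' labels containing spaces or Newick metacharacters are single-quoted.
#'
#' @param tree a `upgma_tree` or `phylo` object with branch lengths
#' @param path output file
#' @return the Newick string, invisibly
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "upgma_tree")) tree <- as_phylo(tree)
  if (!inherits(tree, "phylo")) stop("`tree` must be a upgma_tree or phylo")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label)))
    stop("every leaf must be labelled")
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(.newick_quote(tree$tip.label[node]))
    kid_edges <- children[[as.character(node)]]
    paste0("(", paste(vapply(kid_edges, function(e) {
      paste0(rec(tree$edge[e, 2]),
             ":", format(tree$edge.length[e], digits = 15))
    }, character(1)), collapse = ","), ")")
  }
  root <- ntip + 1L
  s <- paste0(rec(root), ";")
  writeLines(s, path)
  invisible(s)
}
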