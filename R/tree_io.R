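#' Parse and serialize Newick trees
#'
#' Wrappers around ape's Newick support. Trees are treated as unrooted;
#' missing branch lengths are filled in with a default of 0.1 (with a
#' warning), negative lengths are rejected, and duplicate leaf labels are
#' an error.
#'
#' @param text a Newick string.
#' @param default_length branch length substituted when absent.
#' @return `parse_newick` returns an ape `phylo`; `write_newick` returns a
#'   Newick string.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:2):1,C:3);")
parse_newick <- function(text, default_length = 0.1) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to ", default_length)
    tr$edge.length <- rep(default_length, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths; defaulting to ", default_length)
    tr$edge.length[is.na(tr$edge.length)] <- default_length
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (ape::Ntip(tr) > 2L) tr <- ape::unroot(tr)
  tr
}

#' @param tree an ape `phylo`.
#' @rdname parse_newick
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}
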