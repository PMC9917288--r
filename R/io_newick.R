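#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are written with six decimals; internal node labels (e.g.
#' bootstrap supports) are written when present.  Trees without branch lengths
#' get unit lengths.
#'
#' @param tree An `ape` `phylo` object with at least two leaves and unique leaf
#'   labels.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  len <- tree$edge.length
  if (is.null(len)) len <- rep(1, nrow(tree$edge))
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  lab <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    nl <- tree$node.label
    if (is.null(nl)) return("")
    v <- nl[node - n]
    if (is.na(v)) "" else as.character(v)
  }
  render <- function(node) {
    e <- kids[[as.character(node)]]
    if (is.null(e)) return(lab(node))
    parts <- vapply(e, function(i) {
      sprintf("%s:%.6f", render(tree$edge[i, 2L]), len[i])
    }, "")
    paste0("(", paste(parts, collapse = ","), ")", lab(node))
  }
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  writeLines(paste0(render(root), ";"), path)
  invisible(path)
}
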