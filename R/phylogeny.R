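#' Pairwise distance between two aligned (gapped) protein sequences
#'
#' Columns where either sequence has a gap are excluded.  The `p` model is the
#' mismatch proportion; `poisson` applies the Poisson correction
#' `-log(1 - p)`.
#'
#' @param aligned_a,aligned_b Gapped residue strings of equal length.
#' @param model `"p"` or `"poisson"`.
#' @return Distance (substitutions per site).
#' @export
pairwise_distance <- function(aligned_a, aligned_b,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned sequences must have equal length")
  x <- strsplit(aligned_a, "")[[1L]]
  y <- strsplit(aligned_b, "")[[1L]]
  keep <- x != "-" & y != "-"
  if (!any(keep)) stop("no dual-non-gap columns to compare")
  p <- mean(x[keep] != y[keep])
  if (model == "p") return(p)
  if (p >= 1) stop("p >= 1: Poisson distance infinite")
  -log(1 - p)
}

#' Distance matrix over a multiple alignment
#'
#' @param alignment Named character vector of equal-length gapped sequences.
#' @param model Passed to [pairwise_distance()].
#' @return Symmetric numeric matrix with zero diagonal and the sequence names
#'   as dimnames.
#' @export
alignment_distance_matrix <- function(alignment, model = "poisson") {
  n <- length(alignment)
  chars <- do.call(rbind, strsplit(unname(alignment), ""))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      keep <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(keep)) stop("no comparable columns between ",
                           names(alignment)[i], " and ", names(alignment)[j])
      p <- mean(chars[i, keep] != chars[j, keep])
      d[i, j] <- d[j, i] <- if (model == "p") p else {
        if (p >= 1) stop("p >= 1: Poisson distance infinite")
        -log(1 - p)
      }
    }
  }
  d
}

#' Multiple protein alignment
#'
#' Runs the MAFFT aligner (which must be on the PATH) on the input sequences;
#' input order and names are preserved and the result is uppercased.  With
#' exactly two sequences this reduces to a global pairwise alignment.
#'
#' @param seqs Named character vector of protein sequences (at least 2).
#' @param args Extra command-line arguments for MAFFT.
#' @return Named character vector of equal-length gapped sequences.
#' @export
progressive_align <- function(seqs, args = c("--auto", "--anysymbol")) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  if (!nzchar(Sys.which("mafft")))
    stop("the 'mafft' executable was not found on the PATH")
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  # temporary safe ids: mafft truncates/reorders nothing, but keep headers bare
  tmp_ids <- sprintf("s%06d", seq_along(seqs))
  writeLines(paste0(">", tmp_ids, "\n", unname(seqs)), fin)
  status <- system2("mafft", c(args, "--quiet", fin), stdout = fout)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  out <- Biostrings::readBStringSet(fout)
  aligned <- toupper(as.character(out))
  aligned <- aligned[match(tmp_ids, names(out))]
  names(aligned) <- names(seqs)
  aligned
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]); NJ is exact on additive
#' distance matrices.  Negative branch-length estimates are clamped to zero
#' and flagged in the `clamped` attribute.
#'
#' @param dm Symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(dm))) stop("distance matrix must have labels")
  tree <- ape::nj(as.dist(dm))
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Alignment columns are resampled with replacement `n_replicates` times; a
#' tree is rebuilt from each replicate and each internal edge of the original
#' tree receives the percentage of replicates containing its bipartition
#' (stored in `node.label`).
#'
#' @param alignment Named character vector of equal-length gapped sequences.
#' @param n_replicates Number of bootstrap replicates (default 200).
#' @param seed Random seed (resampling is fully reproducible under it).
#' @param model Distance model, see [pairwise_distance()].
#' @return The NJ tree of the full alignment with per-node support values in
#'   `[0, 100]`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 200L, seed = 42L,
                              model = "poisson") {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  tree <- nj_tree(alignment_distance_matrix(alignment, model))
  chars <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(chars) <- names(alignment)
  L <- ncol(chars)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    sub <- chars[, cols, drop = FALSE]
    aln_b <- apply(sub, 1L, paste, collapse = "")
    reps[[b]] <- nj_tree(alignment_distance_matrix(aln_b, model))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_replicates)
  support[1L] <- NA  # root of the unrooted representation carries no split
  tree$node.label <- support
  tree
}

#' Partition a tree into k clades
#'
#' Iteratively cuts the remaining edge with the largest length x support score
#' whose removal increases the number of leaf-containing components, until the
#' leaves fall into `k` groups.  Internal edges are preferred; pendant edges
#' are only cut when no internal edge can split a group further (needed for
#' the degenerate `k = leaf count` case).  Ties break deterministically by
#' edge index.
#'
#' @param tree A `phylo` tree, optionally with bootstrap supports in
#'   `node.label` (missing supports count as 100).
#' @param k Number of clades (default 3, the wheat serpin clade count).
#' @return Named character vector mapping each leaf to a clade label
#'   (`"I"`, `"II"`, ... in order of appearance along the tip order).
#' @export
cut_clades <- function(tree, k = 3L) {
  n <- length(tree$tip.label)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of leaves")
  edges <- tree$edge
  m <- nrow(edges)
  len <- tree$edge.length
  if (is.null(len)) len <- rep(1, m)
  support <- rep(100, m)
  if (!is.null(tree$node.label)) {
    child <- edges[, 2L]
    internal <- child > n
    lab <- suppressWarnings(as.numeric(tree$node.label[child[internal] - n]))
    support[internal][!is.na(lab)] <- lab[!is.na(lab)]
  }
  score <- len * support / 100
  is_internal <- edges[, 2L] > n
  active <- rep(TRUE, m)
  n_nodes <- max(edges)
  leaf_groups <- function(active) {
    parent <- seq_len(n_nodes)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in which(active)) {
      ri <- find(edges[e, 1L]); rj <- find(edges[e, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    vapply(seq_len(n), find, 1L)
  }
  groups <- leaf_groups(active)
  n_groups <- length(unique(groups))
  while (n_groups < k) {
    ord <- order(-score, seq_len(m))
    cut_made <- FALSE
    for (prefer_internal in c(TRUE, FALSE)) {
      for (e in ord) {
        if (!active[e] || is_internal[e] != prefer_internal) next
        trial <- active; trial[e] <- FALSE
        g <- leaf_groups(trial)
        if (length(unique(g)) > n_groups) {
          active <- trial; groups <- g; n_groups <- length(unique(g))
          cut_made <- TRUE
          break
        }
      }
      if (cut_made) break
    }
    if (!cut_made) stop("cannot partition the tree into ", k, " clades")
  }
  labels <- as.character(utils::as.roman(seq_len(k)))
  assignment <- character(n)
  seen <- integer(0)
  for (i in seq_len(n)) {
    g <- groups[i]
    if (!g %in% seen) seen <- c(seen, g)
    assignment[i] <- labels[match(g, seen)]
  }
  names(assignment) <- tree$tip.label
  assignment
}
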