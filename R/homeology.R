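#' Percent identity between two proteins
#'
#' Computed from the global alignment as matches over alignment columns
#' (global pairwise alignments contain no dual-gap columns).
#'
#' @param a,b Protein sequences.
#' @return Percentage in [0, 100].
#' @export
percent_identity <- function(a, b) {
  aln <- global_align(a, b)
  x <- strsplit(aln$a_aln, "")[[1L]]
  y <- strsplit(aln$b_aln, "")[[1L]]
  keep <- !(x == "-" & y == "-")
  100 * sum(x[keep] == y[keep] & x[keep] != "-") / sum(keep)
}

#' Build homeologue sets by identity clustering
#'
#' Single-linkage clustering on the graph with an edge between two genes when
#' their protein identity exceeds `identity_threshold` (strictly) and, when a
#' clade map is supplied, both genes fall in the same phylogenetic clade.
#' Each connected component is one homeologue set; its A:B:D pattern counts
#' the members per subgenome.  Genes with unknown subgenome form singleton
#' sets flagged `unplaced` with pattern `"0:0:0"`.
#'
#' @param genes Data frame with columns `gene_id`, `subgenome`
#'   (`"A"`/`"B"`/`"D"`/`"unknown"`), `protein`, and optionally `chromosome`
#'   and `start` (used for tandem detection).
#' @param identity_threshold Identity percentage; edges require identity
#'   strictly greater than this (default 80).
#' @param clades Optional named character vector mapping gene_id to clade.
#' @param tandem_max_distance Passed to [detect_tandem_duplicates()].
#' @return List of `triad_set` objects: `set_id`, `members` (data frame),
#'   `pattern` (e.g. `"1:1:1"`), `tandem_pairs`, `unplaced`.
#' @export
build_homeologue_sets <- function(genes, identity_threshold = 80,
                                  clades = NULL, tandem_max_distance = 5e5) {
  stopifnot(all(c("gene_id", "subgenome", "protein") %in% names(genes)))
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  placeable <- genes$subgenome %in% c("A", "B", "D")
  for (i in seq_len(n - 1L)) {
    if (!placeable[i]) next
    for (j in seq((i + 1L), n)) {
      if (!placeable[j]) next
      if (!is.null(clades)) {
        ci <- clades[[genes$gene_id[i]]]
        cj <- clades[[genes$gene_id[j]]]
        if (!is.null(ci) && !is.null(cj) && !identical(ci, cj)) next
      }
      if (percent_identity(genes$protein[i], genes$protein[j]) >
          identity_threshold) union2(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  sets <- split(seq_len(n), comp)
  out <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    idx <- sets[[k]]
    members <- genes[idx, setdiff(names(genes), "protein"), drop = FALSE]
    rownames(members) <- NULL
    unplaced <- !all(placeable[idx])
    cnt <- vapply(c("A", "B", "D"),
                  function(s) sum(members$subgenome == s), 0L)
    pattern <- if (unplaced) "0:0:0" else paste(cnt, collapse = ":")
    tandem <- if (all(c("chromosome", "start") %in% names(members)))
      detect_tandem_duplicates(members, tandem_max_distance)
      else data.frame(gene_a = character(0), gene_b = character(0))
    out[[k]] <- structure(list(set_id = "", members = members,
                               pattern = pattern, tandem_pairs = tandem,
                               unplaced = unplaced),
                          class = "triad_set")
  }
  ord <- order(vapply(out, function(s) s$members$gene_id[1L], ""))
  out <- out[ord]
  for (k in seq_along(out)) out[[k]]$set_id <- sprintf("HS%03d", k)
  out
}

#' @export
print.triad_set <- function(x, ...) {
  cat(sprintf("<triad_set> %s pattern %s: %s%s\n", x$set_id, x$pattern,
              paste(x$members$gene_id, collapse = ", "),
              if (nrow(x$tandem_pairs)) sprintf(" (%d tandem pair(s))",
                                                nrow(x$tandem_pairs)) else ""))
  invisible(x)
}

#' Flatten homeologue sets into a table
#'
#' @param sets List of `triad_set` objects from [build_homeologue_sets()].
#' @return Data frame with one row per member gene: `set_id`, `pattern`,
#'   `gene_id`, `subgenome`.
#' @export
triad_table <- function(sets) {
  do.call(rbind, lapply(sets, function(s) {
    data.frame(set_id = s$set_id, pattern = s$pattern,
               gene_id = s$members$gene_id, subgenome = s$members$subgenome,
               stringsAsFactors = FALSE)
  }))
}

#' Detect tandem duplicates within a homeologue set
#'
#' A pair of member genes is tandem when both lie on the same chromosome with
#' a start-to-start distance of at most `max_distance` (default 500 kb).
#'
#' @param members Data frame with columns `gene_id`, `chromosome`, `start`.
#' @param max_distance Maximum start-to-start distance in bp.
#' @return Data frame with columns `gene_a`, `gene_b`, `distance`.
#' @export
detect_tandem_duplicates <- function(members, max_distance = 5e5) {
  out <- list()
  n <- nrow(members)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq(i + 1L, n)) {
      if (members$chromosome[i] != members$chromosome[j]) next
      d <- abs(members$start[i] - members$start[j])
      if (d <= max_distance)
        out[[length(out) + 1L]] <- data.frame(
          gene_a = members$gene_id[i], gene_b = members$gene_id[j],
          distance = d, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(gene_a = character(0), gene_b = character(0),
                  distance = numeric(0))
}
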