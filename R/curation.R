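#' The reference serpin used for scaffold and RCL mapping
#'
#' Candidate proteins are curated by global alignment against a reference
#' serpin whose reactive-centre-loop (RCL) coordinates and conserved core
#' scaffold blocks are annotated.  The packaged default is a constructed,
#' synthetic AtSerpin1-like reference (the consensus hinge
#' `P17..P1 = EEGTEAAAATAVKITLR` followed by the LRS reactive centre at a
#' recorded position); any reference with the same JSON layout can be supplied.
#'
#' @param path Path to a reference JSON file with fields `protein`,
#'   `rcl_start` (0-based index of P17), `rcl_end` (half-open; P1 is at
#'   `rcl_end - 1`) and `core_blocks` (list of 0-based half-open intervals,
#'   all outside the RCL).  Default: the packaged synthetic reference.
#' @return An object of class `reference_serpin`.
#' @export
reference_serpin <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_serpin_synthetic.json",
                        package = "serpinome")
  }
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- ref$core_blocks
  if (is.list(blocks)) blocks <- do.call(rbind, blocks)
  blocks <- matrix(as.integer(blocks), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  stopifnot(ref$rcl_start < ref$rcl_end, ref$rcl_end <= nchar(ref$protein),
            all(diff(blocks[, 1L]) > 0),
            all(blocks[, 2L] <= ref$rcl_start | blocks[, 1L] >= ref$rcl_end + 3L))
  structure(list(protein = ref$protein,
                 rcl_start = as.integer(ref$rcl_start),
                 rcl_end = as.integer(ref$rcl_end),
                 core_blocks = blocks),
            class = "reference_serpin")
}

#' @export
print.reference_serpin <- function(x, ...) {
  cat(sprintf("<reference_serpin> %d aa, RCL [%d,%d), %d core blocks\n",
              nchar(x$protein), x$rcl_start, x$rcl_end, nrow(x$core_blocks)))
  invisible(x)
}

#' Serpin length gate
#'
#' A complete serpin scaffold (8-9 helices, 3 beta-sheets, RCL) requires
#' roughly 330-600 residues (typically ~400); candidates outside this window
#' cannot fold into a functional serpin.
#'
#' @param protein Residue string.
#' @param min_len,max_len Inclusive bounds (defaults 330 and 600).
#' @return List with `pass` (logical) and `reason` (`NA`, `"too_short"` or
#'   `"too_long"`).
#' @export
length_gate <- function(protein, min_len = 330L, max_len = 600L) {
  n <- nchar(protein)
  if (n < min_len) list(pass = FALSE, reason = "too_short")
  else if (n > max_len) list(pass = FALSE, reason = "too_long")
  else list(pass = TRUE, reason = NA_character_)
}

#' Global pairwise protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Thin wrapper around [Biostrings::pairwiseAlignment()] with the package
#' defaults (BLOSUM62, gap opening 10, gap extension 0.5; the cost of a gap of
#' length L is `open + extend * L`).
#'
#' @param a,b Protein sequences.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param substitution Name of the substitution matrix (a `Biostrings` data
#'   set) or a numeric matrix.
#' @return List of class `pairwise_alignment` with gapped strings `a_aln`,
#'   `b_aln` and the alignment `score`.
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         substitution = "BLOSUM62") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  mat <- if (is.matrix(substitution)) substitution
         else subst_matrix(substitution)
  pw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(a_aln = as.character(Biostrings::alignedPattern(pw)),
                 b_aln = as.character(Biostrings::alignedSubject(pw)),
                 score = Biostrings::score(pw)),
            class = "pairwise_alignment")
}

.subst_cache <- new.env(parent = emptyenv())

subst_matrix <- function(name) {
  if (is.null(.subst_cache[[name]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .subst_cache[[name]] <- get(name, envir = e)
  }
  .subst_cache[[name]]
}

# map each 0-based position of b (subject) to the aligned 0-based position of
# a (pattern), NA where a has a gap
alignment_map <- function(aln) {
  a <- strsplit(aln$a_aln, "")[[1L]]
  b <- strsplit(aln$b_aln, "")[[1L]]
  map <- rep(NA_integer_, sum(b != "-"))
  ai <- 0L; bi <- 0L
  for (k in seq_along(a)) {
    if (a[k] != "-") ai <- ai + 1L
    if (b[k] != "-") {
      bi <- bi + 1L
      if (a[k] != "-") map[bi] <- ai - 1L
    }
  }
  map
}

p_site_names <- function(rcl_length) {
  c(paste0("P", seq(rcl_length, 1L)), "P1'", "P2'", "P3'")
}

#' Locate the reactive centre loop of a candidate serpin
#'
#' Globally aligns the candidate to the reference, maps the reference RCL onto
#' the candidate, anchors P1 at the residue aligned to the reference P1 and
#' walks 17 (or, when the P17 column is deleted, 16) residues N-terminal to
#' P17.  The annotation fails (returns `NULL`) when the mapped RCL region has
#' gaps covering more than two P-sites or the protein ends before P3'.
#'
#' @param protein Candidate residue string (should have passed [length_gate()]).
#' @param ref A [reference_serpin()].
#' @param max_gapped_sites Maximum number of gapped P-sites tolerated.
#' @return An object of class `rcl_annotation` (fields `p17_index` [0-based],
#'   `rcl_length`, `p_sites`, `reactive_centre`, `hinge_ok`, `is_LR`) or
#'   `NULL` when no RCL is found.
#' @export
locate_rcl <- function(protein, ref, max_gapped_sites = 2L) {
  aln <- global_align(protein, ref$protein)
  map <- alignment_map(aln)          # ref position (0-based) -> protein position
  p1_ref <- ref$rcl_end - 1L
  if (p1_ref + 1L > length(map)) return(NULL)
  p1 <- map[p1_ref + 1L]
  if (is.na(p1)) return(NULL)
  rcl_length <- 17L
  if (is.na(map[ref$rcl_start + 1L])) rcl_length <- 16L
  p17 <- p1 - (rcl_length - 1L)
  if (p17 < 0L) return(NULL)
  if (p1 + 3L >= nchar(protein)) return(NULL)    # needs P1'..P3'
  span <- seq(ref$rcl_start, min(p1_ref + 3L, length(map) - 1L))
  if (sum(is.na(map[span + 1L])) > max_gapped_sites) return(NULL)
  res <- strsplit(protein, "")[[1L]]
  p_sites <- res[(p17 + 1L):(p1 + 4L)]
  names(p_sites) <- p_site_names(rcl_length)
  rcl <- structure(list(p17_index = p17, rcl_length = rcl_length,
                        p_sites = p_sites,
                        reactive_centre = paste0(p_sites[["P2"]],
                                                 p_sites[["P1"]],
                                                 p_sites[["P1'"]]),
                        hinge_ok = NA, is_LR = NA),
                   class = "rcl_annotation")
  rcl$hinge_ok <- scan_hinge(rcl)
  rcl$is_LR <- extract_reactive_centre(rcl)$is_LR
  rcl
}

#' @export
print.rcl_annotation <- function(x, ...) {
  cat(sprintf("<rcl_annotation> P17 at %d (%d residues), centre %s%s%s\n",
              x$p17_index, x$rcl_length, x$reactive_centre,
              if (isTRUE(x$hinge_ok)) ", hinge ok" else ", hinge broken",
              if (isTRUE(x$is_LR)) " (LR serpin)" else ""))
  invisible(x)
}

#' Validate the RCL hinge region
#'
#' A functional (inhibitory) serpin RCL requires glutamic acid at P17 and a
#' proximal hinge dominated by small residues that permit loop insertion.  The
#' rule applied: the most N-terminal P-site must be `E` and at least
#' `min_small` of the six residues P15..P10 must be in `small_set`.
#'
#' @param rcl An `rcl_annotation`.
#' @param small_set Residues counted as small (default G, A, S, T, V).
#' @param min_small Minimum number of small residues among P15..P10.
#' @return Logical.
#' @export
scan_hinge <- function(rcl, small_set = c("G", "A", "S", "T", "V"),
                       min_small = 4L) {
  sites <- rcl$p_sites
  if (sites[[1L]] != "E") return(FALSE)
  hinge <- sites[paste0("P", 15:10)]
  sum(hinge %in% small_set) >= min_small
}

#' Extract the reactive centre (P2-P1-P1') and LR classification
#'
#' LR serpins (the Zx/AtSerpin1 class) carry P2-P1 = Leu-Arg with a small P1'
#' residue (G, A or S).
#'
#' @param rcl An `rcl_annotation`.
#' @return List with `triplet` (3-residue string) and `is_LR` (logical).
#' @export
extract_reactive_centre <- function(rcl) {
  sites <- rcl$p_sites
  triplet <- paste0(sites[["P2"]], sites[["P1"]], sites[["P1'"]])
  list(triplet = triplet,
       is_LR = sites[["P2"]] == "L" && sites[["P1"]] == "R" &&
         sites[["P1'"]] %in% c("G", "A", "S"))
}

#' Check conservation of the serpin core scaffold
#'
#' Structural defects such as a missing helix or beta-sheet manifest as
#' unaligned reference core blocks; coverage is the fraction of reference block
#' positions aligned to non-gap candidate residues.
#'
#' @param protein Candidate residue string.
#' @param ref A [reference_serpin()].
#' @param block_min Minimum per-block coverage (default 0.5).
#' @param core_min Minimum overall core coverage (default 0.8).
#' @return List with `pass`, `coverage` (overall) and `block_coverage`.
#' @export
check_scaffold <- function(protein, ref, block_min = 0.5, core_min = 0.8) {
  aln <- global_align(protein, ref$protein)
  map <- alignment_map(aln)
  cov <- apply(ref$core_blocks, 1L, function(b) {
    pos <- seq(b[1L], b[2L] - 1L) + 1L
    mean(!is.na(map[pos]))
  })
  total <- sum(ref$core_blocks[, 2L] - ref$core_blocks[, 1L])
  overall <- sum(cov * (ref$core_blocks[, 2L] - ref$core_blocks[, 1L])) / total
  list(pass = all(cov >= block_min) && overall >= core_min,
       coverage = overall, block_coverage = cov)
}

#' Heuristic N-terminal signal-peptide detector
#'
#' Flags proteins whose first residue is Met and whose residues 2-30 contain a
#' hydrophobic stretch of at least `min_run` consecutive residues from
#' `hydrophobic`.  A coarse stand-in for dedicated predictors, sufficient for
#' the secreted serpin classes profiled here.
#'
#' @param protein Residue string (proteins shorter than 40 residues return
#'   `FALSE`).
#' @param min_run Minimum hydrophobic run length (default 8).
#' @param hydrophobic Hydrophobic residue set.
#' @return Logical.
#' @export
detect_signal_peptide <- function(protein, min_run = 8L,
                                  hydrophobic = c("A", "I", "L", "M", "F",
                                                  "V", "W", "C")) {
  if (nchar(protein) < 40L) return(FALSE)
  if (substr(protein, 1L, 1L) != "M") return(FALSE)
  window <- strsplit(substr(protein, 2L, 30L), "")[[1L]]
  runs <- rle(window %in% hydrophobic)
  any(runs$values & runs$lengths >= min_run)
}

#' Curate a candidate serpin protein
#'
#' Composes the length gate, scaffold-conservation check, RCL localisation,
#' hinge validation and reactive-centre extraction into one verdict.  All
#' applicable failure reasons are accumulated (no short-circuiting).
#' Non-inhibitory serpins (RCL present, hinge broken - the Z9-type class) pass
#' curation: only structural grounds fail a candidate.
#'
#' @param protein Candidate residue string.
#' @param ref A [reference_serpin()].
#' @param min_len,max_len Length-gate bounds.
#' @param block_min,core_min Scaffold coverage thresholds.
#' @return An object of class `curation_verdict` with fields `passed`,
#'   `fail_reasons`, `rcl` (an `rcl_annotation` or `NULL`),
#'   `inhibitory_class` (`"inhibitory"`, `"non_inhibitory"` or `"unknown"`)
#'   and `signal_peptide`.
#' @export
curate <- function(protein, ref, min_len = 330L, max_len = 600L,
                   block_min = 0.5, core_min = 0.8) {
  reasons <- character(0)
  lg <- length_gate(protein, min_len, max_len)
  if (!lg$pass) reasons <- c(reasons, lg$reason)
  sc <- check_scaffold(protein, ref, block_min, core_min)
  if (!sc$pass) reasons <- c(reasons, "scaffold_defect")
  rcl <- locate_rcl(protein, ref)
  if (is.null(rcl)) reasons <- c(reasons, "no_rcl")
  cls <- if (is.null(rcl)) "unknown"
         else if (isTRUE(rcl$hinge_ok)) "inhibitory" else "non_inhibitory"
  structure(list(passed = length(reasons) == 0L,
                 fail_reasons = reasons, rcl = rcl,
                 inhibitory_class = cls,
                 scaffold_coverage = sc$coverage,
                 signal_peptide = detect_signal_peptide(protein)),
            class = "curation_verdict")
}

#' @export
print.curation_verdict <- function(x, ...) {
  cat(sprintf("<curation_verdict> %s%s; class %s%s\n",
              if (x$passed) "PASS" else "FAIL",
              if (length(x$fail_reasons))
                paste0(" (", paste(x$fail_reasons, collapse = ", "), ")")
              else "",
              x$inhibitory_class,
              if (x$signal_peptide) "; signal peptide" else ""))
  invisible(x)
}

#' Curate a set of proteins into a verdict table
#'
#' @param proteins Named character vector of protein sequences.
#' @param ref A [reference_serpin()].
#' @param ... Passed to [curate()].
#' @return Data frame with one row per protein: `gene_id`, `passed`,
#'   `fail_reasons`, `rcl_found`, `p17_index`, `rcl_length`,
#'   `reactive_centre`, `is_LR`, `hinge_ok`, `inhibitory_class`,
#'   `signal_peptide`.
#' @export
curate_proteins <- function(proteins, ref, ...) {
  rows <- lapply(names(proteins), function(id) {
    v <- curate(proteins[[id]], ref, ...)
    data.frame(gene_id = id, passed = v$passed,
               fail_reasons = paste(v$fail_reasons, collapse = ","),
               rcl_found = !is.null(v$rcl),
               p17_index = if (is.null(v$rcl)) NA_integer_ else v$rcl$p17_index,
               rcl_length = if (is.null(v$rcl)) NA_integer_ else v$rcl$rcl_length,
               reactive_centre = if (is.null(v$rcl)) NA_character_ else
                 v$rcl$reactive_centre,
               is_LR = if (is.null(v$rcl)) NA else v$rcl$is_LR,
               hinge_ok = if (is.null(v$rcl)) NA else v$rcl$hinge_ok,
               inhibitory_class = v$inhibitory_class,
               signal_peptide = v$signal_peptide,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
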