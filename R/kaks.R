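# Nei-Gojobori (1986) Ka/Ks with equal pathway weighting and Jukes-Cantor
# correction.  Site counting and pathway averaging follow the classic
# convention: substitutions that would create a stop codon are excluded from
# the per-position denominator, and evolutionary pathways passing through a
# stop codon are excluded from the difference averaging.

bases <- c("A", "C", "G", "T")

codon_aa <- function(codon) Biostrings::GENETIC_CODE[[codon]]

is_stop <- function(codon) identical(codon_aa(codon), "*")

#' Synonymous/non-synonymous site fractions of a codon
#'
#' For each codon position, the synonymous fraction is the number of the three
#' possible single-base substitutions that preserve the amino acid, divided by
#' the number of substitutions that do not create a stop codon.
#'
#' @param codon A 3-letter codon (no ambiguity codes, not a stop).
#' @return List with `syn` and `nonsyn` (numeric length-3, per position),
#'   `S` (`sum(syn)`) and `N` (`3 - S`).
#' @export
ng_count_sites <- function(codon) {
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be a 3-letter ACGT string")
  if (is_stop(codon)) stop("stop codon has no defined site counts")
  aa0 <- codon_aa(codon)
  syn <- numeric(3L)
  for (pos in 1:3) {
    alts <- setdiff(bases, substr(codon, pos, pos))
    n_syn <- 0L; n_valid <- 0L
    for (b in alts) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (is_stop(alt)) next
      n_valid <- n_valid + 1L
      if (identical(codon_aa(alt), aa0)) n_syn <- n_syn + 1L
    }
    syn[pos] <- if (n_valid > 0L) n_syn / n_valid else 0
  }
  list(syn = syn, nonsyn = 1 - syn, S = sum(syn), N = 3 - sum(syn))
}

# average synonymous/non-synonymous step counts over all orderings of the
# differing positions, excluding pathways through stop codons (falling back to
# all pathways when every ordering passes through a stop)
ng_codon_diffs <- function(codon_a, codon_b) {
  diff_pos <- which(strsplit(codon_a, "")[[1L]] != strsplit(codon_b, "")[[1L]])
  d <- length(diff_pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- switch(d, list(diff_pos),
                   list(diff_pos, rev(diff_pos)),
                   {
                     p <- diff_pos
                     list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                          p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                   })
  walk <- function(ord) {
    cur <- codon_a
    syn <- 0; nonsyn <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop(nxt)) return(NULL)
      if (identical(codon_aa(cur), codon_aa(nxt))) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- Filter(Negate(is.null), lapply(orders, walk))
  if (length(paths) == 0L) {
    # all orderings pass through a stop: average over them anyway, counting
    # steps through the full path
    walk_all <- function(ord) {
      cur <- codon_a; syn <- 0; nonsyn <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
        if (identical(codon_aa(cur), codon_aa(nxt))) syn <- syn + 1
        else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    }
    paths <- lapply(orders, walk_all)
  }
  Reduce(`+`, paths) / length(paths)
}

#' Nei-Gojobori Ka/Ks between two aligned coding sequences
#'
#' Site counts S and N are averaged over the two sequences; synonymous and
#' non-synonymous differences are counted by equal-weight pathway averaging.
#' Proportions are Jukes-Cantor corrected, `d = -(3/4) log(1 - (4/3) p)`.
#' Codons containing a gap (`-`) or ambiguity code in either sequence are
#' dropped pairwise.
#'
#' @param cds_a,cds_b Nucleotide strings of equal length divisible by 3, with
#'   no internal stop codons.
#' @return Object of class `kaks_result` with fields `syn_sites` (S),
#'   `nonsyn_sites` (N), `syn_diffs` (Sd), `nonsyn_diffs` (Nd), `ps`, `pn`,
#'   `ka`, `ks`, `ratio` (NA when Ks = 0), `n_codons`.
#' @export
kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must be of equal length")
  if (nchar(cds_a) %% 3L != 0L) stop("length must be divisible by 3")
  idx <- seq_len(nchar(cds_a) %/% 3L)
  ca <- substring(cds_a, 3L * idx - 2L, 3L * idx)
  cb <- substring(cds_b, 3L * idx - 2L, 3L * idx)
  keep <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop("no comparable codons")
  if (any(vapply(ca, is_stop, TRUE)) || any(vapply(cb, is_stop, TRUE)))
    stop("internal stop codon in input")
  Sa <- sum(vapply(ca, function(x) ng_count_sites(x)$S, 0))
  Sb <- sum(vapply(cb, function(x) ng_count_sites(x)$S, 0))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(ng_codon_diffs, ca, cb)
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) stop("proportion >= 3/4: Jukes-Cantor correction undefined")
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  structure(list(syn_sites = S, nonsyn_sites = N, syn_diffs = Sd,
                 nonsyn_diffs = Nd, ps = ps, pn = pn, ka = ka, ks = ks,
                 ratio = if (ks == 0) NA_real_ else ka / ks,
                 n_codons = length(ca)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(paste0("<kaks_result> %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f ",
                     "Ka=%.4f Ks=%.4f Ka/Ks=%s\n"),
              x$n_codons, x$syn_sites, x$nonsyn_sites, x$syn_diffs,
              x$nonsyn_diffs, x$ka, x$ks,
              if (is.na(x$ratio)) "undefined (Ks=0)" else
                sprintf("%.4f", x$ratio)))
  invisible(x)
}
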