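#' Translate a CDS with the standard genetic code
#'
#' Translation stops at the first stop codon.  Codons containing ambiguity
#' codes translate to `X`.
#'
#' @param cds Nucleotide string.
#' @return List with `protein` (residues up to, not including, the first
#'   stop), `premature_stop` (a stop occurs before the final codon) and
#'   `incomplete` (length not divisible by 3, or no terminal stop).
#' @export
translate_cds <- function(cds) {
  if (!nzchar(cds)) stop("empty CDS")
  n <- nchar(cds)
  n_codons <- n %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  first_stop <- if (length(stops)) stops[1L] else NA_integer_
  protein <- if (is.na(first_stop)) paste(aa, collapse = "")
             else paste(aa[seq_len(first_stop - 1L)], collapse = "")
  list(protein = protein,
       premature_stop = !is.na(first_stop) && first_stop < n_codons,
       incomplete = (n %% 3L != 0L) || is.na(first_stop) ||
         first_stop != n_codons)
}

#' Extract the CDS sequence of a gene model from the genome
#'
#' CDS intervals are concatenated in genomic order; minus-strand genes return
#' the reverse complement so the result always reads 5' to 3' in transcript
#' orientation.
#'
#' @param model A `gene_model`.
#' @param genome Named character vector of chromosome sequences (or a single
#'   unnamed sequence).
#' @return Nucleotide string.
#' @export
extract_cds <- function(model, genome) {
  chr <- chromosome_sequence(model, genome)
  pieces <- apply(model$cds, 1L, function(iv) substr(chr, iv[1L] + 1L, iv[2L]))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

chromosome_sequence <- function(model, genome) {
  chr <- if (is.null(names(genome)) && length(genome) == 1L) genome[[1L]]
         else genome[[model$chromosome]]
  if (is.null(chr) || is.na(chr))
    stop("chromosome ", model$chromosome, " not in genome")
  if (max(model$exons[, 2L]) > nchar(chr))
    stop("exon outside genome bounds for gene ", model$gene_id)
  chr
}

#' Check splice sites and intron sizes of a gene model
#'
#' Donor/acceptor dinucleotides are read strand-aware (canonical GT..AG);
#' introns are reported in transcription order.  Annotation errors such as
#' 2 bp or 4 bp introns are flagged as `short_intron`.
#'
#' @param model A `gene_model`.
#' @param genome Named character vector of chromosome sequences.
#' @param min_intron Minimum credible intron length in bp (default 20).
#' @return Object of class `splice_report`: `gene_id`, `introns` (data frame
#'   with `length`, `donor`, `acceptor`) and `violations` (data frame with
#'   `intron`, `type`).
#' @export
check_splice_sites <- function(model, genome, min_intron = 20L) {
  chr <- chromosome_sequence(model, genome)
  ex <- model$exons
  n_int <- nrow(ex) - 1L
  introns <- data.frame(length = integer(0), donor = character(0),
                        acceptor = character(0), stringsAsFactors = FALSE)
  if (n_int > 0L) {
    starts <- ex[-nrow(ex), 2L]          # 0-based start of intron
    ends <- ex[-1L, 1L]                  # 0-based end (half-open)
    left <- substr(rep(chr, n_int), starts + 1L, starts + 2L)
    right <- substr(rep(chr, n_int), ends - 1L, ends)
    if (model$strand == "+") {
      introns <- data.frame(length = as.integer(ends - starts), donor = left,
                            acceptor = right, stringsAsFactors = FALSE)
    } else {
      # transcription order is genomic-descending; donor is the revcomp of the
      # genomic right end of each intron
      introns <- data.frame(length = rev(as.integer(ends - starts)),
                            donor = rev(vapply(right, revcomp, "")),
                            acceptor = rev(vapply(left, revcomp, "")),
                            stringsAsFactors = FALSE)
    }
  }
  viol <- list()
  for (i in seq_len(nrow(introns))) {
    if (introns$length[i] < min_intron)
      viol[[length(viol) + 1L]] <- data.frame(intron = i, type = "short_intron")
    if (introns$donor[i] != "GT")
      viol[[length(viol) + 1L]] <- data.frame(intron = i,
                                              type = "non_canonical_donor")
    if (introns$acceptor[i] != "AG")
      viol[[length(viol) + 1L]] <- data.frame(intron = i,
                                              type = "non_canonical_acceptor")
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(intron = integer(0), type = character(0))
  structure(list(gene_id = model$gene_id, introns = introns,
                 violations = violations),
            class = "splice_report")
}

#' @export
print.splice_report <- function(x, ...) {
  cat(sprintf("<splice_report> %s: %d intron(s), %d violation(s)\n",
              x$gene_id, nrow(x$introns), nrow(x$violations)))
  invisible(x)
}

#' Detect pseudogene lesions in a gene model
#'
#' Flags the three lesion mechanisms observed in inactivated wheat serpin
#' copies: frameshift (CDS length not divisible by 3, e.g. an 8-bp exon
#' insertion), premature stop (internal stop with a translation shorter than
#' `trunc_frac` of the reference protein) and splice defects (short introns or
#' non-canonical GT..AG sites; a GC donor is reported by
#' [check_splice_sites()] but does not pseudogenise on its own).
#' `expressed_not_translated` is left `NA`: it is set by the caller from
#' expression evidence, not inferred here.
#'
#' @param model A `gene_model`.
#' @param genome Named character vector of chromosome sequences.
#' @param ref_protein_length Expected intact protein length (residues).
#' @param min_intron Passed to [check_splice_sites()].
#' @param trunc_frac Truncation threshold for calling a premature stop
#'   pseudogenising (default 0.8).
#' @return Object of class `pseudogene_call`: `gene_id`, `is_pseudogene`,
#'   `lesions` (data frame with `type` and `where`), `expressed_not_translated`.
#' @export
detect_pseudogene <- function(model, genome, ref_protein_length,
                              min_intron = 20L, trunc_frac = 0.8) {
  cds <- extract_cds(model, genome)
  tr <- translate_cds(cds)
  lesions <- list()
  if (nchar(cds) %% 3L != 0L)
    lesions[[length(lesions) + 1L]] <-
      data.frame(type = "frameshift", where = nchar(cds) %% 3L)
  if (tr$premature_stop &&
      nchar(tr$protein) < trunc_frac * ref_protein_length)
    lesions[[length(lesions) + 1L]] <-
      data.frame(type = "premature_stop", where = nchar(tr$protein) + 1L)
  sr <- check_splice_sites(model, genome, min_intron)
  bad <- sr$violations[sr$violations$type == "short_intron" |
    (sr$violations$type == "non_canonical_donor" &
       sr$introns$donor[sr$violations$intron] != "GC") |
    sr$violations$type == "non_canonical_acceptor", , drop = FALSE]
  for (i in seq_len(nrow(bad)))
    lesions[[length(lesions) + 1L]] <-
      data.frame(type = "splice_defect", where = bad$intron[i])
  lesions <- if (length(lesions)) do.call(rbind, lesions)
    else data.frame(type = character(0), where = integer(0))
  structure(list(gene_id = model$gene_id,
                 is_pseudogene = nrow(lesions) > 0L,
                 lesions = lesions,
                 expressed_not_translated = NA),
            class = "pseudogene_call")
}

#' @export
print.pseudogene_call <- function(x, ...) {
  cat(sprintf("<pseudogene_call> %s: %s%s\n", x$gene_id,
              if (x$is_pseudogene) "PSEUDOGENE" else "intact",
              if (nrow(x$lesions))
                paste0(" [", paste(x$lesions$type, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Consequence of a single-nucleotide change in a CDS
#'
#' @param cds Nucleotide string (in-frame).
#' @param nt_position 1-based CDS coordinate of the change.
#' @param alt_base Replacement nucleotide.
#' @return Object of class `residue_change`: `nt_position`, `ref_base`,
#'   `alt_base`, `codon_index` (`= ceiling(nt_position / 3)`), `aa_from`,
#'   `aa_to`.
#' @examples
#' # a G->A change at CDS position 65 hits codon 22; CGC (Arg) becomes CAC (His)
#' @export
residue_change <- function(cds, nt_position, alt_base) {
  if (nt_position < 1L || nt_position > nchar(cds))
    stop("nt_position outside the CDS")
  ref_base <- substr(cds, nt_position, nt_position)
  if (ref_base == alt_base) stop("alt base equals the reference base")
  codon_index <- ceiling(nt_position / 3)
  s <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, s, s + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, nt_position - s + 1L, nt_position - s + 1L) <- alt_base
  tr <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa)) "X" else aa
  }
  structure(list(nt_position = nt_position, ref_base = ref_base,
                 alt_base = alt_base, codon_index = as.integer(codon_index),
                 aa_from = tr(ref_codon), aa_to = tr(alt_codon)),
            class = "residue_change")
}

#' @export
print.residue_change <- function(x, ...) {
  cat(sprintf("<residue_change> %s%d%s: codon %d %s -> %s\n", x$ref_base,
              x$nt_position, x$alt_base, x$codon_index, x$aa_from, x$aa_to))
  invisible(x)
}

#' Free amino-acid pKa values (Lehninger)
#'
#' The alpha-carboxyl (`pKa1`), alpha-amino (`pKa2`) and ionisable side-chain
#' (`pKaR`) dissociation constants of the free amino acids.
#'
#' @return Data frame with row names the one-letter codes and columns `pKa1`,
#'   `pKa2`, `pKaR` (NA for non-ionisable side chains), `charge` (sign of the
#'   ionised side chain).
#' @export
lehninger_pka <- function() {
  data.frame(
    pKa1 = c(A = 2.34, R = 2.17, N = 2.02, D = 1.88, C = 1.96, E = 2.19,
             Q = 2.17, G = 2.34, H = 1.82, I = 2.36, L = 2.36, K = 2.18,
             M = 2.28, F = 1.83, P = 1.99, S = 2.21, T = 2.11, W = 2.38,
             Y = 2.20, V = 2.32),
    pKa2 = c(A = 9.69, R = 9.04, N = 8.80, D = 9.60, C = 10.28, E = 9.67,
             Q = 9.13, G = 9.60, H = 9.17, I = 9.68, L = 9.60, K = 8.95,
             M = 9.21, F = 9.13, P = 10.96, S = 9.15, T = 9.62, W = 9.39,
             Y = 9.11, V = 9.62),
    pKaR = c(A = NA, R = 12.48, N = NA, D = 3.65, C = 8.18, E = 4.25,
             Q = NA, G = NA, H = 6.00, I = NA, L = NA, K = 10.53,
             M = NA, F = NA, P = NA, S = NA, T = NA, W = NA,
             Y = 10.07, V = NA),
    charge = c(A = 0, R = 1, N = 0, D = -1, C = -1, E = -1, Q = 0, G = 0,
               H = 1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
               T = 0, W = 0, Y = -1, V = 0))
}

#' Isoelectric point by Henderson-Hasselbalch and bisection
#'
#' The net charge at a given pH sums the protonated fraction of the N-terminus
#' and basic side chains (His, Lys, Arg) and the deprotonated fraction of the
#' C-terminus and acidic side chains (Asp, Glu, Cys, Tyr).  The pI solves
#' `Q(pH) = 0` by bisection on pH in [0, 14] to `|Q| < tol`.  For a single
#' free residue the termini use that residue's own pKa1/pKa2, which reproduces
#' the free-amino-acid values used to explain native-PAGE mobility (free Arg
#' 10.76, free His 7.59).
#'
#' @param seq Residue string.
#' @param pKa_table Table in the layout of [lehninger_pka()].
#' @param nterm_pKa,cterm_pKa Terminal pKa values used for peptides of length
#'   greater than one.
#' @param tol Bisection tolerance on the net charge.
#' @return The isoelectric point (numeric).
#' @export
compute_pI <- function(seq, pKa_table = lehninger_pka(),
                       nterm_pKa = 9.69, cterm_pKa = 2.34, tol = 1e-4) {
  if (!nzchar(seq)) stop("empty sequence")
  res <- strsplit(seq, "")[[1L]]
  if (nchar(seq) == 1L) {
    if (!res %in% rownames(pKa_table)) stop("unknown residue: ", res)
    nterm_pKa <- pKa_table[res, "pKa2"]
    cterm_pKa <- pKa_table[res, "pKa1"]
  }
  counts <- table(factor(res, levels = rownames(pKa_table)))
  side <- pKa_table[!is.na(pKa_table$pKaR), ]
  net_charge <- function(pH) {
    q <- 1 / (1 + 10^(pH - nterm_pKa)) - 1 / (1 + 10^(cterm_pKa - pH))
    for (r in rownames(side)) {
      n <- counts[[r]]
      if (n == 0) next
      q <- q + if (side[r, "charge"] > 0) {
        n / (1 + 10^(pH - side[r, "pKaR"]))
      } else {
        -n / (1 + 10^(side[r, "pKaR"] - pH))
      }
    }
    q
  }
  # bisect to a tight pH interval: near-neutral residues have a very flat
  # charge curve, so stopping on |Q| alone can leave the pH off by ~0.1
  lo <- 0; hi <- 14
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(net_charge(mid)) > tol)
    warning("net charge at the bisection limit exceeds the tolerance")
  mid
}
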