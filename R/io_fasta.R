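#' Read a FASTA file into a named character vector
#'
#' Sequences are returned as a plain named character vector (uppercased), with
#' the declared alphabet attached as an attribute.  IUPAC ambiguity codes are
#' accepted for DNA; `X` is accepted for protein.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Named character vector of sequences with attribute `alphabet`.
#'   Record order is preserved; IDs are the header tokens up to the first
#'   whitespace.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ID: ", dup[1L])
  if (any(!nzchar(ids))) stop("empty FASTA ID in ", path)
  if (any(!nzchar(seqs))) stop("empty sequence for ID: ", ids[!nzchar(seqs)][1L])
  ok <- alphabet_chars(alphabet)
  for (i in seq_along(seqs)) {
    res <- strsplit(seqs[[i]], "")[[1L]]
    bad <- which(!(res %in% ok))
    if (length(bad)) {
      stop("character '", res[bad[1L]], "' at position ", bad[1L],
           " of record '", ids[i], "' is not in the ", alphabet, " alphabet")
    }
  }
  names(seqs) <- ids
  attr(seqs, "alphabet") <- alphabet
  seqs
}

alphabet_chars <- function(alphabet) {
  if (alphabet == "dna") strsplit("ACGTRYSWKMBDHVN", "")[[1L]]
  else strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
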