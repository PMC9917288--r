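#' Parse a Traes-style gene identifier
#'
#' IWGSC RefSeq identifiers such as `TraesCS4A02G235700` encode the chromosome
#' number and subgenome letter after the `TraesCS` prefix.  Identifiers that do
#' not match the pattern degrade to `("", "unknown")` rather than erroring.
#'
#' @param gene_id Character vector of gene identifiers.
#' @return Data frame with columns `gene_id`, `chromosome` (e.g. `"4A"`) and
#'   `subgenome` (`"A"`, `"B"`, `"D"` or `"unknown"`).
#' @examples
#' parse_traes_id("TraesCS4A02G235700")  # chromosome 4A, subgenome A
#' @export
parse_traes_id <- function(gene_id) {
  m <- regmatches(gene_id, regexec("^TraesCS([1-7])([ABD])[0-9]+G", gene_id))
  chrom <- vapply(m, function(x) if (length(x) == 3L) paste0(x[2L], x[3L]) else "", "")
  sub <- vapply(m, function(x) if (length(x) == 3L) x[3L] else "unknown", "")
  data.frame(gene_id = gene_id, chromosome = chrom, subgenome = sub,
             stringsAsFactors = FALSE)
}

chromosome_subgenome <- function(chromosome) {
  # subgenome from the trailing letter of names like "4A", "chr2D"; "Un" -> unknown
  m <- regmatches(chromosome, regexec("^(chr)?([0-9]+)([ABD])$", chromosome))
  vapply(m, function(x) if (length(x) == 4L) x[4L] else "unknown", "")
}

new_gene_model <- function(gene_id, transcript_id, chromosome, strand,
                           exons, cds, pseudogene_flag = FALSE) {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.numeric(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in gene ", gene_id)
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
    if (!inside) stop("CDS interval outside any exon in gene ", gene_id)
  }
  if (!pseudogene_flag && (nrow(cds) == 0L || sum(cds[, 2L] - cds[, 1L]) <= 0))
    stop("gene ", gene_id, " has no CDS and is not flagged as a pseudogene")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chromosome = chromosome,
                 subgenome = chromosome_subgenome(chromosome),
                 strand = strand, exons = exons, cds = cds,
                 pseudogene_flag = pseudogene_flag),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) chr %s [%s] %d exon(s), CDS %d bp%s\n",
              x$gene_id, x$transcript_id, x$chromosome, x$strand,
              nrow(x$exons), sum(x$cds[, 2L] - x$cds[, 1L]),
              if (x$pseudogene_flag) ", pseudogene" else ""))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features (linked through `ID`/`Parent`
#' attributes) into a list of gene models.  GFF3 1-based closed coordinates are
#' converted to the internal 0-based half-open convention.  When a gene has
#' several mRNAs, the first by transcript-ID order is retained and the number of
#' discarded isoforms is recorded in the `discarded_isoforms` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return List of `gene_model` objects (one per gene, in file order of gene
#'   features), with attribute `discarded_isoforms`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(as.list(gr$Parent),
                      function(p) if (length(p)) p[[1L]] else NA_character_, "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]
  discarded <- 0L
  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    if (nrow(tx) == 0L) stop("gene ", g$ID, " has no mRNA feature")
    tx <- tx[order(tx$ID), , drop = FALSE]
    discarded <- discarded + nrow(tx) - 1L
    t1 <- tx[1L, ]
    strand <- as.character(t1$strand)
    if (!strand %in% c("+", "-")) stop("unknown strand for gene ", g$ID)
    ex <- exons[!is.na(exons$Parent) & exons$Parent == t1$ID, , drop = FALSE]
    cd <- cdss[!is.na(cdss$Parent) & cdss$Parent == t1$ID, , drop = FALSE]
    if (nrow(ex) == 0L) stop("gene ", g$ID, " has no exons")
    models[[i]] <- new_gene_model(
      gene_id = g$ID, transcript_id = t1$ID,
      chromosome = as.character(g$seqnames), strand = strand,
      exons = cbind(ex$start - 1L, ex$end),
      cds = cbind(cd$start - 1L, cd$end),
      pseudogene_flag = isTRUE(grepl("pseudogene", g$type)))
  }
  names(models) <- genes$ID
  attr(models, "discarded_isoforms") <- discarded
  models
}

#' Write gene models to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3 1-based
#' closed on output.
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "serpinome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chr, type, s0, e0, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chr, source, type, as.integer(s0) + 1L, as.integer(e0), strand, attrs)
  }
  for (m in models) {
    gs <- min(m$exons[, 1L]); ge <- max(m$exons[, 2L])
    writeLines(fmt(m$chromosome, "gene", gs, ge, m$strand,
                   paste0("ID=", m$gene_id)), con)
    writeLines(fmt(m$chromosome, "mRNA", gs, ge, m$strand,
                   paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)), con)
    for (i in seq_len(nrow(m$exons)))
      writeLines(fmt(m$chromosome, "exon", m$exons[i, 1L], m$exons[i, 2L],
                     m$strand, paste0("Parent=", m$transcript_id)), con)
    for (i in seq_len(nrow(m$cds)))
      writeLines(fmt(m$chromosome, "CDS", m$cds[i, 1L], m$cds[i, 2L],
                     m$strand, paste0("Parent=", m$transcript_id)), con)
  }
  invisible(path)
}
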