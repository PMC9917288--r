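test_that("CDS translation handles stops, incompleteness and ambiguity", {
  tr <- translate_cds("ATGGAATAA")
  expect_identical(tr$protein, "ME")
  expect_false(tr$premature_stop); expect_false(tr$incomplete)
  tr2 <- translate_cds("ATGTGAGAA")
  expect_identical(tr2$protein, "M")
  expect_true(tr2$premature_stop)
  expect_true(translate_cds("ATGGA")$incomplete)
  expect_identical(translate_cds("ATGNNNTAA")$protein, "MX")
})

simple_gene <- function(introns = c("GT", "AG"), intron_len = 100L,
                        strand = "+") {
  # two-exon gene: exon1 = ATGGAA, exon2 = GAATAA
  intron <- paste0(introns[1L],
                   strrep("C", intron_len - 4L), introns[2L])
  locus <- paste0("ATGGAA", intron, "GAATAA")
  pad <- strrep("T", 50L)
  chr <- paste0(pad, if (strand == "+") locus else revcomp(locus), pad)
  s <- 50L
  ex <- rbind(c(0L, 6L), c(6L + intron_len, 12L + intron_len))
  if (strand == "-") {
    L <- nchar(locus)
    ex <- cbind(L - ex[, 2L], L - ex[, 1L])
    ex <- ex[order(ex[, 1L]), ]
  }
  ex <- ex + s
  list(model = new_gene_model("g", "g.1", "4B", strand, ex, ex),
       genome = c(`4B` = chr))
}

test_that("CDS extraction is strand aware", {
  for (strand in c("+", "-")) {
    g <- simple_gene(strand = strand)
    expect_identical(extract_cds(g$model, g$genome), "ATGGAAGAATAA",
                     info = strand)
  }
})

test_that("splice-site checks flag short introns and non-canonical sites", {
  ok <- simple_gene()
  r <- check_splice_sites(ok$model, ok$genome)
  expect_identical(nrow(r$violations), 0L)
  expect_identical(r$introns$donor, "GT")
  gc <- simple_gene(introns = c("GC", "AG"))
  expect_identical(check_splice_sites(gc$model, gc$genome)$violations$type,
                   "non_canonical_donor")
  short <- simple_gene(intron_len = 4L)
  expect_true("short_intron" %in%
                check_splice_sites(short$model, short$genome)$violations$type)
  # donor/acceptor are read in transcript orientation on the minus strand
  neg <- simple_gene(strand = "-")
  rn <- check_splice_sites(neg$model, neg$genome)
  expect_identical(rn$introns$donor, "GT")
  expect_identical(rn$introns$acceptor, "AG")
  expect_identical(nrow(rn$violations), 0L)
})

test_that("pseudogene detection flags planted lesions and spares intact genes", {
  res <- default_pipeline()
  tg <- res$family$truth$genes
  qc <- res$qc
  m <- match(qc$gene_id, tg$gene_id)
  # zero false positives, full recall
  expect_identical(qc$is_pseudogene, tg$is_pseudogene[m])
  # each planted lesion type is among the reported lesions for its gene
  planted <- tg[tg$lesion != "none", c("gene_id", "lesion")]
  for (i in seq_len(nrow(planted))) {
    got <- qc$lesions[qc$gene_id == planted$gene_id[i]]
    expect_true(grepl(planted$lesion[i], got), info = planted$gene_id[i])
  }
  # the 8-bp frameshift insertion also produces a premature stop (WSZ3-7B style)
  fs <- planted$gene_id[planted$lesion == "frameshift"]
  expect_true(grepl("premature_stop", qc$lesions[qc$gene_id == fs]))
})

test_that("single-nucleotide consequences use correct codon arithmetic", {
  cds <- paste0(strrep("GCT", 21L), "CGC", strrep("GCT", 7L))  # codon 22 = CGC
  rc <- residue_change(cds, 65L, "A")
  expect_identical(rc$codon_index, 22L)
  expect_identical(rc$aa_from, "R")
  expect_identical(rc$aa_to, "H")
  rc2 <- residue_change("ATGAAA", 1L, "T")
  expect_identical(rc2$codon_index, 1L)
  expect_identical(rc2$aa_from, "M"); expect_identical(rc2$aa_to, "L")
  expect_error(residue_change("ATG", 1L, "A"), "equals")
  # codon_index = ceiling(position / 3) for every position of a 30-codon toy
  toy <- random_cds(30L, seed = 5L)
  for (p in seq_len(nchar(toy))) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(toy, p, p))[1L]
    expect_identical(residue_change(toy, p, alt)$codon_index,
                     as.integer(ceiling(p / 3)))
  }
})

test_that("pI reproduces free-residue values and analytic midpoints", {
  expect_equal(compute_pI("R"), 10.76, tolerance = 0.01)
  expect_equal(compute_pI("H"), 7.59, tolerance = 0.01)
  expect_equal(compute_pI("G"), 5.97, tolerance = 0.01)
  # for non-ionisable side chains the pI is the terminal pKa midpoint
  tab <- lehninger_pka()
  for (r in rownames(tab)[is.na(tab$pKaR)]) {
    expect_equal(compute_pI(r), (tab[r, "pKa1"] + tab[r, "pKa2"]) / 2,
                 tolerance = 1e-3, info = r)
  }
  # raising a side-chain pKa never lowers the pI
  pep <- "MDEKRHCY"
  up <- tab
  up["D", "pKaR"] <- up["D", "pKaR"] + 1
  expect_gte(compute_pI(pep, up), compute_pI(pep, tab))
  up2 <- tab
  up2["K", "pKaR"] <- up2["K", "pKaR"] + 1
  expect_gte(compute_pI(pep, up2), compute_pI(pep, tab))
})
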