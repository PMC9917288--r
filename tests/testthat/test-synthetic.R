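test_that("the generator is bit-identical under a fixed seed", {
  s <- small_spec()
  f1 <- make_hexaploid_family(s)
  f2 <- make_hexaploid_family(s)
  expect_identical(f1$genome, f2$genome)
  expect_identical(f1$cds, f2$cds)
  expect_identical(f1$proteins, f2$proteins)
  expect_identical(f1$truth$genes, f2$truth$genes)
  p1 <- make_scaffold_serpin("LRS", seed = 9L, divergence = 0.2)
  p2 <- make_scaffold_serpin("LRS", seed = 9L, divergence = 0.2)
  expect_identical(as.character(p1), as.character(p2))
})

test_that("GFF3 coordinates extract exactly the emitted CDS on both strands", {
  fam <- make_hexaploid_family(small_spec())
  for (id in names(fam$models)) {
    expect_identical(extract_cds(fam$models[[id]], fam$genome),
                     unname(fam$cds[[id]]), info = id)
  }
  expect_true(any(vapply(fam$models, function(m) m$strand == "-", TRUE)))
  # generated files pass the io validators
  d <- tempfile()
  write_family(fam, d)
  genome <- read_fasta(file.path(d, "genome.fa"), "dna")
  models <- read_gff3(file.path(d, "genes.gff3"))
  cds <- read_fasta(file.path(d, "cds.fna"), "dna")
  for (id in names(models)) {
    expect_identical(extract_cds(models[[id]], genome), unname(cds[[id]]),
                     info = id)
  }
  # identifier parsing agrees with the GFF3 chromosome for every gene
  p <- parse_traes_id(names(models))
  expect_identical(p$chromosome,
                   unname(vapply(models, function(m) m$chromosome, "")))
})

test_that("CDS evolution keeps exact substitution bookkeeping", {
  cds <- random_cds(200L, seed = 13L)
  out <- evolve_cds(cds, 0.05, omega = 0.5, seed = 14L)
  n_target <- as.integer(round(0.05 * nchar(cds)))
  expect_identical(attr(out, "n_subs"), n_target)
  expect_identical(attr(out, "syn_subs") + attr(out, "nonsyn_subs"), n_target)
  # omega = 0 permits only synonymous change
  syn_only <- evolve_cds(cds, 0.04, omega = 0, seed = 15L)
  expect_identical(attr(syn_only, "nonsyn_subs"), 0L)
  expect_identical(translate_cds(paste0(syn_only, "TAA"))$protein,
                   translate_cds(paste0(cds, "TAA"))$protein)
  expect_equal(kaks(cds, as.character(syn_only))$ka, 0)
  # no stop codons are ever introduced
  expect_false(translate_cds(as.character(out))$premature_stop)
})

test_that("the default family plants every advertised feature", {
  res <- default_pipeline()
  tg <- res$family$truth$genes
  expect_setequal(unique(tg$pattern_planted),
                  c("1:1:1", "1:2:1", "3:1:1", "0:2:1", "1:0:1", "0:1:1"))
  expect_setequal(unique(tg$lesion),
                  c("none", "frameshift", "splice_defect", "premature_stop"))
  expect_setequal(unique(tg$rcl_variant),
                  c("LRS", "LES", "LMS", "hinge_broken", "missing"))
  expect_true(any(tg$signal_peptide))
  # a triad with a pseudogene loses that copy in its effective pattern
  fs_triad <- tg$triad_id[tg$lesion == "frameshift"]
  expect_identical(unique(tg$pattern_effective[tg$triad_id == fs_triad]),
                   "1:0:1")
})

test_that("noiseless expression equals archetype baselines times fold change", {
  fam <- make_hexaploid_family(small_spec())
  em <- make_expression_matrix(fam$truth$genes, spec = small_spec(),
                               noise_cv = 0, seed = 50L)
  m <- em$expr
  stress <- m$samples$condition == "stress"
  for (j in which(stress)) {
    ctrl_col <- match(m$samples$pair_id[j], m$samples$sample_id)
    plan <- em$truth$stress[em$truth$stress$stress_label ==
                              m$samples$stress_label[j], ]
    fc <- rep(0, nrow(m$tpm))
    fc[match(plan$gene_id, rownames(m$tpm))] <- plan$log2fc
    expect_equal(m$tpm[, j], m$tpm[, ctrl_col] * 2^fc, tolerance = 1e-9)
  }
})
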