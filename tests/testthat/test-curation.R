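ref <- reference_serpin()

test_that("length gate applies the 330-600 residue window", {
  expect_identical(length_gate(strrep("A", 329))$reason, "too_short")
  expect_true(length_gate(strrep("A", 400))$pass)
  expect_identical(length_gate(strrep("A", 601))$reason, "too_long")
  expect_true(length_gate(strrep("A", 330))$pass)
  expect_true(length_gate(strrep("A", 600))$pass)
})

test_that("global alignment matches spec toys and a brute-force score oracle", {
  id <- global_align("MEA", "MEA")
  expect_identical(id$a_aln, "MEA")
  expect_identical(id$b_aln, "MEA")
  gap <- global_align("MA", "MEA")
  expect_identical(gap$a_aln, "M-A")
  expect_identical(gap$b_aln, "MEA")
  # optimal score against exhaustive enumeration on short random peptides
  mat <- get(data(BLOSUM62, package = "Biostrings", envir = environment()))
  aa <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1L]]
  set.seed(99)
  for (i in 1:20) {
    a <- paste(sample(aa, sample(2:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score,
                 oracle_align_score(a, b, 10, 0.5, mat), tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("RCL localisation reproduces the reference coordinates on itself", {
  rcl <- locate_rcl(ref$protein, ref)
  expect_identical(rcl$p17_index, ref$rcl_start)
  expect_identical(rcl$rcl_length, 17L)
  expect_identical(rcl$reactive_centre, "LRS")
  expect_identical(unname(rcl$p_sites[["P17"]]), "E")
  # the reactive centre is a substring of the protein
  expect_true(grepl(rcl$reactive_centre, ref$protein, fixed = TRUE))
})

test_that("RCL localisation recovers planted positions under divergence", {
  for (seed in 1:5) {
    prot <- make_scaffold_serpin("LRS", seed = seed, divergence = 0.25)
    rcl <- locate_rcl(as.character(prot), ref)
    expect_identical(rcl$p17_index, attr(prot, "p17_index"))
    expect_identical(rcl$reactive_centre, "LRS")
  }
  # truncation 10 residues before the reference P1 removes the RCL
  trunc <- substr(ref$protein, 1L, ref$rcl_end - 10L)
  expect_null(locate_rcl(trunc, ref))
  # deleted RCL is not found
  miss <- make_scaffold_serpin("missing", seed = 3L)
  expect_null(locate_rcl(as.character(miss), ref))
})

test_that("hinge scan requires Glu at P17 and a small-residue hinge", {
  mk <- function(p17, hinge) {
    sites <- c(p17, "E", strsplit(hinge, "")[[1L]], "A", "T", "A", "V", "K",
               "I", "T", "L", "R", "S", "A", "K")
    names(sites) <- c(paste0("P", 17:1), "P1'", "P2'", "P3'")
    structure(list(p17_index = 0L, rcl_length = 17L, p_sites = sites,
                   reactive_centre = "LRS", hinge_ok = NA, is_LR = NA),
              class = "rcl_annotation")
  }
  expect_true(scan_hinge(mk("E", "GTEAAA")))
  expect_false(scan_hinge(mk("A", "GTEAAA")))   # P17 Glu is mandatory
  expect_false(scan_hinge(mk("E", "WWWWWW")))   # bulky hinge blocks insertion
})

test_that("reactive-centre extraction labels LR serpins and Zy-style variants", {
  get_centre <- function(variant) {
    prot <- make_scaffold_serpin(variant, seed = 7L)
    extract_reactive_centre(locate_rcl(as.character(prot), ref))
  }
  lrs <- get_centre("LRS")
  expect_identical(lrs$triplet, "LRS"); expect_true(lrs$is_LR)
  les <- get_centre("LES")
  expect_identical(les$triplet, "LES"); expect_false(les$is_LR)
  lms <- get_centre("LMS")
  expect_identical(lms$triplet, "LMS"); expect_false(lms$is_LR)
})

test_that("scaffold check measures core-block alignment coverage", {
  self <- check_scaffold(ref$protein, ref)
  expect_true(self$pass)
  expect_equal(self$coverage, 1.0)
  # deleting an entire core block zeroes that block's coverage
  b <- ref$core_blocks[2L, ]
  del <- paste0(substr(ref$protein, 1L, b[1L]),
                substr(ref$protein, b[2L] + 1L, nchar(ref$protein)))
  res <- check_scaffold(del, ref)
  expect_false(res$pass)
  expect_equal(res$block_coverage[2L], 0.0)
  # a 5-residue deletion inside a 40-residue block leaves coverage 35/40
  del5 <- paste0(substr(ref$protein, 1L, b[1L] + 10L),
                 substr(ref$protein, b[1L] + 16L, nchar(ref$protein)))
  res5 <- check_scaffold(del5, ref)
  expect_equal(res5$block_coverage[2L], 35 / 40)
  expect_true(res5$pass)
})

test_that("signal-peptide heuristic finds hydrophobic N-terminal stretches", {
  pos <- paste0("M", strrep("L", 10), substr(ref$protein, 12L, nchar(ref$protein)))
  expect_true(detect_signal_peptide(pos))
  neg <- paste0("MDEDEDKRK", substr(ref$protein, 10L, nchar(ref$protein)))
  expect_false(detect_signal_peptide(neg))
  # planted signal peptides in the synthetic family are recovered
  res <- default_pipeline()
  tg <- res$family$truth$genes
  v <- res$verdicts
  tv <- tg[match(v$gene_id, tg$gene_id), ]
  expect_gte(mean(v$signal_peptide == tv$signal_peptide), 0.9)
})

test_that("curate composes the filters and retains non-inhibitory serpins", {
  good <- curate(as.character(make_scaffold_serpin("LRS", seed = 2L)), ref)
  expect_true(good$passed)
  expect_identical(good$inhibitory_class, "inhibitory")
  # a C-terminal two-thirds fragment (264 aa) fails the length gate
  frag <- substr(ref$protein, nchar(ref$protein) - 263L, nchar(ref$protein))
  vf <- curate(frag, ref)
  expect_false(vf$passed)
  expect_true("too_short" %in% vf$fail_reasons)
  # hinge-broken serpins keep their RCL: retained as non-inhibitory (Z9-like)
  hb <- curate(as.character(make_scaffold_serpin("hinge_broken", seed = 2L)), ref)
  expect_true(hb$passed)
  expect_identical(hb$inhibitory_class, "non_inhibitory")
  # no RCL at all is a structural failure
  nr <- curate(as.character(make_scaffold_serpin("missing", seed = 2L)), ref)
  expect_false(nr$passed)
  expect_true("no_rcl" %in% nr$fail_reasons)
  expect_identical(nr$inhibitory_class, "unknown")
})
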