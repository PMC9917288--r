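test_that("pairwise distances follow the p and Poisson models", {
  expect_equal(pairwise_distance("MEA", "MEA"), 0)
  a <- paste(rep(c("A", "C"), c(90, 10)), collapse = "")
  b <- strrep("A", 100)
  expect_equal(pairwise_distance(a, b, model = "p"), 0.10)
  expect_equal(pairwise_distance(a, b, model = "poisson"), -log(0.9),
               tolerance = 1e-9)
  # gap columns are excluded
  expect_equal(pairwise_distance("ME-A", "MEKA", model = "p"), 0)
})

test_that("multiple alignment reduces to the pairwise case and keeps columns", {
  two <- progressive_align(c(x = "MA", y = "MEA"))
  expect_identical(unname(two), c("M-A", "MEA"))
  same <- progressive_align(c(a = "MEAMEA", b = "MEAMEA", c = "MEAMEA"))
  expect_true(all(!grepl("-", same)))
  # a planted 5-residue deletion appears as one clean gap run
  base <- as.character(make_scaffold_serpin("LRS", seed = 40L))
  del <- paste0(substr(base, 1, 99), substr(base, 105, nchar(base)))
  aln <- progressive_align(c(full = base, full2 = base, del = del))
  expect_identical(gsub("-", "", aln[["del"]]), del)
  expect_identical(nchar(aln[["full"]]), nchar(base))
  gaps <- gregexpr("-+", aln[["del"]])[[1L]]
  expect_identical(attr(gaps, "match.length"), 5L)
  expect_identical(as.integer(gaps), 100L)
})

test_that("NJ recovers additive matrices exactly", {
  # closed form for three taxa
  dm <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  coph <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(coph, dm, tolerance = 1e-9)
  la <- tr$edge.length[tr$edge[, 2L] == which(tr$tip.label == "a")]
  expect_equal(la, (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-9)
  expect_error(nj_tree(dm[1:2, 1:2]), "3 taxa")
  # random additive matrices from random trees, exact recovery
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:10, 1L)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- stats::runif(nrow(true$edge), 0.05, 1)
    dm <- ape::cophenetic.phylo(true)
    est <- nj_tree(dm)
    expect_equal(ape::dist.topo(est, true), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }
})

test_that("NJ topology is invariant under label permutation", {
  set.seed(5)
  true <- ape::rtree(7, rooted = FALSE)
  true$edge.length <- stats::runif(nrow(true$edge), 0.1, 1)
  dm <- ape::cophenetic.phylo(true)
  perm <- sample(rownames(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), structure(0, names = "PH85"),
               ignore_attr = TRUE)
})

test_that("bootstrap supports are reproducible and separate planted clades", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  core <- paste(sample(aa, 120, TRUE), collapse = "")
  jitter <- function(s, k, seed) {
    set.seed(seed); ch <- strsplit(s, "")[[1L]]
    for (p in sample(seq_along(ch), k)) ch[p] <- sample(setdiff(aa, ch[p]), 1)
    paste(ch, collapse = "")
  }
  blockB <- jitter(core, 50, 99)
  aln <- c(a1 = jitter(core, 3, 1), a2 = jitter(core, 3, 2),
           a3 = jitter(core, 3, 3), b1 = jitter(blockB, 3, 4),
           b2 = jitter(blockB, 3, 5), b3 = jitter(blockB, 3, 6))
  t1 <- bootstrap_support(aln, n_replicates = 200L, seed = 7L)
  t2 <- bootstrap_support(aln, n_replicates = 200L, seed = 7L)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  # the a|b split is unambiguous: its edge support is >= 95%
  cl <- cut_clades(t1, 2L)
  expect_identical(unname(cl[c("a1", "a2", "a3")]), rep(cl[["a1"]], 3))
  expect_identical(unname(cl[c("b1", "b2", "b3")]), rep(cl[["b1"]], 3))
  n <- length(t1$tip.label)
  internal_sup <- sup[-1L]
  expect_true(any(internal_sup >= 95, na.rm = TRUE))
})

test_that("clade cutting recovers planted clusters and degenerate cases", {
  res <- default_pipeline()
  tg <- res$family$truth$genes
  cl <- res$clades
  tc <- tg$clade[match(names(cl), tg$gene_id)]
  # the partition matches the planted clusters exactly (labels are arbitrary)
  tab <- table(cl, tc)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # every leaf is assigned exactly once
  expect_identical(sort(names(cl)), sort(res$tree$tip.label))
  # k = 2 cuts the single longest internal edge
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):1.0,(c:0.1,d:0.1):0.2);")
  k2 <- cut_clades(tr, 2L)
  expect_identical(unname(k2["a"]), unname(k2["b"]))
  expect_identical(unname(k2["c"]), unname(k2["d"]))
  expect_false(k2[["a"]] == k2[["c"]])
  # k equal to the leaf count isolates every leaf
  k4 <- cut_clades(tr, 4L)
  expect_identical(length(unique(k4)), 4L)
})
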