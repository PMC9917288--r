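toy_matrix <- function() {
  tpm <- matrix(c(0.4, 0.5, 8, 1,
                  0, 0, 0, 0,
                  5, 6, 0.1, 0.2,
                  4, 7, 3, 9), nrow = 4, byrow = TRUE,
                dimnames = list(c("g_mixed", "g_silent", "g_root", "g_ubi"),
                                c("r1", "r2", "l1", "l2")))
  samples <- data.frame(
    sample_id = c("r1", "r2", "l1", "l2"),
    tissue = c("root", "root", "leaf", "leaf"),
    stage = "vegetative", cultivar = "CS", condition = "control",
    stress_label = "", pair_id = "", stringsAsFactors = FALSE)
  expression_matrix(tpm, samples)
}

test_that("TPM flooring uses the strictly-lower rule and is idempotent", {
  m <- floor_tpm(toy_matrix())
  expect_equal(m$tpm["g_mixed", "r1"], 0)     # 0.4 -> 0
  expect_equal(m$tpm["g_mixed", "r2"], 0.5)   # 0.5 kept
  twice <- floor_tpm(m)
  expect_identical(twice$tpm, m$tpm)
  expect_true(all(m$tpm <= toy_matrix()$tpm))
})

test_that("log2 transform keeps zeros as a sentinel", {
  m <- floor_tpm(toy_matrix())
  lg <- log2_matrix(m)
  expect_equal(lg["g_root", "r2"], log2(6))
  expect_equal(log2_matrix(floor_tpm(matrix(8, 1, 1,
    dimnames = list("g", "s"))))[1, 1], 3)
  expect_true(is.na(lg["g_silent", "r1"]))
  expect_error(log2_matrix(toy_matrix()), "floor")
})

test_that("expressed calls respond to any above-floor sample", {
  m <- floor_tpm(toy_matrix())
  expect_false(call_expressed(m, "g_silent"))
  expect_true(call_expressed(m, "g_root"))
  expect_error(call_expressed(m, "nope"), "unknown")
})

test_that("tissue specificity labels silent, specific and ubiquitous genes", {
  m <- floor_tpm(toy_matrix())
  sp <- tissue_specificity(m)
  expect_identical(sp$label[sp$gene_id == "g_silent"], "not_expressed")
  expect_identical(sp$label[sp$gene_id == "g_root"], "specific")
  expect_identical(sp$tissues[sp$gene_id == "g_root"], "root")
  # the root mean of g_mixed is (0 + 0.5)/2 = 0.25, below the floor: it is
  # leaf-specific under the mean statistic
  expect_identical(sp$label[sp$gene_id == "g_mixed"], "specific")
  expect_identical(sp$tissues[sp$gene_id == "g_mixed"], "leaf")
  expect_identical(sp$label[sp$gene_id == "g_ubi"], "ubiquitous")
})

test_that("stress response applies the pseudo-count fold-change rule", {
  r <- stress_response(2, 8)
  expect_equal(r$log2fc, log2(8.5 / 2.5), tolerance = 1e-12)
  expect_identical(r$direction, "up")
  # exact antisymmetry under swapping control and stress
  r2 <- stress_response(8, 2)
  expect_identical(r2$log2fc, -r$log2fc)
  expect_identical(r2$direction, "down")
  r3 <- stress_response(1, 20)
  expect_equal(r3$log2fc, log2(20.5 / 1.5), tolerance = 1e-12)
  expect_true(r3$log2fc > 2)
  expect_true(r3$highly_up)
  both0 <- stress_response(0, 0)
  expect_true(is.na(both0$log2fc))
  expect_identical(both0$direction, "none")
})

test_that("direction and highly-up flip at the stated thresholds", {
  # engineer control/stress pairs whose log2FC brackets each threshold
  pair_for <- function(fc) c(control = 1.5, stress = 2 * 2^fc - 0.5)
  for (fc in c(0.49, -0.49)) {
    p <- pair_for(fc)
    expect_identical(stress_response(p[1L], p[2L])$direction, "none")
  }
  expect_identical(stress_response(1.5, 2 * 2^0.51 - 0.5)$direction, "up")
  expect_identical(stress_response(1.5, 2 * 2^-0.51 - 0.5)$direction, "down")
  near2 <- stress_response(1.5, 2 * 2^1.99 - 0.5)
  expect_identical(near2$direction, "up")
  expect_false(near2$highly_up)
  over2 <- stress_response(1.5, 2 * 2^2.01 - 0.5)
  expect_true(over2$highly_up)
})

test_that("heat-map export renders sentinels as NA and orders by clade", {
  m <- floor_tpm(toy_matrix())
  f <- tempfile(fileext = ".tsv")
  df <- export_heatmap_matrix(m, f)
  expect_true(is.na(df[df$gene_id == "g_silent", "root"]))
  lines <- readLines(f)
  expect_identical(length(lines), 5L)
  expect_true(grepl("NA", lines[grep("g_silent", lines)]))
  df2 <- export_heatmap_matrix(m, f, clade_map = c(g_mixed = "II",
                                                   g_silent = "I",
                                                   g_root = "I",
                                                   g_ubi = "II"))
  expect_identical(df2$clade, c("I", "I", "II", "II"))
})
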