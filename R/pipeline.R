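#' Run the full serpin-family pipeline on a synthetic family
#'
#' Orchestrates gene-model QC and pseudogene detection, structural curation,
#' phylogeny (alignment, NJ, bootstrap, clade cut), homeologue-set
#' construction with Ka/Ks, and expression profiling, then assembles the
#' summary census.  Re-running with an identical spec reproduces identical
#' output.
#'
#' @param spec A [family_spec()] describing the synthetic inputs.
#' @param out_dir Optional directory to write all stage tables into.
#' @param identity_threshold Homeologue identity threshold (%).
#' @param n_bootstrap Bootstrap replicates for the phylogeny (default 200).
#' @param k_clades Number of clades to cut (default 3).
#' @param tpm_floor TPM floor (default 0.5).
#' @param fc_threshold,high_threshold Stress log2FC thresholds (0.5 and 2).
#' @param min_intron Minimum credible intron length for QC.
#' @param tandem_max_distance Tandem-duplicate distance threshold (bp).
#' @return Object of class `serpin_pipeline`: the family and expression truth
#'   plus per-stage outputs (`qc`, `verdicts`, `tree`, `clades`, `sets`,
#'   `triads`, `kaks`, `expressed`, `specificity`, `stress`, `census`).
#' @export
run_pipeline <- function(spec = family_spec(), out_dir = NULL,
                         identity_threshold = 80, n_bootstrap = 200L,
                         k_clades = 3L, tpm_floor = 0.5, fc_threshold = 0.5,
                         high_threshold = 2, min_intron = 20L,
                         tandem_max_distance = 5e5) {
  fam <- make_hexaploid_family(spec)
  ref <- reference_serpin()
  ref_len <- nchar(ref$protein)

  # stage 1: gene-model QC / pseudogene detection
  qc_calls <- lapply(fam$models, detect_pseudogene, genome = fam$genome,
                     ref_protein_length = ref_len, min_intron = min_intron)
  qc <- do.call(rbind, lapply(qc_calls, function(x) {
    data.frame(gene_id = x$gene_id, is_pseudogene = x$is_pseudogene,
               lesions = paste(x$lesions$type, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL
  intact_ids <- qc$gene_id[!qc$is_pseudogene]

  # stage 2: structural curation of non-pseudogene proteins
  verdicts <- curate_proteins(fam$proteins[intact_ids], ref)
  loc <- parse_traes_id(verdicts$gene_id)
  verdicts$chromosome <- loc$chromosome
  verdicts$subgenome <- loc$subgenome
  curated_ids <- verdicts$gene_id[verdicts$passed]

  # stage 3: phylogeny on curated proteins
  tree <- NULL; clades <- NULL
  if (length(curated_ids) >= 4L) {
    aln <- progressive_align(fam$proteins[curated_ids])
    tree <- bootstrap_support(aln, n_replicates = n_bootstrap,
                              seed = sub_seed(spec$seed, 555L))
    clades <- cut_clades(tree, k = k_clades)
  }

  # stage 4: homeologue sets and Ka/Ks on curated genes
  starts <- vapply(fam$models[curated_ids],
                   function(m) m$exons[1L, 1L], 0)
  genes_df <- data.frame(
    gene_id = curated_ids,
    subgenome = parse_traes_id(curated_ids)$subgenome,
    chromosome = vapply(fam$models[curated_ids],
                        function(m) m$chromosome, ""),
    start = starts, protein = unname(fam$proteins[curated_ids]),
    stringsAsFactors = FALSE)
  sets <- build_homeologue_sets(genes_df, identity_threshold,
                                clades = clades,
                                tandem_max_distance = tandem_max_distance)
  triads <- triad_table(sets)
  kaks_tab <- pipeline_kaks(sets, fam$cds)

  # stage 5: expression profiling
  em <- make_expression_matrix(fam$truth$genes, spec = spec,
                               seed = sub_seed(spec$seed, 888L))
  floored <- floor_tpm(em$expr, tpm_floor)
  ctrl <- floored$samples$condition == "control"
  ctrl_m <- expression_matrix(floored$tpm[, ctrl, drop = FALSE],
                              floored$samples[ctrl, , drop = FALSE])
  attr(ctrl_m, "floored") <- TRUE
  expressed <- call_expressed(ctrl_m)
  specificity <- tissue_specificity(ctrl_m)
  stress <- stress_response_table(floored, floor = tpm_floor,
                                  fc_threshold = fc_threshold,
                                  high_threshold = high_threshold)

  census <- census_tables(verdicts, sets, expressed[curated_ids],
                          stress[stress$gene_id %in% curated_ids, ], clades)
  res <- structure(list(family = fam, expr_truth = em$truth, qc = qc,
                        verdicts = verdicts, tree = tree, clades = clades,
                        sets = sets, triads = triads, kaks = kaks_tab,
                        expr = floored, expressed = expressed,
                        specificity = specificity, stress = stress,
                        census = census),
                   class = "serpin_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

pipeline_kaks <- function(sets, cds) {
  rows <- list()
  strip_stop <- function(x) {
    n <- nchar(x)
    last <- substr(x, n - 2L, n)
    if (!is.na(Biostrings::GENETIC_CODE[last]) &&
        Biostrings::GENETIC_CODE[last] == "*") substr(x, 1L, n - 3L) else x
  }
  for (s in sets) {
    ids <- s$members$gene_id
    if (length(ids) < 2L) next
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        a <- strip_stop(cds[[ids[i]]]); b <- strip_stop(cds[[ids[j]]])
        if (nchar(a) != nchar(b)) next
        k <- kaks(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = s$set_id, gene_a = ids[i], gene_b = ids[j],
          S = k$syn_sites, N = k$nonsyn_sites, Sd = k$syn_diffs,
          Nd = k$nonsyn_diffs, ka = k$ka, ks = k$ks, ratio = k$ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(set_id = character(0), gene_a = character(0),
                  gene_b = character(0), S = numeric(0), N = numeric(0),
                  Sd = numeric(0), Nd = numeric(0), ka = numeric(0),
                  ks = numeric(0), ratio = numeric(0))
}

#' Summary census tables
#'
#' Assembles the per-chromosome x subgenome counts of curated genes, the
#' homeologue-pattern census with integer-rounded percentages, the
#' expressed/not-expressed counts, and the stress-responsive gene table.
#'
#' @param verdicts Curation verdict table with `chromosome` and `subgenome`.
#' @param sets Homeologue sets from [build_homeologue_sets()].
#' @param expressed Named logical vector of expressed calls for curated genes.
#' @param stress Stress-response table restricted to curated genes.
#' @param clades Optional clade map.
#' @return List of class `serpin_census` with `chromosome_table`,
#'   `pattern_census`, `expression_counts`, `stress_table` and `totals`.
#' @export
census_tables <- function(verdicts, sets, expressed = NULL, stress = NULL,
                          clades = NULL) {
  cur <- verdicts[verdicts$passed, , drop = FALSE]
  total <- nrow(cur)
  chrom_num <- sub("[ABD]$", "", cur$chromosome)
  chrom_levels <- sort(unique(chrom_num))
  tab <- matrix(0L, length(chrom_levels) + 1L, 4L,
                dimnames = list(c(chrom_levels, "Total"),
                                c("A", "B", "D", "Total")))
  for (i in seq_along(chrom_levels)) {
    for (s in c("A", "B", "D"))
      tab[i, s] <- sum(chrom_num == chrom_levels[i] & cur$subgenome == s)
    tab[i, "Total"] <- sum(chrom_num == chrom_levels[i])
  }
  tab["Total", ] <- as.integer(colSums(tab[seq_along(chrom_levels), ,
                                            drop = FALSE]))
  tt <- triad_table(sets)
  pat_sets <- vapply(sets, function(s) s$pattern, "")
  pat_genes <- table(tt$pattern)[unique(pat_sets)]
  pattern_census <- data.frame(
    pattern = unique(pat_sets),
    n_sets = as.integer(table(pat_sets)[unique(pat_sets)]),
    n_genes = as.integer(pat_genes),
    stringsAsFactors = FALSE)
  pattern_census$pct_genes <- round(100 * pattern_census$n_genes /
                                      max(1L, total))
  pattern_census$formatted <- sprintf("%d (%d%%)", pattern_census$n_genes,
                                      pattern_census$pct_genes)
  expression_counts <- if (!is.null(expressed)) {
    c(expressed = sum(expressed), not_expressed = sum(!expressed))
  } else c(expressed = NA_integer_, not_expressed = NA_integer_)
  stress_table <- NULL
  if (!is.null(stress) && nrow(stress)) {
    up <- stress[stress$direction == "up", , drop = FALSE]
    if (nrow(up)) {
      agg <- split(up, up$gene_id)
      stress_table <- do.call(rbind, lapply(agg, function(d) {
        data.frame(gene_id = d$gene_id[1L],
                   clade = if (!is.null(clades))
                     unname(clades[d$gene_id[1L]]) else NA_character_,
                   stresses = paste(sort(d$stress_label), collapse = ","),
                   highly_up = any(d$highly_up), stringsAsFactors = FALSE)
      }))
      rownames(stress_table) <- NULL
    }
  }
  structure(list(chromosome_table = tab, pattern_census = pattern_census,
                 expression_counts = expression_counts,
                 stress_table = stress_table, totals = tab["Total", ]),
            class = "serpin_census")
}

#' @export
print.serpin_census <- function(x, ...) {
  cat("Curated genes per chromosome and subgenome:\n")
  print(x$chromosome_table)
  cat("\nHomeologue pattern census:\n")
  print(x$pattern_census[, c("pattern", "n_sets", "formatted")],
        row.names = FALSE)
  cat(sprintf("\nExpressed: %s; not expressed: %s\n",
              x$expression_counts[["expressed"]],
              x$expression_counts[["not_expressed"]]))
  if (!is.null(x$stress_table)) {
    cat("\nStress-upregulated genes:\n")
    print(x$stress_table, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.serpin_pipeline <- function(x, ...) {
  cat(sprintf("<serpin_pipeline> %d genes (%d curated), %d homeologue sets\n",
              length(x$family$models), sum(x$verdicts$passed),
              length(x$sets)))
  print(x$census)
  invisible(x)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(res$qc, "qc.tsv")
  wt(res$verdicts, "verdicts.tsv")
  wt(res$triads, "triads.tsv")
  wt(res$kaks, "kaks.tsv")
  if (!is.null(res$tree)) write_newick(res$tree, file.path(out_dir, "tree.nwk"))
  if (!is.null(res$clades))
    wt(data.frame(gene_id = names(res$clades), clade = unname(res$clades)),
       "clades.tsv")
  wt(res$specificity, "specificity.tsv")
  wt(res$stress, "stress.tsv")
  export_heatmap_matrix(res$expr, file.path(out_dir, "heatmap_tissue.tsv"),
                        clade_map = res$clades)
  utils::write.table(res$census$chromosome_table,
                     file.path(out_dir, "census_chromosomes.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  wt(res$census$pattern_census, "census_patterns.tsv")
  invisible(out_dir)
}
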