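#' Floor low TPM values to zero
#'
#' TPM values lower than `floor` (default 0.5) are treated as no expression
#' and set to 0; values at or above the floor are unchanged.  Idempotent.
#'
#' @param m An `expr_matrix` or plain numeric matrix.
#' @param floor Floor value; the strictly-less rule keeps values equal to the
#'   floor.
#' @return Same type as the input, with attribute `floored = TRUE`.
#' @export
floor_tpm <- function(m, floor = 0.5) {
  if (inherits(m, "expr_matrix")) {
    m$tpm[m$tpm < floor] <- 0
    attr(m, "floored") <- TRUE
    return(m)
  }
  m[m < floor] <- 0
  attr(m, "floored") <- TRUE
  m
}

is_floored <- function(m) isTRUE(attr(m, "floored"))

#' Log2-transform a floored expression matrix
#'
#' Non-zero entries become `log2(TPM)`; zero ("not expressed") entries become
#' the sentinel `NA` rather than `-Inf`, so they are excluded from any
#' downstream scaling.
#'
#' @param m A floored `expr_matrix` or matrix (see [floor_tpm()]).
#' @return Numeric matrix of log2 values with `NA` sentinels.
#' @export
log2_matrix <- function(m) {
  if (!is_floored(m)) stop("apply floor_tpm() before log2_matrix()")
  tpm <- if (inherits(m, "expr_matrix")) m$tpm else m
  out <- log2(tpm)
  out[tpm == 0] <- NA_real_
  out
}

#' Expressed / not-expressed calls
#'
#' A gene is called expressed when any sample entry is greater than zero after
#' flooring.
#'
#' @param m A floored `expr_matrix`.
#' @param gene_id Optional single gene (returns a logical); default all genes.
#' @return Logical vector named by gene.
#' @export
call_expressed <- function(m, gene_id = NULL) {
  if (!is_floored(m)) stop("apply floor_tpm() first")
  tpm <- if (inherits(m, "expr_matrix")) m$tpm else m
  if (!is.null(gene_id)) {
    if (!gene_id %in% rownames(tpm)) stop("unknown gene: ", gene_id)
    return(any(tpm[gene_id, ] > 0))
  }
  apply(tpm > 0, 1L, any)
}

#' Tissue-specificity calls
#'
#' A gene is expressed in a tissue group when the chosen statistic (mean by
#' default) of its floored TPM over the group's samples is at least
#' `min_level`.  Genes expressed nowhere are `not_expressed`; genes expressed
#' in every group are `ubiquitous`; the rest are `specific` and report their
#' tissue set.
#'
#' @param m A floored `expr_matrix`.
#' @param grouping Optional factor/character of tissue groups per sample;
#'   defaults to `m$samples$tissue`.  Every sample must be assigned a
#'   non-empty group.
#' @param min_level Expression threshold on the per-group statistic (default
#'   0.5, the TPM floor).
#' @param stat `"mean"` or `"max"`.
#' @return Data frame: `gene_id`, `label`
#'   (`not_expressed`/`ubiquitous`/`specific`), `tissues` (comma-separated).
#' @export
tissue_specificity <- function(m, grouping = NULL, min_level = 0.5,
                               stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (!is_floored(m)) stop("apply floor_tpm() first")
  tpm <- if (inherits(m, "expr_matrix")) m$tpm else m
  if (is.null(grouping)) {
    if (!inherits(m, "expr_matrix")) stop("grouping required for bare matrices")
    grouping <- m$samples$tissue
  }
  if (any(is.na(grouping) | !nzchar(grouping)))
    stop("every sample needs a tissue group")
  groups <- unique(grouping)
  f <- if (stat == "mean") rowMeans else function(x) apply(x, 1L, max)
  per_group <- vapply(groups, function(g) {
    cols <- which(grouping == g)
    if (!length(cols)) stop("empty tissue group: ", g)
    f(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  expressed <- per_group >= min_level
  lab <- function(i) {
    tt <- groups[expressed[i, ]]
    if (!length(tt)) list("not_expressed", "")
    else if (length(tt) == length(groups)) list("ubiquitous", paste(sort(tt), collapse = ","))
    else list("specific", paste(sort(tt), collapse = ","))
  }
  res <- lapply(seq_len(nrow(tpm)), lab)
  data.frame(gene_id = rownames(tpm),
             label = vapply(res, `[[`, "", 1L),
             tissues = vapply(res, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Stress-response classification of a control/stress TPM pair
#'
#' The fold change is computed with a pseudo-count equal to the TPM floor,
#' `log2FC = log2((stress + eps) / (control + eps))`, which keeps fold changes
#' finite when one side is silent and is exactly antisymmetric under swapping
#' control and stress.  Direction is `up` when log2FC > `fc_threshold`,
#' `down` when < -`fc_threshold`; `highly_up` requires log2FC >
#' `high_threshold`.
#'
#' @param control_tpm,stress_tpm Floored TPM values (vectorised).
#' @param floor TPM floor; also the pseudo-count `eps`.
#' @param fc_threshold Direction threshold on |log2FC| (default 0.5).
#' @param high_threshold Threshold for `highly_up` (default 2).
#' @return Data frame: `log2fc`, `direction` (`up`/`down`/`none`),
#'   `highly_up`.  Pairs with both sides zero get `log2fc = NA` and direction
#'   `none`.
#' @export
stress_response <- function(control_tpm, stress_tpm, floor = 0.5,
                            fc_threshold = 0.5, high_threshold = 2) {
  if (any(control_tpm < 0) || any(stress_tpm < 0)) stop("negative TPM")
  eps <- floor
  # difference of logs, so swapping control and stress negates exactly
  log2fc <- log2(stress_tpm + eps) - log2(control_tpm + eps)
  both_zero <- control_tpm == 0 & stress_tpm == 0
  log2fc[both_zero] <- NA_real_
  direction <- rep("none", length(log2fc))
  direction[!is.na(log2fc) & log2fc > fc_threshold] <- "up"
  direction[!is.na(log2fc) & log2fc < -fc_threshold] <- "down"
  data.frame(log2fc = log2fc, direction = direction,
             highly_up = !is.na(log2fc) & log2fc > high_threshold)
}

#' Stress-response table over all control/stress pairings
#'
#' For each gene and stress label, control and stress TPM are averaged over
#' the paired samples and classified with [stress_response()].
#'
#' @param m A floored `expr_matrix` whose metadata contains stress samples
#'   with `pair_id` pointing at their control samples.
#' @param ... Passed to [stress_response()].
#' @return Data frame: `gene_id`, `stress_label`, `log2fc`, `direction`,
#'   `highly_up`.
#' @export
stress_response_table <- function(m, ...) {
  if (!inherits(m, "expr_matrix")) stop("m must be an expr_matrix")
  if (!is_floored(m)) stop("apply floor_tpm() first")
  s <- m$samples
  stress_labels <- unique(s$stress_label[s$condition == "stress"])
  out <- list()
  for (lbl in stress_labels) {
    st_cols <- which(s$condition == "stress" & s$stress_label == lbl)
    ct_ids <- unique(s$pair_id[st_cols])
    ct_cols <- which(s$sample_id %in% ct_ids)
    ctrl <- rowMeans(m$tpm[, ct_cols, drop = FALSE])
    strs <- rowMeans(m$tpm[, st_cols, drop = FALSE])
    resp <- stress_response(ctrl, strs, ...)
    out[[lbl]] <- data.frame(gene_id = rownames(m$tpm), stress_label = lbl,
                             resp, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a heat-map matrix as TSV
#'
#' Writes a genes x tissue-groups matrix of log2 mean expression (sentinel
#' zeros rendered `NA`).  When a clade map is supplied, rows are grouped by
#' clade (I, II, III, ...) and a `clade` column is included.
#'
#' @param m A floored `expr_matrix`.
#' @param path Output TSV path.
#' @param grouping Optional tissue grouping (default `m$samples$tissue`).
#' @param clade_map Optional named vector mapping gene_id to clade label.
#' @return The exported data frame, invisibly.
#' @export
export_heatmap_matrix <- function(m, path, grouping = NULL, clade_map = NULL) {
  if (!is_floored(m)) stop("apply floor_tpm() first")
  if (is.null(grouping)) grouping <- m$samples$tissue
  groups <- unique(grouping)
  means <- vapply(groups, function(g) {
    rowMeans(m$tpm[, grouping == g, drop = FALSE])
  }, numeric(nrow(m$tpm)))
  vals <- log2(means)
  vals[means == 0] <- NA_real_
  df <- data.frame(gene_id = rownames(m$tpm), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(clade_map)) {
    df$clade <- unname(clade_map[df$gene_id])
    df <- df[order(df$clade, df$gene_id), c("gene_id", "clade", groups)]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(df)
}
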