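#' Construct an expression matrix with sample metadata
#'
#' The container pairs a genes x samples TPM matrix with a sample-metadata
#' table (tissue, growth stage, cultivar, control/stress pairing).  All
#' downstream tissue-specificity and stress-response calls operate on it.
#'
#' @param tpm Numeric matrix (genes x samples) of non-negative TPM values with
#'   row and column names.
#' @param samples Data frame with one row per matrix column and columns
#'   `sample_id`, `tissue`, `stage`, `cultivar`, `condition`
#'   (`"control"`/`"stress"`), `stress_label`, `pair_id`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(tpm, samples) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("tpm must have gene row names and sample column names")
  if (anyNA(tpm)) stop("missing values in TPM matrix")
  if (any(tpm < 0)) {
    bad <- which(tpm < 0, arr.ind = TRUE)[1L, ]
    stop("negative TPM value for gene '", rownames(tpm)[bad[1L]], "'")
  }
  required <- c("sample_id", "tissue", "stage", "cultivar", "condition",
                "stress_label", "pair_id")
  miss <- setdiff(required, names(samples))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  absent <- setdiff(colnames(tpm), samples$sample_id)
  if (length(absent))
    stop("sample '", absent[1L], "' in matrix is absent from metadata")
  samples <- samples[match(colnames(tpm), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  stress <- samples$condition == "stress"
  if (any(stress & !nzchar(samples$stress_label)))
    stop("stress sample without a stress_label")
  ctrl_ids <- samples$sample_id[samples$condition == "control"]
  bad_pair <- stress & !(samples$pair_id %in% ctrl_ids)
  if (any(bad_pair))
    stop("stress sample '", samples$sample_id[bad_pair][1L],
         "' pair_id does not name a control sample")
  structure(list(tpm = tpm, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d control, %d stress)%s\n",
              nrow(x$tpm), ncol(x$tpm),
              sum(x$samples$condition == "control"),
              sum(x$samples$condition == "stress"),
              if (isTRUE(attr(x, "floored"))) ", floored" else ""))
  invisible(x)
}

#' Read a TPM matrix and its sample metadata from TSV files
#'
#' @param matrix_path TSV with gene rows (first column = gene ID) and sample
#'   columns of non-negative TPM values.
#' @param meta_path TSV with one row per sample column.
#' @return An `expr_matrix` object.
#' @export
read_expression_tsv <- function(matrix_path, meta_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  tpm <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(tpm)) stop("non-numeric TPM values in ", matrix_path)
  rownames(tpm) <- raw[[1L]]
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_matrix(tpm, meta)
}

#' Write an expression matrix and its metadata to TSV files
#'
#' @param m An `expr_matrix`.
#' @param matrix_path,meta_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_tsv <- function(m, matrix_path, meta_path) {
  df <- data.frame(gene_id = rownames(m$tpm), m$tpm, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}
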