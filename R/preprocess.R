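# Expression pre-processing: gene/cell filtering, normalization-state
# detection, median-library size-factor normalization, log transform.

#' Pre-processing parameters
#'
#' @param gene_min_cell_fraction Keep a gene when it is non-zero in at least
#'   this fraction of cells (default 0.001, i.e. genes with zero values in
#'   more than 99.9% of cells are removed).
#' @param cell_min_genes Keep a cell when it expresses at least this many
#'   genes (non-zero entries; default 200).
#' @return A `PreprocessParams` list.
#' @export
preprocess_params <- function(gene_min_cell_fraction = 0.001,
                              cell_min_genes = 200L) {
  if (!(gene_min_cell_fraction > 0 && gene_min_cell_fraction < 1))
    domain_error("gene_min_cell_fraction must be in (0, 1)")
  if (cell_min_genes < 0) domain_error("cell_min_genes must be >= 0")
  structure(list(gene_min_cell_fraction = gene_min_cell_fraction,
                 cell_min_genes = as.integer(cell_min_genes)),
            class = "PreprocessParams")
}

#' Filter genes and cells
#'
#' Removes genes that are non-zero in less than `gene_min_cell_fraction` of
#' cells, then cells with fewer than `cell_min_genes` non-zero genes. The
#' gene filter is applied first and is not recomputed after cell removal.
#'
#' @param em An [expression_matrix()].
#' @param p A [preprocess_params()].
#' @return The filtered [expression_matrix()].
#' @export
filter_matrix <- function(em, p = preprocess_params()) {
  v <- em$values
  nz_cells <- rowSums(v != 0)
  keep_genes <- nz_cells / ncol(v) >= p$gene_min_cell_fraction
  if (!any(keep_genes))
    abort(sprintf("all %d genes removed by the %.4f min-cell-fraction filter",
                  nrow(v), p$gene_min_cell_fraction), "scregulon_empty_error")
  v <- v[keep_genes, , drop = FALSE]
  nz_genes <- colSums(v != 0)
  keep_cells <- nz_genes >= p$cell_min_genes
  if (!any(keep_cells))
    abort(sprintf("all %d cells removed by the %d min-genes filter",
                  ncol(v), p$cell_min_genes), "scregulon_empty_error")
  expression_matrix(v[, keep_cells, drop = FALSE],
                    em$gene_ids[keep_genes], em$cell_ids[keep_cells],
                    em$normalized, em$log_transformed)
}

#' Detect whether a matrix is already normalized
#'
#' Integer-valued matrices are treated as raw (non-normalized) counts;
#' any fractional entry marks the matrix as normalized. Integer counts
#' stored as floating point (e.g. `5.0`) count as integers (tolerance
#' 1e-9 on the fractional part).
#'
#' @param em An [expression_matrix()].
#' @return `TRUE` when the matrix looks normalized, `FALSE` for raw counts.
#' @export
detect_normalization <- function(em) {
  v <- em$values[em$values != 0]
  if (!length(v)) return(FALSE)
  any(abs(v - round(v)) >= 1e-9)
}

#' Normalize and log-transform
#'
#' For raw counts, each cell is divided by its size factor
#' `s_c = library_size(c) / median(library sizes)`; already-normalized
#' input is left unscaled. In both cases `log(x + 1)` (natural log) is then
#' applied and the normalization flags are set.
#'
#' @param em An [expression_matrix()].
#' @param p A [preprocess_params()] (unused fields reserved).
#' @return The normalized, log-transformed [expression_matrix()].
#' @export
normalize_and_log <- function(em, p = preprocess_params()) {
  v <- em$values
  if (!em$normalized && !detect_normalization(em)) {
    lib <- colSums(v)
    if (any(lib == 0))
      domain_error(sprintf("%d cell(s) have zero library size", sum(lib == 0)))
    s <- lib / stats::median(lib)
    v <- sweep(v, 2L, s, "/")
  }
  if (!em$log_transformed) v <- log1p(v)
  expression_matrix(v, em$gene_ids, em$cell_ids,
                    normalized = TRUE, log_transformed = TRUE)
}

#' Run the full pre-processing stage
#'
#' Convenience wrapper: [filter_matrix()] then [normalize_and_log()]. An
#' optional imputation hook is accepted but defaults to the identity (no
#' imputation is implemented).
#'
#' @param em An [expression_matrix()].
#' @param p A [preprocess_params()].
#' @param impute_fn Optional function `ExpressionMatrix -> ExpressionMatrix`
#'   applied between filtering and normalization.
#' @param skip_normalize If `TRUE`, only filtering (and the hook) is applied.
#' @return The pre-processed [expression_matrix()].
#' @export
preprocess <- function(em, p = preprocess_params(), impute_fn = NULL,
                       skip_normalize = FALSE) {
  em <- filter_matrix(em, p)
  if (!is.null(impute_fn)) em <- impute_fn(em)
  if (!skip_normalize) em <- normalize_and_log(em, p)
  em
}
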