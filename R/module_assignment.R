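# Active gene-module determination: hypergeometric enrichment of each
# bicluster's cell set in each cell type, Bonferroni-adjusted over all
# (cell type, bicluster) tests.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` cells of a `K`-cell type when sampling `n` of `N`
#' cells without replacement. Computed through the stable distribution
#' function rather than naive term summation.
#'
#' @param k Observed overlap.
#' @param K Number of cells in the cell type.
#' @param n Number of cells in the bicluster.
#' @param N Total number of cells.
#' @return The upper-tail probability (1 when `k = 0`).
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    domain_error("hypergeometric arguments must satisfy 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assign biclusters to cell types as active gene modules
#'
#' Every (bicluster, cell type) pair is tested for enrichment of the
#' bicluster's cell set in the cell type with [hypergeom_tail()]. Raw
#' p-values are Bonferroni-adjusted by multiplying by
#' `n_cell_types * n_biclusters` (the total number of biclusters supplied,
#' before any filtering). Each significant pair yields a gene module, so a
#' bicluster may be active in several cell types; the most significant type
#' per bicluster is flagged.
#'
#' @param biclusters List of `Bicluster` objects from [run_biclustering()].
#' @param labeling A [cell_labeling()] covering all bicluster cells.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A list of `GeneModule` lists with `genes`, `cell_type`, `p_raw`,
#'   `p_adj`, `source_bicluster`, `is_best`.
#' @export
assign_modules <- function(biclusters, labeling, alpha = 0.05) {
  if (!length(biclusters)) return(list())
  lab_map <- stats::setNames(labeling$labels, labeling$cell_ids)
  N <- length(labeling$cell_ids)
  multiplier <- length(labeling$label_set) * length(biclusters)
  type_sizes <- table(factor(labeling$labels, levels = labeling$label_set))
  modules <- list()
  for (b in seq_along(biclusters)) {
    bc <- biclusters[[b]]
    cells <- bc$cells
    if (!all(cells %in% names(lab_map)))
      domain_error(sprintf("bicluster %d contains cells absent from the labeling", b))
    bc_labels <- lab_map[cells]
    p_raw <- vapply(labeling$label_set, function(ct)
      hypergeom_tail(sum(bc_labels == ct), type_sizes[[ct]], length(cells), N),
      numeric(1))
    p_adj <- pmin(p_raw * multiplier, 1)
    best_ct <- labeling$label_set[which.min(p_raw)]
    for (ct in labeling$label_set[p_adj < alpha]) {
      modules[[length(modules) + 1L]] <- structure(
        list(genes = bc$genes, cell_type = ct,
             p_raw = unname(p_raw[[ct]]), p_adj = unname(p_adj[[ct]]),
             source_bicluster = b, is_best = identical(ct, best_ct)),
        class = "GeneModule")
    }
  }
  modules
}

#' Write a module table
#'
#' @param modules List of `GeneModule`s from [assign_modules()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_module_table <- function(modules, path) {
  tab <- do.call(rbind, lapply(modules, function(m) data.frame(
    cell_type = m$cell_type, source_bicluster = m$source_bicluster,
    n_genes = length(m$genes), p_raw = fmt_num(m$p_raw),
    p_adj = fmt_num(m$p_adj), stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(cell_type = character(), source_bicluster = integer(),
                      n_genes = integer(), p_raw = character(), p_adj = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a user-supplied gene-module list
#'
#' One gene list per column: the header row names each module, and each
#' column below lists that module's genes (columns may have different
#' lengths; empty fields are ignored). Such modules bypass biclustering and
#' are considered candidate modules for every cell type.
#'
#' @param path Path to the delimited module-list file.
#' @return A named list of character vectors (one per column).
#' @export
read_gene_modules <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) format_error(sprintf("module list file has no genes: %s", path))
  delim <- guess_delimiter(lines[[1L]])
  rows <- lapply(lines, split_fields, delimiter = delim)
  header <- rows[[1L]]
  cols <- lapply(seq_along(header), function(j) {
    vals <- vapply(rows[-1L], function(r) if (length(r) >= j) r[[j]] else "", "")
    unique(vals[nzchar(trimws(vals))])
  })
  stats::setNames(cols, header)
}
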