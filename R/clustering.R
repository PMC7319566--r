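# Cell clustering fallback, clustering-agreement indexes, and one-vs-rest
# Wilcoxon marker-gene (DEG) detection used for evaluation.

#' Cluster cells by PCA + k-means
#'
#' A deterministic fallback clusterer for when no cell labels are supplied:
#' the top `n_top_genes` most variable genes (variance of log values) are
#' standardized, projected onto `n_pcs` principal components, and clustered
#' with k-means. User-provided labels always take precedence in the
#' pipeline; this is plumbing, not a reimplementation of graph-based
#' single-cell clustering.
#'
#' @param em A log-normalized [expression_matrix()].
#' @param k Number of clusters.
#' @param n_pcs Number of principal components (default 10).
#' @param n_top_genes Number of top-variable genes used (default 2000).
#' @param seed Integer seed; the labeling is reproducible given the seed.
#' @return A [cell_labeling()] with labels `"C1".."Ck"` numbered by first
#'   appearance in cell order.
#' @export
cluster_cells <- function(em, k, n_pcs = 10L, n_top_genes = 2000L, seed = 1L) {
  n_cells <- ncol(em$values)
  if (n_cells < k) domain_error(sprintf("fewer cells (%d) than clusters (%d)",
                                        n_cells, k))
  if (k == 1L)
    return(cell_labeling(em$cell_ids, rep("C1", n_cells)))
  vars <- apply(em$values, 1L, stats::var)
  top <- order(vars, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(em$values)))]
  x <- t(em$values[top, , drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  x <- scale(x[, sds > 0, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(x), n_cells - 1L)
  pcs <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)$x
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(pcs, centers = k, nstart = 10L, iter.max = 100L)
  # relabel clusters by first appearance so labels are order-stable
  first_seen <- unique(km$cluster)
  labs <- paste0("C", match(km$cluster, first_seen))
  cell_labeling(em$cell_ids, labs)
}

# 2x2 pair counts between two labelings: (a11, a10, a01, a00).
pair_counts <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  total <- choose(n, 2)
  s_ij <- sum(choose(tab, 2))
  s_i <- sum(choose(rowSums(tab), 2))
  s_j <- sum(choose(colSums(tab), 2))
  c(a11 = s_ij, a10 = s_i - s_ij, a01 = s_j - s_ij,
    a00 = total - s_i - s_j + s_ij)
}

#' Clustering-agreement indexes
#'
#' Computes the Rand index, adjusted Rand index, Jaccard index and
#' Fowlkes-Mallows index between two labelings of the same cells, using the
#' pair-counting definitions. All four are invariant to label renaming and
#' symmetric in their arguments.
#'
#' @param a,b Two [cell_labeling()]s over the same cell set.
#' @return A list with `rand`, `adjusted_rand`, `jaccard`, `fowlkes_mallows`.
#' @export
clustering_agreement <- function(a, b) {
  if (!setequal(a$cell_ids, b$cell_ids) ||
      length(a$cell_ids) != length(b$cell_ids))
    domain_error("labelings cover different cell sets")
  bl <- b$labels[match(a$cell_ids, b$cell_ids)]
  pc <- pair_counts(a$labels, bl)
  total <- sum(pc)
  rand <- (pc[["a11"]] + pc[["a00"]]) / total
  denom11 <- pc[["a11"]] + pc[["a10"]] + pc[["a01"]]
  jac <- if (denom11 == 0) 1 else pc[["a11"]] / denom11
  fm_den <- sqrt((pc[["a11"]] + pc[["a10"]]) * (pc[["a11"]] + pc[["a01"]]))
  fm <- if (fm_den == 0) 1 else pc[["a11"]] / fm_den
  # ARI via expected-index correction on the contingency table
  s_ij <- pc[["a11"]]
  s_i <- pc[["a11"]] + pc[["a10"]]
  s_j <- pc[["a11"]] + pc[["a01"]]
  expected <- s_i * s_j / total
  max_idx <- (s_i + s_j) / 2
  ari <- if (max_idx == expected) 1 else (s_ij - expected) / (max_idx - expected)
  list(rand = unname(rand), adjusted_rand = unname(ari),
       jaccard = unname(jac), fowlkes_mallows = unname(fm))
}

# Two-sided Wilcoxon rank-sum p-value for one gene, given precomputed ranks
# over all cells. Uses the exact distribution for small tie-free groups
# (matching stats::wilcox.test defaults) and the normal approximation with
# tie correction and continuity correction otherwise.
wilcox_p <- function(ranks, in_group, tie_term, has_ties) {
  n1 <- sum(in_group)
  n2 <- length(ranks) - n1
  r1 <- sum(ranks[in_group])
  u <- r1 - n1 * (n1 + 1) / 2
  if (!has_ties && n1 < 50 && n2 < 50) {
    if (u > n1 * n2 / 2) {
      p <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- stats::pwilcox(u, n1, n2)
    }
    return(min(1, 2 * p))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5) # continuity correction
  min(1, 2 * stats::pnorm(abs(z) / sqrt(sigma2), lower.tail = FALSE))
}

#' One-vs-rest differentially expressed genes
#'
#' For every cell type with at least 3 cells, tests each gene with a
#' two-sided Wilcoxon rank-sum test of that type's cells against all other
#' cells (exact for small tie-free groups, normal approximation with tie
#' correction otherwise). P-values are Benjamini-Hochberg adjusted within
#' each cell type. The log2 fold change is computed on means of `expm1`
#' values with a +1 pseudocount.
#'
#' @param em A log-normalized [expression_matrix()].
#' @param labeling A [cell_labeling()] aligned with `em`.
#' @param deg_alpha Adjusted-p threshold for the `is_deg` flag (default 0.05).
#' @param lfc_min Minimum log2 fold change for the `is_deg` flag (default 0.25).
#' @return A `DEGTable` data frame with columns `gene_id`, `cell_type`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `is_deg`.
#' @export
find_degs <- function(em, labeling, deg_alpha = 0.05, lfc_min = 0.25) {
  if (length(labeling$label_set) < 2L)
    domain_error("DEG detection needs at least 2 cell types")
  stopifnot(identical(em$cell_ids, labeling$cell_ids))
  v <- em$values
  expv <- expm1(v)
  # rank each gene's values across all cells once; reused for every type
  rk <- t(apply(v, 1L, rank))
  tie_terms <- apply(v, 1L, function(x) {
    t <- table(x); sum(t^3 - t)
  })
  has_ties <- tie_terms > 0
  out <- list()
  for (ct in labeling$label_set) {
    in_ct <- labeling$labels == ct
    if (sum(in_ct) < 3L) {
      warning(sprintf("cell type '%s' has fewer than 3 cells; skipped", ct),
              call. = FALSE)
      next
    }
    p <- vapply(seq_len(nrow(v)), function(i)
      wilcox_p(rk[i, ], in_ct, tie_terms[i], has_ties[i]), numeric(1))
    lfc <- log2((rowMeans(expv[, in_ct, drop = FALSE]) + 1) /
                (rowMeans(expv[, !in_ct, drop = FALSE]) + 1))
    padj <- stats::p.adjust(p, method = "BH")
    out[[ct]] <- data.frame(gene_id = em$gene_ids, cell_type = ct,
                            log2_fold_change = lfc, p_value = p,
                            adjusted_p = padj,
                            is_deg = padj < deg_alpha & lfc >= lfc_min,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out)) domain_error("no cell type had enough cells for DEG testing")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("DEGTable", "data.frame")
  res
}

#' Fraction of a regulon's genes that are DEGs of a cell type
#'
#' @param regulon_genes Character vector of the regulon's genes (non-empty).
#' @param deg_table A `DEGTable` from [find_degs()].
#' @param cell_type The cell type the regulon is assigned to.
#' @return The fraction of regulon genes flagged as DEGs in that cell type.
#' @export
deg_coverage <- function(regulon_genes, deg_table, cell_type) {
  if (!length(regulon_genes)) domain_error("empty regulon")
  degs <- deg_table$gene_id[deg_table$cell_type == cell_type & deg_table$is_deg]
  length(intersect(regulon_genes, degs)) / length(regulon_genes)
}
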