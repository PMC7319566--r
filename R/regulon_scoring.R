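# Regulon scoring: per-cell rank matrix, recovery-curve regulon activity
# scores (RAS), divergence-based regulon specificity scores (RSS), bootstrap
# empirical p-values against random gene sets, and CTSR calling/naming.

#' Per-cell descending expression ranks
#'
#' For each cell, genes are ranked by expression value descending (rank 1 =
#' highest); ties are broken by ascending gene index so the ranking is a
#' deterministic permutation.
#'
#' @param em A log-normalized [expression_matrix()].
#' @return A `RankMatrix`: integer genes-by-cells matrix, each column a
#'   permutation of `1..n_genes`.
#' @export
rank_genes_per_cell <- function(em) {
  v <- em$values
  n <- nrow(v)
  rk <- matrix(0L, n, ncol(v), dimnames = dimnames(v))
  gi <- seq_len(n)
  for (j in seq_len(ncol(v))) {
    rk[order(-v[, j], gi), j] <- gi
  }
  structure(rk, class = c("RankMatrix", class(rk)))
}

# Recovery-curve weight matrix: contribution of a gene at rank r to the
# cumulative recovery sum over k = 1..K is max(K - r + 1, 0).
ras_weights <- function(ranks, K) {
  w <- K - unclass(ranks) + 1L
  w[w < 0L] <- 0L
  w
}

ras_denominator <- function(g, K) {
  m <- min(g, K)
  sum(seq.int(K, K - m + 1L))
}

#' Regulon activity score (RAS) per cell
#'
#' The recovery-curve AUC of the regulon's genes in each cell's ranking:
#' for `k = 1..K` (with `K = ceiling(top_fraction * n_genes)`) count the
#' regulon genes at rank `<= k`; the RAS is the sum of these counts divided
#' by the maximum achievable sum for this regulon size, so RAS is 1 when
#' the regulon occupies the top ranks and 0 when no gene is in the top `K`.
#'
#' @param ranks A `RankMatrix` from [rank_genes_per_cell()].
#' @param regulon_genes Character vector of the regulon's genes.
#' @param top_fraction Fraction of the ranking forming the recovery window
#'   (default 0.05).
#' @return Numeric RAS vector over cells, in `[0, 1]`.
#' @export
regulon_activity <- function(ranks, regulon_genes, top_fraction = 0.05) {
  present <- regulon_genes %in% rownames(ranks)
  if (any(!present)) {
    warning(sprintf("%d regulon gene(s) missing from matrix; dropped",
                    sum(!present)), call. = FALSE)
    regulon_genes <- regulon_genes[present]
  }
  if (!length(regulon_genes)) domain_error("no regulon genes present in matrix")
  K <- max(1L, as.integer(ceiling(top_fraction * nrow(ranks))))
  w <- ras_weights(ranks[regulon_genes, , drop = FALSE], K)
  colSums(w) / ras_denominator(length(regulon_genes), K)
}

# Shannon entropy in bits with 0 log 0 = 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Regulon specificity score (RSS)
#'
#' Measures how concentrated a regulon's activity is in one cell type:
#' the RAS vector is normalized to a distribution `p` over cells, compared
#' with the normalized cell-type indicator `q`, and
#' `RSS = 1 - sqrt(JSD(p, q))` with the Jensen-Shannon divergence in
#' base-2 logs, so RSS is in `[0, 1]` and equals 1 exactly when the
#' activity distribution matches the indicator.
#'
#' @param ras Non-negative RAS vector over cells.
#' @param labeling A [cell_labeling()] aligned with the RAS vector.
#' @param cell_type The cell type to score against.
#' @return The RSS in `[0, 1]` (0, with a warning, for an all-zero RAS).
#' @export
regulon_specificity <- function(ras, labeling, cell_type) {
  if (length(ras) != length(labeling$cell_ids))
    domain_error("RAS length does not match labeling")
  if (any(ras < 0)) domain_error("RAS must be non-negative")
  if (all(ras == 0)) {
    warning("all-zero RAS vector; RSS defined as 0", call. = FALSE)
    return(0)
  }
  p <- ras / sum(ras)
  ind <- as.numeric(labeling$labels == cell_type)
  if (sum(ind) == 0) domain_error(sprintf("no cells of type '%s'", cell_type))
  q <- ind / sum(ind)
  m <- (p + q) / 2
  jsd <- entropy_bits(m) - (entropy_bits(p) + entropy_bits(q)) / 2
  jsd <- min(1, max(0, jsd)) # clamp floating-point drift
  1 - sqrt(jsd)
}

# Vectorized null RSS over many random gene sets (rows of ras_null).
rss_rows <- function(ras_null, q) {
  totals <- rowSums(ras_null)
  zero <- totals == 0
  totals[zero] <- 1
  p <- ras_null / totals
  qm <- matrix(q, nrow(p), length(q), byrow = TRUE)
  m <- (p + qm) / 2
  h <- function(x) {
    x[x <= 0] <- 1 # log2(1) = 0 contribution
    -rowSums(x * log2(x))
  }
  hq <- entropy_bits(q)
  jsd <- pmin(1, pmax(0, h(m) - (h(p) + hq) / 2))
  out <- 1 - sqrt(jsd)
  out[zero] <- 0
  out
}

#' Bootstrap empirical p-value of a regulon's RSS
#'
#' Draws `n_boot` random gene sets of the regulon's size (uniformly,
#' without replacement, from all matrix genes), scores each against the
#' same cell type, and returns
#' `p = (1 + #\{RSS_null >= RSS_obs\}) / (1 + n_boot)`.
#'
#' @param regulon_genes Character vector of the regulon's genes.
#' @param ranks A `RankMatrix`.
#' @param labeling A [cell_labeling()].
#' @param cell_type Cell type scored against.
#' @param n_boot Number of null draws (default 10000).
#' @param seed Integer seed for the draws.
#' @param top_fraction Recovery-window fraction (default 0.05).
#' @return A list with `p`, `rss_observed`, `n_boot`.
#' @export
empirical_pvalue <- function(regulon_genes, ranks, labeling, cell_type,
                             n_boot = 10000L, seed = 1L, top_fraction = 0.05) {
  if (n_boot < 1L) domain_error("n_boot must be >= 1")
  n_genes <- nrow(ranks)
  g <- length(regulon_genes)
  if (g > n_genes) domain_error("regulon larger than gene universe")
  if (g < 1L) domain_error("empty regulon")
  if (!all(regulon_genes %in% rownames(ranks)))
    domain_error("regulon gene(s) absent from the rank matrix")
  K <- max(1L, as.integer(ceiling(top_fraction * n_genes)))
  w <- ras_weights(ranks, K)
  denom <- ras_denominator(g, K)
  obs_ras <- colSums(w[regulon_genes, , drop = FALSE]) / denom
  rss_obs <- regulon_specificity(obs_ras, labeling, cell_type)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  idx <- vapply(seq_len(n_boot), function(i) sample.int(n_genes, g),
                integer(g))
  sel <- Matrix::sparseMatrix(i = rep(seq_len(n_boot), each = g),
                              j = as.vector(idx), x = 1,
                              dims = c(n_boot, n_genes))
  ras_null <- as.matrix(sel %*% w) / denom
  ind <- as.numeric(labeling$labels == cell_type)
  q <- ind / sum(ind)
  rss_null <- rss_rows(ras_null, q)
  list(p = (1 + sum(rss_null >= rss_obs)) / (1 + n_boot),
       rss_observed = rss_obs, n_boot = as.integer(n_boot))
}

#' Call cell-type-specific regulons and assign CTn-Rm names
#'
#' Adjusts each regulon's empirical p-value by the number of regulons in
#' its own cell type (Bonferroni), flags CTSRs at the chosen significance
#' level, and names regulons `CT{n}-R{m}` where `n` numbers cell types in
#' `label_set` order and `m` ranks regulons within a type by ascending
#' empirical p-value (ties: descending RSS, then TF name).
#'
#' @param score_rows Data frame with one row per scored regulon: columns
#'   `cell_type`, `tf`, `n_genes`, `rss`, `p_empirical`, `regulon_index`.
#' @param labeling The [cell_labeling()] used (fixes cell-type numbering).
#' @param alpha Significance threshold on the adjusted p-value; one of
#'   0.001, 0.01, 0.05 (default 0.05).
#' @return A `RegulonScoreTable` data frame adding `p_adjusted`, `is_ctsr`,
#'   `rank`, `name`.
#' @export
call_ctsrs <- function(score_rows, labeling, alpha = 0.05) {
  if (!alpha %in% c(0.001, 0.01, 0.05))
    domain_error("alpha must be one of 0.001, 0.01, 0.05")
  st <- score_rows
  st$p_adjusted <- rep(NA_real_, nrow(st))
  st$is_ctsr <- rep(NA, nrow(st))
  st$rank <- rep(NA_integer_, nrow(st))
  st$name <- rep(NA_character_, nrow(st))
  for (ct in unique(st$cell_type)) {
    rows <- which(st$cell_type == ct)
    n_ct <- length(rows)
    st$p_adjusted[rows] <- pmin(1, st$p_empirical[rows] * n_ct)
    ord <- rows[order(st$p_empirical[rows], -st$rss[rows], st$tf[rows])]
    st$rank[ord] <- seq_len(n_ct)
    ct_index <- match(ct, labeling$label_set)
    st$name[ord] <- sprintf("CT%d-R%d", ct_index, seq_len(n_ct))
  }
  st$is_ctsr <- st$p_adjusted < alpha
  class(st) <- c("RegulonScoreTable", "data.frame")
  st
}

#' Score a list of regulons end to end
#'
#' Computes the RAS matrix, the RSS of each regulon in its own cell type,
#' bootstrap empirical p-values, and the CTSR calls/names.
#'
#' @param em A log-normalized [expression_matrix()].
#' @param regulons List of `Regulon`s from [build_regulons()].
#' @param labeling A [cell_labeling()] aligned with `em`.
#' @param alpha CTSR significance threshold (default 0.05).
#' @param n_boot Bootstrap draws per regulon (default 10000).
#' @param top_fraction Recovery-window fraction (default 0.05).
#' @param seed Integer seed; regulon `i` uses `seed + i - 1`.
#' @return A list with `score_table` (a `RegulonScoreTable`) and `ras`
#'   (regulons-by-cells matrix).
#' @export
score_regulons <- function(em, regulons, labeling, alpha = 0.05,
                           n_boot = 10000L, top_fraction = 0.05, seed = 1L) {
  if (!length(regulons))
    return(list(score_table = call_ctsrs(
      data.frame(cell_type = character(), tf = character(),
                 n_genes = integer(), rss = numeric(),
                 p_empirical = numeric(), regulon_index = integer()),
      labeling, alpha), ras = NULL))
  ranks <- rank_genes_per_cell(em)
  ras <- matrix(0, length(regulons), ncol(em$values),
                dimnames = list(NULL, em$cell_ids))
  rows <- vector("list", length(regulons))
  for (i in seq_along(regulons)) {
    r <- regulons[[i]]
    genes <- intersect(r$genes, em$gene_ids)
    ep <- empirical_pvalue(genes, ranks, labeling, r$cell_type,
                           n_boot = n_boot, seed = seed + i - 1L,
                           top_fraction = top_fraction)
    ras[i, ] <- regulon_activity(ranks, genes, top_fraction)
    rows[[i]] <- data.frame(cell_type = r$cell_type, tf = r$tf_name,
                            n_genes = length(genes), rss = ep$rss_observed,
                            p_empirical = ep$p, regulon_index = i,
                            stringsAsFactors = FALSE)
  }
  st <- call_ctsrs(do.call(rbind, rows), labeling, alpha)
  rownames(ras) <- st$name
  list(score_table = st, ras = ras)
}
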