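# Qualitative (QUBIC-style) biclustering for gene-module detection:
# quantile discretization into {-1, 0, +1}, seeding by pairwise co-level
# counts, greedy seed expansion under a consistency constraint, and an
# overlap-filtered collection loop.

#' Biclustering parameters
#'
#' @param q Discretization quantile: per gene, the top and bottom
#'   `ceiling(q * n_cells)` cells receive +1 / -1 (default 0.06).
#' @param consistency Expansion consistency `c`: a seed may only grow while
#'   at least `c` of its initial cell set is retained (default 0.95).
#' @param max_biclusters Maximum number of biclusters kept (default 500;
#'   fast mode uses 100).
#' @param overlap_filter Maximum gene-set Jaccard overlap `f` allowed
#'   between a new bicluster and any kept one (default 0.75).
#' @param levels Which discretization levels to seed on; `1L` (default)
#'   searches up-regulated blocks only, `c(1L, -1L)` includes down-regulated.
#' @return A `BiclusterParams` list.
#' @export
bicluster_params <- function(q = 0.06, consistency = 0.95,
                             max_biclusters = 500L, overlap_filter = 0.75,
                             levels = 1L) {
  if (!(q > 0 && q < 0.5)) domain_error("q must be in (0, 0.5)")
  if (!(consistency > 0.5 && consistency <= 1))
    domain_error("consistency must be in (0.5, 1]")
  if (max_biclusters < 1) domain_error("max_biclusters must be >= 1")
  if (!(overlap_filter > 0 && overlap_filter <= 1))
    domain_error("overlap_filter must be in (0, 1]")
  if (!all(levels %in% c(1L, -1L))) domain_error("levels must be within {1, -1}")
  structure(list(q = q, consistency = consistency,
                 max_biclusters = as.integer(max_biclusters),
                 overlap_filter = overlap_filter, levels = as.integer(levels)),
            class = "BiclusterParams")
}

#' Discretize an expression matrix into qualitative levels
#'
#' Per gene, the top `ceiling(q * n)` cells by value become +1 and the
#' bottom `ceiling(q * n)` become -1; everything else is 0. Zero raw values
#' never become +1, constant genes stay all-zero, and ties are broken by
#' ascending cell index so the result is deterministic.
#'
#' @param em A log-normalized [expression_matrix()].
#' @param q Discretization quantile (default 0.06).
#' @return A `DiscreteMatrix`: integer matrix in \{-1, 0, +1\} with the
#'   `q` used stored as an attribute.
#' @export
discretize <- function(em, q = 0.06) {
  v <- em$values
  n <- ncol(v)
  if (n * q < 1) {
    warning(sprintf("q = %g selects < 1 cell for n = %d; raised to 1/n", q, n),
            call. = FALSE)
    q <- 1 / n
  }
  m <- ceiling(q * n)
  lv <- matrix(0L, nrow(v), n, dimnames = dimnames(v))
  idx <- seq_len(n)
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    if (max(x) == min(x)) next # constant gene: no discrimination
    ord_desc <- order(-x, idx)
    top <- ord_desc[seq_len(m)]
    top <- top[x[top] > 0] # zeros never become +1
    ord_asc <- order(x, idx)
    bot <- setdiff(ord_asc[seq_len(m)], top)
    lv[i, top] <- 1L
    lv[i, bot] <- -1L
  }
  structure(lv, q = q, class = c("DiscreteMatrix", class(lv)))
}

#' Rank candidate seed gene pairs
#'
#' For each discretization level requested, the weight of a gene pair is the
#' number of cells where both genes carry that same non-zero level. Pairs
#' with weight < 2 are dropped; the rest are returned sorted by weight
#' descending, ties by lexicographic gene ids (then level).
#'
#' @param dm A `DiscreteMatrix` from [discretize()].
#' @param levels Levels to seed on (default `c(1L, -1L)`).
#' @return A data frame with columns `g1`, `g2` (gene ids), `level`, `weight`.
#' @export
seed_pairs <- function(dm, levels = c(1L, -1L)) {
  gene_ids <- rownames(dm)
  out <- list()
  for (lev in levels) {
    ind <- Matrix::Matrix(dm == lev, sparse = TRUE) * 1
    w <- Matrix::tcrossprod(ind)
    tri <- Matrix::which(w >= 2, arr.ind = TRUE)
    tri <- tri[tri[, 1L] < tri[, 2L], , drop = FALSE]
    if (!nrow(tri)) next
    out[[length(out) + 1L]] <- data.frame(
      g1 = gene_ids[tri[, 1L]], g2 = gene_ids[tri[, 2L]],
      level = lev, weight = as.integer(w[tri]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(g1 = character(), g2 = character(),
                      level = integer(), weight = integer()))
  res <- do.call(rbind, out)
  res[order(-res$weight, res$g1, res$g2, -res$level), , drop = FALSE]
}

#' Expand a seed pair into a bicluster
#'
#' Starting from the cells where the seed pair agrees on the shared level,
#' genes are added greedily: each candidate gene would trim the cell set to
#' the cells where it also carries the level, and the gene retaining the
#' most cells is added, provided at least `max(2, c * |initial cells|)`
#' cells survive. Ties are broken by gene id. Every (gene, cell) entry of
#' the returned block carries the shared level.
#'
#' @param dm A `DiscreteMatrix`.
#' @param g1,g2 Gene ids of the seed pair.
#' @param level Shared level of the seed (+1 or -1).
#' @param consistency Consistency `c` (default 0.95).
#' @return A `Bicluster` list with `genes`, `cells`, `level`, `score`, or
#'   `NULL` when the pair agrees in fewer than 2 cells.
#' @export
expand_seed <- function(dm, g1, g2, level = 1L, consistency = 0.95) {
  lv <- unclass(dm) == level
  expand_core(lv, rownames(dm), colnames(dm),
              match(g1, rownames(dm)), match(g2, rownames(dm)),
              level, consistency)
}

# Greedy expansion on a precomputed level-indicator matrix (internal).
expand_core <- function(lv, gene_ids, cell_ids, i1, i2, level, consistency) {
  cells <- which(lv[i1, ] & lv[i2, ])
  if (length(cells) < 2L) return(NULL)
  min_keep <- max(2, consistency * length(cells))
  in_block <- logical(nrow(lv))
  in_block[c(i1, i2)] <- TRUE
  repeat {
    retained <- rowSums(lv[, cells, drop = FALSE])
    retained[in_block] <- -1L
    best <- max(retained)
    if (best < min_keep) break
    cand <- which(retained == best)
    pick <- cand[order(gene_ids[cand])][[1L]]
    cells <- cells[lv[pick, cells]]
    in_block[pick] <- TRUE
  }
  genes <- sort(gene_ids[in_block])
  structure(list(genes = genes, cells = cell_ids[cells], level = as.integer(level),
                 score = length(genes) * length(cells)),
            class = "Bicluster")
}

#' @export
print.Bicluster <- function(x, ...) {
  cat(sprintf("Bicluster: %d genes x %d cells (level %+d, score %d)\n",
              length(x$genes), length(x$cells), x$level, x$score))
  invisible(x)
}

#' Run the full biclustering stage
#'
#' Discretizes, ranks seed pairs, expands them in rank order, and keeps a
#' new bicluster only when its gene-set Jaccard overlap with every kept
#' bicluster is below `overlap_filter`. Stops at `max_biclusters` kept
#' blocks or seed exhaustion; output is sorted by score descending (ties by
#' gene ids) and is fully deterministic.
#'
#' @param em A pre-processed [expression_matrix()].
#' @param params A [bicluster_params()].
#' @return A list of `Bicluster` objects (possibly empty, with a warning).
#' @export
run_biclustering <- function(em, params = bicluster_params()) {
  dm <- discretize(em, params$q)
  seeds <- seed_pairs(dm, levels = params$levels)
  gene_ids <- rownames(dm)
  cell_ids <- colnames(dm)
  lv_by_level <- lapply(stats::setNames(params$levels, params$levels),
                        function(l) unclass(dm) == l)
  kept <- list()
  kept_genes <- list()
  for (i in seq_len(nrow(seeds))) {
    if (length(kept) >= params$max_biclusters) break
    bc <- expand_core(lv_by_level[[as.character(seeds$level[i])]],
                      gene_ids, cell_ids,
                      match(seeds$g1[i], gene_ids), match(seeds$g2[i], gene_ids),
                      seeds$level[i], params$consistency)
    if (is.null(bc)) next
    ok <- TRUE
    for (kg in kept_genes) {
      if (jaccard_sets(bc$genes, kg) >= params$overlap_filter) { ok <- FALSE; break }
    }
    if (!ok) next
    kept[[length(kept) + 1L]] <- bc
    kept_genes[[length(kept_genes) + 1L]] <- bc$genes
  }
  if (!length(kept)) {
    warning("no biclusters found", call. = FALSE)
    return(list())
  }
  scores <- vapply(kept, `[[`, numeric(1), "score")
  keys <- vapply(kept, function(b) paste(b$genes, collapse = ","), character(1))
  kept[order(-scores, keys)]
}
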