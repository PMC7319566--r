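# Shared fixture builders: everything is generated in code at test time.

# A small expression matrix with named genes/cells.
make_em <- function(values, normalized = FALSE, log_transformed = FALSE) {
  values <- as.matrix(values)
  expression_matrix(values,
                    sprintf("g%02d", seq_len(nrow(values))),
                    sprintf("c%02d", seq_len(ncol(values))),
                    normalized, log_transformed)
}

# Write a dense matrix file and return its path.
write_dense_fixture <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Write a 10x-style triplet directory.
write_mtx_fixture <- function(entries, n_genes, n_cells, gzip = FALSE,
                              features_two_col = FALSE) {
  dir <- tempfile()
  dir.create(dir)
  mtx <- c("%%MatrixMarket matrix coordinate integer general",
           sprintf("%d %d %d", n_genes, n_cells, nrow(entries)),
           sprintf("%d %d %g", entries[, 1], entries[, 2], entries[, 3]))
  feats <- sprintf("gene%d", seq_len(n_genes))
  if (features_two_col) feats <- paste(feats, sprintf("SYM%d", seq_len(n_genes)),
                                       sep = "\t")
  bcs <- sprintf("cell%d", seq_len(n_cells))
  ext <- if (gzip) ".gz" else ""
  wl <- function(x, f) {
    con <- if (gzip) gzfile(file.path(dir, paste0(f, ext)), "wt")
           else file(file.path(dir, f), "wt")
    writeLines(x, con); close(con)
  }
  wl(mtx, "matrix.mtx"); wl(bcs, "barcodes.tsv"); wl(feats, "features.tsv")
  dir
}

# A minimal MEME motif text for given probability matrices.
write_meme_fixture <- function(mats, ids = NULL, tfs = NULL) {
  ids <- ids %||% sprintf("M%d", seq_along(mats))
  tfs <- tfs %||% ids
  lib <- motif_library(Map(function(m, i, t)
    list(motif_id = i, tf_name = t, matrix = m), mats, ids, tfs))
  path <- tempfile(fileext = ".meme")
  write_motif_meme(lib, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consensus-indicator PWM (probability ~1 on each consensus base).
consensus_pwm <- function(word, p = 0.997) {
  bases <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p) / 3, length(bases), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), bases)] <- p
  m
}

# Brute-force maximal all-level block containing a given gene pair, used as
# the oracle for noise-free seed expansion on small matrices.
brute_force_block <- function(dm, g1, g2, level = 1L) {
  lv <- unclass(dm) == level
  genes <- rownames(dm)
  base_cells <- which(lv[g1, ] & lv[g2, ])
  best <- NULL
  others <- setdiff(genes, c(g1, g2))
  for (k in 0:length(others)) {
    for (extra in if (k == 0) list(character(0)) else
         asplit(utils::combn(others, k), 2)) {
      gs <- c(g1, g2, unlist(extra))
      cells <- base_cells
      for (g in gs) cells <- cells[lv[g, cells]]
      if (length(cells) < 2) next
      score <- length(gs) * length(cells)
      if (is.null(best) || score > best$score)
        best <- list(genes = sort(gs), cells = colnames(dm)[cells],
                     score = score)
    }
  }
  best
}

# Brute-force double-strand PWM scan oracle.
brute_force_scan <- function(seq_chr, log_odds_int, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq_chr, "")[[1]]
  w <- nrow(log_odds_int)
  hits <- list()
  score_word <- function(word) {
    idx <- match(word, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    sum(log_odds_int[cbind(seq_len(w), idx)])
  }
  for (off in seq_len(length(chars) - w + 1)) {
    word <- chars[off:(off + w - 1)]
    s_fwd <- score_word(word)
    if (!is.na(s_fwd) && s_fwd >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = off - 1L, strand = "+",
                                             score_int = s_fwd)
    s_rev <- score_word(rev(unname(comp[word])))
    if (!is.na(s_rev) && s_rev >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = off - 1L, strand = "-",
                                             score_int = s_rev)
  }
  if (!length(hits)) return(data.frame(offset = integer(), strand = character(),
                                       score_int = numeric()))
  do.call(rbind, hits)
}

# Brute-force recovery-curve RAS oracle for one cell.
brute_force_ras <- function(gene_ranks, K, g) {
  counts <- vapply(seq_len(K), function(k) sum(gene_ranks <= k), numeric(1))
  denom <- sum(vapply(seq_len(K), function(k) min(k, g), numeric(1)))
  sum(counts) / denom
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
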