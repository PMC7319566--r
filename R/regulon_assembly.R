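# Regulon assembly: promoter extraction from a genome + annotation, PWM
# log-odds scoring with an exact null score distribution (FIMO-style),
# double-strand promoter scanning, and per-cell-type regulon construction.

DNA_BASES <- c("A", "C", "G", "T")

#' Extract strand-oriented promoter sequences
#'
#' For each annotated gene, the promoter is the `L`-bp region immediately
#' upstream of the TSS: `[max(1, tss - L), tss - 1]` on the plus strand and
#' the reverse complement of `[tss + 1, min(tss + L, chrom_end)]` on the
#' minus strand (1-based closed coordinates). Promoters are clipped at
#' chromosome boundaries; genes on missing chromosomes, or with an empty
#' upstream region, are skipped with a warning. `N` bases are preserved.
#'
#' @param annotation A `GeneAnnotation` from [read_gene_annotation()].
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param L Promoter length in bp (default 1000).
#' @return A `PromoterSet`: list with `table` (gene_id, chrom, start, end,
#'   strand), `seqs` (named `DNAStringSet`) and `L`.
#' @export
extract_promoters <- function(annotation, genome, L = 1000L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  rows <- list(); seqs <- list(); skipped <- character()
  for (i in seq_len(nrow(annotation))) {
    gid <- annotation$gene_id[i]
    chrom <- annotation$chrom[i]
    strand <- annotation$strand[i]
    tss <- annotation$tss[i]
    if (!chrom %in% names(genome)) { skipped <- c(skipped, gid); next }
    if (strand == "+") {
      if (tss <= 1L) { skipped <- c(skipped, gid); next }
      s <- max(1L, tss - L); e <- tss - 1L
      seq <- Biostrings::subseq(genome[[chrom]], s, e)
    } else {
      if (tss >= chrom_len[[chrom]]) { skipped <- c(skipped, gid); next }
      s <- tss + 1L; e <- min(chrom_len[[chrom]], tss + L)
      seq <- Biostrings::reverseComplement(Biostrings::subseq(genome[[chrom]], s, e))
    }
    rows[[length(rows) + 1L]] <- data.frame(gene_id = gid, chrom = chrom,
                                            start = s, end = e, strand = strand,
                                            stringsAsFactors = FALSE)
    seqs[[gid]] <- seq
  }
  if (length(skipped))
    warning(sprintf("skipped %d gene(s) without usable promoter: %s%s",
                    length(skipped), paste(utils::head(skipped, 5), collapse = ", "),
                    if (length(skipped) > 5) ", ..." else ""), call. = FALSE)
  if (!length(rows)) domain_error("no promoters could be extracted")
  structure(list(table = do.call(rbind, rows),
                 seqs = Biostrings::DNAStringSet(seqs), L = as.integer(L)),
            class = "PromoterSet")
}

#' Write promoters as BED
#'
#' Converts the internal 1-based closed coordinates to 0-based half-open.
#'
#' @param promoters A `PromoterSet`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_promoters_bed <- function(promoters, path) {
  t <- promoters$table
  bed <- data.frame(t$chrom, t$start - 1L, t$end, t$gene_id, 0L, t$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a log-odds scoring matrix from a PWM
#'
#' `score(i, b) = log2((p_ib + pseudocount * bg_b) / (norm * bg_b))` with
#' `norm = 1 + pseudocount`, in bits. The matrix is also integer-scaled at a
#' resolution of 1/1000 bit for the exact null-distribution dynamic program.
#'
#' @param pwm A width-by-4 row-stochastic probability matrix (A,C,G,T).
#' @param background Background base frequencies (default uniform).
#' @param pseudocount Pseudocount weight (default 1e-4).
#' @return A `PWMScoring` list with `log_odds`, `int_matrix`, `scale`,
#'   `background`, `width`.
#' @export
pwm_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 1e-4) {
  pwm <- as.matrix(pwm)
  background <- background / sum(background)
  norm <- 1 + pseudocount
  lo <- log2(sweep(pwm + pseudocount * rep(background, each = nrow(pwm)),
                   2L, norm * background, "/"))
  scale <- 1000L
  structure(list(log_odds = lo,
                 int_matrix = round(lo * scale),
                 scale = scale, background = background, width = nrow(pwm)),
            class = "PWMScoring")
}

#' Exact null score distribution of a scoring matrix
#'
#' Convolves the per-position integer score distributions under the
#' background model, yielding the exact distribution of the total score
#' over all `4^w` words (weighted by background probability).
#'
#' @param scoring A `PWMScoring` from [pwm_log_odds()].
#' @return A list with integer `scores`, `probs`, and `tail`
#'   (`P(score >= s)`), class `PWMScoreDistribution`.
#' @export
pwm_score_distribution <- function(scoring) {
  S <- scoring$int_matrix
  bg <- scoring$background
  lo_total <- sum(apply(S, 1L, min))
  hi_total <- sum(apply(S, 1L, max))
  span <- hi_total - lo_total + 1L
  dist <- numeric(span)
  dist[[1L]] <- 1 # offset representation: index 1 == lo_total
  cur_lo <- 0L
  for (j in seq_len(nrow(S))) {
    row <- S[j, ]
    new_lo <- cur_lo + min(row)
    new <- numeric(span)
    for (b in 1:4) {
      shift <- row[[b]] - min(row)
      idx <- which(dist > 0)
      new[idx + shift] <- new[idx + shift] + dist[idx] * bg[[b]]
    }
    dist <- new
    cur_lo <- new_lo
  }
  nz <- which(dist > 0)
  scores <- as.integer(lo_total + nz - 1L)
  probs <- dist[nz]
  tail <- rev(cumsum(rev(probs)))
  structure(list(scores = scores, probs = probs, tail = tail),
            class = "PWMScoreDistribution")
}

# P(score >= s) lookup against a PWMScoreDistribution, vectorized over s.
score_tail_p <- function(dist, s) {
  pos <- findInterval(s - 1L, dist$scores) + 1L
  out <- numeric(length(s))
  inside <- pos <= length(dist$scores)
  out[inside] <- dist$tail[pos[inside]]
  out[!inside] <- 0
  out
}

#' Score threshold at a p-value level
#'
#' The smallest integer score `s` with `P(score >= s) <= alpha` under the
#' exact null distribution. When `alpha` is below the smallest attainable
#' tail probability, the maximum score is used with a warning.
#'
#' @param scoring A `PWMScoring`.
#' @param alpha Tail probability level (default 1e-4).
#' @param dist Optional precomputed [pwm_score_distribution()].
#' @return A list with `threshold` (integer units), `threshold_bits`,
#'   `alpha`, and the `dist` used.
#' @export
score_pvalue_threshold <- function(scoring, alpha = 1e-4, dist = NULL) {
  if (is.null(dist)) dist <- pwm_score_distribution(scoring)
  ok <- which(dist$tail <= alpha)
  if (!length(ok)) {
    warning(sprintf("alpha = %g below minimum attainable tail %g; using max score",
                    alpha, dist$tail[length(dist$tail)]), call. = FALSE)
    thr <- dist$scores[length(dist$scores)]
  } else {
    thr <- dist$scores[ok[[1L]]]
  }
  list(threshold = thr, threshold_bits = thr / scoring$scale,
       alpha = alpha, dist = dist)
}

encode_dna <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1L]]
  match(chars, DNA_BASES) # N and other ambiguity codes become NA
}

# Score every window of an encoded sequence with an integer matrix; windows
# containing NA codes score NA.
score_windows <- function(code, S) {
  w <- nrow(S)
  n_win <- length(code) - w + 1L
  if (n_win < 1L) return(numeric(0))
  sc <- numeric(n_win)
  for (j in seq_len(w)) {
    sc <- sc + S[j, ][code[j:(j + n_win - 1L)]]
  }
  sc
}

#' Scan a promoter sequence with a PWM
#'
#' Slides the scoring matrix over both strands and reports every window
#' scoring at or above the threshold. Minus-strand matches are reported at
#' the 0-based offset of the window in the forward sequence. Windows
#' containing `N` are skipped.
#'
#' @param sequence A `DNAString`, or a character string over A,C,G,T,N.
#' @param scoring A `PWMScoring`.
#' @param threshold Result of [score_pvalue_threshold()] (or an integer
#'   threshold in scaled units).
#' @return A data frame with `offset`, `strand`, `score` (bits), `p_value`.
#' @export
scan_promoter <- function(sequence, scoring, threshold) {
  thr <- if (is.list(threshold)) threshold$threshold else threshold
  dist <- if (is.list(threshold)) threshold$dist else NULL
  code <- encode_dna(sequence)
  S <- scoring$int_matrix
  w <- nrow(S)
  if (length(code) < w)
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric()))
  # reverse-complement matrix scans the forward sequence for minus-strand hits
  S_rc <- S[rev(seq_len(w)), rev(1:4), drop = FALSE]
  hits <- list()
  for (strand in c("+", "-")) {
    sc <- score_windows(code, if (strand == "+") S else S_rc)
    hit <- which(!is.na(sc) & sc >= thr)
    if (length(hit))
      hits[[strand]] <- data.frame(offset = hit - 1L, strand = strand,
                                   score = sc[hit] / scoring$scale,
                                   score_int = sc[hit],
                                   stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  out$p_value <- if (!is.null(dist)) score_tail_p(dist, out$score_int) else NA_real_
  rownames(out) <- NULL
  out[, c("offset", "strand", "score", "p_value")]
}

#' Assemble cell-type regulons from modules, promoters and motifs
#'
#' For every cell type with at least one active module and every motif in
#' the library, the candidate regulon is the nonredundant union, over that
#' type's modules, of genes whose promoter carries at least one motif hit
#' at the scan significance level. Motifs sharing a TF name are merged
#' (union of genes). Regulons with fewer than `min_genes` genes are
#' dropped.
#'
#' @param modules List of `GeneModule`s from [assign_modules()].
#' @param promoters A `PromoterSet` from [extract_promoters()].
#' @param motif_lib A [motif_library()].
#' @param min_genes Minimum regulon size (default 5).
#' @param scan_alpha Per-window score p-value threshold (default 1e-4).
#' @param background Background base frequencies for scoring (default uniform).
#' @return A list of `Regulon` lists with `cell_type`, `tf_name`,
#'   `motif_id`, `genes`, `hits`.
#' @export
build_regulons <- function(modules, promoters, motif_lib, min_genes = 5L,
                           scan_alpha = 1e-4, background = rep(0.25, 4)) {
  if (!length(modules)) return(list())
  cell_types <- unique(vapply(modules, `[[`, "", "cell_type"))
  pool_by_type <- lapply(stats::setNames(cell_types, cell_types), function(ct) {
    sort(unique(unlist(lapply(modules[vapply(modules, `[[`, "", "cell_type") == ct],
                              `[[`, "genes"))))
  })
  all_genes <- sort(unique(unlist(pool_by_type)))
  have <- all_genes %in% names(promoters$seqs)
  if (!any(have))
    domain_error(sprintf("no promoters available for any module gene (missing: %s%s)",
                         paste(utils::head(all_genes, 5), collapse = ", "),
                         if (length(all_genes) > 5) ", ..." else ""))
  if (any(!have))
    warning(sprintf("no promoter for %d module gene(s); they cannot enter regulons",
                    sum(!have)), call. = FALSE)
  scan_genes <- all_genes[have]
  # scan each needed promoter once per motif; reuse across cell types
  hit_by_motif <- list()
  for (m in motif_lib$motifs) {
    scoring <- pwm_log_odds(m$matrix, background)
    thr <- score_pvalue_threshold(scoring, scan_alpha)
    per_gene <- lapply(scan_genes, function(g)
      scan_promoter(promoters$seqs[[g]], scoring, thr))
    names(per_gene) <- scan_genes
    hit_by_motif[[m$motif_id]] <- per_gene
  }
  tf_of <- vapply(motif_lib$motifs, `[[`, "", "tf_name")
  id_of <- vapply(motif_lib$motifs, `[[`, "", "motif_id")
  regulons <- list()
  for (ct in cell_types) {
    pool <- intersect(pool_by_type[[ct]], scan_genes)
    for (tf in unique(tf_of)) {
      ids <- id_of[tf_of == tf]
      genes <- character(); hit_rows <- list()
      for (mid in ids) {
        for (g in pool) {
          h <- hit_by_motif[[mid]][[g]]
          if (nrow(h)) {
            genes <- c(genes, g)
            h$gene_id <- g; h$motif_id <- mid
            hit_rows[[length(hit_rows) + 1L]] <- h
          }
        }
      }
      genes <- sort(unique(genes))
      if (length(genes) < min_genes) next
      hits <- do.call(rbind, hit_rows)
      regulons[[length(regulons) + 1L]] <- structure(
        list(cell_type = ct, tf_name = tf,
             motif_id = paste(ids, collapse = ","),
             genes = genes,
             hits = hits[, c("gene_id", "motif_id", "offset", "strand",
                             "score", "p_value")]),
        class = "Regulon")
    }
  }
  regulons
}

#' @export
print.Regulon <- function(x, ...) {
  cat(sprintf("Regulon: TF %s in %s, %d genes\n",
              x$tf_name, x$cell_type, length(x$genes)))
  invisible(x)
}

#' Write motif scan hits as TSV
#'
#' @param regulons List of `Regulon`s from [build_regulons()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hits_tsv <- function(regulons, path) {
  rows <- do.call(rbind, lapply(regulons, function(r) {
    h <- r$hits
    h$cell_type <- r$cell_type
    h
  }))
  if (is.null(rows))
    rows <- data.frame(gene_id = character(), motif_id = character(),
                       offset = integer(), strand = character(),
                       score = numeric(), p_value = numeric(),
                       cell_type = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
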