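# Synthetic dataset generator with planted ground truth: cell types,
# up-regulated gene modules, TF regulons with consensus motifs planted in
# target promoters, and a matching PWM library. Used to exercise every
# pipeline stage without external downloads.

#' Generate a synthetic dataset with planted regulons
#'
#' Baseline counts are negative binomial (mean `nb_mean`, dispersion
#' `nb_dispersion`, i.e. `size = 1/dispersion`); each planted regulon's
#' target genes have their mean multiplied by `fold_change` in the cells of
#' the regulon's cell type before sampling, and dropout zeroes entries
#' independently with probability `dropout`. Promoters are i.i.d. uniform
#' ACGT with the regulon TF's consensus word planted at a random offset in
#' every target gene's promoter; each TF's PWM puts probability 0.85 on the
#' consensus base. Each gene sits on its own chromosome (promoter followed
#' by a short gene body) so promoter extraction is exercised end to end.
#' Output is fully determined by `seed`.
#'
#' @param n_genes,n_cells Matrix dimensions (defaults 2000 x 600).
#' @param n_types Number of equally sized cell types (default 3, min 2).
#' @param n_regulons Number of planted regulons (default 3), assigned to
#'   cell types round-robin.
#' @param regulon_size Target genes per regulon (default 30).
#' @param fold_change Expression multiplier of target genes in their cell
#'   type (default 4; 1 gives a signal-free negative control).
#' @param dropout Independent zeroing probability (default 0.3).
#' @param promoter_len Promoter length in bp (default 1000).
#' @param motif_width Consensus width (default 12).
#' @param nb_mean,nb_dispersion Negative binomial baseline (defaults 2, 0.5).
#' @param seed Integer seed.
#' @return A list with `expression` (raw-count [expression_matrix()]),
#'   `labeling`, `annotation`, `genome` (`DNAStringSet`), `motifs`
#'   ([motif_library()]) and `truth` (planted modules/regulons/offsets and
#'   all parameters).
#' @export
generate_dataset <- function(n_genes = 2000L, n_cells = 600L, n_types = 3L,
                             n_regulons = 3L, regulon_size = 30L,
                             fold_change = 4, dropout = 0.3,
                             promoter_len = 1000L, motif_width = 12L,
                             nb_mean = 2, nb_dispersion = 0.5, seed = 1L) {
  if (n_types < 2L) domain_error("n_types must be >= 2")
  if (n_regulons < 1L) domain_error("n_regulons must be >= 1")
  if (fold_change < 1) domain_error("fold_change must be >= 1")
  if (n_regulons * regulon_size > n_genes)
    domain_error("regulon genes exceed the gene pool")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  cell_ids <- sprintf("C%04d", seq_len(n_cells))
  type_names <- sprintf("CT%d", seq_len(n_types))
  labels <- type_names[(seq_len(n_cells) - 1L) %% n_types + 1L]
  labeling <- cell_labeling(cell_ids, labels, type_names)
  # planted target gene sets, disjoint across regulons
  target_pool <- sample.int(n_genes, n_regulons * regulon_size)
  regulon_types <- type_names[(seq_len(n_regulons) - 1L) %% n_types + 1L]
  regulons_truth <- lapply(seq_len(n_regulons), function(r) {
    idx <- target_pool[((r - 1L) * regulon_size + 1L):(r * regulon_size)]
    list(tf = sprintf("TF%d", r), cell_type = regulon_types[[r]],
         genes = sort(gene_ids[idx]), gene_index = idx,
         fold_change = fold_change)
  })
  mu <- matrix(nb_mean, n_genes, n_cells)
  for (r in regulons_truth) {
    mu[r$gene_index, labels == r$cell_type] <- nb_mean * fold_change
  }
  counts <- matrix(stats::rnbinom(n_genes * n_cells, size = 1 / nb_dispersion,
                                  mu = as.vector(mu)), n_genes, n_cells)
  if (dropout > 0)
    counts[stats::runif(n_genes * n_cells) < dropout] <- 0L
  em <- expression_matrix(counts, gene_ids, cell_ids)
  # promoters, planted consensus words, genome and annotation
  rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")
  promoter_seq <- vapply(seq_len(n_genes), function(i) rand_dna(promoter_len), "")
  consensus <- vapply(seq_len(n_regulons), function(r) rand_dna(motif_width), "")
  motif_offsets <- list()
  for (r in seq_len(n_regulons)) {
    for (gi in regulons_truth[[r]]$gene_index) {
      off <- sample.int(promoter_len - motif_width + 1L, 1L)
      substr(promoter_seq[gi], off, off + motif_width - 1L) <- consensus[[r]]
      motif_offsets[[gene_ids[gi]]] <- off - 1L # 0-based, forward strand
    }
  }
  body_len <- 100L
  chrom_names <- paste0("chr_", gene_ids)
  genome <- Biostrings::DNAStringSet(vapply(seq_len(n_genes), function(i)
    paste0(promoter_seq[i], rand_dna(body_len)), ""))
  names(genome) <- chrom_names
  annotation <- data.frame(gene_id = gene_ids, chrom = chrom_names,
                           strand = "+", tss = promoter_len + 1L,
                           stringsAsFactors = FALSE)
  class(annotation) <- c("GeneAnnotation", "data.frame")
  motifs <- motif_library(lapply(seq_len(n_regulons), function(r) {
    bases <- match(strsplit(consensus[[r]], "")[[1L]], DNA_BASES)
    mat <- matrix(0.05, motif_width, 4, dimnames = list(NULL, DNA_BASES))
    mat[cbind(seq_len(motif_width), bases)] <- 0.85
    list(motif_id = sprintf("MOTIF%d", r), tf_name = sprintf("TF%d", r),
         matrix = mat)
  }))
  truth <- list(
    labels = labels,
    modules = lapply(regulons_truth, function(r)
      list(cell_type = r$cell_type, genes = r$genes, fold_change = fold_change)),
    regulons = lapply(regulons_truth, function(r)
      list(cell_type = r$cell_type, tf = r$tf, genes = r$genes)),
    consensus = consensus,
    motif_offsets = motif_offsets,
    params = list(n_genes = n_genes, n_cells = n_cells, n_types = n_types,
                  n_regulons = n_regulons, regulon_size = regulon_size,
                  fold_change = fold_change, dropout = dropout,
                  promoter_len = promoter_len, motif_width = motif_width,
                  nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                  seed = seed))
  list(expression = em, labeling = labeling, annotation = annotation,
       genome = genome, motifs = motifs, truth = truth)
}

#' Write a motif library in MEME minimal format
#'
#' @param motif_lib A [motif_library()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_motif_meme <- function(motif_lib, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "")
  for (m in motif_lib$motifs) {
    lines <- c(lines,
               sprintf("MOTIF %s %s", m$motif_id, m$tf_name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(m$matrix)),
               apply(m$matrix, 1L, function(r)
                 paste(sprintf("%.6f", r), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Writes `matrix.csv`, `labels.tsv`, `genome.fa`, `genes.gtf`,
#' `motifs.meme` and `truth.json` into a directory, in the formats the
#' pipeline readers accept.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  em <- dataset$expression
  mat <- data.frame(gene = em$gene_ids, em$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(mat) <- c("gene", em$cell_ids)
  utils::write.table(mat, file.path(dir, "matrix.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = dataset$labeling$cell_ids,
                                cell_type = dataset$labeling$labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(dataset$genome, file.path(dir, "genome.fa"))
  a <- dataset$annotation
  gtf <- sprintf("%s\tscregulon\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                 a$chrom, a$tss, a$tss + 99L, a$strand, a$gene_id)
  writeLines(gtf, file.path(dir, "genes.gtf"))
  write_motif_meme(dataset$motifs, file.path(dir, "motifs.meme"))
  writeLines(jsonlite::toJSON(dataset$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Evaluate recovery of planted regulons
#'
#' A planted regulon counts as recovered when some predicted CTSR matches
#' its cell type and TF with gene-set Jaccard at least `min_jaccard`.
#' Precision is the fraction of predictions matching some planted regulon;
#' with no predictions, precision is 1 by convention (no false claims) and
#' the result is flagged.
#'
#' @param truth The `truth` component of [generate_dataset()].
#' @param predicted List of predictions, each with `cell_type`, `tf`,
#'   `genes` (e.g. CTSR rows joined with regulon gene lists).
#' @param min_jaccard Gene-overlap threshold for a match (default 0.5).
#' @return A list with `precision`, `recall`, `jaccard` (per planted
#'   regulon, named by TF) and `no_predictions`.
#' @export
evaluate_recovery <- function(truth, predicted, min_jaccard = 0.5) {
  planted <- truth$regulons
  jac <- stats::setNames(numeric(length(planted)),
                         vapply(planted, `[[`, "", "tf"))
  recovered <- logical(length(planted))
  matched_pred <- logical(length(predicted))
  for (i in seq_along(planted)) {
    tr <- planted[[i]]
    for (j in seq_along(predicted)) {
      pr <- predicted[[j]]
      if (!identical(pr$cell_type, tr$cell_type) || !identical(pr$tf, tr$tf))
        next
      jj <- jaccard_sets(pr$genes, tr$genes)
      jac[[i]] <- max(jac[[i]], jj)
      if (jj >= min_jaccard) {
        recovered[i] <- TRUE
        matched_pred[j] <- TRUE
      }
    }
  }
  no_pred <- length(predicted) == 0L
  list(precision = if (no_pred) 1 else mean(matched_pred),
       recall = mean(recovered),
       jaccard = jac,
       no_predictions = no_pred)
}
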