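# End-to-end pipeline driver: pre-processing, clustering or user labels,
# biclustering or user modules, module assignment, regulon assembly,
# scoring, and report/manifest writing.

#' Build and validate a pipeline configuration
#'
#' @param expression Path to a dense matrix file or a 10x-style triplet
#'   directory.
#' @param genome Path to the genome FASTA.
#' @param annotation Path to the gene annotation (GTF or BED).
#' @param motifs Path to a MEME minimal-format motif library.
#' @param out_dir Output directory.
#' @param labels Optional path to a two-column cell-label file; when given,
#'   clustering is skipped.
#' @param modules Optional path to a gene-module list file (one gene list
#'   per column); when given, biclustering is skipped and each uploaded
#'   module is a candidate for every cell type.
#' @param annotation_format `"gtf"` or `"bed"`.
#' @param k Number of clusters for the fallback clusterer (required when no
#'   labels are given).
#' @param alpha CTSR significance threshold: 0.001, 0.01 or 0.05.
#' @param module_alpha Adjusted-p threshold for active modules (default 0.05).
#' @param n_boot Bootstrap draws per regulon (default 10000).
#' @param top_fraction RAS recovery-window fraction (default 0.05).
#' @param promoter_length Promoter length in bp (default 1000).
#' @param scan_alpha PWM scan p-value threshold (default 1e-4).
#' @param min_regulon_genes Minimum regulon size (default 5).
#' @param preprocess_params A [preprocess_params()].
#' @param bicluster_params A [bicluster_params()].
#' @param fast Fast mode: caps biclusters at the top 100 (default FALSE).
#' @param seed Integer seed driving every stochastic stage.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(expression, genome, annotation, motifs, out_dir,
                            labels = NULL, modules = NULL,
                            annotation_format = "gtf", k = NULL,
                            alpha = 0.05, module_alpha = 0.05,
                            n_boot = 10000L, top_fraction = 0.05,
                            promoter_length = 1000L, scan_alpha = 1e-4,
                            min_regulon_genes = 5L,
                            preprocess_params = scregulon::preprocess_params(),
                            bicluster_params = scregulon::bicluster_params(),
                            fast = FALSE, seed = 1L) {
  for (p in c(expression, genome, annotation, motifs))
    if (!file.exists(p)) io_error(sprintf("input not found: %s", p))
  if (!is.null(labels) && !file.exists(labels))
    io_error(sprintf("label file not found: %s", labels))
  if (is.null(labels) && is.null(k))
    domain_error("either a label file or k (number of clusters) is required")
  if (!alpha %in% c(0.001, 0.01, 0.05))
    domain_error("alpha must be one of 0.001, 0.01, 0.05")
  if (isTRUE(fast)) bicluster_params$max_biclusters <- 100L
  cfg <- list(expression = expression, genome = genome,
              annotation = annotation, motifs = motifs, out_dir = out_dir,
              labels = labels, modules = modules,
              annotation_format = annotation_format, k = k,
              alpha = alpha, module_alpha = module_alpha,
              n_boot = as.integer(n_boot), top_fraction = top_fraction,
              promoter_length = as.integer(promoter_length),
              scan_alpha = scan_alpha,
              min_regulon_genes = as.integer(min_regulon_genes),
              preprocess_params = preprocess_params,
              bicluster_params = bicluster_params,
              fast = isTRUE(fast), seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

log_stage <- function(log_lines, msg) {
  message(msg)
  c(log_lines, msg)
}

#' Run the full CTSR inference pipeline
#'
#' Executes pre-processing, clustering (or label loading), biclustering (or
#' module loading), active-module assignment, promoter extraction, regulon
#' assembly, regulon scoring and report writing, logging per-stage counts.
#' Two runs with identical configuration and seed produce identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the output directory, score table,
#'   regulons and per-stage counts.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  lg <- character()
  counts <- list()
  # Stage: input + pre-processing
  em <- if (dir.exists(cfg$expression)) read_expression_mtx(cfg$expression)
        else read_expression_dense(cfg$expression)
  lg <- log_stage(lg, sprintf("input: %d genes x %d cells",
                              nrow(em$values), ncol(em$values)))
  em <- preprocess(em, cfg$preprocess_params)
  counts$genes <- nrow(em$values); counts$cells <- ncol(em$values)
  lg <- log_stage(lg, sprintf("preprocess: retained %d genes x %d cells",
                              counts$genes, counts$cells))
  # Stage: cell labels
  if (!is.null(cfg$labels)) {
    labeling <- read_cell_labels(cfg$labels)
    al <- align_cells(em, labeling)
    em <- al$em; labeling <- al$labeling
    label_source <- "user"
  } else {
    labeling <- cluster_cells(em, k = cfg$k, seed = cfg$seed)
    label_source <- "clustered"
  }
  counts$cell_types <- length(labeling$label_set)
  lg <- log_stage(lg, sprintf("labels (%s): %d cell types over %d cells",
                              label_source, counts$cell_types,
                              length(labeling$cell_ids)))
  # Stage: gene modules
  if (!is.null(cfg$modules)) {
    user_mods <- read_gene_modules(cfg$modules)
    modules <- list()
    for (ct in labeling$label_set) {
      for (nm in names(user_mods)) {
        genes <- intersect(user_mods[[nm]], em$gene_ids)
        if (length(genes) < 2L) next
        modules[[length(modules) + 1L]] <- structure(
          list(genes = sort(genes), cell_type = ct, p_raw = NA_real_,
               p_adj = NA_real_, source_bicluster = NA_integer_,
               is_best = NA), class = "GeneModule")
      }
    }
    counts$biclusters <- 0L
    module_source <- "user"
  } else {
    biclusters <- run_biclustering(em, cfg$bicluster_params)
    counts$biclusters <- length(biclusters)
    lg <- log_stage(lg, sprintf("biclustering: %d bicluster(s)",
                                counts$biclusters))
    modules <- assign_modules(biclusters, labeling, cfg$module_alpha)
    module_source <- "biclustering"
  }
  counts$modules <- length(modules)
  lg <- log_stage(lg, sprintf("modules (%s): %d active module(s)",
                              module_source, counts$modules))
  # Stage: regulon assembly
  regulons <- list()
  if (length(modules)) {
    ann <- read_gene_annotation(cfg$annotation, cfg$annotation_format)
    module_genes <- sort(unique(unlist(lapply(modules, `[[`, "genes"))))
    ann <- ann[ann$gene_id %in% module_genes, , drop = FALSE]
    promoters <- extract_promoters(ann, cfg$genome, cfg$promoter_length)
    motif_lib <- read_motif_library(cfg$motifs)
    regulons <- build_regulons(modules, promoters, motif_lib,
                               min_genes = cfg$min_regulon_genes,
                               scan_alpha = cfg$scan_alpha)
  }
  counts$regulons <- length(regulons)
  lg <- log_stage(lg, sprintf("regulons: %d candidate regulon(s)",
                              counts$regulons))
  # Stage: scoring + report
  scored <- score_regulons(em, regulons, labeling, alpha = cfg$alpha,
                           n_boot = cfg$n_boot,
                           top_fraction = cfg$top_fraction,
                           seed = cfg$seed)
  st <- scored$score_table
  counts$ctsrs <- sum(st$is_ctsr)
  lg <- log_stage(lg, sprintf("scoring: %d regulon(s), %d CTSR(s)",
                              nrow(st), counts$ctsrs))
  write_regulon_report(st, regulons, cfg$out_dir)
  write_module_table(modules, file.path(cfg$out_dir, "modules.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("scregulon")),
    config = cfg[setdiff(names(cfg), c("preprocess_params", "bicluster_params"))],
    preprocess_params = unclass(cfg$preprocess_params),
    bicluster_params = unclass(cfg$bicluster_params),
    labels = label_source, modules_source = module_source,
    counts = counts)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(cfg$out_dir, "manifest.json"))
  writeLines(lg, file.path(cfg$out_dir, "run.log"))
  invisible(list(out_dir = cfg$out_dir, score_table = st,
                 regulons = regulons, counts = counts,
                 labeling = labeling, em = em))
}

#' Score user-supplied regulon gene lists
#'
#' The scoring-only entry point: each uploaded gene list is scored as a
#' regulon against every cell type (RAS, RSS, empirical p, CTSR call).
#'
#' @param em A log-normalized [expression_matrix()].
#' @param labeling A [cell_labeling()] aligned with `em`.
#' @param gene_lists Named list of character vectors.
#' @param ... Passed to [score_regulons()].
#' @return The `score_table` from [score_regulons()].
#' @export
score_user_regulons <- function(em, labeling, gene_lists, ...) {
  regulons <- list()
  for (nm in names(gene_lists)) {
    genes <- sort(intersect(gene_lists[[nm]], em$gene_ids))
    if (!length(genes)) {
      warning(sprintf("gene list '%s' shares no genes with the matrix", nm),
              call. = FALSE)
      next
    }
    for (ct in labeling$label_set) {
      regulons[[length(regulons) + 1L]] <- structure(
        list(cell_type = ct, tf_name = nm, motif_id = NA_character_,
             genes = genes, hits = NULL), class = "Regulon")
    }
  }
  scored <- score_regulons(em, regulons, labeling, ...)
  scored$score_table
}
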