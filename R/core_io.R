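# Readers and writers for the external formats the pipeline touches, and the
# shared data model (expression matrix, cell labeling, motif library, gene
# annotation).

#' Construct an expression matrix object
#'
#' The central container of the package: a dense numeric genes-by-cells
#' matrix together with gene and cell identifiers and two flags recording
#' the normalization state.
#'
#' @param values Numeric matrix, rows are genes, columns are cells.
#' @param gene_ids Character vector of unique gene identifiers (row order).
#' @param cell_ids Character vector of unique cell identifiers (column order).
#' @param normalized Logical; `TRUE` once size-factor normalization has been
#'   applied (or the input was detected as already normalized).
#' @param log_transformed Logical; `TRUE` once `log1p` has been applied.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              normalized = FALSE, log_transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(gene_ids))
    domain_error("row count does not match number of gene ids")
  if (ncol(values) != length(cell_ids))
    domain_error("column count does not match number of cell ids")
  if (anyDuplicated(gene_ids))
    domain_error("duplicate gene ids in ExpressionMatrix")
  if (anyDuplicated(cell_ids))
    domain_error("duplicate cell ids in ExpressionMatrix")
  if (any(!is.finite(values)))
    domain_error("ExpressionMatrix values must be finite")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 normalized = isTRUE(normalized),
                 log_transformed = isTRUE(log_transformed)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (normalized: %s, log: %s)\n",
              nrow(x$values), ncol(x$values), x$normalized, x$log_transformed))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Construct a cell labeling
#'
#' @param cell_ids Character vector of cell identifiers.
#' @param labels Character vector, one label per cell.
#' @param label_set Optional ordered set of distinct labels; defaults to the
#'   order of first appearance in `labels`.
#' @return An object of class `CellLabeling`.
#' @export
cell_labeling <- function(cell_ids, labels, label_set = NULL) {
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)
  if (length(cell_ids) != length(labels))
    domain_error("cell_ids and labels must have equal length")
  if (length(labels) == 0L)
    domain_error("empty cell labeling")
  if (is.null(label_set)) label_set <- unique(labels)
  if (!all(labels %in% label_set))
    domain_error("labels outside label_set")
  structure(list(cell_ids = cell_ids, labels = labels,
                 label_set = as.character(label_set)),
            class = "CellLabeling")
}

#' @export
print.CellLabeling <- function(x, ...) {
  cat(sprintf("CellLabeling: %d cells, %d cell types (%s)\n",
              length(x$cell_ids), length(x$label_set),
              paste(utils::head(x$label_set, 5), collapse = ", ")))
  invisible(x)
}

# Collapse duplicate gene rows: keep the row with the largest total signal.
dedup_gene_rows <- function(values, gene_ids) {
  if (!anyDuplicated(gene_ids)) return(list(values = values, gene_ids = gene_ids))
  totals <- rowSums(values)
  keep <- rep(TRUE, length(gene_ids))
  dup_ids <- unique(gene_ids[duplicated(gene_ids)])
  for (id in dup_ids) {
    idx <- which(gene_ids == id)
    best <- idx[which.max(totals[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  warning(sprintf("collapsed %d duplicate gene id(s) (kept row with largest total)",
                  sum(!keep)), call. = FALSE)
  list(values = values[keep, , drop = FALSE], gene_ids = gene_ids[keep])
}

#' Read a dense delimited expression matrix
#'
#' Expects the first row to hold cell identifiers and the first column gene
#' identifiers. The delimiter is guessed from the header (comma or tab)
#' unless given. Duplicate gene ids are collapsed to the row with the
#' largest total, with a warning. Gzip input is handled transparently.
#'
#' @param path Path to a `.txt`/`.csv`/`.tsv` file, optionally gzipped.
#' @param delimiter Field delimiter; `NULL` to auto-detect.
#' @return An [expression_matrix()] with normalization flags unset.
#' @export
read_expression_dense <- function(path, delimiter = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    format_error(sprintf("expression file is empty or has no data rows: %s", path))
  if (is.null(delimiter)) delimiter <- guess_delimiter(lines[[1L]])
  header <- split_fields(lines[[1L]], delimiter)
  body <- strsplit(lines[-1L],
                   if (identical(delimiter, "")) "[ \t]+" else delimiter,
                   fixed = !identical(delimiter, ""))
  widths <- lengths(body)
  if (length(unique(widths)) != 1L)
    format_error("ragged rows in expression matrix")
  n_fields <- widths[[1L]]
  n_cells <- n_fields - 1L
  if (n_cells < 1L) format_error("expression matrix has no cell columns")
  # header may or may not carry a corner label above the gene-id column
  cells <- if (length(header) == n_fields) header[-1L] else header
  if (length(cells) != n_cells)
    format_error("header length does not match data rows")
  flat <- unlist(body, use.names = FALSE)
  mat_chr <- matrix(flat, ncol = n_fields, byrow = TRUE)
  gene_ids <- mat_chr[, 1L]
  num <- suppressWarnings(as.numeric(mat_chr[, -1L, drop = FALSE]))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1L]
    r <- ((bad - 1L) %% nrow(mat_chr)) + 1L
    c <- ((bad - 1L) %/% nrow(mat_chr)) + 1L
    parse_error(sprintf("non-numeric value '%s' at gene '%s' (row %d), cell '%s' (column %d)",
                        mat_chr[r, c + 1L], gene_ids[r], r, cells[c], c))
  }
  values <- matrix(num, nrow = nrow(mat_chr))
  dd <- dedup_gene_rows(values, gene_ids)
  expression_matrix(dd$values, dd$gene_ids, make.unique(cells))
}

find_one_file <- function(dir, patterns) {
  files <- list.files(dir, full.names = TRUE)
  for (p in patterns) {
    hit <- files[grepl(p, basename(files), ignore.case = TRUE)]
    if (length(hit)) return(hit[[1L]])
  }
  NULL
}

#' Read a 10x-style triplet directory
#'
#' Reads a Matrix Market coordinate file together with barcode and feature
#' lists (plain or gzipped) and densifies into an [expression_matrix()].
#' Gene ids are taken from the first column of the feature file.
#'
#' @param directory Directory containing `matrix.mtx(.gz)`,
#'   `barcodes.tsv(.gz)` and `features.tsv(.gz)` (or `genes.tsv`).
#' @return An [expression_matrix()] with normalization flags unset.
#' @export
read_expression_mtx <- function(directory) {
  if (!dir.exists(directory)) io_error(sprintf("not a directory: %s", directory))
  mtx <- find_one_file(directory, c("^matrix\\.mtx(\\.gz)?$", "\\.mtx(\\.gz)?$"))
  bcs <- find_one_file(directory, c("^barcodes\\.tsv(\\.gz)?$", "barcode"))
  fts <- find_one_file(directory, c("^features\\.tsv(\\.gz)?$",
                                    "^genes\\.tsv(\\.gz)?$", "feature", "gene"))
  if (is.null(mtx) || is.null(bcs) || is.null(fts))
    format_error("triplet directory must contain matrix, barcodes and features files")
  con <- open_text(mtx)
  m <- tryCatch(Matrix::readMM(con), error = function(e) {
    close(con); format_error(sprintf("cannot parse Matrix Market file: %s",
                                     conditionMessage(e)))
  })
  close(con)
  barcodes <- read_text_lines(bcs)
  barcodes <- vapply(strsplit(barcodes, "\t", fixed = TRUE), `[[`, "", 1L)
  feat_lines <- strsplit(read_text_lines(fts), "\t", fixed = TRUE)
  gene_ids <- vapply(feat_lines, `[[`, "", 1L)
  if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes))
    format_error(sprintf(
      "matrix dimensions (%d x %d) disagree with features (%d) / barcodes (%d)",
      nrow(m), ncol(m), length(gene_ids), length(barcodes)))
  dd <- dedup_gene_rows(as.matrix(m), gene_ids)
  expression_matrix(dd$values, dd$gene_ids, make.unique(barcodes))
}

#' Read a two-column cell-label file
#'
#' First column: cell name; second column: cell type. An optional header row
#' is auto-detected: the first row is treated as a header when its second
#' field is not reused as a label by more than one other row.
#'
#' @param path Path to the delimited label file (optionally gzipped).
#' @return A [cell_labeling()].
#' @export
read_cell_labels <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) format_error(sprintf("empty label file: %s", path))
  delim <- guess_delimiter(lines[[1L]])
  fields <- lapply(lines, split_fields, delimiter = delim)
  if (any(lengths(fields) < 2L))
    format_error("label file must have two columns on every row")
  cells <- vapply(fields, `[[`, "", 1L)
  labs <- vapply(fields, `[[`, "", 2L)
  if (length(labs) > 1L) {
    reused <- sum(labs[-1L] == labs[[1L]])
    if (reused <= 1L) {
      cells <- cells[-1L]
      labs <- labs[-1L]
    }
  }
  if (!length(cells)) format_error("label file contains no data rows")
  if (anyDuplicated(cells)) {
    conflict <- tapply(labs, cells, function(v) length(unique(v)) > 1L)
    if (any(conflict))
      format_error(sprintf("conflicting labels for cell(s): %s",
                           paste(names(conflict)[conflict], collapse = ", ")))
    keep <- !duplicated(cells)
    cells <- cells[keep]
    labs <- labs[keep]
  }
  cell_labeling(cells, labs)
}

#' Align a labeling to an expression matrix
#'
#' Intersects cells by id, preserving the matrix cell order. Cells missing
#' from either side are dropped with a warning.
#'
#' @param em An [expression_matrix()].
#' @param labeling A [cell_labeling()].
#' @return A list with the subset `em` and the aligned `labeling`.
#' @export
align_cells <- function(em, labeling) {
  common <- intersect(em$cell_ids, labeling$cell_ids)
  if (!length(common)) domain_error("no cells shared between matrix and labels")
  n_drop_m <- length(em$cell_ids) - length(common)
  n_drop_l <- length(labeling$cell_ids) - length(common)
  if (n_drop_m + n_drop_l > 0L)
    warning(sprintf("dropped %d unlabeled matrix cell(s) and %d label-only cell(s)",
                    n_drop_m, n_drop_l), call. = FALSE)
  keep <- em$cell_ids[em$cell_ids %in% common]
  em2 <- expression_matrix(em$values[, keep, drop = FALSE], em$gene_ids, keep,
                           em$normalized, em$log_transformed)
  lab_map <- stats::setNames(labeling$labels, labeling$cell_ids)
  labs <- unname(lab_map[keep])
  lset <- labeling$label_set[labeling$label_set %in% labs]
  list(em = em2, labeling = cell_labeling(keep, labs, lset))
}

#' Construct a motif library
#'
#' @param motifs List of entries, each a list with `motif_id`, `tf_name` and
#'   `matrix` (a width-by-4 row-stochastic probability matrix over A,C,G,T).
#' @return An object of class `MotifLibrary`.
#' @export
motif_library <- function(motifs) {
  for (m in motifs) {
    if (!all(c("motif_id", "tf_name", "matrix") %in% names(m)))
      domain_error("each motif needs motif_id, tf_name and matrix")
    if (nrow(m$matrix) < 2L) domain_error("motif width must be >= 2")
    if (ncol(m$matrix) != 4L) domain_error("motif matrix must have 4 columns (A,C,G,T)")
    if (any(m$matrix < 0)) domain_error("motif probabilities must be non-negative")
    if (any(abs(rowSums(m$matrix) - 1) > 1e-6))
      domain_error(sprintf("motif %s rows do not sum to 1", m$motif_id))
  }
  structure(list(motifs = motifs), class = "MotifLibrary")
}

#' @export
print.MotifLibrary <- function(x, ...) {
  cat(sprintf("MotifLibrary: %d motif(s)\n", length(x$motifs)))
  invisible(x)
}

#' Read a MEME minimal-format motif library
#'
#' Supports the minimal MEME motif format: a `MEME version` line, an
#' `ALPHABET= ACGT` line, and one or more `MOTIF` blocks each followed by a
#' `letter-probability matrix` section. Rows within 1e-3 of summing to 1 are
#' renormalized; larger deviations raise an error.
#'
#' @param path Path to the motif file (optionally gzipped).
#' @return A [motif_library()].
#' @export
read_motif_library <- function(path) {
  lines <- read_text_lines(path)
  if (!length(lines)) format_error(sprintf("empty motif file: %s", path))
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_line)) {
    alpha <- gsub("[^A-Za-z]", "", sub("^ALPHABET\\s*=?", "", alpha_line[[1L]]))
    if (toupper(alpha) != "ACGT")
      abort(sprintf("unsupported alphabet '%s' (only ACGT is supported)", alpha),
            "scregulon_alphabet_error")
  }
  motif_starts <- grep("^MOTIF\\b", lines)
  if (!length(motif_starts)) format_error("no MOTIF blocks found")
  motifs <- vector("list", length(motif_starts))
  bounds <- c(motif_starts, length(lines) + 1L)
  for (i in seq_along(motif_starts)) {
    block <- lines[motif_starts[i]:(bounds[i + 1L] - 1L)]
    head_fields <- strsplit(trimws(block[[1L]]), "\\s+")[[1L]]
    motif_id <- if (length(head_fields) >= 2L) head_fields[[2L]] else
      format_error("MOTIF line without identifier")
    tf_name <- if (length(head_fields) >= 3L) head_fields[[3L]] else motif_id
    lp <- grep("letter-probability matrix", block)
    if (!length(lp)) format_error(sprintf("motif %s has no letter-probability matrix", motif_id))
    rows <- list()
    for (ln in block[-seq_len(lp[[1L]])]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) { if (length(rows)) break else next }
      if (grepl("^(URL|MOTIF)", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (anyNA(vals) || length(vals) != 4L) break
      rows[[length(rows) + 1L]] <- vals
    }
    if (length(rows) < 2L)
      format_error(sprintf("motif %s has width < 2", motif_id))
    mat <- do.call(rbind, rows)
    sums <- rowSums(mat)
    if (any(abs(sums - 1) > 1e-3))
      format_error(sprintf("motif %s has a row summing to %.4f (outside 1 +/- 1e-3)",
                           motif_id, sums[which.max(abs(sums - 1))]))
    mat <- mat / sums
    colnames(mat) <- c("A", "C", "G", "T")
    motifs[[i]] <- list(motif_id = motif_id, tf_name = tf_name, matrix = mat)
  }
  motif_library(motifs)
}

#' Read gene annotation from GTF or BED
#'
#' Retains one record per gene with chromosome, strand and transcription
#' start site (TSS). For GTF, the TSS is the record start on the plus strand
#' and the record end on the minus strand; gene identifiers come from the
#' `gene_id` attribute. BED input (0-based half-open) is converted to the
#' 1-based TSS convention, with gene identifiers from the name column.
#' Records without a strand are skipped with a warning.
#'
#' @param path Path to the annotation file.
#' @param format Either `"gtf"` or `"bed"`.
#' @return A data frame of class `GeneAnnotation` with columns `gene_id`,
#'   `chrom`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) format_error(sprintf(
                   "cannot parse %s file %s: %s", format, path, conditionMessage(e))))
  if (!length(gr)) format_error(sprintf("no records in annotation file: %s", path))
  if (format == "gtf") {
    types <- as.character(gr$type %||% character())
    if (length(types) && any(types == "gene")) gr <- gr[types == "gene"]
    ids <- as.character(gr$gene_id %||% gr$ID %||% seq_along(gr))
  } else {
    ids <- as.character(gr$name %||% seq_along(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  ok <- strand %in% c("+", "-")
  if (any(!ok))
    warning(sprintf("skipped %d record(s) with missing strand", sum(!ok)),
            call. = FALSE)
  ids <- ids[ok]; strand <- strand[ok]; chrom <- chrom[ok]
  start <- start[ok]; end <- end[ok]
  tss <- ifelse(strand == "+", start, end)
  keep <- !duplicated(ids)
  out <- data.frame(gene_id = ids[keep], chrom = chrom[keep],
                    strand = strand[keep], tss = as.integer(tss[keep]),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) format_error("no usable annotation records (all lacked strand?)")
  class(out) <- c("GeneAnnotation", "data.frame")
  out
}

# Fixed-format number printing for byte-stable report files.
fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Write the regulon report
#'
#' Writes `regulons.tsv` (one row per scored regulon, sorted by cell type
#' then within-type rank), `regulon_genes.tsv` (regulon-to-gene map) and
#' `results.json` (machine-readable copy of both). Reruns on identical
#' inputs produce byte-identical files.
#'
#' @param score_table A `RegulonScoreTable` data frame from [call_ctsrs()].
#' @param regulons The list of regulons that was scored (for gene lists).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_regulon_report <- function(score_table, regulons, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) io_error(sprintf("cannot create directory: %s", out_dir))
  st <- score_table[order(match(score_table$cell_type, unique(score_table$cell_type)),
                          score_table$rank), , drop = FALSE]
  tab <- data.frame(name = st$name, cell_type = st$cell_type, tf = st$tf,
                    n_genes = st$n_genes, rss = fmt_num(st$rss),
                    p_empirical = fmt_num(st$p_empirical),
                    p_adjusted = fmt_num(st$p_adjusted),
                    is_ctsr = tolower(as.character(st$is_ctsr)),
                    stringsAsFactors = FALSE)
  f_reg <- file.path(out_dir, "regulons.tsv")
  utils::write.table(tab, f_reg, sep = "\t", quote = FALSE, row.names = FALSE)
  gene_rows <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    genes <- regulons[[st$regulon_index[i]]]$genes
    data.frame(name = rep(st$name[i], length(genes)), gene_id = genes,
               stringsAsFactors = FALSE)
  }))
  f_genes <- file.path(out_dir, "regulon_genes.tsv")
  utils::write.table(gene_rows, f_genes, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    regulons = lapply(seq_len(nrow(st)), function(i) list(
      name = st$name[i], cell_type = st$cell_type[i], tf = st$tf[i],
      n_genes = st$n_genes[i], rss = st$rss[i],
      p_empirical = st$p_empirical[i], p_adjusted = st$p_adjusted[i],
      is_ctsr = st$is_ctsr[i],
      genes = as.list(regulons[[st$regulon_index[i]]]$genes))))
  f_json <- file.path(out_dir, "results.json")
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             f_json)
  invisible(c(f_reg, f_genes, f_json))
}

#' Read back a regulon report JSON
#'
#' Inverse of the JSON part of [write_regulon_report()]; used for round-trip
#' checks and downstream consumption of results.
#'
#' @param path Path to `results.json`.
#' @return A list with a `score_table` data frame and a named list `genes`.
#' @export
read_regulon_results <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  regs <- x$regulons
  if (is.null(regs)) format_error("results.json has no 'regulons' field")
  st <- do.call(rbind, lapply(regs, function(r) data.frame(
    name = r$name, cell_type = r$cell_type, tf = r$tf,
    n_genes = as.integer(r$n_genes), rss = as.numeric(r$rss),
    p_empirical = as.numeric(r$p_empirical),
    p_adjusted = as.numeric(r$p_adjusted), is_ctsr = isTRUE(r$is_ctsr),
    stringsAsFactors = FALSE)))
  genes <- stats::setNames(lapply(regs, function(r) unlist(r$genes)),
                           vapply(regs, `[[`, "", "name"))
  list(score_table = st, genes = genes)
}
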