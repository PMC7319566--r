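# Readers/writers and the shared data model.

test_that("dense reader parses CSV and TSV equivalently and reports bad cells", {
  csv <- write_dense_fixture(c("gene,cA,cB", "G1,1,2", "G2,0,5", "G3,3.5,0"))
  em <- read_expression_dense(csv)
  expect_s3_class(em, "ExpressionMatrix")
  expect_equal(dim(em), c(3L, 2L))
  expect_equal(em$gene_ids, c("G1", "G2", "G3"))
  expect_equal(em$cell_ids, c("cA", "cB"))
  expect_false(em$normalized)

  tsv <- write_dense_fixture(c("gene\tcA\tcB", "G1\t1\t2", "G2\t0\t5",
                               "G3\t3.5\t0"), ".txt")
  expect_equal(read_expression_dense(tsv), em)

  # header without corner label
  csv2 <- write_dense_fixture(c("cA,cB", "G1,1,2", "G2,0,5"))
  expect_equal(read_expression_dense(csv2)$cell_ids, c("cA", "cB"))

  bad <- write_dense_fixture(c("gene,cA,cB", "G1,1,x", "G2,0,5"))
  err <- expect_error(read_expression_dense(bad), class = "scregulon_parse_error")
  expect_match(conditionMessage(err), "G1")
  expect_match(conditionMessage(err), "cB")

  empty <- write_dense_fixture(character(0))
  expect_error(read_expression_dense(empty), class = "scregulon_format_error")
})

test_that("duplicate gene ids collapse to the row with the largest total", {
  csv <- write_dense_fixture(c("gene,cA,cB", "GENE1,1,1", "GENE1,10,10",
                               "G2,2,2"))
  expect_warning(em <- read_expression_dense(csv), "duplicate")
  expect_equal(dim(em), c(2L, 2L))
  expect_equal(unname(em$values["GENE1", ]), c(10, 10))
})

test_that("triplet reader honours coordinate semantics, gzip and 2-column features", {
  dir <- write_mtx_fixture(rbind(c(1, 1, 5), c(3, 2, 7)), 3, 2)
  em <- read_expression_mtx(dir)
  expect_equal(sum(em$values != 0), 2)
  expect_equal(em$values["gene1", "cell1"], 5)
  expect_equal(em$values["gene3", "cell2"], 7)

  gz <- write_mtx_fixture(rbind(c(1, 1, 5), c(3, 2, 7)), 3, 2, gzip = TRUE)
  expect_equal(read_expression_mtx(gz), em)

  two <- write_mtx_fixture(rbind(c(1, 1, 5), c(3, 2, 7)), 3, 2,
                           features_two_col = TRUE)
  expect_equal(read_expression_mtx(two)$gene_ids, c("gene1", "gene2", "gene3"))

  bad <- write_mtx_fixture(rbind(c(1, 1, 5)), 3, 2)
  extra <- file.path(bad, "barcodes.tsv")
  writeLines(c("cell1", "cell2", "cell3"), extra)
  expect_error(read_expression_mtx(bad), class = "scregulon_format_error")
})

test_that("dense and triplet readers agree on equivalent content", {
  dir <- write_mtx_fixture(rbind(c(1, 1, 2), c(2, 2, 3), c(3, 1, 4)), 3, 2)
  em_mtx <- read_expression_mtx(dir)
  dense <- write_dense_fixture(c("gene,cell1,cell2", "gene1,2,0",
                                 "gene2,0,3", "gene3,4,0"))
  em_dense <- read_expression_dense(dense)
  expect_equal(em_dense$values, em_mtx$values)
})

test_that("cell-label reader detects headers and rejects conflicts", {
  f <- write_dense_fixture(c("c1\tA", "c2\tA", "c3\tB", "c4\tB", "c5\tA"),
                           ".tsv")
  lab <- read_cell_labels(f)
  expect_equal(length(lab$label_set), 2L)
  expect_equal(length(lab$cell_ids), 5L)

  fh <- write_dense_fixture(c("cell,type", "c1,A", "c2,A", "c3,B"), ".csv")
  labh <- read_cell_labels(fh)
  expect_equal(labh$cell_ids, c("c1", "c2", "c3"))

  # first row's second field reused as a label by >1 other rows: kept as data
  fk <- write_dense_fixture(c("c0,A", "c1,A", "c2,A", "c3,B"), ".csv")
  expect_equal(length(read_cell_labels(fk)$cell_ids), 4L)

  fc <- write_dense_fixture(c("c1,A", "c2,A", "c3,A", "c1,B"), ".csv")
  expect_error(read_cell_labels(fc), class = "scregulon_format_error")
})

test_that("label alignment drops extra cells with a warning, keeping matrix order", {
  em <- make_em(matrix(1:6, 2))
  lab <- cell_labeling(c("c03", "c01", "ghost"), c("B", "A", "A"))
  expect_warning(al <- align_cells(em, lab), "dropped")
  expect_equal(al$em$cell_ids, c("c01", "c03"))
  expect_equal(al$labeling$labels, c("A", "B"))
})

test_that("MEME reader renormalizes within tolerance and rejects bad input", {
  m <- matrix(0.25, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  path <- write_meme_fixture(list(m), ids = "M1", tfs = "TFX")
  lib <- read_motif_library(path)
  expect_length(lib$motifs, 1L)
  expect_equal(nrow(lib$motifs[[1]]$matrix), 4L)
  expect_equal(lib$motifs[[1]]$tf_name, "TFX")

  # row summing to 1.0005: renormalized
  txt <- c("MEME version 4", "", "ALPHABET= ACGT", "", "MOTIF M2",
           "letter-probability matrix: alength= 4 w= 2",
           "0.2505 0.25 0.25 0.25", "0.25 0.25 0.25 0.25")
  f <- write_dense_fixture(txt, ".meme")
  lib2 <- read_motif_library(f)
  expect_equal(rowSums(lib2$motifs[[1]]$matrix), c(1, 1))

  # row summing to 0.8: error
  txt[7] <- "0.2 0.2 0.2 0.2"
  f3 <- write_dense_fixture(txt, ".meme")
  expect_error(read_motif_library(f3), class = "scregulon_format_error")

  txt_alpha <- sub("ALPHABET= ACGT", "ALPHABET= ACGU", txt)
  f4 <- write_dense_fixture(txt_alpha, ".meme")
  expect_error(read_motif_library(f4), class = "scregulon_alphabet_error")

  # width < 2
  txt_w <- c("MEME version 4", "ALPHABET= ACGT", "MOTIF M3",
             "letter-probability matrix: alength= 4 w= 1",
             "0.25 0.25 0.25 0.25")
  f5 <- write_dense_fixture(txt_w, ".meme")
  expect_error(read_motif_library(f5), class = "scregulon_format_error")
})

test_that("gene annotation reader applies TSS conventions for GTF and BED", {
  gtf <- write_dense_fixture(c(
    'chr1\tsrc\tgene\t100\t200\t.\t+\t.\tgene_id "gP";',
    'chr1\tsrc\tgene\t100\t200\t.\t-\t.\tgene_id "gM";',
    'chr2\tsrc\tgene\t50\t80\t.\t.\t.\tgene_id "gNA";'), ".gtf")
  expect_warning(ann <- read_gene_annotation(gtf, "gtf"), "strand")
  expect_equal(ann$tss[ann$gene_id == "gP"], 100L)
  expect_equal(ann$tss[ann$gene_id == "gM"], 200L)
  expect_false("gNA" %in% ann$gene_id)

  bed <- write_dense_fixture("chr1\t99\t200\tgeneA\t0\t+", ".bed")
  annb <- read_gene_annotation(bed, "bed")
  expect_equal(annb$tss, 100L)
  expect_equal(annb$gene_id, "geneA")
})

test_that("regulon report writes deterministic files and round-trips via JSON", {
  st <- data.frame(cell_type = c("A", "A"), tf = c("TF1", "TF2"),
                   n_genes = c(3L, 2L), rss = c(0.9, 0.4),
                   p_empirical = c(0.001, 0.3), regulon_index = 1:2,
                   stringsAsFactors = FALSE)
  lab <- cell_labeling(c("x", "y"), c("A", "A"))
  st <- call_ctsrs(st, lab, alpha = 0.05)
  regs <- list(structure(list(cell_type = "A", tf_name = "TF1",
                              genes = c("g1", "g2", "g3")), class = "Regulon"),
               structure(list(cell_type = "A", tf_name = "TF2",
                              genes = c("g4", "g5")), class = "Regulon"))
  d1 <- tempfile(); d2 <- tempfile()
  write_regulon_report(st, regs, d1)
  tab <- read.delim(file.path(d1, "regulons.tsv"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$name, c("CT1-R1", "CT1-R2"))
  expect_equal(tolower(as.character(tab$is_ctsr)), c("true", "false"))

  back <- read_regulon_results(file.path(d1, "results.json"))
  expect_equal(back$score_table$rss, st$rss[order(st$rank)])
  expect_equal(back$score_table$p_empirical, st$p_empirical[order(st$rank)])
  expect_equal(back$genes[["CT1-R1"]], c("g1", "g2", "g3"))

  write_regulon_report(st, regs, d2)
  for (f in c("regulons.tsv", "regulon_genes.tsv", "results.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("readers reject empty inputs with typed errors", {
  empty <- write_dense_fixture(character(0))
  expect_error(read_expression_dense(empty), class = "scregulon_error")
  expect_error(read_cell_labels(empty), class = "scregulon_error")
  expect_error(read_motif_library(empty), class = "scregulon_error")
  expect_error(read_expression_mtx(tempfile()), class = "scregulon_error")
})
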