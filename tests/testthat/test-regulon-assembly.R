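# Promoter extraction, PWM scoring, exact null distribution, scanning,
# regulon construction.

test_that("promoter intervals follow the upstream conventions with clipping", {
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(6000)))
  ann <- data.frame(gene_id = c("gFar", "gNear"), chrom = "chr1",
                    strand = "+", tss = c(5000L, 500L))
  class(ann) <- c("GeneAnnotation", "data.frame")
  pr <- extract_promoters(ann, genome, L = 1000)
  t1 <- pr$table[pr$table$gene_id == "gFar", ]
  expect_equal(c(t1$start, t1$end), c(4000L, 4999L))
  expect_equal(unname(Biostrings::width(pr$seqs["gFar"])), 1000L)
  t2 <- pr$table[pr$table$gene_id == "gNear", ]
  expect_equal(c(t2$start, t2$end), c(1L, 499L))
  expect_equal(unname(Biostrings::width(pr$seqs["gNear"])), 499L)
})

test_that("minus-strand promoters are reverse-complemented and edge genes skipped", {
  genome <- Biostrings::DNAStringSet(c(chrM = "GGGGAAAC"))
  # tss = 4 on minus strand: upstream is [5, 8] = "AAAC" -> promoter "GTTT"
  ann <- data.frame(gene_id = c("gM", "gEdge", "gNoChrom"),
                    chrom = c("chrM", "chrM", "chrX"),
                    strand = c("-", "+", "+"), tss = c(4L, 1L, 10L))
  class(ann) <- c("GeneAnnotation", "data.frame")
  expect_warning(pr <- extract_promoters(ann, genome, L = 4), "skipped")
  expect_equal(as.character(pr$seqs[["gM"]]), "GTTT")
  expect_setequal(pr$table$gene_id, "gM")
})

test_that("log-odds scores have the expected closed-form values", {
  uni <- matrix(0.25, 3, 4)
  sc <- pwm_log_odds(uni)
  expect_true(all(abs(sc$log_odds) < 0.001))
  det <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  sc2 <- pwm_log_odds(det)
  expect_equal(sc2$log_odds[1, 1], 2, tolerance = 1e-3)
  expect_lt(sc2$log_odds[1, 2], -10)
  # integer scaling resolution: 1/1000 bit
  expect_true(all(abs(sc2$int_matrix / sc2$scale - sc2$log_odds) <= 5e-4))
})

test_that("exact null distribution matches 4^w enumeration", {
  set.seed(3)
  for (w in c(3, 4, 6)) {
    pwm <- matrix(stats::rgamma(w * 4, 1), w)
    pwm <- pwm / rowSums(pwm)
    sc <- pwm_log_odds(pwm)
    dist <- pwm_score_distribution(sc)
    expect_equal(sum(dist$probs), 1, tolerance = 1e-12)
    # enumerate all 4^w words
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- apply(words, 1, function(idx)
      sum(sc$int_matrix[cbind(1:w, idx)]))
    enum <- table(scores) / 4^w
    got <- setNames(dist$probs, dist$scores)
    expect_equal(sort(as.numeric(names(enum))), sort(dist$scores))
    expect_equal(unname(got[names(enum)]), as.numeric(enum), tolerance = 1e-12)
  }
})

test_that("p-value thresholds behave at the boundaries and are monotone in alpha", {
  pwm <- consensus_pwm("ACGT")
  sc <- pwm_log_odds(pwm)
  dist <- pwm_score_distribution(sc)
  t_all <- score_pvalue_threshold(sc, alpha = 1, dist = dist)
  expect_equal(t_all$threshold, min(dist$scores))
  alphas <- c(0.5, 0.1, 0.05, 0.01)
  thrs <- vapply(alphas, function(a)
    score_pvalue_threshold(sc, a, dist)$threshold, numeric(1))
  expect_true(all(diff(thrs) >= 0))
  expect_warning(t_tiny <- score_pvalue_threshold(sc, alpha = 1e-12, dist = dist),
                 "max score")
  expect_equal(t_tiny$threshold, max(dist$scores))
})

test_that("scanning finds exact consensus matches on both strands and skips N", {
  sc <- pwm_log_odds(consensus_pwm("ACGT"))
  thr <- score_pvalue_threshold(sc, alpha = 0.004) # 1/256 is the minimum tail for w=4
  hits <- scan_promoter("TTACGTTT", sc, thr)
  # ACGT is its own reverse complement, so the match is reported on both strands
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$offset, c(2L, 2L))
  expect_setequal(hits$strand, c("+", "-"))
  expect_true(all(hits$p_value > 0 & hits$p_value <= 1))

  # reverse complement of ACGT is ACGT (palindrome); use a non-palindrome
  sc2 <- pwm_log_odds(consensus_pwm("AACCG"))
  thr2 <- score_pvalue_threshold(sc2, alpha = 1e-3)
  # forward sequence contains CGGTT = revcomp(AACCG)
  hits2 <- scan_promoter("TTCGGTTAT", sc2, thr2)
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$offset, 2L)

  expect_equal(nrow(scan_promoter("NNNNNNNN", sc, thr)), 0L)
  expect_equal(nrow(scan_promoter("AC", sc, thr)), 0L)
})

test_that("scan hits match brute-force double-strand window scoring", {
  set.seed(9)
  for (i in 1:20) {
    w <- sample(3:6, 1)
    pwm <- matrix(stats::rgamma(w * 4, 1), w)
    pwm <- pwm / rowSums(pwm)
    sc <- pwm_log_odds(pwm)
    thr <- score_pvalue_threshold(sc, alpha = 0.05)
    seq_chr <- random_dna(60)
    got <- scan_promoter(seq_chr, sc, thr)
    want <- brute_force_scan(seq_chr, sc$int_matrix, thr$threshold)
    want <- want[order(want$offset, want$strand), , drop = FALSE]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score * sc$scale, want$score_int, tolerance = 1e-9)
  }
})

test_that("scan results survive a double reverse-complement round trip", {
  sc <- pwm_log_odds(consensus_pwm("AACCG"))
  thr <- score_pvalue_threshold(sc, alpha = 0.01)
  seq_chr <- random_dna(80)
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::reverseComplement(Biostrings::DNAString(seq_chr))))
  expect_identical(scan_promoter(seq_chr, sc, thr), scan_promoter(rc2, sc, thr))
})

make_promoters <- function(seqs) {
  structure(list(table = data.frame(gene_id = names(seqs), chrom = "chr1",
                                    start = 1L, end = unname(nchar(seqs))[1],
                                    strand = "+"),
                 seqs = Biostrings::DNAStringSet(seqs), L = 1000L),
            class = "PromoterSet")
}

make_module <- function(genes, ct) {
  structure(list(genes = genes, cell_type = ct, p_raw = 1e-5, p_adj = 1e-3,
                 source_bicluster = 1L, is_best = TRUE), class = "GeneModule")
}

test_that("regulons are nonredundant unions over modules with a size floor", {
  set.seed(14)
  word <- "ACGTACGTACGT"
  genes <- sprintf("g%02d", 1:8)
  seqs <- setNames(vapply(genes, function(g) random_dna(200), ""), genes)
  with_motif <- genes[1:5]
  for (g in with_motif) {
    s <- seqs[[g]]
    substr(s, 50, 61) <- word
    seqs[[g]] <- s
  }
  lib <- motif_library(list(list(motif_id = "M1", tf_name = "TFA",
                                 matrix = consensus_pwm(word))))
  prom <- make_promoters(seqs)
  mods <- list(make_module(genes[1:4], "T1"), make_module(genes[3:8], "T1"))
  regs <- build_regulons(mods, prom, lib, min_genes = 5)
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$genes, sort(with_motif)) # union, no duplicates
  expect_equal(regs[[1]]$cell_type, "T1")
  expect_equal(regs[[1]]$tf_name, "TFA")
  # min_genes floor: demand 6 genes -> no regulon
  expect_length(build_regulons(mods, prom, lib, min_genes = 6), 0L)
  # regulon genes are a subset of the cell type's module genes
  expect_true(all(regs[[1]]$genes %in% unique(unlist(lapply(mods, `[[`, "genes")))))
})

test_that("motifs sharing a TF name are merged and missing promoters handled", {
  word1 <- "AAAACCCC"; word2 <- "GGGGTTTT"
  genes <- sprintf("g%02d", 1:6)
  set.seed(15)
  seqs <- setNames(vapply(genes, function(g) random_dna(120), ""), genes)
  for (g in genes[1:3]) { s <- seqs[[g]]; substr(s, 10, 17) <- word1; seqs[[g]] <- s }
  for (g in genes[4:6]) { s <- seqs[[g]]; substr(s, 10, 17) <- word2; seqs[[g]] <- s }
  lib <- motif_library(list(
    list(motif_id = "M1", tf_name = "TFA", matrix = consensus_pwm(word1)),
    list(motif_id = "M2", tf_name = "TFA", matrix = consensus_pwm(word2))))
  prom <- make_promoters(seqs)
  mods <- list(make_module(genes, "T1"))
  regs <- build_regulons(mods, prom, lib, min_genes = 5)
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$genes, sort(genes)) # both motifs' targets merged
  # promoters missing for all module genes -> error
  empty_prom <- make_promoters(setNames(random_dna(50), "unrelated"))
  expect_error(build_regulons(mods, empty_prom, lib),
               class = "scregulon_domain_error")
})

test_that("planted motifs are recovered with high recall and few false targets", {
  set.seed(31)
  word <- "ACGTTGCAACGT"
  n_genes <- 30; n_targets <- 20; L <- 1000
  genes <- sprintf("g%02d", 1:n_genes)
  seqs <- setNames(vapply(genes, function(g) random_dna(L), ""), genes)
  targets <- genes[1:n_targets]
  for (g in targets) {
    off <- sample(L - 12, 1)
    s <- seqs[[g]]
    substr(s, off, off + 11) <- word
    seqs[[g]] <- s
  }
  pwm <- consensus_pwm(word, p = 0.85)
  lib <- motif_library(list(list(motif_id = "M1", tf_name = "TFP", matrix = pwm)))
  prom <- make_promoters(seqs)
  mods <- list(make_module(genes, "T1"))
  regs <- build_regulons(mods, prom, lib, min_genes = 5, scan_alpha = 1e-4)
  expect_length(regs, 1L)
  found <- regs[[1]]$genes
  recall <- mean(targets %in% found)
  expect_gte(recall, 0.95)
  false_targets <- setdiff(found, targets)
  # expected false genes <= n_genes * (1 - (1-alpha)^(2*(L-w+1))) ~= 6
  expect_lte(length(false_targets), 12)
})
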