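test_that("read_bed maps fields verbatim across dialects", {
  f <- withr::local_tempfile()
  writeLines(c("track name=peaks", "# comment",
               "chr1\t100\t200\tp1\t5\t+",
               "chr2\t0\t50\tp2\t1.5\t-"), f)
  x <- read_bed(f, dialect = "bed6")
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(100, 0))
  expect_equal(x$end, c(200, 50))
  expect_equal(x$name, c("p1", "p2"))
  expect_equal(x$score, c(5, 1.5))
  expect_equal(x$strand, c("+", "-"))

  np <- withr::local_tempfile()
  writeLines(paste(c("chr1", 10, 90, "peak_1", 100, ".",
                     4.5, 10, 8, 40), collapse = "\t"), np)
  y <- read_bed(np, dialect = "narrowPeak")
  expect_equal(y$start, 10)
  expect_equal(y$name, "peak_1")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(read_bed(empty)), 0)
})

test_that("read_bed rejects malformed records with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), f)
  expect_error(read_bed(f, "bed3"), "line 2")
  writeLines("chr1\tabc\t200", f)
  expect_error(read_bed(f, "bed3"), "non-integer")
  writeLines("chr1\t100", f)
  expect_error(read_bed(f, "bed3"), "line 1")
})

test_that("BED write/read round-trips interval lists", {
  withr::local_seed(42)
  x <- rand_intervals(150)
  x$name <- sprintf("p%03d", seq_len(nrow(x)))
  x$score <- round(runif(150) * 100, 2)
  x$strand <- sample(c("+", "-", "."), 150, replace = TRUE)
  f <- withr::local_tempfile()
  write_bed(x, f)
  y <- read_bed(f, "bed6")
  expect_equal(y, x, ignore_attr = TRUE)
  f3 <- withr::local_tempfile()
  write_bed(x[c("chrom", "start", "end")], f3)
  y3 <- read_bed(f3, "bed3")
  expect_equal(y3[c("chrom", "start", "end")],
               x[c("chrom", "start", "end")], ignore_attr = TRUE)
})

test_that("overlap_length closed forms, symmetry and bound", {
  a <- intervals("chr1", 0, 100)
  expect_equal(overlap_length(a, intervals("chr1", 50, 150)), 50)
  expect_equal(overlap_length(intervals("chr1", 0, 10),
                              intervals("chr1", 10, 20)), 0)
  b <- intervals("chr1", 5, 25)
  expect_equal(overlap_length(b, b), 20)
  expect_equal(overlap_length(a, intervals("chr2", 0, 100)), 0)
  withr::local_seed(7)
  for (i in 1:50) {
    u <- rand_intervals(1); v <- rand_intervals(1)
    ov <- overlap_length(u, v)
    expect_identical(ov, overlap_length(v, u))
    expect_lte(ov, min(u$end - u$start, v$end - v$start))
    expect_gte(ov, 0)
  }
})

test_that("intersect_sets equals the all-pairs oracle", {
  a <- intervals("chr1", 0, 100)
  b <- intervals("chr1", 50, 60)
  expect_equal(intersect_sets(a, b)$index_a, 1L)
  expect_equal(nrow(intersect_sets(a, intervals("chr2", 0, 10))), 0)
  withr::local_seed(101)
  for (i in 1:20) {
    x <- rand_intervals(200); y <- rand_intervals(200)
    min_bp <- sample(c(1, 5, 50), 1)
    got <- intersect_sets(x, y, min_bp)
    want <- bf_pairs(x, y, min_bp)
    expect_equal(got$index_a, want$index_a)
    expect_equal(got$index_b, want$index_b)
  }
})

test_that("classify_genomic_region follows precedence and is total", {
  ann <- toy_annotation(tss = c(10000, 50000), strand = c("+", "+"))
  peaks <- intervals("chr1",
                     c(9000, 12500, 200, 30000),
                     c(9100, 12600, 300, 30100))
  # 12500 lies in the gene body past the promoter window [8000,12000)
  got <- classify_genomic_region(peaks, ann)
  expect_equal(got[1], "promoter")
  expect_equal(got[4], "intergenic")
  expect_equal(got[3], "intergenic")
  expect_length(got, 4)
  expect_equal(sum(table(got)), 4)

  # intron precedence: gene with two exons; peak inside the gap, away
  # from the promoter
  ann2 <- genome_annotation(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               tx_start = 10000, tx_end = 40000,
               exon_starts = "10000,30000", exon_ends = "15000,40000"),
    c(chr1 = 1e5))
  expect_equal(classify_genomic_region(
    intervals("chr1", 20000, 20100), ann2), "intron")
  expect_equal(classify_genomic_region(
    intervals("chr1", 31000, 31100), ann2), "exon")
  # promoter wins over exon at the TSS
  expect_equal(classify_genomic_region(
    intervals("chr1", 10000, 10100), ann2), "promoter")
  # chromosome with no genes
  expect_equal(classify_genomic_region(
    intervals("chrX", 0, 100), ann2), "intergenic")
})

test_that("assign_peaks_to_genes honors mode and matches brute force", {
  ann <- toy_annotation(tss = c(10000, 13500), strand = c("+", "+"),
                        gene_len = 3000)
  # one peak overlapping both promoter windows [8000,12000) & [11500,15500)
  both <- intervals("chr1", 11800, 11900)
  asg <- assign_peaks_to_genes(both, ann, "promoter_only")
  expect_equal(asg$g01, 1L)
  expect_equal(asg$g02, 1L)
  # gene-body-only peak unassigned in promoter_only
  body <- intervals("chr1", 12500, 12600)  # body of g01 only
  expect_equal(assign_peaks_to_genes(body, ann, "promoter_only")$g01,
               integer(0))
  expect_equal(assign_peaks_to_genes(body, ann, "gene_or_promoter")$g01,
               1L)

  withr::local_seed(202)
  cfg <- sim_config(seed = 9, n_genes = 20, n_chroms = 2)
  ann2 <- simulate_annotation(cfg)
  peaks <- rand_intervals(50, chroms = c("chr1", "chr2"),
                          max_pos = max(ann2$genes$tx_end), max_len = 3000)
  for (mode in c("promoter_only", "gene_or_promoter")) {
    got <- assign_peaks_to_genes(peaks, ann2, mode)
    g <- ann2$genes
    site <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
    ts <- pmax(0, site - 2000); te <- site + 2000
    if (mode == "gene_or_promoter") {
      ts <- pmin(ts, g$tx_start); te <- pmax(te, g$tx_end)
    }
    for (i in seq_len(nrow(g))) {
      want <- which(bf_overlap_vec(
        list(chrom = g$chrom[i], start = ts[i], end = te[i]), peaks) >= 1)
      expect_equal(got[[g$gene_id[i]]], want)
    }
  }
})
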