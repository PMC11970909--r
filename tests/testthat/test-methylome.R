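test_that("coverage files parse with counts as the source of truth", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t101\t50.0\t5\t5",
               "chr1\t200\t201\t0.0\t0\t0",
               "chr1\t300\t301\t90.0\t1\t9"), f)
  expect_message(calls <- read_cpg_calls(f), "zero-coverage")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$pos, c(100, 300))
  expect_equal(calls$level[1], 0.5)
  # percentage column inconsistent with counts: counts win
  expect_equal(calls$level[2], 0.1)
  writeLines("chr1\t100\t101\t50.0\t-1\t5", f)
  expect_error(read_cpg_calls(f), "negative")
  writeLines("chr1\t100\t101\t50.0\tx\t5", f)
  expect_error(read_cpg_calls(f), "non-numeric")
})

test_that("cpg calls round-trip through the coverage dialect", {
  withr::local_seed(808)
  calls <- data.frame(chrom = "chr1", pos = sort(sample(1e5, 50)),
                      meth_count = rbinom(50, 30, 0.3), total_count = 30)
  calls$level <- calls$meth_count / calls$total_count
  f <- withr::local_tempfile()
  write_cpg_calls(calls, f)
  back <- read_cpg_calls(f)
  expect_equal(back, calls, ignore_attr = TRUE)
})

test_that("element means use non-exclusive membership and both weightings", {
  elements <- list(
    promoter = intervals("chr1", 0, 1000),
    cgi = intervals("chr1", 500, 1500))
  calls <- data.frame(chrom = "chr1", pos = c(100, 600, 900, 1200),
                      meth_count = c(2, 4, 6, 8),
                      total_count = c(10, 10, 10, 10))
  calls$level <- calls$meth_count / calls$total_count
  un <- element_mean_methylation(calls, elements)
  expect_equal(un$mean_level[un$class == "promoter"], mean(c(.2, .4, .6)))
  # CpGs at 600 and 900 count in both classes
  expect_equal(un$n_cpgs[un$class == "cgi"], 3L)
  cw <- element_mean_methylation(calls, elements,
                                 weighting = "coverage_weighted")
  expect_equal(cw$mean_level[cw$class == "promoter"], 12 / 30)
  # pooled-count weighting on unequal depths
  calls2 <- data.frame(chrom = "chr1", pos = c(10, 20),
                       meth_count = c(2, 8), total_count = c(10, 10))
  calls2$level <- calls2$meth_count / calls2$total_count
  cw2 <- element_mean_methylation(calls2, list(promoter =
                                                 intervals("chr1", 0, 100)),
                                  weighting = "coverage_weighted")
  expect_equal(cw2$mean_level, 0.5)
  # empty class reported as missing, never 0
  un2 <- element_mean_methylation(calls, c(elements,
                                           list(repeats = intervals("chr2",
                                                                    0, 10))))
  expect_equal(un2$n_cpgs[un2$class == "repeats"], 0L)
  expect_true(is.na(un2$mean_level[un2$class == "repeats"]))
})

test_that("genebody/intergenic partition conserves the global mean", {
  withr::local_seed(909)
  elements <- list(genebody = intervals("chr1", 0, 5e4),
                   intergenic = intervals("chr1", 5e4, 1e5))
  n <- 400
  calls <- data.frame(chrom = "chr1", pos = sample(1e5, n) - 1,
                      meth_count = rbinom(n, 30, 0.4),
                      total_count = sample(10:30, n, replace = TRUE))
  calls$meth_count <- pmin(calls$meth_count, calls$total_count)
  calls$level <- calls$meth_count / calls$total_count
  cw <- element_mean_methylation(calls, elements,
                                 weighting = "coverage_weighted")
  in_gb <- calls$pos < 5e4
  w_gb <- sum(calls$total_count[in_gb])
  w_ig <- sum(calls$total_count[!in_gb])
  global <- sum(calls$meth_count) / sum(calls$total_count)
  combo <- (cw$mean_level[cw$class == "genebody"] * w_gb +
              cw$mean_level[cw$class == "intergenic"] * w_ig) /
    (w_gb + w_ig)
  expect_equal(combo, global)
  expect_true(all(cw$mean_level >= 0 & cw$mean_level <= 1))
})

test_that("raising min_coverage never gains CpGs", {
  withr::local_seed(910)
  elements <- list(promoter = intervals("chr1", 0, 1e5))
  calls <- data.frame(chrom = "chr1", pos = sample(1e5, 200) - 1,
                      meth_count = rbinom(200, 20, 0.2),
                      total_count = sample(1:20, 200, replace = TRUE))
  calls$meth_count <- pmin(calls$meth_count, calls$total_count)
  calls$level <- calls$meth_count / calls$total_count
  ns <- vapply(c(1, 5, 10, 15), function(mc)
    element_mean_methylation(calls, elements, min_coverage = mc)$n_cpgs,
    integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("gene_element_map partitions genebody and intergenic", {
  ann <- toy_annotation(tss = c(10000, 50000))
  el <- gene_element_map(ann, cgi = intervals("chr1", 0, 500),
                         repeats = intervals("chr1", 600, 800))
  expect_setequal(names(el), c("promoter", "utr5", "exon", "intron",
                               "utr3", "genebody", "intergenic", "cgi",
                               "repeats"))
  covered <- sum(el$genebody$end - el$genebody$start) +
    sum(el$intergenic$end - el$intergenic$start)
  expect_equal(covered, sum(ann$chrom_sizes))
})
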