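test_that("adjacent promoter peaks merge into one spanning domain", {
  ann <- toy_annotation(tss = 10000)
  peaks <- intervals("chr1", c(9000, 10000), c(10000, 16000))
  dom <- measure_domains(peaks, ann)
  expect_equal(nrow(dom), 1)
  expect_equal(dom$start, 9000)
  expect_equal(dom$end, 16000)
  expect_equal(dom$width, 7000)
  expect_equal(dom$klass, "broad")
  # a gene with no promoter-overlapping peak is absent
  dom2 <- measure_domains(intervals("chr1", 100000, 100500), ann)
  expect_equal(nrow(dom2), 0)
})

test_that("merge_gap controls bridging and the TSS-proximal block wins", {
  ann <- toy_annotation(tss = 10000)
  # promoter-window peaks separated by a 400 bp gap
  peaks <- intervals("chr1", c(9500, 10400), c(10000, 11500))
  expect_equal(measure_domains(peaks, ann, merge_gap = 0)$width, 1100)
  expect_equal(measure_domains(peaks, ann, merge_gap = 400)$width, 2000)
})

test_that("domain spans equal the brute-force promoter-peak union", {
  withr::local_seed(404)
  cfg <- sim_config(seed = 31, n_genes = 40)
  ann <- simulate_annotation(cfg)
  chrom <- simulate_chromatin(cfg, ann)
  # add clutter peaks so merging is non-trivial
  clutter <- rand_intervals(100, chroms = names(ann$chrom_sizes),
                            max_pos = max(ann$genes$tx_end),
                            max_len = 2000)
  peaks <- rbind(chrom$peaks$H3K4me3_WT[names(clutter)], clutter)
  dom <- measure_domains(peaks, ann)
  prom <- make_promoters(ann)
  for (i in seq_len(nrow(prom))) {
    hit <- which(bf_overlap_vec(prom[i, ], peaks) >= 1)
    rec <- dom[dom$gene_id == prom$name[i], ]
    if (!length(hit)) {
      expect_equal(nrow(rec), 0)
      next
    }
    # brute-force chain merge at gap 0
    p <- peaks[hit, ][order(peaks$start[hit]), ]
    bs <- p$start[1]; be <- p$end[1]; blocks <- NULL
    for (j in seq_len(nrow(p))[-1]) {
      if (p$start[j] <= be) be <- max(be, p$end[j]) else {
        blocks <- rbind(blocks, c(bs, be)); bs <- p$start[j]; be <- p$end[j]
      }
    }
    blocks <- rbind(blocks, c(bs, be))
    ov <- pmax(0, pmin(blocks[, 2], prom$end[i]) -
                 pmax(blocks[, 1], prom$start[i]))
    best <- blocks[order(-ov, -(blocks[, 2] - blocks[, 1]),
                         blocks[, 1])[1], ]
    expect_equal(c(rec$start, rec$end), unname(best))
  }
})

test_that("breadth classes honor the stated strict boundaries", {
  expect_equal(classify_breadth(c(999, 1000, 3000, 5000, 5001, 6000)),
               c("narrow", "medium", "medium", "medium", "broad",
                 "broad"))
  expect_error(classify_breadth(0), "> 0")
  # monotone: widening never narrows the class
  w <- sort(c(1, 999, 1000, 2500, 5000, 5001, 99999))
  ranks <- match(classify_breadth(w), c("narrow", "medium", "broad"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("call_bd flags exactly the ceiling-count widest domains", {
  dom <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                    start = seq(0, by = 200000, length.out = 100),
                    end = seq(0, by = 200000, length.out = 100) + 1:100,
                    width = 1:100, klass = "narrow", is_bd = FALSE)
  out <- call_bd(dom, 0.05)
  expect_equal(sum(out$is_bd), 5)
  expect_equal(sort(out$width[out$is_bd]), 96:100)
  expect_equal(sum(call_bd(dom[1:10, ], 0.05)$is_bd), 1)
  expect_equal(which(call_bd(dom[1:10, ], 0.05)$is_bd), 10L)
  # ties: first ceil(fraction*N) by (chrom, start)
  tie <- dom; tie$width <- 7
  out_tie <- call_bd(tie, 0.05)
  expect_equal(which(out_tie$is_bd), 1:5)
  expect_error(call_bd(dom[0, ], 0.05), "empty")
  for (n in c(1, 7, 19, 20, 21, 333)) {
    expect_equal(sum(call_bd(dom[rep(1, n), ], 0.05)$is_bd),
                 ceiling(0.05 * n))
  }
})

test_that("differential breadth computes fold changes as defined", {
  dom <- data.frame(gene_id = "g1", chrom = "chr1", start = 0,
                    end = 1000, width = 1000, klass = "medium",
                    is_bd = TRUE)
  wt <- intervals("chr1", seq(0, 900, length.out = 4),
                  seq(0, 900, length.out = 4) + 50)
  ko <- wt[1:2, ]
  res <- differential_breadth(dom, wt, ko, wt_total = 1e6,
                              ko_total = 1e6, epsilon = 1e-9)
  expect_equal(res$wt_rpkm, 4)
  expect_equal(res$ko_rpkm, 2)
  expect_equal(res$log2fc, -1, tolerance = 1e-6)
  expect_true(res$reduced)
  # identical streams: zero fold change, nothing reduced
  res0 <- differential_breadth(dom, wt, wt)
  expect_equal(res0$log2fc, 0)
  expect_false(any(res0$reduced))
  expect_equal(bd_reduced_genes(res), "g1")
  expect_equal(bd_reduced_genes(res0), character(0))
})

test_that("planted KO reduction is recovered with high specificity", {
  cfg <- sim_config(seed = 33, n_genes = 500)
  ann <- simulate_annotation(cfg)
  ch <- simulate_chromatin(cfg, ann)
  dom <- call_bd(measure_domains(ch$peaks$H3K4me3_WT, ann), 0.05)
  db <- differential_breadth(dom, ch$fragments$H3K4me3_WT,
                             ch$fragments$H3K4me3_KO)
  tr <- ch$truth[match(db$gene_id, ch$truth$gene_id), ]
  expect_gte(mean(db$reduced[db$is_bd & tr$reduced_planted]), 0.9)
  expect_lte(mean(db$reduced[db$is_bd & !tr$reduced_planted]), 0.05)
})
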