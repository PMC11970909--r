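test_that("gene binding flags match brute-force recomputation", {
  withr::local_seed(505)
  cfg <- sim_config(seed = 41, n_genes = 30)
  ann <- simulate_annotation(cfg)
  mk <- function(n) rand_intervals(n, chroms = names(ann$chrom_sizes),
                                   max_pos = max(ann$genes$tx_end),
                                   max_len = 1500)
  fox <- mk(40); cxx <- mk(40); k4 <- mk(40)
  sets <- gene_binding_sets(ann, fox, cxx, k4,
                            bd_reduced = ann$genes$gene_id[1:3])
  g <- ann$genes
  site <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
  ps <- pmax(0, site - 2000); pe <- site + 2000
  gs <- pmin(ps, g$tx_start); ge <- pmax(pe, g$tx_end)
  for (i in seq_len(nrow(g))) {
    tf_win <- list(chrom = g$chrom[i], start = gs[i], end = ge[i])
    pr_win <- list(chrom = g$chrom[i], start = ps[i], end = pe[i])
    expect_equal(sets$foxp3_bound[i], any(bf_overlap_vec(tf_win, fox) >= 1))
    expect_equal(sets$cxxc1_bound[i], any(bf_overlap_vec(tf_win, cxx) >= 1))
    expect_equal(sets$k4me3_enriched[i],
                 any(bf_overlap_vec(pr_win, k4) >= 1))
  }
  expect_equal(sum(sets$bd_reduced), 3)
  # a gene with no peaks has all flags false
  far <- gene_binding_sets(ann, fox[0, ], cxx[0, ], k4[0, ])
  expect_false(any(far$foxp3_bound | far$cxxc1_bound |
                     far$k4me3_enriched | far$bd_reduced))
})

test_that("venn_counts enumerates the seven regions plus outside", {
  universe <- paste0("g", 1:10)
  v <- venn_counts(paste0("g", 1:4), paste0("g", 1:3), paste0("g", 1:2),
                   universe)
  counts <- setNames(v$count, v$region)
  expect_equal(counts[["ABC"]], 2)
  expect_equal(counts[["AB_only"]], 1)
  expect_equal(counts[["A_only"]], 1)
  expect_equal(counts[["outside"]], 6)
  expect_equal(sum(v$count), 10)

  d <- venn_counts("g1", "g2", "g3", universe)
  expect_true(all(d$count[grepl("only$", d$region) &
                            nchar(d$region) > 7] == 0))
  e <- venn_counts(paste0("g", 1:3), paste0("g", 1:3), paste0("g", 1:3),
                   universe)
  expect_equal(setNames(e$count, e$region)[["ABC"]], 3)
  expect_error(venn_counts("zz", "g1", "g2", universe), "universe")
})

test_that("venn regions agree with independent set algebra", {
  withr::local_seed(606)
  for (i in 1:10) {
    universe <- paste0("g", seq_len(sample(50:500, 1)))
    a <- sample(universe, sample(length(universe), 1))
    b <- sample(universe, sample(length(universe), 1))
    cc <- sample(universe, sample(length(universe), 1))
    v <- setNames(venn_counts(a, b, cc, universe)$count,
                  venn_counts(a, b, cc, universe)$region)
    expect_equal(v[["ABC"]], length(intersect(intersect(a, b), cc)))
    expect_equal(v[["A_only"]], length(setdiff(setdiff(a, b), cc)))
    expect_equal(v[["BC_only"]],
                 length(setdiff(intersect(b, cc), a)))
    expect_equal(sum(v), length(universe))
  }
})

test_that("cooccupancy_fraction nests numerator in denominator", {
  sets <- data.frame(
    gene_id = paste0("g", 1:300),
    foxp3_bound = c(rep(TRUE, 283), rep(FALSE, 17)),
    cxxc1_bound = c(rep(TRUE, 294), rep(FALSE, 6)),
    k4me3_enriched = TRUE,
    bd_reduced = c(rep(TRUE, 294), rep(FALSE, 6)))
  cf <- cooccupancy_fraction(sets, c("cxxc1_bound", "bd_reduced"),
                             "foxp3_bound")
  expect_equal(cf$count_num, 283)
  expect_equal(cf$count_den, 294)
  expect_equal(cf$fraction, 283 / 294)
  expect_equal(cf$label, "96%")
  # all denominator genes in the numerator
  all_in <- cooccupancy_fraction(sets, "bd_reduced", "cxxc1_bound")
  expect_equal(all_in$fraction, 1)
  expect_error(cooccupancy_fraction(sets, c("foxp3_bound", "k4me3_enriched",
                                            "bd_reduced", "cxxc1_bound"),
                                    "foxp3_bound"),
               NA)
  none <- sets; none$bd_reduced <- FALSE
  expect_error(cooccupancy_fraction(none, "bd_reduced", "foxp3_bound"),
               "empty")
  # invariance to row order
  cf2 <- cooccupancy_fraction(sets[sample(nrow(sets)), ],
                              c("cxxc1_bound", "bd_reduced"),
                              "foxp3_bound")
  expect_equal(cf2$fraction, cf$fraction)
})

test_that("peak_level_overlap counts each peak once and is asymmetric", {
  a <- intervals("chr1", c(0, 100), c(10, 110))
  b <- intervals("chr1", 0, 200)
  expect_equal(peak_level_overlap(a, b), 1)
  expect_equal(peak_level_overlap(
    intervals("chr1", 0, 10), intervals("chr2", 0, 10)), 0)
  # constructed asymmetric instance
  x <- intervals("chr1", 0, 10)
  y <- intervals("chr1", c(0, 50), c(5, 60))
  expect_equal(peak_level_overlap(x, y), 1)
  expect_equal(peak_level_overlap(y, x), 0.5)
  expect_error(peak_level_overlap(x[0, ], y), "empty")

  withr::local_seed(707)
  for (i in 1:10) {
    p <- rand_intervals(300); q <- rand_intervals(300)
    want <- mean(vapply(seq_len(nrow(p)), function(j)
      any(bf_overlap_vec(p[j, ], q) >= 1), logical(1)))
    expect_equal(peak_level_overlap(p, q), want)
  }
})
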