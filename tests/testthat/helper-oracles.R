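# Brute-force oracles and fixture builders, independent of the package's
# GRanges-backed overlap engine.

rand_intervals <- function(n, chroms = c("chr1", "chr2"),
                           max_pos = 10000, max_len = 400) {
  start <- floor(runif(n) * max_pos)
  len <- 1 + floor(runif(n) * max_len)
  intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

# all-pairs overlap length of row i of a vs every row of b
bf_overlap_vec <- function(a_row, b) {
  same <- b$chrom == a_row$chrom
  ov <- pmin(b$end, a_row$end) - pmax(b$start, a_row$start)
  ifelse(same, pmax(0, ov), 0)
}

bf_pairs <- function(a, b, min_bp = 1) {
  res <- list()
  for (i in seq_len(nrow(a))) {
    hit <- which(bf_overlap_vec(a[i, ], b) >= min_bp)
    if (length(hit))
      res[[length(res) + 1]] <- data.frame(index_a = i, index_b = hit)
  }
  if (!length(res))
    return(data.frame(index_a = integer(0), index_b = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$index_a, out$index_b), , drop = FALSE]
}

bf_counts <- function(fragments, windows, min_bp = 1) {
  vapply(seq_len(nrow(windows)), function(i)
    sum(bf_overlap_vec(windows[i, ], fragments) >= min_bp), integer(1))
}

# tiny non-overlapping annotation on one or two chromosomes
toy_annotation <- function(tss = c(10000, 50000, 90000),
                           strand = rep("+", length(tss)),
                           chrom = rep("chr1", length(tss)),
                           gene_len = 6000, chrom_len = 2e5) {
  tx_start <- ifelse(strand == "+", tss, tss - gene_len)
  tx_end <- tx_start + gene_len
  cs <- tapply(rep(chrom_len, length(chrom)), chrom, max)
  genome_annotation(
    data.frame(gene_id = sprintf("g%02d", seq_along(tss)), chrom = chrom,
               strand = strand, tx_start = tx_start, tx_end = tx_end,
               exon_starts = as.character(tx_start),
               exon_ends = as.character(tx_end),
               stringsAsFactors = FALSE),
    setNames(as.numeric(cs), names(cs)))
}

# minimal promoter_states skeleton for label-rule tests
fake_states <- function(centroids) {
  rownames(centroids) <- paste0("state", seq_len(nrow(centroids)))
  colnames(centroids) <- c("H3K4me3", "H3K27me3")
  structure(list(k = nrow(centroids), centroids = centroids,
                 labels = NULL,
                 assignment = data.frame(gene_id = character(0),
                                         cluster = integer(0),
                                         label = character(0)),
                 marks = c("H3K4me3", "H3K27me3")),
            class = "promoter_states")
}

cells_df <- function(keys, clusters) {
  data.frame(cell_id = sprintf("cell%03d", seq_along(keys)),
             clonotype_key = keys, cluster_label = clusters,
             stringsAsFactors = FALSE)
}
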