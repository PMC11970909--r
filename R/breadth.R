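#' Measure TSS-associated H3K4me3 domains
#'
#' For every gene, the H3K4me3 peaks overlapping its promoter window
#' (TSS +/- `promoter_halfwidth`) are chain-merged, bridging gaps of at
#' most `merge_gap` bp; the merged block with the largest promoter-window
#' overlap (ties: wider block, then leftmost) becomes the gene's domain.
#' Genes whose promoter touches no peak get no record. Domain width is the
#' span `end - start` and is immediately classified with
#' [classify_breadth()]; the broad-domain flag is left `FALSE` until
#' [call_bd()].
#'
#' @param peaks H3K4me3 peak intervals.
#' @param annotation A [genome_annotation()].
#' @param promoter_halfwidth Promoter half-width in bp (default 2000).
#' @param merge_gap Maximum gap bridged when merging peaks (default 0:
#'   only overlapping or book-ended peaks merge).
#' @return Data frame of domain records: `gene_id`, `chrom`, `start`,
#'   `end`, `width`, `klass`, `is_bd`.
#' @export
measure_domains <- function(peaks, annotation, promoter_halfwidth = 2000,
                            merge_gap = 0) {
  validate_intervals(peaks)
  prom <- make_promoters(annotation, halfwidth = promoter_halfwidth)
  hits <- intersect_sets(prom, peaks, min_bp = 1L)
  if (nrow(hits) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      width = numeric(0), klass = character(0),
                      is_bd = logical(0), stringsAsFactors = FALSE))
  sp <- split(hits$index_b, hits$index_a)
  recs <- lapply(names(sp), function(wi) {
    wi <- as.integer(wi)
    p <- peaks[sp[[as.character(wi)]], , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    # chain-merge with gaps <= merge_gap bridged
    blk_start <- p$start[1]; blk_end <- p$end[1]
    blocks <- list()
    if (nrow(p) > 1) {
      for (j in 2:nrow(p)) {
        if (p$start[j] - blk_end <= merge_gap) {
          blk_end <- max(blk_end, p$end[j])
        } else {
          blocks[[length(blocks) + 1]] <- c(blk_start, blk_end)
          blk_start <- p$start[j]; blk_end <- p$end[j]
        }
      }
    }
    blocks[[length(blocks) + 1]] <- c(blk_start, blk_end)
    bs <- vapply(blocks, `[`, numeric(1), 1)
    be <- vapply(blocks, `[`, numeric(1), 2)
    ov <- pmax(0, pmin(be, prom$end[wi]) - pmax(bs, prom$start[wi]))
    pick <- order(-ov, -(be - bs), bs)[1]
    data.frame(gene_id = prom$name[wi], chrom = prom$chrom[wi],
               start = bs[pick], end = be[pick],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$width <- out$end - out$start
  out$klass <- classify_breadth(out$width)
  out$is_bd <- FALSE
  rownames(out) <- NULL
  out
}

#' Classify domain breadth
#'
#' Width-based three-class rule: broad for widths strictly above 5 kb,
#' narrow strictly below 1 kb, medium for the closed interval 1-5 kb.
#'
#' @param width Numeric vector of domain widths in bp (> 0).
#' @return Character vector in `{"narrow", "medium", "broad"}`.
#' @examples
#' classify_breadth(c(999, 1000, 5000, 5001))
#' @export
classify_breadth <- function(width) {
  if (any(width <= 0)) stop("widths must be > 0")
  ifelse(width > 5000, "broad", ifelse(width >= 1000, "medium", "narrow"))
}

#' Call broad domains (BDs)
#'
#' Flags the top `fraction` (default 5%) widest domains as broad domains:
#' exactly `ceiling(fraction * N)` records get `is_bd = TRUE`. Ties at the
#' cutoff are broken deterministically by (width descending, chrom,
#' start). The width-rank BD flag is reported separately from the >5 kb
#' `klass`; the two broad definitions are never conflated.
#'
#' @param domains Domain records from [measure_domains()].
#' @param fraction Proportion of domains to flag, in (0, 1).
#' @return The domain data frame with `is_bd` set.
#' @export
call_bd <- function(domains, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  if (nrow(domains) == 0) stop("domain list is empty")
  n_bd <- ceiling(fraction * nrow(domains))
  ord <- order(-domains$width, domains$chrom, domains$start)
  domains$is_bd <- FALSE
  domains$is_bd[ord[seq_len(n_bd)]] <- TRUE
  domains
}

#' Differential H3K4me3 breadth signal between genotypes
#'
#' Quantifies each domain span in the WT and KO fragment streams (RPKM
#' over the identical WT-defined coordinates for both genotypes) and calls
#' a gene "reduced" when
#' `log2((ko_rpkm + epsilon) / (wt_rpkm + epsilon)) <= -lfc_threshold`.
#'
#' @param domains Domain records from [measure_domains()] (optionally
#'   after [call_bd()]).
#' @param wt_fragments,ko_fragments Fragment interval `data.frame`s.
#' @param wt_total,ko_total Library sizes; default `nrow()` of each
#'   stream.
#' @param lfc_threshold Reduction threshold on |log2 fold change|
#'   (default `log2(1.5)`).
#' @param epsilon Pseudocount on the RPKM scale (default 0.1).
#' @param min_overlap Minimum fragment/domain overlap in bp.
#' @return Data frame: `gene_id`, `width`, `is_bd`, `wt_rpkm`, `ko_rpkm`,
#'   `log2fc`, `reduced`.
#' @export
differential_breadth <- function(domains, wt_fragments, ko_fragments,
                                 wt_total = NULL, ko_total = NULL,
                                 lfc_threshold = log2(1.5), epsilon = 0.1,
                                 min_overlap = 1L) {
  if (nrow(domains) == 0) stop("domain list is empty")
  if (is.null(wt_total)) wt_total <- nrow(wt_fragments)
  if (is.null(ko_total)) ko_total <- nrow(ko_fragments)
  if (wt_total <= 0 || ko_total <= 0) stop("library totals must be > 0")
  dom_iv <- data.frame(chrom = domains$chrom, start = domains$start,
                       end = domains$end, stringsAsFactors = FALSE)
  wt_cnt <- count_fragments(wt_fragments, dom_iv, min_overlap = min_overlap)
  ko_cnt <- count_fragments(ko_fragments, dom_iv, min_overlap = min_overlap)
  wt_rpkm <- rpkm(wt_cnt, domains$width, wt_total)
  ko_rpkm <- rpkm(ko_cnt, domains$width, ko_total)
  log2fc <- log2((ko_rpkm + epsilon) / (wt_rpkm + epsilon))
  data.frame(gene_id = domains$gene_id, width = domains$width,
             is_bd = if ("is_bd" %in% names(domains)) domains$is_bd
                     else FALSE,
             wt_rpkm = wt_rpkm, ko_rpkm = ko_rpkm, log2fc = log2fc,
             reduced = log2fc <= -lfc_threshold,
             stringsAsFactors = FALSE)
}

#' BD-associated genes with reduced H3K4me3
#'
#' The gene set at the heart of the three-way co-occupancy analysis:
#' genes whose domain is both a called BD and significantly reduced in
#' the KO genotype.
#'
#' @param differential Result of [differential_breadth()] computed on
#'   BD-called domains.
#' @return Character vector of gene_ids.
#' @export
bd_reduced_genes <- function(differential) {
  differential$gene_id[differential$is_bd & differential$reduced]
}
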