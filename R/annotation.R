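#' Construct a genome annotation
#'
#' A genome annotation bundles strand-aware gene models with chromosome
#' sizes. Gene models carry the transcript span and exon structure; the
#' transcription start site (TSS) is `tx_start` on the `+` strand and
#' `tx_end` on the `-` strand, and anchors all promoter-window logic.
#'
#' @param genes A `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tx_start`, `tx_end` (0-based half-open span) and either
#'   list columns `exon_starts`/`exon_ends` (numeric vectors per gene) or
#'   comma-separated strings of the same.
#' @param chrom_sizes Named numeric vector, chromosome name -> length (bp).
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (normalized data frame with list columns `exon_starts`,
#'   `exon_ends`) and `chrom_sizes`.
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'              tx_start = 1000, tx_end = 5000,
#'              exon_starts = "1000,3000", exon_ends = "1500,5000"),
#'   c(chr1 = 100000))
#' tss(ann)
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  genes$tx_start <- as.numeric(genes$tx_start)
  genes$tx_end <- as.numeric(genes$tx_end)

  parse_list <- function(col, default) {
    if (is.null(col)) return(default)
    if (is.list(col)) return(lapply(col, as.numeric))
    lapply(strsplit(as.character(col), ","),
           function(s) as.numeric(s[nzchar(s)]))
  }
  genes$exon_starts <- parse_list(genes$exon_starts,
                                  as.list(genes$tx_start))
  genes$exon_ends <- parse_list(genes$exon_ends,
                                as.list(genes$tx_end))

  if (anyDuplicated(genes$gene_id))
    stop("gene_ids must be unique")
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$tx_start >= genes$tx_end))
    stop("gene models must satisfy tx_start < tx_end")
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("genes on chromosomes absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  over <- genes$tx_end > chrom_sizes[genes$chrom]
  if (any(over))
    stop("gene(s) extend beyond chromosome length: ",
         paste(genes$gene_id[over][1]))
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) != length(ee) || length(es) == 0)
      stop("gene ", genes$gene_id[i], ": malformed exon lists")
    if (any(ee <= es) || is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]))
      stop("gene ", genes$gene_id[i],
           ": exons must be sorted and non-overlapping")
    if (es[1] < genes$tx_start[i] || ee[length(ee)] > genes$tx_end[i])
      stop("gene ", genes$gene_id[i],
           ": exons must lie within the transcript span")
  }

  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosomes\n")
  invisible(x)
}

#' Transcription start sites
#'
#' Strand-aware TSS per gene: `tx_start` for `+` genes, `tx_end` for `-`.
#'
#' @param annotation A [genome_annotation()].
#' @return Named numeric vector gene_id -> TSS coordinate.
#' @export
tss <- function(annotation) {
  g <- annotation$genes
  stats::setNames(ifelse(g$strand == "+", g$tx_start, g$tx_end), g$gene_id)
}

#' Read a gene annotation table
#'
#' Tab-separated with header `gene_id`, `chrom`, `strand`, `tx_start`,
#' `tx_end`, `exon_starts`, `exon_ends` (the last two comma-separated).
#'
#' @param gene_path Path to the gene TSV.
#' @param chrom_sizes_path Path to a two-column TSV (chrom, length).
#' @return A [genome_annotation()].
#' @export
read_gene_table <- function(gene_path, chrom_sizes_path) {
  genes <- utils::read.table(gene_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cs <- utils::read.table(chrom_sizes_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  genome_annotation(genes, stats::setNames(as.numeric(cs[[2]]),
                                           as.character(cs[[1]])))
}

#' Write a gene annotation table
#'
#' Inverse of [read_gene_table()]; exon lists are serialized as
#' comma-separated strings.
#'
#' @param annotation A [genome_annotation()].
#' @param gene_path,chrom_sizes_path Output paths.
#' @return `gene_path`, invisibly.
#' @export
write_gene_table <- function(annotation, gene_path, chrom_sizes_path) {
  g <- annotation$genes
  out <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    tx_start = format_coord(g$tx_start), tx_end = format_coord(g$tx_end),
    exon_starts = vapply(g$exon_starts, function(v)
      paste(format_coord(v), collapse = ","), character(1)),
    exon_ends = vapply(g$exon_ends, function(v)
      paste(format_coord(v), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cs <- data.frame(names(annotation$chrom_sizes),
                   format_coord(annotation$chrom_sizes))
  utils::write.table(cs, chrom_sizes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(gene_path)
}

# Exon intervals across all genes.
exon_intervals <- function(annotation) {
  g <- annotation$genes
  n <- lengths(g$exon_starts)
  data.frame(chrom = rep(g$chrom, n),
             start = unlist(g$exon_starts, use.names = FALSE),
             end = unlist(g$exon_ends, use.names = FALSE),
             name = rep(g$gene_id, n),
             score = NA_real_, strand = rep(g$strand, n),
             stringsAsFactors = FALSE)
}

# Intronic remainder: transcript span minus exons, per gene.
intron_intervals <- function(annotation) {
  g <- annotation$genes
  res <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
    bounds_s <- c(g$tx_start[i], ee)
    bounds_e <- c(es, g$tx_end[i])
    keep <- bounds_e > bounds_s
    if (!any(keep)) next
    res[[i]] <- data.frame(chrom = g$chrom[i], start = bounds_s[keep],
                           end = bounds_e[keep], name = g$gene_id[i],
                           score = NA_real_, strand = g$strand[i],
                           stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_intervals())
  do.call(rbind, res)
}

#' Classify peaks by genomic context
#'
#' Assigns each peak exactly one category with precedence
#' promoter > exon > intron > intergenic. A peak overlapping any promoter
#' window (TSS +/- `promoter_halfwidth`, strand-aware) is a promoter peak
#' regardless of other overlaps; otherwise any exon overlap wins over
#' intron; a peak touching no gene feature is intergenic. Membership is
#' any-overlap (>= 1 bp).
#'
#' @param peaks Interval `data.frame`.
#' @param annotation A [genome_annotation()] with at least one gene.
#' @param promoter_halfwidth Promoter half-width in bp (default 2000).
#' @return Character vector, one of `"promoter"`, `"exon"`, `"intron"`,
#'   `"intergenic"` per peak.
#' @export
classify_genomic_region <- function(peaks, annotation,
                                    promoter_halfwidth = 2000) {
  validate_intervals(peaks)
  if (nrow(annotation$genes) == 0) stop("annotation has no genes")
  if (nrow(peaks) == 0) return(character(0))
  prom <- make_promoters(annotation, halfwidth = promoter_halfwidth)
  cat <- rep("intergenic", nrow(peaks))
  intr <- intron_intervals(annotation)
  if (nrow(intr)) cat[count_overlapping(peaks, intr) > 0] <- "intron"
  cat[count_overlapping(peaks, exon_intervals(annotation)) > 0] <- "exon"
  cat[count_overlapping(peaks, prom) > 0] <- "promoter"
  cat
}

#' Assign peaks to genes
#'
#' Maps each gene to the peaks overlapping its promoter window
#' (`mode = "promoter_only"`) or the union of promoter window and
#' transcript span (`mode = "gene_or_promoter"`). A peak may be assigned
#' to several genes; genes with no peak map to empty index vectors.
#'
#' @param peaks Interval `data.frame`.
#' @param annotation A [genome_annotation()].
#' @param mode `"promoter_only"` or `"gene_or_promoter"`.
#' @param promoter_halfwidth Promoter half-width in bp.
#' @param min_bp Minimum overlap (bp) for assignment.
#' @return Named list gene_id -> integer vector of peak row indices.
#' @export
assign_peaks_to_genes <- function(peaks, annotation,
                                  mode = c("promoter_only",
                                           "gene_or_promoter"),
                                  promoter_halfwidth = 2000, min_bp = 1L) {
  mode <- match.arg(mode)
  validate_intervals(peaks)
  g <- annotation$genes
  prom <- make_promoters(annotation, halfwidth = promoter_halfwidth)
  if (mode == "gene_or_promoter") {
    targets <- prom
    targets$start <- pmin(prom$start, g$tx_start)
    targets$end <- pmax(prom$end, g$tx_end)
  } else {
    targets <- prom
  }
  out <- stats::setNames(rep(list(integer(0)), nrow(g)), g$gene_id)
  if (nrow(peaks) == 0) return(out)
  hits <- intersect_sets(targets, peaks, min_bp = min_bp)
  if (nrow(hits)) {
    sp <- split(hits$index_b, g$gene_id[hits$index_a])
    out[names(sp)] <- lapply(sp, function(v) sort(unique(v)))
  }
  out
}
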