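#' Read per-CpG methylation calls (coverage dialect)
#'
#' Reads a Bismark-coverage-style TSV with columns chrom, start, end,
#' methylation percentage, methylated count, unmethylated count. The
#' methylation level is always recomputed from the counts; a percentage
#' column inconsistent with the counts is reported (message) but never
#' trusted. Zero-coverage rows are dropped with a message.
#'
#' @param path Path to the coverage TSV (no header).
#' @return Data frame of CpG calls: `chrom`, `pos` (0-based), `meth_count`,
#'   `total_count`, `level`.
#' @export
read_cpg_calls <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    stop("coverage file needs 6 columns: chrom, start, end, percent, ",
         "meth_count, unmeth_count")
  meth <- suppressWarnings(as.numeric(df[[5]]))
  unmeth <- suppressWarnings(as.numeric(df[[6]]))
  bad <- which(is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop("line ", bad[1], ": non-numeric methylation counts")
  neg <- which(meth < 0 | unmeth < 0)
  if (length(neg))
    stop("line ", neg[1], ": negative methylation counts")
  total <- meth + unmeth
  zero <- total == 0
  if (any(zero))
    message(sum(zero), " zero-coverage CpG call(s) dropped")
  level <- ifelse(zero, NA_real_, meth / total)
  pct <- suppressWarnings(as.numeric(df[[4]]))
  inconsistent <- !zero & !is.na(pct) & abs(pct - 100 * level) > 0.51
  if (any(inconsistent))
    message(sum(inconsistent), " call(s) had a percentage column ",
            "inconsistent with the counts; counts used")
  out <- data.frame(chrom = as.character(df[[1]]),
                    pos = as.numeric(df[[2]]),
                    meth_count = meth, total_count = total, level = level,
                    stringsAsFactors = FALSE)
  out[!zero, , drop = FALSE]
}

#' Write CpG calls in coverage dialect
#'
#' @param calls CpG call data frame (see [read_cpg_calls()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path) {
  out <- data.frame(calls$chrom, format_coord(calls$pos),
                    format_coord(calls$pos + 1),
                    round(100 * calls$level, 6), calls$meth_count,
                    calls$total_count - calls$meth_count)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean CpG methylation per genome-element class
#'
#' A CpG contributes to every element class whose intervals contain its
#' position: classes are non-exclusive (a promoter CpG inside a CpG
#' island counts in both), except that genebody and intergenic are
#' complementary by construction of the element map. The default
#' `cpg_unweighted` mean averages per-CpG levels; `coverage_weighted`
#' pools counts (sum meth / sum total). Classes with no qualifying CpG
#' are reported with `n_cpgs = 0` and `NA` mean, never 0.
#'
#' @param calls CpG call data frame.
#' @param elements Named list of interval `data.frame`s, class ->
#'   intervals (see [gene_element_map()]).
#' @param min_coverage Minimum `total_count` for a call to qualify.
#' @param weighting `"cpg_unweighted"` (default) or `"coverage_weighted"`.
#' @return Data frame `class`, `n_cpgs`, `mean_level`.
#' @export
element_mean_methylation <- function(calls, elements, min_coverage = 1,
                                     weighting = c("cpg_unweighted",
                                                   "coverage_weighted")) {
  weighting <- match.arg(weighting)
  stopifnot(min_coverage >= 1, is.list(elements), length(elements) > 0)
  calls <- calls[calls$total_count >= min_coverage, , drop = FALSE]
  cpg_iv <- data.frame(chrom = calls$chrom, start = calls$pos,
                       end = calls$pos + 1, stringsAsFactors = FALSE)
  res <- lapply(names(elements), function(cl) {
    el <- elements[[cl]]
    inside <- if (nrow(calls) == 0 || is.null(el) || nrow(el) == 0)
      logical(nrow(calls))
    else count_overlapping(cpg_iv, el) > 0
    n <- sum(inside)
    m <- if (n == 0) NA_real_
    else if (weighting == "cpg_unweighted") mean(calls$level[inside])
    else sum(calls$meth_count[inside]) / sum(calls$total_count[inside])
    data.frame(class = cl, n_cpgs = n, mean_level = m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Derive gene-anchored element classes from an annotation
#'
#' Builds the interval map for promoter, 5'-UTR, exon, intron, 3'-UTR,
#' genebody and intergenic classes from gene models, with optional CpG
#' island and repeat tracks appended. Gene models carry no CDS records,
#' so UTRs are approximated as the terminal `utr_bp` of the transcript at
#' each end (strand-aware). Intergenic is the complement of gene bodies
#' over each chromosome, so genebody and intergenic partition the genome.
#'
#' @param annotation A [genome_annotation()].
#' @param promoter_halfwidth Promoter half-width in bp.
#' @param utr_bp UTR approximation length in bp (default 200).
#' @param cgi,repeats Optional interval `data.frame`s for CpG islands and
#'   repeats.
#' @return Named list of interval `data.frame`s.
#' @export
gene_element_map <- function(annotation, promoter_halfwidth = 2000,
                             utr_bp = 200, cgi = NULL, repeats = NULL) {
  g <- annotation$genes
  genebody <- data.frame(chrom = g$chrom, start = g$tx_start,
                         end = g$tx_end, stringsAsFactors = FALSE)
  utr_len <- pmin(utr_bp, g$tx_end - g$tx_start)
  utr5 <- data.frame(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$tx_start, g$tx_end - utr_len),
    end = ifelse(g$strand == "+", g$tx_start + utr_len, g$tx_end),
    stringsAsFactors = FALSE)
  utr3 <- data.frame(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$tx_end - utr_len, g$tx_start),
    end = ifelse(g$strand == "+", g$tx_end, g$tx_start + utr_len),
    stringsAsFactors = FALSE)
  intergenic <- interval_complement(genebody, annotation$chrom_sizes)
  out <- list(
    promoter = make_promoters(annotation, halfwidth = promoter_halfwidth),
    utr5 = utr5,
    exon = exon_intervals(annotation),
    intron = intron_intervals(annotation),
    utr3 = utr3,
    genebody = genebody,
    intergenic = intergenic
  )
  if (!is.null(cgi)) out$cgi <- cgi
  if (!is.null(repeats)) out$repeats <- repeats
  out
}

# Complement of an interval set over whole chromosomes.
interval_complement <- function(x, chrom_sizes) {
  res <- lapply(names(chrom_sizes), function(ch) {
    xi <- x[x$chrom == ch, , drop = FALSE]
    len <- chrom_sizes[[ch]]
    if (nrow(xi) == 0)
      return(data.frame(chrom = ch, start = 0, end = len,
                        stringsAsFactors = FALSE))
    xi <- xi[order(xi$start), , drop = FALSE]
    # merge overlapping spans
    ms <- xi$start[1]; me <- xi$end[1]
    starts <- numeric(0); ends <- numeric(0)
    if (nrow(xi) > 1) {
      for (j in 2:nrow(xi)) {
        if (xi$start[j] <= me) me <- max(me, xi$end[j]) else {
          starts <- c(starts, ms); ends <- c(ends, me)
          ms <- xi$start[j]; me <- xi$end[j]
        }
      }
    }
    starts <- c(starts, ms); ends <- c(ends, me)
    gs <- c(0, ends); ge <- c(starts, len)
    keep <- ge > gs
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = gs[keep], end = ge[keep],
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
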