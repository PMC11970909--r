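#' Build strand-aware promoter windows
#'
#' Promoters are the +/- `halfwidth` regions flanking the annotated TSS
#' (default +/- 2 kb), clipped at chromosome boundaries. Clipped windows
#' keep their true (clipped) length, which also enters the RPKM
#' denominator downstream.
#'
#' @param annotation A [genome_annotation()].
#' @param halfwidth Promoter half-width in bp (> 0).
#' @return Interval `data.frame` with one window per gene; `name` carries
#'   the gene_id.
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
#'              tx_start = 4000, tx_end = 10000,
#'              exon_starts = "4000", exon_ends = "10000"),
#'   c(chr1 = 1e6))
#' make_promoters(ann)  # window [8000, 12000) around the - strand TSS
#' @export
make_promoters <- function(annotation, halfwidth = 2000) {
  stopifnot(halfwidth > 0)
  g <- annotation$genes
  unknown <- !g$chrom %in% names(annotation$chrom_sizes)
  if (any(unknown))
    stop("gene on unknown chromosome: ", g$gene_id[unknown][1])
  site <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
  len <- annotation$chrom_sizes[g$chrom]
  data.frame(chrom = g$chrom,
             start = pmax(0, site - halfwidth),
             end = pmin(len, site + halfwidth),
             name = g$gene_id, score = NA_real_, strand = g$strand,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count fragments per window
#'
#' A fragment increments a window's count iff it overlaps the window by at
#' least `min_overlap` bp (any-overlap by default, matching coverage-style
#' counting). A fragment may count toward several windows.
#'
#' @param fragments Interval `data.frame` of aligned fragments.
#' @param windows Interval `data.frame` of windows (e.g. from
#'   [make_promoters()]).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Integer vector of counts, one per window row.
#' @export
count_fragments <- function(fragments, windows, min_overlap = 1L) {
  validate_intervals(windows)
  if (nrow(windows) == 0) stop("windows must be nonempty")
  validate_intervals(fragments)
  count_overlapping(windows, fragments, min_bp = min_overlap)
}

#' Reads per kilobase per million mapped fragments
#'
#' `rpkm = count / ((window_length/1000) * (total_fragments/1e6))`.
#' Vectorized over all arguments.
#'
#' @param count Fragment count(s), >= 0.
#' @param window_length Window length(s) in bp, > 0.
#' @param total_fragments Library size(s): total mapped fragments, > 0.
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 4000, 1e6)  # 2.5
#' @export
rpkm <- function(count, window_length, total_fragments) {
  if (any(total_fragments <= 0)) stop("total_fragments must be > 0")
  if (any(window_length <= 0)) stop("window_length must be > 0")
  count / ((window_length / 1000) * (total_fragments / 1e6))
}

#' Promoter RPKM signal matrix
#'
#' Counts fragments of each sample in every promoter window and normalizes
#' to RPKM, producing the genes x samples matrix consumed by chromatin
#' state clustering and differential breadth. Library size defaults to the
#' total number of fragments supplied for the sample.
#'
#' @param annotation A [genome_annotation()].
#' @param fragments Named list of interval `data.frame`s, one per sample.
#' @param totals Optional named numeric of library sizes; defaults to
#'   `nrow()` of each fragment set.
#' @param halfwidth Promoter half-width in bp.
#' @param min_overlap Minimum fragment/window overlap in bp.
#' @return An object of class `signal_matrix`: list with `values` (RPKM
#'   matrix, genes x samples), `counts`, `totals`, `gene_ids`,
#'   `sample_ids`, `window_bp`.
#' @export
promoter_signal_matrix <- function(annotation, fragments, totals = NULL,
                                   halfwidth = 2000, min_overlap = 1L) {
  stopifnot(is.list(fragments), length(fragments) > 0)
  if (is.null(names(fragments)) || any(!nzchar(names(fragments))))
    stop("fragments must be a named list of samples")
  win <- make_promoters(annotation, halfwidth = halfwidth)
  if (is.null(totals))
    totals <- vapply(fragments, nrow, numeric(1))
  totals <- totals[names(fragments)]
  if (any(is.na(totals) | totals <= 0))
    stop("library totals must be > 0 for every sample")
  counts <- vapply(fragments, function(fr)
    count_fragments(fr, win, min_overlap = min_overlap),
    numeric(nrow(win)))
  counts <- matrix(counts, nrow = nrow(win),
                   dimnames = list(win$name, names(fragments)))
  wlen <- win$end - win$start
  values <- sweep(counts / (wlen / 1000), 2, totals / 1e6, "/")
  structure(list(values = values, counts = counts, totals = totals,
                 gene_ids = win$name, sample_ids = names(fragments),
                 window_bp = stats::setNames(wlen, win$name)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples (RPKM)\n")
  cat("samples:", paste(x$sample_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a signal matrix as TSV
#'
#' The matrix is written with gene_id rows and sample columns; library
#' totals travel in a `#totals:` header comment so the round trip is
#' lossless for the RPKM values.
#'
#' @param x A `signal_matrix`.
#' @param path Output path.
#' @return `path` (writer) or a `signal_matrix` (reader).
#' @export
write_signal_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#totals:", paste(x$sample_ids, x$totals[x$sample_ids],
                                      sep = "=", collapse = ",")), con)
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  first <- readLines(path, n = 1)
  totals <- NULL
  if (startsWith(first, "#totals:")) {
    kv <- strsplit(strsplit(sub("^#totals:", "", first), ",")[[1]], "=")
    totals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]),
                                     numeric(1)),
                              vapply(kv, `[`, character(1), 1))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  if (is.null(totals))
    totals <- stats::setNames(rep(NA_real_, ncol(vals)), colnames(vals))
  structure(list(values = vals, counts = NULL, totals = totals,
                 gene_ids = df$gene_id, sample_ids = colnames(vals),
                 window_bp = NULL),
            class = "signal_matrix")
}
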