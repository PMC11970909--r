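#' Construct a genomic interval table
#'
#' Intervals are the universal currency of the package: peaks, aligned
#' fragments, promoter windows, domains and genome elements are all stored
#' as plain data frames in BED convention, i.e. 0-based half-open
#' `[start, end)` coordinates.
#'
#' @param chrom Character vector of chromosome names (nonempty strings).
#' @param start Integer-like vector of 0-based inclusive start coordinates.
#' @param end Integer-like vector of exclusive end coordinates; `end > start`.
#' @param name Optional identifiers (recycled).
#' @param score Optional numeric scores (recycled).
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."` (recycled).
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' intervals("chr1", c(0, 500), c(100, 900), name = c("p1", "p2"))
#' @export
intervals <- function(chrom, start, end, name = NA_character_,
                      score = NA_real_, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(
    chrom  = rep_len(as.character(chrom), n),
    start  = rep_len(as.numeric(start), n),
    end    = rep_len(as.numeric(end), n),
    name   = rep_len(as.character(name), n),
    score  = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop("interval chromosome names must be nonempty strings")
  if (any(!is.finite(x$start) | !is.finite(x$end)))
    stop("interval coordinates must be finite")
  if (any(x$start < 0))
    stop("interval start coordinates must be >= 0")
  if (any(x$end <= x$start))
    stop("intervals must satisfy end > start (0-based half-open)")
  invisible(x)
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> 1-based closed GRanges (internal currency
# for the overlap engine).
iv_granges <- function(x) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Read a BED-family peak or fragment file
#'
#' Reads BED3/BED6, narrowPeak or broadPeak records into an interval table.
#' Coordinates are taken verbatim (BED files are already 0-based half-open);
#' record order is preserved. Lines starting with `track`, `browser` or `#`
#' are ignored.
#'
#' @param path Path to a tab-separated BED-family file.
#' @param dialect One of `"auto"`, `"bed3"`, `"bed6"`, `"narrowPeak"`,
#'   `"broadPeak"`. `"auto"` infers the dialect from the column count of the
#'   first data line (3 -> bed3, 6 -> bed6, 9 -> broadPeak, 10 -> narrowPeak).
#'
#' @return An interval `data.frame` (see [intervals()]).
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, dialect = c("auto", "bed3", "bed6",
                                       "narrowPeak", "broadPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) return(empty_intervals())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)

  if (dialect == "auto") {
    dialect <- switch(as.character(ncols[1]),
      "3" = "bed3", "4" = "bed6", "5" = "bed6", "6" = "bed6",
      "9" = "broadPeak", "10" = "narrowPeak",
      stop("cannot infer BED dialect from ", ncols[1], " columns; ",
           "pass dialect explicitly"))
  }
  need <- switch(dialect, bed3 = 3L, bed6 = 3L, broadPeak = 9L,
                 narrowPeak = 10L)
  bad <- which(ncols < need)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": expected >= ", need,
         " tab-separated fields for dialect '", dialect, "', got ",
         ncols[bad[1]])

  get_col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))

  chrom <- get_col(1)
  start_s <- get_col(2)
  end_s <- get_col(3)
  bad_int <- which(!grepl("^[0-9]+$", start_s) | !grepl("^[0-9]+$", end_s))
  if (length(bad_int))
    stop("line ", lineno[bad_int[1]],
         ": non-integer coordinates '", start_s[bad_int[1]], "', '",
         end_s[bad_int[1]], "'")
  start <- as.numeric(start_s)
  end <- as.numeric(end_s)
  bad_ord <- which(end <= start)
  if (length(bad_ord))
    stop("line ", lineno[bad_ord[1]], ": end (", end[bad_ord[1]],
         ") must be > start (", start[bad_ord[1]], ")")

  name <- get_col(4)
  score_s <- get_col(5)
  score <- suppressWarnings(as.numeric(score_s))
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."

  data.frame(chrom = chrom, start = start, end = end,
             name = name, score = score, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write an interval table as BED
#'
#' Writes BED6 when any of `name`, `score`, `strand` is informative,
#' otherwise BED3. Round-trips with [read_bed()].
#'
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  has6 <- nrow(x) > 0 && any(
    (!is.na(x$name) & x$name != "") |
    (!is.na(x$score) & x$score != 0) |
    (!is.na(x$strand) & x$strand != ".")
  )
  if (has6) {
    out <- data.frame(
      x$chrom, format_coord(x$start), format_coord(x$end),
      ifelse(is.na(x$name), ".", x$name),
      ifelse(is.na(x$score), 0, x$score),
      ifelse(is.na(x$strand), ".", x$strand)
    )
  } else {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Overlap length of two intervals
#'
#' Base-pair overlap of two 0-based half-open intervals; 0 when the
#' chromosomes differ or the spans are disjoint (adjacent half-open
#' intervals share no base).
#'
#' @param a,b Single-row interval `data.frame`s (or lists with `chrom`,
#'   `start`, `end`).
#' @return Integer overlap in bp.
#' @examples
#' overlap_length(intervals("chr1", 0, 100), intervals("chr1", 50, 150))
#' @export
overlap_length <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
}

#' All overlapping pairs between two interval sets
#'
#' Returns every pair `(index_a, index_b)` whose overlap is at least
#' `min_bp`, sorted by `(index_a, index_b)`. Equivalent to the all-pairs
#' scan, computed with an interval-tree sweep.
#'
#' @param set_a,set_b Interval `data.frame`s.
#' @param min_bp Minimum overlap in bp (>= 1).
#' @return A `data.frame` with integer columns `index_a`, `index_b`
#'   (1-based row indices).
#' @export
intersect_sets <- function(set_a, set_b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  validate_intervals(set_a); validate_intervals(set_b)
  if (nrow(set_a) == 0 || nrow(set_b) == 0)
    return(data.frame(index_a = integer(0), index_b = integer(0)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    iv_granges(set_a), iv_granges(set_b), minoverlap = as.integer(min_bp)))
  out <- data.frame(index_a = S4Vectors::queryHits(hits),
                    index_b = S4Vectors::subjectHits(hits))
  out[order(out$index_a, out$index_b), , drop = FALSE]
}

# Number of intervals in `query` overlapping (>= min_bp) any interval in
# `subject`; and per-query counts.
count_overlapping <- function(query, subject, min_bp = 1L) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(integer(nrow(query)))
  suppressWarnings(GenomicRanges::countOverlaps(
    iv_granges(query), iv_granges(subject), minoverlap = as.integer(min_bp)))
}
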