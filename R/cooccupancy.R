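#' Gene-level binding-set membership flags
#'
#' Builds the boolean membership table behind the Venn and co-occupancy
#' statistics: a gene is FOXP3- or CXXC1-bound when a peak overlaps its
#' promoter window or transcript span (`tf_mode = "gene_or_promoter"`),
#' and H3K4me3-enriched when at least one H3K4me3 peak overlaps its
#' promoter window (`k4_mode = "promoter_only"`). The `bd_reduced` flag
#' is taken from a supplied gene set (see [bd_reduced_genes()]).
#'
#' @param annotation A [genome_annotation()].
#' @param foxp3_peaks,cxxc1_peaks,k4me3_peaks Peak interval data frames.
#' @param bd_reduced Character vector of BD-reduced gene_ids.
#' @param tf_mode Assignment mode for the TF peak sets.
#' @param k4_mode Assignment mode for the H3K4me3 enrichment flag.
#' @param promoter_halfwidth Promoter half-width in bp.
#' @return Data frame with columns `gene_id`, `foxp3_bound`,
#'   `cxxc1_bound`, `k4me3_enriched`, `bd_reduced` (one row per annotated
#'   gene).
#' @export
gene_binding_sets <- function(annotation, foxp3_peaks, cxxc1_peaks,
                              k4me3_peaks, bd_reduced = character(0),
                              tf_mode = "gene_or_promoter",
                              k4_mode = "promoter_only",
                              promoter_halfwidth = 2000) {
  flag <- function(peaks, mode) {
    asg <- assign_peaks_to_genes(peaks, annotation, mode = mode,
                                 promoter_halfwidth = promoter_halfwidth)
    lengths(asg) > 0
  }
  g <- annotation$genes$gene_id
  data.frame(gene_id = g,
             foxp3_bound = flag(foxp3_peaks, tf_mode),
             cxxc1_bound = flag(cxxc1_peaks, tf_mode),
             k4me3_enriched = flag(k4me3_peaks, k4_mode),
             bd_reduced = g %in% bd_reduced,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Three-set Venn region counts
#'
#' Exact cardinalities of the seven non-empty regions of a three-set Venn
#' diagram plus the outside count, over an explicit gene universe.
#'
#' @param set_a,set_b,set_c Character vectors of gene_ids, subsets of
#'   `universe`.
#' @param universe Character vector of all gene_ids under consideration.
#' @param setnames Length-3 names used in the region labels.
#' @return Data frame `region`, `count`; counts sum to
#'   `length(universe)`.
#' @export
venn_counts <- function(set_a, set_b, set_c, universe,
                        setnames = c("A", "B", "C")) {
  universe <- unique(as.character(universe))
  sets <- list(unique(as.character(set_a)), unique(as.character(set_b)),
               unique(as.character(set_c)))
  for (i in 1:3) {
    out <- setdiff(sets[[i]], universe)
    if (length(out))
      stop("set ", setnames[i], " contains element(s) outside the ",
           "universe: ", out[1])
  }
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  region <- c(paste0(setnames[1], "_only"), paste0(setnames[2], "_only"),
              paste0(setnames[3], "_only"),
              paste0(setnames[1], setnames[2], "_only"),
              paste0(setnames[1], setnames[3], "_only"),
              paste0(setnames[2], setnames[3], "_only"),
              paste0(setnames[1], setnames[2], setnames[3]),
              "outside")
  count <- c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
             sum(!inA & !inB & inC), sum(inA & inB & !inC),
             sum(inA & !inB & inC), sum(!inA & inB & inC),
             sum(inA & inB & inC), sum(!inA & !inB & !inC))
  data.frame(region = region, count = count, stringsAsFactors = FALSE)
}

#' Co-occupancy fraction over flagged gene sets
#'
#' Counts genes carrying all `denominator_flags`, and the subset also
#' carrying all `extra_flags` (the numerator is by construction a subset
#' of the denominator), and reports the fraction plus a rounded
#' percentage string. This is the statistic behind e.g. "283 out of 294
#' (96%) CXXC1-bound, BD-reduced genes are also FOXP3-bound".
#'
#' @param sets A [gene_binding_sets()] table.
#' @param denominator_flags Character vector of flag column names whose
#'   conjunction defines the denominator set.
#' @param extra_flags Flag column names added (conjunction) for the
#'   numerator.
#' @return List with `count_num`, `count_den`, `fraction`, `percent`
#'   (integer, half-up), `label` (e.g. `"96%"`).
#' @export
cooccupancy_fraction <- function(sets, denominator_flags, extra_flags) {
  flags <- c(denominator_flags, extra_flags)
  miss <- setdiff(flags, names(sets))
  if (length(miss)) stop("unknown flag column(s): ",
                         paste(miss, collapse = ", "))
  den <- Reduce(`&`, sets[denominator_flags])
  if (!any(den)) stop("denominator gene set is empty")
  num <- den & Reduce(`&`, sets[extra_flags])
  fraction <- sum(num) / sum(den)
  pct <- round_half_up(100 * fraction)
  list(count_num = sum(num), count_den = sum(den), fraction = fraction,
       percent = pct, label = paste0(pct, "%"))
}

#' Fraction of peaks overlapped by another peak set
#'
#' Fraction of `peaks_a` overlapping (>= `min_bp`) at least one peak in
#' `peaks_b`; each A peak is counted once no matter how many partners it
#' has. The statistic is deliberately asymmetric in its arguments.
#'
#' @param peaks_a,peaks_b Interval `data.frame`s; `peaks_a` nonempty.
#' @param min_bp Minimum overlap in bp.
#' @return Fraction in `[0, 1]`.
#' @export
peak_level_overlap <- function(peaks_a, peaks_b, min_bp = 1L) {
  validate_intervals(peaks_a)
  if (nrow(peaks_a) == 0) stop("peaks_a is empty")
  validate_intervals(peaks_b)
  sum(count_overlapping(peaks_a, peaks_b, min_bp = min_bp) > 0) /
    nrow(peaks_a)
}
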