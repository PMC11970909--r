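#' Call paired-CDR3 clonotypes per cell
#'
#' A cell's clonotype key is the concatenation of its TRA and TRB CDR3
#' nucleotide sequences (`"TRAcdr3_TRBcdr3"`). For cells with several
#' chains per locus, the chain with the highest UMI count is selected
#' (ties broken by lexicographically smallest CDR3); a missing locus is
#' encoded as `"NA"` so single-chain clones can still expand. Chains
#' whose cell has no cluster label are dropped with a message; cells
#' lacking both loci are dropped.
#'
#' @param chains Data frame with columns `cell_id`, `locus`
#'   (`TRA`/`TRB`), `cdr3_nt`, `umi_count` (>= 1).
#' @param clusters Named character vector cell_id -> cluster label, or a
#'   data frame with columns `cell_id`, `cluster`.
#' @return Data frame `cell_id`, `clonotype_key`, `cluster_label`.
#' @export
call_clonotypes <- function(chains, clusters) {
  stopifnot(all(c("cell_id", "locus", "cdr3_nt", "umi_count")
                %in% names(chains)))
  if (is.data.frame(clusters))
    clusters <- stats::setNames(as.character(clusters$cluster),
                                clusters$cell_id)
  if (any(chains$umi_count < 1)) stop("umi_count must be >= 1")
  if (any(!chains$locus %in% c("TRA", "TRB")))
    stop("locus must be 'TRA' or 'TRB'")
  known <- chains$cell_id %in% names(clusters)
  if (any(!known))
    message(sum(!known), " chain(s) from cells without cluster labels ",
            "dropped")
  chains <- chains[known, , drop = FALSE]
  if (nrow(chains) == 0)
    return(data.frame(cell_id = character(0), clonotype_key = character(0),
                      cluster_label = character(0),
                      stringsAsFactors = FALSE))
  # top-UMI chain per (cell, locus); ties -> lexicographically smallest CDR3
  ord <- order(chains$cell_id, chains$locus, -chains$umi_count,
               chains$cdr3_nt)
  chains <- chains[ord, , drop = FALSE]
  keep <- !duplicated(chains[c("cell_id", "locus")])
  top <- chains[keep, , drop = FALSE]
  cells <- unique(top$cell_id)
  tra <- stats::setNames(rep("NA", length(cells)), cells)
  trb <- tra
  ia <- top$locus == "TRA"
  tra[top$cell_id[ia]] <- top$cdr3_nt[ia]
  trb[top$cell_id[!ia]] <- top$cdr3_nt[!ia]
  data.frame(cell_id = cells,
             clonotype_key = paste(tra, trb, sep = "_"),
             cluster_label = unname(clusters[cells]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expanded clonotypes
#'
#' A clonotype is expanded when it is detected in at least two cells.
#'
#' @param cells Data frame from [call_clonotypes()].
#' @return Character vector of expanded clonotype keys (unordered set).
#' @export
expanded_clonotypes <- function(cells) {
  tab <- table(cells$clonotype_key)
  names(tab)[tab >= 2]
}

#' Cross-cluster clonal overlap matrix
#'
#' For clusters X and Y with clonotype sets Sx and Sy (restricted to
#' expanded clonotypes when `expanded_only = TRUE`), the overlap
#' coefficient is `|Sx intersect Sy| / min(|Sx|, |Sy|)`; `"jaccard"`
#' divides by the union instead. The diagonal is 1 for nonempty sets;
#' clusters whose set is empty get 0 with a warning.
#'
#' @param cells Data frame from [call_clonotypes()].
#' @param expanded_only Restrict to expanded clonotypes (default TRUE).
#' @param method `"overlap"` (default) or `"jaccard"`.
#' @return Symmetric numeric matrix cluster x cluster with entries in
#'   `[0, 1]`.
#' @export
clonal_overlap <- function(cells, expanded_only = TRUE,
                           method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  cl <- sort(unique(cells$cluster_label))
  if (length(cl) < 2) stop("need at least 2 clusters")
  keep <- cells
  if (expanded_only)
    keep <- cells[cells$clonotype_key %in% expanded_clonotypes(cells), ,
                  drop = FALSE]
  sets <- lapply(cl, function(c)
    unique(keep$clonotype_key[keep$cluster_label == c]))
  names(sets) <- cl
  if (any(lengths(sets) == 0))
    warning("cluster(s) with no qualifying clonotypes: ",
            paste(cl[lengths(sets) == 0], collapse = ", "))
  m <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
  for (i in seq_along(cl)) for (j in seq_len(i)) {
    si <- sets[[i]]; sj <- sets[[j]]
    if (length(si) == 0 || length(sj) == 0) { m[i, j] <- m[j, i] <- 0; next }
    inter <- length(intersect(si, sj))
    denom <- if (method == "overlap") min(length(si), length(sj))
             else length(union(si, sj))
    m[i, j] <- m[j, i] <- inter / denom
  }
  m
}

#' Per-cluster clonal expansion density and richness
#'
#' For every cluster: number of cells, fraction of cells belonging to
#' expanded clonotypes (expansion assessed over the whole dataset), and
#' clonotype richness (distinct keys in the cluster).
#'
#' @param cells Data frame from [call_clonotypes()].
#' @return Data frame `cluster`, `n_cells`, `expanded_fraction`,
#'   `richness`.
#' @export
expansion_density <- function(cells) {
  exp_keys <- expanded_clonotypes(cells)
  sp <- split(cells$clonotype_key, cells$cluster_label)
  data.frame(cluster = names(sp),
             n_cells = vapply(sp, length, integer(1)),
             expanded_fraction = vapply(sp, function(k)
               mean(k %in% exp_keys), numeric(1)),
             richness = vapply(sp, function(k) length(unique(k)),
                               integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
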