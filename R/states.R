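#' Cluster promoters into chromatin states
#'
#' Runs Lloyd's k-means on the (optionally log2-transformed) H3K4me3 and
#' H3K27me3 promoter RPKM values, keeping the best of `n_init` seeded
#' restarts by within-cluster sum of squares. Clusters are re-indexed by
#' descending H3K4me3 centroid and given semantic labels: the two clusters
#' with the highest mean H3K4me3 become `K4_high_A` (higher) and
#' `K4_high_B`; of the remaining two, the one with the higher H3K27me3
#' centroid becomes `K27_high` and the last `both_low`. The default of
#' four states mirrors the active/bivalent-repressed/quiescent promoter
#' landscape of regulatory T cells.
#'
#' @param matrix A `signal_matrix` (see [promoter_signal_matrix()]) whose
#'   columns include the two `marks`.
#' @param k Number of clusters (default 4; labels require `k = 4`).
#' @param seed Integer seed; the i-th restart uses `seed + i - 1`.
#' @param n_init Number of restarts (default 10).
#' @param transform `"log2p1"` (log2(RPKM + 1), default) or `"none"`.
#' @param marks Length-2 character, the H3K4me3 and H3K27me3 column names
#'   (in that order).
#' @return An object of class `promoter_states`: list with `k`,
#'   `centroids` (k x 2, transformed space, rows ordered by descending
#'   H3K4me3), `labels` (per cluster), `assignment` (data frame gene_id,
#'   cluster, label), `tot_withinss`, `restart_withinss`, `seed`,
#'   `n_init`, `transform`, `marks`.
#' @export
cluster_promoters <- function(matrix, k = 4, seed = 1L, n_init = 10,
                              transform = c("log2p1", "none"),
                              marks = c("H3K4me3", "H3K27me3")) {
  transform <- match.arg(transform)
  stopifnot(inherits(matrix, "signal_matrix"), k >= 2, n_init >= 1)
  miss <- setdiff(marks, colnames(matrix$values))
  if (length(miss))
    stop("signal matrix lacks mark column(s): ", paste(miss, collapse = ", "))
  x <- matrix$values[, marks, drop = FALSE]
  if (transform == "log2p1") x <- log2(x + 1)
  ux <- unique(x)
  if (nrow(ux) < k)
    stop("only ", nrow(ux), " distinct promoter signal points; ",
         "use a smaller k")

  best <- NULL
  restart_wss <- numeric(0)
  for (i in seq_len(n_init)) {
    set.seed(as.integer(seed) + i - 1L)
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    km <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = 200,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = 500,
                                       algorithm = "Lloyd"))
      })
    if (is.null(km)) next
    restart_wss <- c(restart_wss, km$tot.withinss)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on every restart")

  # re-index clusters by descending H3K4me3 centroid
  ord <- order(-best$centers[, 1], -best$centers[, 2])
  remap <- match(seq_len(k), ord)
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("state", seq_len(k))
  colnames(centroids) <- marks
  cluster <- remap[best$cluster]

  obj <- structure(list(
    k = k, centroids = centroids, labels = NULL,
    assignment = data.frame(gene_id = rownames(matrix$values),
                            cluster = cluster,
                            label = NA_character_,
                            stringsAsFactors = FALSE),
    tot_withinss = best$tot.withinss, restart_withinss = restart_wss,
    seed = as.integer(seed), n_init = n_init, transform = transform,
    marks = marks), class = "promoter_states")
  if (k == 4) obj <- label_states(obj) else
    obj$assignment$label <- paste0("state", cluster)
  obj
}

#' Attach semantic state labels
#'
#' Labels the four clusters of a `promoter_states` object by centroid
#' ranking: the two highest-H3K4me3 clusters are `K4_high_A` (higher) and
#' `K4_high_B`; of the remaining two, the higher-H3K27me3 cluster is
#' `K27_high`, the last `both_low`. Ties are broken by cluster index.
#' Labels depend only on the centroids, never on cluster numbering.
#'
#' @param states A `promoter_states` object with `k = 4`.
#' @return The object with `labels` and per-gene `assignment$label` set.
#' @export
label_states <- function(states) {
  stopifnot(inherits(states, "promoter_states"))
  if (states$k != 4)
    stop("semantic labels are defined for k = 4")
  cen <- states$centroids
  k4_rank <- order(-cen[, 1], seq_len(4))  # ties -> lower cluster index
  top2 <- k4_rank[1:2]
  rest <- k4_rank[3:4]
  labels <- character(4)
  labels[top2] <- c("K4_high_A", "K4_high_B")
  k27_first <- rest[order(-cen[rest, 2], rest)][1]
  labels[k27_first] <- "K27_high"
  labels[setdiff(rest, k27_first)] <- "both_low"
  states$labels <- stats::setNames(labels, rownames(cen))
  states$assignment$label <- labels[states$assignment$cluster]
  states
}

#' @export
print.promoter_states <- function(x, ...) {
  cat("promoter_states: k =", x$k, "(", x$transform, "transform ),",
      nrow(x$assignment), "genes\n")
  tab <- table(x$assignment$label)
  cen <- round(x$centroids, 2)
  for (i in seq_len(x$k)) {
    lab <- if (!is.null(x$labels)) x$labels[i] else rownames(cen)[i]
    cat(sprintf("  %-10s centroid (%s=%.2f, %s=%.2f)  n=%d\n", lab,
                x$marks[1], cen[i, 1], x$marks[2], cen[i, 2],
                sum(x$assignment$cluster == i)))
  }
  cat("total within-cluster SS:", signif(x$tot_withinss, 5), "\n")
  invisible(x)
}

#' @export
plot.promoter_states <- function(x, matrix = NULL, ...) {
  cen <- x$centroids
  graphics::plot(cen[, 1], cen[, 2],
                 xlab = paste0(x$marks[1], " (transformed RPKM)"),
                 ylab = paste0(x$marks[2], " (transformed RPKM)"),
                 pch = 19, col = seq_len(x$k),
                 main = "Promoter chromatin state centroids", ...)
  labs <- if (!is.null(x$labels)) x$labels else rownames(cen)
  graphics::text(cen[, 1], cen[, 2], labels = labs, pos = 3)
  invisible(x)
}

#' Summarize expression by chromatin state
#'
#' Mean and median expression per state label. Genes without an
#' expression value are skipped (their count is messaged), never imputed.
#'
#' @param states A labelled `promoter_states` object.
#' @param expression Named numeric vector gene_id -> normalized
#'   expression, or a data frame with columns `gene_id`, `value`.
#' @return Data frame with columns `label`, `n_genes`, `mean_expr`,
#'   `median_expr`, one row per label present.
#' @export
state_expression_summary <- function(states, expression) {
  stopifnot(inherits(states, "promoter_states"))
  if (is.data.frame(expression))
    expression <- stats::setNames(as.numeric(expression$value),
                                  expression$gene_id)
  asg <- states$assignment
  has <- asg$gene_id %in% names(expression)
  if (!any(has))
    stop("no clustered gene has an expression value")
  n_skip <- sum(!has)
  if (n_skip > 0)
    message(n_skip, " clustered gene(s) lack expression values; skipped")
  if (mean(has) < 0.5)
    warning("expression covers under 50% of clustered genes")
  asg <- asg[has, ]
  vals <- expression[asg$gene_id]
  sp <- split(vals, asg$label)
  data.frame(label = names(sp),
             n_genes = vapply(sp, length, integer(1)),
             mean_expr = vapply(sp, mean, numeric(1)),
             median_expr = vapply(sp, stats::median, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
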