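#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with the defaults
#' that define the package's study conditions: four promoter chromatin
#' states in equal proportion with Poisson fragment rates separated by
#' well over 5 SD in log2(RPKM+1) space; a narrow/medium/broad domain
#' width mixture (0.35/0.55/0.10) spanning 300 bp - 12 kb; a 60% KO
#' signal reduction planted in 20% of broad domains; element-specific
#' Beta-Binomial CpG methylation; and a geometric clone-size repertoire
#' with 40% planted expansion per cluster and low cross-cluster sharing.
#'
#' @param seed Integer master seed; sub-generators use fixed offsets.
#' @param n_genes,n_chroms Number of genes and chromosomes.
#' @param chrom_length Chromosome length in bp, or `NULL` to size each
#'   chromosome to its content.
#' @param gene_length Min/max transcript length (bp).
#' @param n_exons Min/max exon count per gene.
#' @param min_spacing,spacing_jitter Minimum and additional random gap
#'   between consecutive genes (bp); the default keeps every planted
#'   domain and promoter window inside its own gene's territory.
#' @param state_proportions Named proportions of the four states
#'   (sum to 1).
#' @param state_rates Named matrix state x mark of expected promoter
#'   fragment counts.
#' @param width_mixture Named proportions of narrow/medium/broad domains.
#' @param width_ranges Named list of min/max width (bp) per class.
#' @param domain_rate_base,domain_rate_per_kb Expected WT fragment count
#'   per domain: `base + per_kb * width_kb`.
#' @param bd_fraction Broad-domain calling fraction (top widest).
#' @param ko_effect List `reduction` (fractional signal loss in affected
#'   domains) and `bd_fraction` (fraction of BDs affected).
#' @param foxp3_background,cxxc1_background Background gene-level binding
#'   probabilities.
#' @param cooccupancy_design Optional list `n_denominator`,
#'   `n_numerator`: plants exactly `n_denominator` genes that are BD,
#'   KO-reduced and CXXC1-bound, of which `n_numerator` are also
#'   FOXP3-bound (three-way Venn design).
#' @param expression_means Named per-state mean expression used for the
#'   synthetic expression table.
#' @param methylation List `means` (per element class), `dispersion`
#'   (Beta-Binomial, in (0,1)), `depth`, `n_cpgs`.
#' @param tcr List `n_cells`, `n_clusters`, `expansion_fraction`,
#'   `clone_geom_p`, `sharing_rate`, `cdr3_length`, `missing_tra_rate`,
#'   `extra_chain_rate`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000,
                       n_chroms = 4,
                       chrom_length = NULL,
                       gene_length = c(2000, 10000),
                       n_exons = c(2, 5),
                       min_spacing = 14000,
                       spacing_jitter = 4000,
                       state_proportions = c(K4_high_A = 0.25,
                                             K4_high_B = 0.25,
                                             K27_high = 0.25,
                                             both_low = 0.25),
                       state_rates = rbind(
                         K4_high_A = c(H3K4me3 = 800, H3K27me3 = 10),
                         K4_high_B = c(H3K4me3 = 150, H3K27me3 = 10),
                         K27_high  = c(H3K4me3 = 8,   H3K27me3 = 300),
                         both_low  = c(H3K4me3 = 8,   H3K27me3 = 8)),
                       width_mixture = c(narrow = 0.35, medium = 0.55,
                                         broad = 0.10),
                       width_ranges = list(narrow = c(300, 999),
                                           medium = c(1000, 5000),
                                           broad = c(5001, 12000)),
                       domain_rate_base = 250,
                       domain_rate_per_kb = 25,
                       bd_fraction = 0.05,
                       ko_effect = list(reduction = 0.6,
                                        bd_fraction = 0.2),
                       foxp3_background = 0.30,
                       cxxc1_background = 0.10,
                       cooccupancy_design = NULL,
                       expression_means = c(K4_high_A = 100,
                                            K4_high_B = 60,
                                            K27_high = 5, both_low = 5),
                       methylation = list(
                         means = c(promoter = 0.10, genebody = 0.75,
                                   intergenic = 0.60, cgi = 0.05,
                                   repeats = 0.80),
                         dispersion = 0.02, depth = 30, n_cpgs = 5000),
                       tcr = list(n_cells = 2000, n_clusters = 4,
                                  expansion_fraction = 0.4,
                                  clone_geom_p = 0.5, sharing_rate = 0.05,
                                  cdr3_length = c(12, 18),
                                  missing_tra_rate = 0.03,
                                  extra_chain_rate = 0.10)) {
  stopifnot(n_genes >= 0, n_chroms >= 1)
  if (abs(sum(state_proportions) - 1) > 1e-9)
    stop("state_proportions must sum to 1")
  if (any(state_proportions <= 0 | state_proportions >= 1))
    stop("state_proportions must lie in (0, 1)")
  if (!setequal(names(state_proportions), rownames(state_rates)))
    stop("state_rates rows must match state_proportions names")
  if (abs(sum(width_mixture) - 1) > 1e-9)
    stop("width_mixture must sum to 1")
  stopifnot(all(unlist(width_ranges) > 0), domain_rate_base > 0,
            bd_fraction > 0, bd_fraction < 1,
            ko_effect$reduction >= 0, ko_effect$reduction <= 1,
            methylation$depth >= 1, methylation$dispersion >= 0,
            methylation$dispersion < 1, tcr$n_cells >= 0)
  if (!is.null(cooccupancy_design)) {
    need <- ceiling(bd_fraction * n_genes)
    if (cooccupancy_design$n_denominator > need)
      stop("co-occupancy design needs ", cooccupancy_design$n_denominator,
           " broad domains but only ", need, " will be called on ",
           n_genes, " genes; increase n_genes")
    if (cooccupancy_design$n_numerator > cooccupancy_design$n_denominator)
      stop("design numerator exceeds denominator")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_genes, "genes on", x$n_chroms,
      "chromosomes |", x$tcr$n_cells, "cells |",
      x$methylation$n_cpgs, "CpGs\n")
  invisible(x)
}

#' Simulate a genome annotation
#'
#' Places non-overlapping genes with random strands and exon structures
#' sequentially along each chromosome, separated by at least
#' `min_spacing` bp. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  sizes <- stats::setNames(rep(0, config$n_chroms),
                           paste0("chr", seq_len(config$n_chroms)))
  if (n == 0) {
    if (!is.null(config$chrom_length)) sizes[] <- config$chrom_length
    else sizes[] <- 1e6
    return(genome_annotation(
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), tx_start = numeric(0),
                 tx_end = numeric(0), exon_starts = character(0),
                 exon_ends = character(0), stringsAsFactors = FALSE),
      sizes))
  }
  chrom_of <- rep(seq_len(config$n_chroms), length.out = n)
  recs <- vector("list", n)
  pos <- rep(0, config$n_chroms)
  gid <- sprintf("g%05d", seq_len(n))
  for (i in seq_len(n)) {
    ch <- chrom_of[i]
    gap <- config$min_spacing +
      floor(stats::runif(1) * (config$spacing_jitter + 1))
    len <- config$gene_length[1] +
      floor(stats::runif(1) *
              (config$gene_length[2] - config$gene_length[1] + 1))
    tx_start <- pos[ch] + gap
    tx_end <- tx_start + len
    pos[ch] <- tx_end
    n_ex <- sample(config$n_exons[1]:config$n_exons[2], 1)
    if (n_ex > 1 && len > 4 * n_ex) {
      cuts <- sort(sample(seq(tx_start + 1, tx_end - 1), 2 * (n_ex - 1)))
      es <- c(tx_start, cuts[seq(2, length(cuts), by = 2)])
      ee <- c(cuts[seq(1, length(cuts), by = 2)], tx_end)
    } else {
      es <- tx_start; ee <- tx_end
    }
    recs[[i]] <- data.frame(
      gene_id = gid[i], chrom = names(sizes)[ch],
      strand = if (stats::runif(1) < 0.5) "+" else "-",
      tx_start = tx_start, tx_end = tx_end,
      exon_starts = paste(es, collapse = ","),
      exon_ends = paste(ee, collapse = ","),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, recs)
  content <- pos + config$min_spacing + config$spacing_jitter + 20000
  if (is.null(config$chrom_length)) {
    sizes[] <- content
  } else {
    if (any(content > config$chrom_length))
      stop("genes do not fit: increase chrom_length to at least ",
           max(content))
    sizes[] <- config$chrom_length
  }
  genome_annotation(genes, sizes)
}

#' Simulate chromatin peaks, fragments and planted truth
#'
#' Draws a chromatin state per gene, a TSS-anchored H3K4me3 domain with a
#' class-conditional width, binding flags, and Poisson fragment streams:
#' promoter-mark streams (`H3K4me3`, `H3K27me3`) with state-dependent
#' rates for state clustering, and genotype streams (`H3K4me3_WT`,
#' `H3K4me3_KO`) over the domain spans, with the KO rate thinned by
#' `ko_effect$reduction` in the affected domains. When a
#' `cooccupancy_design` is set, exactly `n_denominator` genes are planted
#' as BD + KO-reduced + CXXC1-bound (given the widest domains so the
#' top-fraction BD call captures them) with `n_numerator` of them also
#' FOXP3-bound; background binding stays off the remaining BD genes so
#' the planted Venn cardinalities survive the pipeline.
#'
#' @param config A [sim_config()].
#' @param annotation Annotation from [simulate_annotation()].
#' @return List with `peaks` (named list: FOXP3, CXXC1, H3K4me3_WT,
#'   H3K4me3_KO, H3K27me3), `fragments` (named list: H3K4me3, H3K27me3,
#'   H3K4me3_WT, H3K4me3_KO), `totals`, `truth` (per-gene data frame),
#'   `expression` (named vector).
#' @export
simulate_chromatin <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  g <- annotation$genes
  n <- nrow(g)
  if (n == 0) stop("annotation has no genes")
  site <- ifelse(g$strand == "+", g$tx_start, g$tx_end)

  states <- sample(names(config$state_proportions), n, replace = TRUE,
                   prob = config$state_proportions)

  klass <- sample(names(config$width_mixture), n, replace = TRUE,
                  prob = config$width_mixture)
  rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))
  width <- numeric(n)
  for (cl in names(config$width_ranges)) {
    idx <- klass == cl
    r <- config$width_ranges[[cl]]
    width[idx] <- rint(sum(idx), r[1], r[2])
  }

  design <- config$cooccupancy_design
  broad_max <- config$width_ranges$broad[2]
  if (!is.null(design)) {
    designed <- sample.int(n, design$n_denominator)
    # widest tier: guaranteed inside the top-fraction BD call
    lo <- max(config$width_ranges$broad[1],
              floor(0.75 * broad_max)) + 1
    width[designed] <- rint(length(designed), lo, broad_max)
    klass[designed] <- "broad"
    other_broad <- setdiff(which(klass == "broad"), designed)
    squeeze <- width[other_broad] >= lo
    width[other_broad[squeeze]] <-
      rint(sum(squeeze), config$width_ranges$broad[1], lo - 1)
  } else {
    designed <- integer(0)
  }

  # planted BD set: the widths the top-fraction call will flag
  n_bd <- ceiling(config$bd_fraction * n)
  ord <- order(-width, g$chrom, g$tx_start)
  bd_planted <- logical(n)
  bd_planted[ord[seq_len(n_bd)]] <- TRUE

  if (!is.null(design)) {
    reduced <- logical(n); reduced[designed] <- TRUE
    cxxc1 <- logical(n); cxxc1[designed] <- TRUE
    bg_pool <- which(!bd_planted)
    cxxc1[bg_pool] <- cxxc1[bg_pool] |
      stats::runif(length(bg_pool)) < config$cxxc1_background
    foxp3 <- logical(n)
    foxp3[sample(designed, design$n_numerator)] <- TRUE
    fox_pool <- setdiff(seq_len(n), designed)
    foxp3[fox_pool] <- stats::runif(length(fox_pool)) <
      config$foxp3_background
  } else {
    reduced <- logical(n)
    bd_idx <- which(bd_planted)
    n_red <- round(config$ko_effect$bd_fraction * length(bd_idx))
    if (n_red > 0) reduced[sample(bd_idx, n_red)] <- TRUE
    cxxc1 <- stats::runif(n) < config$cxxc1_background
    foxp3 <- stats::runif(n) < config$foxp3_background
  }

  # peaks -----------------------------------------------------------------
  flank <- pmin(1000, round(width / 4))
  dom_start <- ifelse(g$strand == "+", site - flank, site + flank - width)
  dom_start <- pmax(0, dom_start)
  dom_end <- dom_start + width
  k4_peaks <- data.frame(chrom = g$chrom, start = dom_start,
                         end = dom_end, name = g$gene_id,
                         score = NA_real_, strand = ".",
                         stringsAsFactors = FALSE)
  tf_peak <- function(idx, w_lo = 300, w_hi = 800) {
    if (!length(idx)) return(empty_intervals())
    w <- rint(length(idx), w_lo, w_hi)
    ctr <- site[idx] + rint(length(idx), -500, 500)
    data.frame(chrom = g$chrom[idx], start = pmax(0, ctr - w %/% 2),
               end = pmax(0, ctr - w %/% 2) + w,
               name = g$gene_id[idx], score = NA_real_, strand = ".",
               stringsAsFactors = FALSE)
  }
  foxp3_peaks <- tf_peak(which(foxp3))
  cxxc1_peaks <- tf_peak(which(cxxc1))
  k27_idx <- which(states == "K27_high")
  k27_peaks <- data.frame(chrom = g$chrom[k27_idx],
                          start = pmax(0, site[k27_idx] - 1000),
                          end = site[k27_idx] + 1000,
                          name = g$gene_id[k27_idx], score = NA_real_,
                          strand = ".", stringsAsFactors = FALSE)

  # fragment streams ------------------------------------------------------
  frag_in <- function(start, end, counts, fraglen) {
    idx <- rep.int(seq_along(counts), counts)
    span <- pmax(1, (end - start)[idx] - fraglen)
    fs <- start[idx] + floor(stats::runif(length(idx)) * span)
    data.frame(chrom = g$chrom[idx], start = fs, end = fs + fraglen,
               name = NA_character_, score = NA_real_, strand = ".",
               stringsAsFactors = FALSE)
  }
  win_start <- pmax(0, site - 2000)
  win_end <- site + 2000
  prom_frags <- list()
  for (mark in colnames(config$state_rates)) {
    rate <- config$state_rates[states, mark]
    prom_frags[[mark]] <- frag_in(win_start, win_end,
                                  stats::rpois(n, rate), 200)
  }
  dom_rate <- config$domain_rate_base +
    config$domain_rate_per_kb * width / 1000
  wt_frags <- frag_in(dom_start, dom_end, stats::rpois(n, dom_rate), 150)
  ko_rate <- dom_rate * ifelse(reduced, 1 - config$ko_effect$reduction, 1)
  ko_frags <- frag_in(dom_start, dom_end, stats::rpois(n, ko_rate), 150)

  expr_mu <- config$expression_means[states]
  expression <- stats::setNames(
    expr_mu * exp(stats::rnorm(n, 0, 0.25)), g$gene_id)

  truth <- data.frame(gene_id = g$gene_id, state = states, width = width,
                      klass = klass, bd_planted = bd_planted,
                      foxp3 = foxp3, cxxc1 = cxxc1,
                      reduced_planted = reduced,
                      stringsAsFactors = FALSE)
  fragments <- c(prom_frags,
                 list(H3K4me3_WT = wt_frags, H3K4me3_KO = ko_frags))
  list(peaks = list(FOXP3 = foxp3_peaks, CXXC1 = cxxc1_peaks,
                    H3K4me3_WT = k4_peaks, H3K4me3_KO = k4_peaks,
                    H3K27me3 = k27_peaks),
       fragments = fragments,
       totals = vapply(fragments, nrow, numeric(1)),
       truth = truth, expression = expression)
}

#' Tile disjoint element classes along chromosomes
#'
#' Lays fixed-size blocks of each class down in rotation, separated by
#' gaps, producing a deliberately disjoint element map in which every
#' position belongs to at most one class. Useful for planting clean
#' per-class methylation means.
#'
#' @param chrom_sizes Named numeric of chromosome lengths.
#' @param classes Character vector of class names.
#' @param block_bp Block width per element (default 2000).
#' @param gap_bp Gap between consecutive blocks (default 500).
#' @return Named list of interval `data.frame`s.
#' @export
tile_elements <- function(chrom_sizes, classes, block_bp = 2000,
                          gap_bp = 500) {
  out <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes)
    out[[cl]] <- list()
  ci <- 0L
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - block_bp, by = block_bp + gap_bp)
    if (!length(starts)) next
    cls <- classes[((ci + seq_along(starts) - 1L) %% length(classes)) + 1L]
    ci <- ci + length(starts)
    for (k in seq_along(classes)) {
      s <- starts[cls == classes[k]]
      if (length(s))
        out[[classes[k]]][[ch]] <- data.frame(
          chrom = ch, start = s, end = s + block_bp,
          stringsAsFactors = FALSE)
    }
  }
  lapply(out, function(l) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (!length(l))
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), stringsAsFactors = FALSE)
    else do.call(rbind, c(l, list(make.row.names = FALSE)))
  })
}

#' Simulate a CpG methylome with planted element means
#'
#' Samples CpG positions uniformly within each element class present in
#' both `elements` and `config$methylation$means`, allocating CpGs
#' equally across classes, and draws methylated counts from a
#' Beta-Binomial with the class mean and configured dispersion at fixed
#' depth. If the supplied element map has overlapping classes the
#' estimated means will mix accordingly; use [tile_elements()] for a
#' disjoint map.
#'
#' @param config A [sim_config()].
#' @param elements Named list of interval `data.frame`s.
#' @return List with `calls` (CpG call data frame) and `truth`
#'   (per-CpG class and planted mean; per-class planted means as
#'   attribute `planted_means`).
#' @export
simulate_methylome <- function(config, elements) {
  stopifnot(inherits(config, "sim_config"), length(elements) > 0)
  set.seed(config$seed + 2L)
  m <- config$methylation
  classes <- intersect(names(m$means), names(elements))
  classes <- classes[vapply(elements[classes], nrow, integer(1)) > 0]
  if (!length(classes)) stop("no element class matches methylation means")
  n_per <- floor(m$n_cpgs / length(classes))
  rho <- m$dispersion
  res <- lapply(classes, function(cl) {
    el <- elements[[cl]]
    w <- el$end - el$start
    pick <- sample.int(nrow(el), n_per, replace = TRUE, prob = w)
    pos <- el$start[pick] + floor(stats::runif(n_per) * w[pick])
    mu <- m$means[[cl]]
    p <- if (rho < 1e-8) rep(mu, n_per)
    else stats::rbeta(n_per, mu * (1 - rho) / rho,
                      (1 - mu) * (1 - rho) / rho)
    meth <- stats::rbinom(n_per, m$depth, p)
    data.frame(chrom = el$chrom[pick], pos = pos, meth_count = meth,
               total_count = m$depth, class = cl, mu = mu,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, res)
  all <- all[order(all$chrom, all$pos), , drop = FALSE]
  calls <- data.frame(chrom = all$chrom, pos = all$pos,
                      meth_count = all$meth_count,
                      total_count = all$total_count,
                      level = all$meth_count / all$total_count,
                      stringsAsFactors = FALSE, row.names = NULL)
  truth <- all[c("chrom", "pos", "class", "mu")]
  rownames(truth) <- NULL
  attr(truth, "planted_means") <- m$means[classes]
  list(calls = calls, truth = truth)
}

#' Simulate a single-cell TCR repertoire
#'
#' Builds per-cluster repertoires in which a planted fraction of cells
#' belong to multi-cell clones with geometric (>= 2) sizes and the rest
#' are singletons; a configurable fraction of expanded clones is shared
#' into a second cluster (absorbing one of its singletons, so cluster
#' sizes are preserved). Each clonotype gets unique random TRA/TRB CDR3
#' nucleotide sequences; chain tables carry UMI counts, occasional decoy
#' secondary chains with strictly lower UMI, and occasional missing TRA
#' chains.
#'
#' @param config A [sim_config()].
#' @return List with `chains` (cell_id, locus, cdr3_nt, umi_count),
#'   `clusters` (cell_id, cluster), `truth` (per cell: planted clone id
#'   and clone size).
#' @export
simulate_tcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  tc <- config$tcr
  k <- tc$n_clusters
  sizes <- rep(tc$n_cells %/% k, k)
  sizes[k] <- sizes[k] + tc$n_cells - sum(sizes)
  cl_names <- paste0("c", seq_len(k))

  clone_of <- integer(0); cluster_of <- character(0)
  next_clone <- 0L
  singleton_ids <- list()
  expanded_clones <- integer(0)
  for (ci in seq_len(k)) {
    n_c <- sizes[ci]
    n_multi <- round(tc$expansion_fraction * n_c)
    left <- n_multi
    while (left >= 2) {
      s <- min(2 + stats::rgeom(1, tc$clone_geom_p), left)
      if (left - s == 1) s <- s + 1  # never strand a lone cell
      next_clone <- next_clone + 1L
      clone_of <- c(clone_of, rep(next_clone, s))
      cluster_of <- c(cluster_of, rep(cl_names[ci], s))
      expanded_clones <- c(expanded_clones, next_clone)
      left <- left - s
    }
    n_single <- n_c - (n_multi - left)
    ids <- next_clone + seq_len(n_single)
    next_clone <- next_clone + n_single
    clone_of <- c(clone_of, ids)
    cluster_of <- c(cluster_of, rep(cl_names[ci], n_single))
    singleton_ids[[ci]] <- ids
  }

  # share a fraction of expanded clones into a second cluster by
  # converting one of its singletons
  n_share <- round(tc$sharing_rate * length(expanded_clones))
  if (n_share > 0 && k >= 2) {
    share <- sample(expanded_clones, n_share)
    for (cid in share) {
      home <- cluster_of[match(cid, clone_of)]
      partner <- sample(setdiff(seq_len(k), match(home, cl_names)), 1)
      pool <- intersect(singleton_ids[[partner]], clone_of)
      if (!length(pool)) next
      victim <- pool[1]
      i <- match(victim, clone_of)
      clone_of[i] <- cid
      singleton_ids[[partner]] <- setdiff(singleton_ids[[partner]], victim)
    }
  }

  n_cells_total <- length(clone_of)
  cell_id <- sprintf("cell%05d", seq_len(n_cells_total))

  # unique CDR3 pair per clonotype
  rand_nt <- function(n) {
    len <- tc$cdr3_length[1] + floor(stats::runif(n) *
      (tc$cdr3_length[2] - tc$cdr3_length[1] + 1))
    vapply(len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1))
  }
  clone_ids <- sort(unique(clone_of))
  repeat {
    tra <- rand_nt(length(clone_ids))
    trb <- rand_nt(length(clone_ids))
    if (!anyDuplicated(paste(tra, trb))) break
  }
  names(tra) <- names(trb) <- clone_ids

  ci <- as.character(clone_of)
  umi_a <- 1 + stats::rpois(n_cells_total, 3)
  umi_b <- 1 + stats::rpois(n_cells_total, 3)
  has_tra <- stats::runif(n_cells_total) >= tc$missing_tra_rate
  chains <- rbind(
    data.frame(cell_id = cell_id[has_tra], locus = "TRA",
               cdr3_nt = unname(tra[ci[has_tra]]),
               umi_count = umi_a[has_tra], stringsAsFactors = FALSE),
    data.frame(cell_id = cell_id, locus = "TRB",
               cdr3_nt = unname(trb[ci]), umi_count = umi_b,
               stringsAsFactors = FALSE))
  # decoy secondary TRA chains with strictly lower UMI
  decoy <- which(has_tra & umi_a >= 2 &
                   stats::runif(n_cells_total) < tc$extra_chain_rate)
  if (length(decoy)) {
    chains <- rbind(chains, data.frame(
      cell_id = cell_id[decoy], locus = "TRA",
      cdr3_nt = rand_nt(length(decoy)),
      umi_count = pmax(1, umi_a[decoy] -
                         (1 + floor(stats::runif(length(decoy)) *
                                      umi_a[decoy] / 2))),
      stringsAsFactors = FALSE))
  }
  chains <- chains[order(chains$cell_id, chains$locus,
                         -chains$umi_count), , drop = FALSE]
  rownames(chains) <- NULL

  clone_size <- table(clone_of)
  truth <- data.frame(cell_id = cell_id, cluster = cluster_of,
                      clone_id = clone_of,
                      clone_size = as.integer(clone_size[ci]),
                      stringsAsFactors = FALSE)
  list(chains = chains,
       clusters = data.frame(cell_id = cell_id, cluster = cluster_of,
                             stringsAsFactors = FALSE),
       truth = truth)
}
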