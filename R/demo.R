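#' Run the full demo pipeline on synthetic data
#'
#' Generates a compact synthetic dataset, writes every input in its
#' standard on-disk format (gene TSV, chrom sizes, peak/fragment BEDs,
#' CpG coverage TSV, TCR contig and cluster tables), reads the files back
#' and runs the whole analysis: promoter quantification, chromatin-state
#' clustering, domain breadth and BD calling, differential breadth,
#' binding-set Venn and co-occupancy fractions, element methylation
#' summary, and clonotype expansion/sharing. All stage outputs are
#' written as TSVs under `out_dir`. The run is a pure function of the
#' config: identical configs give byte-identical output trees.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()]; default is a small demo configuration.
#' @param seed Seed used for the default config when `config` is `NULL`.
#' @return Invisibly, a list with the main in-memory results (`states`,
#'   `domains`, `differential`, `venn`, `cooccupancy`, `methylation`,
#'   `tcr_overlap`, `tcr_density`, `truth`).
#' @export
run_demo <- function(out_dir, config = NULL, seed = 1L) {
  if (is.null(config)) {
    base <- sim_config()
    config <- sim_config(seed = seed, n_genes = 400,
                         cooccupancy_design = list(n_denominator = 20,
                                                   n_numerator = 19),
                         methylation = utils::modifyList(
                           base$methylation, list(n_cpgs = 4000)),
                         tcr = utils::modifyList(
                           base$tcr, list(n_cells = 600)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- file.path(out_dir, "inputs")
  dir.create(inp, showWarnings = FALSE)
  p <- function(...) file.path(inp, paste0(...))
  o <- function(...) file.path(out_dir, paste0(...))
  wtsv <- function(x, path) utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE)

  # --- generate + write inputs
  ann <- simulate_annotation(config)
  write_gene_table(ann, p("genes.tsv"), p("chrom.sizes"))
  chrom <- simulate_chromatin(config, ann)
  for (nm in names(chrom$peaks))
    write_bed(chrom$peaks[[nm]], p("peaks_", nm, ".bed"))
  for (nm in names(chrom$fragments))
    write_bed(chrom$fragments[[nm]], p("frags_", nm, ".bed"))
  wtsv(data.frame(gene_id = names(chrom$expression),
                  value = chrom$expression), p("expression.tsv"))
  elements <- tile_elements(ann$chrom_sizes,
                            names(config$methylation$means))
  meth <- simulate_methylome(config, elements)
  write_cpg_calls(meth$calls, p("cpg_coverage.tsv"))
  tcr <- simulate_tcr(config)
  wtsv(tcr$chains, p("tcr_contigs.tsv"))
  wtsv(tcr$clusters, p("tcr_clusters.tsv"))

  # --- read inputs back and run the pipeline
  ann2 <- read_gene_table(p("genes.tsv"), p("chrom.sizes"))
  frags <- list(
    H3K4me3 = read_bed(p("frags_H3K4me3.bed")),
    H3K27me3 = read_bed(p("frags_H3K27me3.bed")))
  mat <- promoter_signal_matrix(ann2, frags)
  write_signal_matrix(mat, o("promoter_rpkm.tsv"))

  states <- cluster_promoters(mat, k = 4, seed = config$seed)
  wtsv(states$assignment, o("state_assignments.tsv"))
  wtsv(data.frame(state = rownames(states$centroids),
                  label = states$labels, states$centroids,
                  check.names = FALSE), o("state_centroids.tsv"))
  expr <- utils::read.table(p("expression.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  wtsv(state_expression_summary(states, expr),
       o("state_expression.tsv"))

  k4_wt_peaks <- read_bed(p("peaks_H3K4me3_WT.bed"))
  domains <- call_bd(measure_domains(k4_wt_peaks, ann2),
                     fraction = config$bd_fraction)
  wtsv(domains, o("domains.tsv"))
  diffb <- differential_breadth(domains,
                                read_bed(p("frags_H3K4me3_WT.bed")),
                                read_bed(p("frags_H3K4me3_KO.bed")))
  wtsv(diffb, o("differential_breadth.tsv"))

  sets <- gene_binding_sets(ann2,
                            read_bed(p("peaks_FOXP3.bed")),
                            read_bed(p("peaks_CXXC1.bed")),
                            k4_wt_peaks,
                            bd_reduced = bd_reduced_genes(diffb))
  wtsv(sets, o("gene_binding_sets.tsv"))
  venn <- venn_counts(sets$gene_id[sets$foxp3_bound],
                      sets$gene_id[sets$cxxc1_bound],
                      sets$gene_id[sets$bd_reduced],
                      universe = sets$gene_id,
                      setnames = c("FOXP3", "CXXC1", "BDreduced"))
  wtsv(venn, o("venn_counts.tsv"))
  cooc <- tryCatch(
    cooccupancy_fraction(sets, c("cxxc1_bound", "bd_reduced"),
                         "foxp3_bound"),
    error = function(e) NULL)
  if (!is.null(cooc))
    wtsv(data.frame(count_num = cooc$count_num,
                    count_den = cooc$count_den,
                    fraction = cooc$fraction, label = cooc$label),
         o("cooccupancy_fraction.tsv"))

  calls <- read_cpg_calls(p("cpg_coverage.tsv"))
  meth_summary <- element_mean_methylation(calls, elements)
  wtsv(meth_summary, o("methylation_by_element.tsv"))

  chains <- utils::read.table(p("tcr_contigs.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  clusters <- utils::read.table(p("tcr_clusters.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  cells <- call_clonotypes(chains, clusters)
  wtsv(cells, o("clonotypes.tsv"))
  ov <- clonal_overlap(cells)
  utils::write.table(data.frame(cluster = rownames(ov), ov,
                                check.names = FALSE),
                     o("clonal_overlap.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dens <- expansion_density(cells)
  wtsv(dens, o("expansion_density.tsv"))

  invisible(list(states = states, domains = domains,
                 differential = diffb, sets = sets, venn = venn,
                 cooccupancy = cooc, methylation = meth_summary,
                 tcr_overlap = ov, tcr_density = dens,
                 truth = list(chromatin = chrom$truth,
                              methylome = meth$truth,
                              tcr = tcr$truth)))
}
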