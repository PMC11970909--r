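---
title: "Methods: promoter chromatin states, broad H3K4me3 domains and co-occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter chromatin states, broad H3K4me3 domains and co-occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccmap)
```

## Scope and model

`cooccmap` implements the computational core of an integrative
epigenomic analysis of regulatory T (T~reg~) cells, centred on the
interplay between the lineage transcription factor FOXP3, the
SET1/COMPASS subunit CXXC1 (CFP1), and the promoter mark H3K4me3. The
pipeline has five analytical stages, all operating on plain interval
data (BED convention, 0-based half-open coordinates, exact chromosome
string matching):

1. **Promoter quantification.** Promoters are the ±2 kb windows
   flanking the strand-aware TSS. Fragments are counted into windows by
   any-overlap (≥ 1 bp, half-open boundaries), and counts are
   normalized to RPKM,
   $\mathrm{RPKM} = c \,/\, \big((L/10^3)(N/10^6)\big)$, with $L$ the
   (possibly boundary-clipped) window length and $N$ the total mapped
   fragments of the sample. The library-size definition is not uniquely
   determined by convention; we use total supplied fragments, which
   keeps samples comparable, and expose it as an argument.
2. **Chromatin states.** Lloyd's k-means with $k = 4$ on the two-column
   matrix of log2(RPKM + 1) H3K4me3/H3K27me3 promoter signal, best of
   `n_init = 10` seeded restarts by within-cluster sum of squares.
   Restart $i$ draws its initial centres from the distinct signal rows
   under seed $s + i - 1$, so the fit is deterministic given
   (seed, n_init). Clusters are re-indexed by descending H3K4me3
   centroid and labelled by centroid ranking only (`K4_high_A`,
   `K4_high_B`, `K27_high`, `both_low`); ties break by cluster index.
   We log2-transform for variance stabilization but do not z-score
   (the two marks are on a common RPKM scale, and z-scoring would
   inflate the low-signal axis); `transform = "none"` is available.
   Genes with zero signal in both marks are retained — they are
   precisely what the `both_low` state should capture.
3. **Domain breadth.** Per gene, H3K4me3 peaks overlapping the promoter
   window are chain-merged (gaps ≤ `merge_gap`, default 0, bridged).
   When several merged blocks remain, "one domain per TSS" needs a
   tie-break rule; we keep the block with the largest
   promoter-window overlap (ties: wider, then leftmost), so the domain
   is always a single contiguous span and width = end − start. Widths
   are classified narrow (< 1 kb), medium (1–5 kb, closed interval) or
   broad (> 5 kb), with both "more than" and "less than" read strictly.
   Independently, the top 5% widest domains are flagged as broad
   domains (BDs): exactly `ceiling(0.05 N)` records, ties broken by
   (width desc, chrom, start). The > 5 kb class and the width-rank BD
   flag are reported separately and never conflated.
4. **Differential breadth and co-occupancy.** WT and KO fragment
   streams are quantified over the identical WT-defined domain spans;
   a gene is *reduced* when
   $\log_2\!\big((\mathrm{KO}+\varepsilon)/(\mathrm{WT}+\varepsilon)\big)
   \le -\log_2 1.5$ (pseudocount $\varepsilon = 0.1$ RPKM; both
   configurable — no printed threshold exists for this call, so the
   default is a conventional 1.5-fold change). The BD-reduced gene set
   (`is_bd & reduced`) is intersected with gene-level FOXP3/CXXC1
   binding flags (TF peaks assigned by promoter-or-gene-body overlap;
   H3K4me3 enrichment by promoter-only overlap, default definition
   "≥ 1 peak") to produce three-set Venn counts and co-occupancy
   fractions; report percentages round half-up.
5. **Methylome and repertoire summaries.** Per-CpG calls (counts are
   authoritative; the percentage column is only checked) are averaged
   per element class with non-exclusive membership — the only reading
   under which CGIs and repeats can coexist with gene elements — using
   an unweighted per-CpG mean by default and a pooled
   coverage-weighted mean as an option. TCR clonotypes are the paired
   TRA/TRB CDR3 nucleotide key with the top-UMI chain per locus (we
   read "top two clonotypes with highest expression" as one TRA + one
   TRB chain; a literal two-clonotypes-per-cell reading would break the
   one-key-per-cell model all downstream statistics rely on). A
   clonotype is expanded when seen in ≥ 2 cells; cross-cluster sharing
   uses the overlap coefficient $|S_x \cap S_y|/\min(|S_x|,|S_y|)$
   (Jaccard behind a flag), with missing loci encoded as `"NA"` so
   single-chain clones can still expand.

## What the synthetic generator emulates

All validation runs on synthetic data with planted ground truth
(`sim_config()`, `simulate_annotation()`, `simulate_chromatin()`,
`simulate_methylome()`, `simulate_tcr()`). The generator's defaults
define the study conditions and were chosen once:

* **Genome.** Non-overlapping genes with ≥ 14 kb spacing, so every
  planted domain (≤ 12 kb) and promoter window stays inside its own
  gene's territory and planted truth survives the pipeline exactly.
* **States.** Equal proportions of the four states with Poisson
  promoter fragment rates (H3K4me3, H3K27me3) of (800, 10), (150, 10),
  (8, 300) and (8, 8): centroid separations of several log2 units
  against Poisson noise of ≲ 0.1–0.5 SD, i.e. ≥ 5 SD separation.
  Planted per-state expression means (100/60/5/5) give the expected
  K4-high > K27-high transcription ordering.
* **Domains.** Width mixture 0.35/0.55/0.10 over narrow
  (300–999 bp), medium (1–5 kb) and broad (5–12 kb) ranges. Expected
  WT fragment count per domain is `250 + 25 × width_kb`, large enough
  that a 1.5-fold Poisson excursion is far outside the operating
  range — the null configuration (`reduction = 0`) therefore yields
  zero reduced calls, and a planted 60% reduction (default in 20% of
  BDs) is detected with sensitivity ≈ 1 and BD false-positive rate
  ≈ 0.
* **Co-occupancy design.** `cooccupancy_design` plants exact Venn
  cardinalities: the designated denominator genes receive the widest
  broad domains (so the top-5% call captures them), KO thinning and
  CXXC1 peaks, with the designated numerator subset also FOXP3-bound;
  background binding stays off the remaining BD genes. With
  `n_denominator = 294`, `n_numerator = 283` on 6000 genes the
  pipeline returns exactly (283, 294) and the report string "96%".
* **Methylome.** Beta-Binomial calls (depth 30, dispersion 0.02) with
  per-class means (promoter 0.10, genebody 0.75, intergenic 0.60,
  CGI 0.05, repeats 0.80) sampled inside a disjoint tiled element map
  (`tile_elements()`); planted means are recovered within ±0.02 at
  5000 CpGs.
* **Repertoire.** Per cluster, 40% of cells are allocated to
  multi-cell clones with geometric (≥ 2) sizes (p = 0.5, a heavy-ish
  tail at desk scale); 5% of expanded clones are shared into a second
  cluster by absorbing one of its singletons, preserving cluster
  sizes. Missing-TRA (3%) and decoy low-UMI chains (10%) exercise the
  key-building rules and perturb the realized expansion fraction by
  ≈ 0.01.

The generator emulates the *statistical* structure of CUT&Tag/ChIP-seq,
WGBS and single-cell V(D)J data — state-dependent intensities, width
mixtures, planted overlaps, element-specific methylation, clone-size
skew. It does not model read-level sequence, mappability or GC bias,
duplicate structure, or biological coupling between states and domain
width (a `both_low` gene may still carry a planted peak). Passing tests
therefore demonstrate correctness of the computations under the stated
generative assumptions, not robustness to every artefact of real
libraries.

## Numerical choices and degenerate inputs

* Half-open adjacency never counts as overlap; `min_bp`/`min_overlap`
  floors are configurable where counting semantics matter.
* `call_bd` uses the ceiling rule, so `|BD| = ceiling(fraction × N)`
  for every `N ≥ 1`, with a deterministic tie-break.
* k-means with fewer distinct rows than `k` is an error advising a
  smaller `k`; restarts that collapse a cluster are retried or skipped.
* Empty denominators (co-occupancy), empty peak sets
  (`peak_level_overlap`), unknown chromosomes and malformed records are
  errors naming the offending element or line, never silent `NaN`s.
* Zero-coverage CpGs are dropped (messaged); element classes with no
  qualifying CpG are reported missing, never as 0.
* All randomness flows from explicit seeds; every generator is a pure
  function of its config, and the demo pipeline is byte-identical
  across reruns of the same config.

## Worked example

```{r demo, eval = FALSE}
out <- run_demo(tempfile("cooccmap_demo_"), seed = 1)
out$cooccupancy$label      # co-occupancy percentage, e.g. "95%"
print(out$states)          # four labelled promoter states
head(out$domains)          # TSS-anchored domains with class and BD flag
out$methylation            # per-element methylation means
out$tcr_density            # per-cluster expansion fraction and richness
```

The demo uses a compact configuration (400 genes, 600 cells, 4000
CpGs, a planted 19/20 co-occupancy design) sized to run in seconds;
the validation suite and `scripts/acceptance.R` use 2000–6000 genes,
2000 cells and 5000 CpGs. These sizes are the package's chosen
operating points for desk-scale validation; all stages scale linearly
in fragments and log-linearly in intervals.

## Known limitations

* The genomic-distribution classifier fixes any-overlap membership with
  promoter > exon > intron > intergenic precedence; tools differ here
  (e.g. midpoint-based assignment), so exact category proportions are
  convention-dependent.
* The domain definition anchors on promoter overlap and imposes no
  distance cap beyond it; very long merged peaks can extend well into
  gene bodies.
* "High H3K4me3 at promoters" defaults to ≥ 1 overlapping peak; an
  RPKM-quantile alternative can be built from
  `promoter_signal_matrix()` output.
* The Venn universe is always an explicit input — results depend on
  whether all annotated or only expressed genes are supplied.
* Expansion is assessed over all retained cells; carrying sample tags
  in the cluster label is the supported route to per-sample expansion.
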