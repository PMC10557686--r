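# Demo scenario for fiberhap::run_pipeline().
#
# Schema
# ------
# seed:            integer; every stochastic stage derives from it
# outdir:          output directory (TSV/BED/bedGraph/JSON only)
# simulate:        n_cells, coverage_per_hap (expected fibers per
#                  cell-haplotype per locus; may be < 1)
# model:           the synthetic genome —
#   chrom_sizes:   map chromosome -> length (bp)
#   elements:      regulatory elements; per-haplotype Bernoulli actuation
#                  probabilities, optional couple_to/couple_corr for
#                  correlated single-molecule actuation
#   cpg_regions:   expanded to CpG sites every `spacing` bp with
#                  per-haplotype baseline methylation probabilities
#   silencing:     cell-level region silencing: in `fraction` of cells the
#                  stated haplotype of the region has element actuation
#                  `residual_actuation` (default 0) and CpG methylation
#                  `silenced_methylation` (default 0.9)
#   genes:         expected transcripts per cell per haplotype; a located
#                  gene is zeroed on its silenced haplotype
# fire:            alpha (Bonferroni level, 0.01), genome_size (assayed bp,
#                  defaults to sum of chrom_sizes), merge_gap
# hap_test:        min_precision (accessible-patch FIRE precision cutoff,
#                  0.90), fdr_level, nominal_p
# codependency:    anchor (element id or interval), min_precision (0.95),
#                  min_span
# imbalance:       min_precision (0.90), min_reads (10), sd_mult (3),
#                  regions to test against the genomic background,
#                  exclude_chroms
# methylome:       unit (fiber|call), min_sites, regions to test
#
# The scenario below stages the package's three motifs on one 400-kb
# chromosome: (i) a promoter-enhancer pair with correlated single-molecule
# actuation, where the promoter is fully silenced and hypermethylated on
# H2 (a readthrough-silencing analogue) and the linked gene goes
# monoallelic; (ii) an imprinted-like element with strongly skewed
# actuation; (iii) a 60-kb region whose H2 copy is silenced in half the
# cells (an XCI-spreading analogue), read out against background elements.

seed: 42
outdir: fiberhap_demo

simulate:
  n_cells: 80
  coverage_per_hap: 0.6

model:
  chrom_sizes: {chrA: 400000}
  fiber_length_mean: 15000
  fiber_length_sd: 2000
  background_msp_rate: 1.0
  unassigned_rate: 0.05
  locus_merge_gap: 4000
  elements:
    - {element_id: promoter,  chrom: chrA, start: 50000,  end: 50200,  actuation_h1: 0.60, actuation_h2: 0.60}
    - {element_id: enhancer,  chrom: chrA, start: 53000,  end: 53200,  actuation_h1: 0.50, actuation_h2: 0.50, couple_to: promoter, couple_corr: 0.8}
    - {element_id: imprinted, chrom: chrA, start: 100000, end: 100200, actuation_h1: 0.70, actuation_h2: 0.05}
    - {element_id: bg1,       chrom: chrA, start: 150000, end: 150200, actuation_h1: 0.50, actuation_h2: 0.50}
    - {element_id: bg2,       chrom: chrA, start: 170000, end: 170200, actuation_h1: 0.40, actuation_h2: 0.40}
    - {element_id: bg3,       chrom: chrA, start: 190000, end: 190200, actuation_h1: 0.55, actuation_h2: 0.55}
    - {element_id: bg4,       chrom: chrA, start: 210000, end: 210200, actuation_h1: 0.45, actuation_h2: 0.45}
    - {element_id: xci1,      chrom: chrA, start: 310000, end: 310200, actuation_h1: 0.50, actuation_h2: 0.50}
    - {element_id: xci2,      chrom: chrA, start: 330000, end: 330200, actuation_h1: 0.50, actuation_h2: 0.50}
    - {element_id: xci3,      chrom: chrA, start: 350000, end: 350200, actuation_h1: 0.50, actuation_h2: 0.50}
  cpg_regions:
    - {chrom: chrA, start: 49800, end: 50400, spacing: 20, baseline_h1: 0.10, baseline_h2: 0.10}
  silencing:
    # readthrough-silencing analogue: H2 promoter copy off in every cell,
    # promoter CpGs hypermethylated
    - {chrom: chrA, start: 49000, end: 51000, haplotype: H2, fraction: 1.0, silenced_methylation: 0.9}
    # XCI-spreading analogue: H2 copy of a 60-kb region silenced in half
    # the cells
    - {chrom: chrA, start: 300000, end: 360000, haplotype: H2, fraction: 0.5}
  genes:
    - {gene_id: geneA, mean_h1: 6, mean_h2: 6, chrom: chrA, start: 49000, end: 51000}
    - {gene_id: geneB, mean_h1: 5, mean_h2: 5}

fire:
  alpha: 0.01
  genome_size: 400000
  merge_gap: 0

hap_test:
  min_precision: 0.90
  fdr_level: 0.05
  nominal_p: 0.01

codependency:
  anchor: promoter
  min_precision: 0.95
  min_span: 10

imbalance:
  min_precision: 0.90
  min_reads: 10
  sd_mult: 3
  exclude_chroms: []
  regions:
    - {chrom: chrA, start: 300000, end: 360000, name: xci_region}

methylome:
  unit: fiber
  min_sites: 3
  regions:
    - {chrom: chrA, start: 49800, end: 50400, name: promoter_cpg}
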