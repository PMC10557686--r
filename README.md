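# fiberhap

Haplotype-resolved analysis of single-molecule chromatin architecture
(Fiber-seq) data in R.

Fiber-seq stencils the chromatin architecture of individual DNA molecules
onto the DNA itself: a non-specific m6A methyltransferase marks accessible
DNA, and long-read sequencing then reports, for every multi-kilobase
"fiber", the positions of methyltransferase-sensitive patches (MSPs) —
stretches between nucleosome footprints that are a mixture of
internucleosomal linkers and genuinely accessible regulatory elements. An
upstream classifier assigns each MSP a *FIRE precision* `p`, the
confidence that the patch is a regulatory element (a Fiber-seq Inferred
Regulatory Element) rather than a linker. Because each fiber, CpG call and
full-length transcript can be phased to a parental haplotype through
heterozygous variants, one genome provides its own internal control: the
two haplotypes can be compared molecule by molecule.

`fiberhap` takes phased, precision-scored tabular data (fiber, CpG-call
and transcript tables — documented TSV formats, plus BED/bedGraph for
intervals and tracks) and provides the downstream statistics:

* **Aggregate FIRE signal and peak calling.** Per base,
  `S_g = -10 · Σ_k log10(1 - p_k)` over the MSPs covering position `g` —
  the phred-scaled probability that no overlapping patch is a true
  regulatory element. Peaks are maximal runs with
  `S_g ≥ S* = -10 · log10(α / G)`, a genome-wide Bonferroni threshold at
  level α (default 0.01) over `G` assayed bases.
* **Haplotype-specific accessibility.** Per peak, spanning fibers are
  classified accessible/inaccessible (MSP with `p ≥ 0.90` overlapping the
  peak), counted by haplotype, and tested with Fisher's exact test;
  Benjamini–Hochberg correction across peaks gives the genome-wide
  volcano view that exposes imprinted and variant-driven loci.
* **Single-molecule co-dependency.** For two elements and the fibers
  spanning both, `score = P(A∧B) - P(A)·P(B)` (accessible patches at
  `p ≥ 0.95`), with Fisher's exact test on the joint 2×2 — the statistic
  that nominates enhancer–promoter couplings on single molecules.
* **Regional allelic imbalance.** Signed per-peak differences in percent
  accessibility between haplotypes, a coverage filter
  (`max(10, median - 3·sd)` phased reads), a Mann–Whitney U comparison of
  a region against the genomic background, and a silenced-cell-fraction
  estimator `f̂` = median per-peak relative actuation loss — the machinery
  for detecting X-inactivation skewing and XCI spreading into
  translocated autosomal DNA.
* **Haplotype methylation and allele-specific expression.** Per-site CpG
  pileups by haplotype, pooled Fisher tests of regional (e.g. promoter)
  hypermethylation, and exact binomial tests of phased full-length
  transcript counts against the balanced 0.5 null.
* **A synthetic-fiber generator** (`genome_model()`, `simulate_fibers()`,
  `simulate_cpg()`, `simulate_transcripts()`) with per-haplotype Bernoulli
  element actuation, imprinted skews, correlated element pairs (exact
  joint Bernoulli), promoter-hypermethylation-with-silencing and
  cell-persistent region silencing, so the entire pipeline is testable
  without sequencing data.

## Worked example

Simulate a locus with one balanced element and one imprinted element
(actuation 0.70 on H1 vs 0.05 on H2), call peaks, and test for
haplotype-specific accessibility:

```r
library(fiberhap)

m <- genome_model(
  c(chr1 = 100000),
  elements = list(
    element_spec("chr1", 30000, 30200, 0.55, 0.55, element_id = "balanced"),
    element_spec("chr1", 70000, 70200, 0.70, 0.05, element_id = "imprinted")))
fs <- simulate_fibers(m, n_cells = 100, coverage_per_hap = 1, seed = 7)
fs
#> <fiber_set> 400 fibers (H1: 190, H2: 187, UNASSIGNED: 23), 5442 MSPs on 1 chromosome(s)

tr <- aggregate_fire_signal(fs, "chr1", 69000, 71000)
thr <- peak_score_threshold(alpha = 0.01, genome_size = 1e5)  # 70
peaks <- call_fire_peaks(tr, thr)
peaks
#>   chrom start   end          peak_id max_signal
#> 1  chr1 70000 70200 chr1_70000_70200   1172.617

counts <- peak_haplotype_counts(fs, peaks, min_precision = 0.90)
haplotype_specific_accessibility(counts)
#>            peak_id pct_h1 pct_h2 abs_delta odds_ratio  p_value  q_value nominal_sig fdr_sig
#> 1 chr1_70000_70200     74   4.44      69.5       61.1 2.03e-24 2.03e-24        TRUE    TRUE
```

The imprinted element is accessible on 74% of phased H1 fibers but only
4.4% of H2 fibers (Δ = 69.5 percentage points), and Fisher's exact test
rejects balance at p ≈ 2e-24 — a textbook haplotype-specific regulatory
element. The signal maximum (S ≈ 1173, from ~80 stacked
precision-0.97 MSPs) dwarfs the Bonferroni threshold of 70.

The full pipeline — simulation, signal, peaks, haplotype tests,
co-dependency scan, imbalance report, methylation and ASE, with a
manifest of output hashes — runs from a single YAML config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "fiberhap"),
             outdir = "fiberhap_demo")
```

Reruns with the same config and seed are byte-identical.

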