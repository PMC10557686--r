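---
title: "Models and methods behind fiberhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fiberhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberhap)
```

# The data model

A Fiber-seq experiment yields one record per sequenced chromatin fiber: a
genomic interval, a haplotype tag (`H1`, `H2`, or `UNASSIGNED` when the
molecule carries no informative heterozygous variant), and a list of
methyltransferase-sensitive patches (MSPs). Every MSP carries a FIRE
precision `p` in [0, 1] — the upstream classifier's confidence that the
patch is a regulatory element rather than an internucleosomal linker. The
classifier itself is out of scope here: `fiberhap` consumes its output.
Alongside fibers travel per-fiber CpG methylation calls and per-read
transcript gene assignments, both haplotype-tagged.

All coordinates inside the package are 0-based half-open (BED
convention); 1-based display coordinates are converted at the boundary.
A single pair of predicates (`interval_overlaps()`,
`interval_contains()`) backs every interval decision, so the convention
cannot drift between modules. Internally a `fiber_set` is relational
(a fiber table plus an MSP table keyed by `fiber_id`) for vectorised
overlap work at the 10^5-fiber scale, while the on-disk contract stays
one row per fiber with MSPs encoded as `start-end:precision` triples.

# Aggregate FIRE signal and peak calling

For a genomic position $g$ covered by MSPs with precisions $p_k$,

$$S_g = -10 \sum_{k=1}^{C_g} \log_{10}(1 - p_k),$$

where fibers covering $g$ without an MSP contribute a $p = 0$ term, i.e.
nothing. Interpreting $1 - p_k$ as the per-molecule probability that the
patch is *not* a regulatory element, $\prod_k (1 - p_k)$ is the per-base
probability that no covering molecule shows a true element, and $S_g$ is
its phred scaling. That interpretation is what makes a Bonferroni
correction meaningful: a base is significant when
$\prod_k (1 - p_k) \le \alpha / G$, equivalently
$S_g \ge S^* = -10\log_{10}(\alpha/G)$, with $\alpha = 0.01$ by default
and $G$ the number of assayed bases. $G$ is a required, explicit
parameter rather than a constant because the appropriate value (assembly
length vs assayed bases) depends on the experiment. Peaks are maximal
runs of significant bases; an optional `merge_gap` (default 0 bp)
bridges short sub-threshold gaps.

Two numerical choices: $1 - p$ is clamped below at $10^{-10}$ so
$p = 1$ keeps the score finite (one such MSP contributes 100 score
units); and all MSPs contribute to the sum regardless of precision —
the 0.90 precision rule defines element calls on individual fibers, not
the aggregate sum, and sub-0.3 linker precisions add negligible mass
(a $p = 0.3$ MSP contributes 1.5 units against thresholds of 60+). A
`min_precision` argument restricts the sum for users who prefer an
elements-only track.

# Haplotype tests at peaks

A fiber is informative for a peak only when it **fully contains** the
peak interval; a molecule that merely overlaps cannot distinguish closed
chromatin from truncation, so it is `NOT_SPANNING` rather than
inaccessible. A spanning fiber is accessible iff an MSP with
`p >= min_precision` overlaps the peak by at least one base.

The precision conventions are 0.90 for haplotype/imbalance analyses and
0.95 for co-dependency. These reconcile two notations used for the same
quantity in the field — "precision over 90%" alongside "FIRE precision
≤ 0.10"/"≤ 0.05"; we read the latter as thresholds on $1 - p$. Both are
plain arguments, so either convention can be applied.

Per peak, accessible/total counts by haplotype form a 2×2 table tested
with Fisher's exact test. The two-sided p-value uses the
minimum-likelihood rule — sum the hypergeometric probabilities of all
tables (margins fixed) whose point probability is at most that observed,
within a relative tolerance of $10^{-7}$ — the convention of standard
statistical libraries. The odds ratio is the sample estimate $ad/bc$
(`Inf`/`NaN` sentinels at zero cells), not the conditional MLE. Peaks
with zero spanning fibers on either haplotype carry no information about
imbalance and are dropped with a message rather than assigned p = 1.
Benjamini–Hochberg adjustment across peaks marks `fdr_sig` (default
level 0.05); `nominal_sig` uses p < 0.01.

# Single-molecule co-dependency

For peaks A and B and the set of fibers spanning **both**,

$$\mathrm{score} = \hat P(A \wedge B) - \hat P(A)\,\hat P(B),$$

with significance from Fisher's exact test on the
(both / A-only / B-only / neither) table. Marginal proportions default
to the jointly spanning denominator: then
$\hat P(A \wedge B) \le \min(\hat P(A), \hat P(B))$ holds exactly and
the Fisher table and the score describe the same sample. A
`marginals = "per-peak"` switch computes each marginal among fibers
spanning that peak alone, for users who want marginals that match
per-peak accessibility tracks. Below `min_span` (default 10) spanning
fibers the result is flagged `insufficient` with no p-value — Fisher on
smaller tables is uninformative, and the flag makes the censoring
explicit. A scan against an anchor attaches BH q-values across
candidates.

# Regional imbalance and the silenced-cell fraction

Per peak, the signed delta `pct_h1 - pct_h2` (percentage points) is
computed from spanning phased fibers. Peaks with summed phased coverage
below `max(min_reads, median - sd_mult * sd)` are excluded
(defaults 10 reads and 3 sd; median and sd computed once on the full
input set, before removal) — the screen for mapping/phasing artifacts.
Coverage is the summed phased coverage; a per-haplotype variant would
double the filter's knobs without changing the cases it is meant to
catch. Each named region's delta distribution is compared against the
background (all filtered peaks outside every named region, minus
excluded chromosomes) with a two-sided Mann–Whitney U test — exact
enumeration when both sides have ≤ 20 tie-free values, the tie-corrected
normal approximation otherwise. Deltas are signed, not absolute, because
silencing is directional.

If a haplotype is silenced (with residual accessibility ~0) in a
fraction $f$ of cells, its accessible-fiber proportion at every peak in
the region scales by $1 - f$. The estimator inverts this per peak,
$r_i = (\mathrm{pct}_{\mathrm{active}} -
\mathrm{pct}_{\mathrm{silenced}})/\mathrm{pct}_{\mathrm{active}}$
where the active side is positive, and takes the median over peaks,
clipped to [0, 1]. The median is chosen over the mean for robustness to
low-coverage outlier peaks; under the generative model above the
estimator is consistent as coverage and peak count grow. The silenced
side is inferred from the sign of the median delta unless given. This
estimator is a declared model-based choice: it assumes silencing is the
only source of regional haplotype asymmetry and that residual actuation
in silenced cells is negligible; with residual actuation $r > 0$ it
estimates $f(1 - r/a)$ rather than $f$, i.e. it is conservative.

# CpG methylation and allele-specific expression

Per-site pileups tally calls and methylation percentages by haplotype
(unassigned calls tallied separately). A region test pools the region's
calls per haplotype into one 2×2 Fisher table. Because one fiber
contributes calls at many CpGs, pooled raw calls are not independent
units; the default `unit = "fiber"` therefore collapses each phased
fiber to a single majority vote across the region's sites (ties count
methylated) before testing. `unit = "call"` provides the naive pooled
version, which is anti-conservative under within-fiber correlation but
matches a bare pileup comparison. At least `min_sites` (default 3) CpG
sites with calls on both haplotypes are required.

Allele-specific expression uses the exact binomial test of phased
transcript counts against 0.5, two-sided by the point-probability rule.
Haplotype assignment of reads is an input: the variant-based phasing of
full-length transcripts happens upstream.

# The synthetic-data generator

The generator exists so that every statistic above can be exercised,
calibrated and power-checked without sequencing data. It emulates:

* **Per-haplotype Bernoulli actuation.** Each element actuates on each
  covering fiber independently with `actuation_h1`/`actuation_h2`;
  actuated elements emit an MSP at the element interval with precision
  `high_precision` (default 0.97, a typical confident element call).
  Imprinted-like loci are skewed pairs such as (0.70, 0.05).
* **Coupled pairs.** Two elements can target a Pearson correlation
  $\rho$; the pair is drawn from the exact joint Bernoulli with
  $P_{11} = p_a p_b + \rho\sqrt{p_a(1-p_a)p_b(1-p_b)}$ after a
  feasibility check against the Fréchet–Hoeffding bounds (violations
  are errors, not silent clamps). This avoids copula machinery while
  hitting the requested marginals and correlation exactly.
* **Cell-persistent silencing.** Each cell draws one Bernoulli state per
  silencing spec. All fibers, CpG calls and transcripts of a silenced
  cell-haplotype-region are jointly affected (actuation drops to
  `residual_actuation`, default 0; CpG methylation rises to
  `silenced_methylation`, default 0.9; located genes are zeroed). The
  cell, not the fiber, is the unit because regional silencing is a
  cell-level epigenetic state — this is what makes a fraction-$f$
  scenario produce a coherent $\approx f$ shift rather than extra noise.
* **Fiber sampling.** Elements and CpG sites are merged into loci
  (`locus_merge_gap`, default 5 kb); per locus and haplotype,
  `round(n_cells * coverage_per_hap)` fibers are drawn from uniformly
  sampled cells, with lengths Normal(15 kb, 3 kb) truncated below at
  max(1 kb, locus width) and positioned to span the locus. Coverage
  below 1 means a locus samples a subset of cells, as in real data.
  Defaults mirror HiFi Fiber-seq molecules (10–20 kb).
* **Background linker MSPs.** Scattered at `background_msp_rate` per kb
  (default 1/kb) with precisions uniform on [0, 0.3] (no linker-score
  distribution is published; anything below every analysis threshold
  and spread over a plausible range serves). Placement uses one
  Bernoulli per 200-bp window — the nucleosome-repeat scale — with each
  MSP confined to its window, which guarantees the sorted,
  non-overlapping MSP invariant without rejection sampling; MSPs landing
  in element footprints are discarded.
* **Phasing noise.** Fibers and transcript reads are relabelled
  `UNASSIGNED` at `unassigned_rate` (default 0.05, reflecting the ~90%
  phasing typical of variant-rich long reads). Actuation always follows
  the true haplotype; only the label is masked.

What it does **not** emulate: raw sequences or base-level m6A, mapping
and alignment artifacts, copy-number or breakpoint structure, fiber
length-accessibility correlations, position-specific nucleosome
phasing, and linkage between the fiber, CpG and transcript assays at
the level of individual cells (`simulate_transcripts()` draws a fresh
cell sample from the same population). Tests passing on this generator
therefore validate the statistics under the stated generative model,
not robustness to upstream artifact classes — which is exactly the
coverage filter's job on real data.

Determinism: every `simulate_*` call takes an explicit seed and restores
the caller's RNG state; identical inputs give byte-identical outputs.
Elements must be pairwise non-overlapping so per-fiber MSPs cannot
collide.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated
data, sized so the checks are sharp but quick: exhaustive Fisher
verification over all 2×2 tables with N ≤ 30; calibration at 10,000
fibers (binomial/correlation bounds ±0.02/±0.05); imprinting recovery at
100 fibers per haplotype across 100 seeded runs with a 1,000-peak null
calibration; region silencing at $f = 0.10$ over 200 region peaks
against 2,000 background peaks (~50 phased fibers per haplotype per
peak, 1,000 cells) across 20 seeded runs, plus an $f$-monotonicity sweep
over {0.05, 0.1, 0.2, 0.4} at 40 peaks; methylation detection at 30
calls per haplotype across 100 runs. The end-to-end demo config covers
all three scenario motifs on a 400-kb chromosome in under a minute.

# Known limitations

* The silenced-fraction estimator assumes the generative model above;
  on real data with residual accessibility or escape loci it reads low.
* Pooled methylation testing treats fibers as exchangeable within a
  region; allele-specific *sites* inside an otherwise balanced region
  are better served by per-site volcano analysis of the pileup.
* Peak calling operates per chromosome on dense per-base tracks;
  whole-genome human-scale track assembly is memory-bound and should be
  windowed by the caller.
* The co-dependency scan conditions on fibers spanning both elements,
  so its reach is bounded by the fiber length distribution; distal
  pairs are reported `insufficient` rather than extrapolated.
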