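test_that("degenerate generator inputs behave as specified", {
  m <- tiled_model(2, 0.5, 0.5)
  expect_equal(n_fibers(simulate_fibers(m, 0, 1, seed = 1)), 0L)
  expect_equal(nrow(simulate_transcripts(m, 0, seed = 1)), 0L)

  # actuation 1.0: every phased-or-not H1-derived fiber carries the MSP
  m1 <- tiled_model(1, 1.0, 0.0, unassigned_rate = 0)
  fs <- simulate_fibers(m1, 50, 1, seed = 2)
  counts <- peak_haplotype_counts(fs, element_peaks(m1), 0.9)
  expect_equal(counts$acc_h1, counts$total_h1)
  expect_gt(counts$total_h1, 0)
  expect_equal(counts$acc_h2, 0L)
})

test_that("the generator is deterministic under a fixed seed", {
  m <- tiled_model(3, 0.6, 0.3,
                   silencing = silencing_spec("chr1", 0, 50000, "H2", 0.5))
  a <- simulate_fibers(m, 30, 1, seed = 99)
  b <- simulate_fibers(m, 30, 1, seed = 99)
  fa <- withr::local_tempfile()
  fb <- withr::local_tempfile()
  write_fiber_table(a, fa)
  write_fiber_table(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_false(identical(
    readLines(fa),
    {write_fiber_table(simulate_fibers(m, 30, 1, seed = 100), fb)
      readLines(fb)}))

  cpg_m <- genome_model(
    c(chr1 = 100000),
    elements = element_spec("chr1", 50000, 50200, 0.5, 0.5),
    cpg_sites = data.frame(chrom = "chr1", pos = seq(50000, 50100, 20),
                           baseline_h1 = 0.3, baseline_h2 = 0.3))
  fs <- simulate_fibers(cpg_m, 20, 1, seed = 4)
  expect_identical(simulate_cpg(cpg_m, fs, seed = 5),
                   simulate_cpg(cpg_m, fs, seed = 5))
  expect_identical(simulate_transcripts(m, 10, seed = 6),
                   simulate_transcripts(m, 10, seed = 6))
})

test_that("empirical actuation matches the specified marginals", {
  # 10,000 fibers at actuation 0.5: 99% binomial CI half-width
  # 2.58 * sqrt(0.25/10000) = 0.0129 < 0.02
  m <- tiled_model(1, 0.5, 0.5, unassigned_rate = 0)
  fs <- simulate_fibers(m, 5000, 1, seed = 31)
  counts <- peak_haplotype_counts(fs, element_peaks(m), 0.9)
  expect_equal(counts$total_h1 + counts$total_h2, 10000L)
  expect_lt(abs(counts$acc_h1 / counts$total_h1 - 0.5), 0.02)
  expect_lt(abs(counts$acc_h2 / counts$total_h2 - 0.5), 0.02)
})

test_that("coupled elements reproduce the target per-fiber correlation", {
  m <- coupled_cluster_model(corr = 0.8, n_candidates = 1, coupled_at = 1)
  fs <- simulate_fibers(m, 10000, 1, seed = 13)
  fs$fibers <- fs$fibers[fs$fibers$hap_true == "H1", ]
  anchor <- list(chrom = "chr1", start = 50000, end = 50200)
  cand <- list(chrom = "chr1", start = 51000, end = 51200)
  a <- classify_fiber_at_peak(fs, anchor, 0.9) == "ACCESSIBLE"
  b <- classify_fiber_at_peak(fs, cand, 0.9) == "ACCESSIBLE"
  expect_lt(abs(cor(a, b) - 0.8), 0.05)
})

test_that("infeasible couplings are rejected at the Frechet bound", {
  specs <- list(
    element_spec("chr1", 1000, 1200, 0.9, 0.9, element_id = "a"),
    element_spec("chr1", 3000, 3200, 0.9, 0.9, element_id = "b",
                 couple_to = "a", couple_corr = -1))
  expect_error(genome_model(c(chr1 = 10000), elements = specs),
               "Frechet")
})

test_that("CpG methylation follows baselines and silencing overrides", {
  base_sites <- data.frame(chrom = "chr1", pos = seq(10000, 10400, 20),
                           baseline_h1 = 0, baseline_h2 = 0)
  m0 <- genome_model(c(chr1 = 50000), cpg_sites = base_sites,
                     unassigned_rate = 0)
  fs <- simulate_fibers(m0, 50, 1, seed = 8)
  calls <- simulate_cpg(m0, fs, seed = 9)
  expect_gt(nrow(calls), 0)
  expect_false(any(calls$methylated))

  base_sites$baseline_h1 <- 1
  base_sites$baseline_h2 <- 1
  m1 <- genome_model(c(chr1 = 50000), cpg_sites = base_sites,
                     unassigned_rate = 0)
  fs <- simulate_fibers(m1, 50, 1, seed = 8)
  expect_true(all(simulate_cpg(m1, fs, seed = 9)$methylated))

  # baseline 0.2 vs silenced 0.9 at fraction 1 on H2, ~1000 calls/hap
  sites <- data.frame(chrom = "chr1", pos = seq(10000, 10380, 20),
                      baseline_h1 = 0.2, baseline_h2 = 0.2)
  m2 <- genome_model(
    c(chr1 = 50000), cpg_sites = sites, unassigned_rate = 0,
    silencing = silencing_spec("chr1", 9000, 11000, "H2", 1.0,
                               silenced_methylation = 0.9))
  fs <- simulate_fibers(m2, 50, 1, seed = 10)
  calls <- simulate_cpg(m2, fs, seed = 11)
  h1 <- calls$methylated[calls$haplotype == "H1"]
  h2 <- calls$methylated[calls$haplotype == "H2"]
  expect_gte(length(h1), 900)
  expect_lt(abs(mean(h1) - 0.2), 0.05)
  expect_lt(abs(mean(h2) - 0.9), 0.05)
})

test_that("transcript counts follow per-haplotype Poisson means and silencing", {
  genes <- data.frame(gene_id = c("bal", "mono"),
                      mean_h1 = c(10, 10), mean_h2 = c(10, 0))
  m <- genome_model(c(chr1 = 10000), genes = genes, unassigned_rate = 0)
  reads <- simulate_transcripts(m, 200, seed = 21)
  counts <- gene_haplotype_counts(reads)
  bal <- counts[counts$gene_id == "bal", ]
  # Poisson(2000) each side: ratio within ~3 sd of 1
  expect_lt(abs(bal$n_h1 / bal$n_h2 - 1), 0.15)
  mono <- counts[counts$gene_id == "mono", ]
  expect_equal(mono$n_h2, 0L)
  expect_gt(mono$n_h1, 0L)

  sil_genes <- data.frame(gene_id = "g", mean_h1 = 10, mean_h2 = 10,
                          chrom = "chr1", start = 1000, end = 2000)
  ms <- genome_model(
    c(chr1 = 10000), genes = sil_genes, unassigned_rate = 0,
    silencing = silencing_spec("chr1", 0, 5000, "H2", 1.0))
  counts <- gene_haplotype_counts(simulate_transcripts(ms, 50, seed = 3))
  expect_equal(counts$n_h2, 0L)
  expect_error(genome_model(c(chr1 = 1000),
                            genes = data.frame(gene_id = "g",
                                               mean_h1 = -1, mean_h2 = 1)),
               ">= 0")
})

test_that("simulated fibers span their loci and satisfy the fiber-set invariants", {
  m <- tiled_model(5, 0.5, 0.5, spacing = 30000)
  fs <- simulate_fibers(m, 40, 1, seed = 17)
  expect_s3_class(fs, "fiber_set")  # constructor validated the invariants
  el <- m$elements
  ov <- with(fs$fibers, outer(start, el$start, `<=`) &
               outer(end, el$end, `>=`))
  # every fiber spans at least one element end-to-end
  expect_true(all(rowSums(ov) >= 1))
  # fiber lengths truncated at >= 1 kb and within the chromosome
  expect_true(all(fs$fibers$end - fs$fibers$start >= 1000))
  expect_true(all(fs$fibers$start >= 0 &
                    fs$fibers$end <= m$chrom_sizes["chr1"]))
})
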