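peak_at <- function(start, end, chrom = "chrA") {
  list(chrom = chrom, start = start, end = end)
}

test_that("spanning_fibers keeps exactly the fibers containing both peaks", {
  fs <- toy_fiber_set(
    starts = c(0, 0, 4000, 0), ends = c(10000, 3000, 12000, 5000),
    haps = c("H1", "H2", "H1", "H2"))
  a <- peak_at(1000, 1200)
  b <- peak_at(4500, 4700)
  sp <- spanning_fibers(fs, a, b)
  expect_equal(sp$fibers$fiber_id, c("f001", "f004"))
  # peaks 100 kb apart with short fibers: nothing spans
  expect_equal(n_fibers(spanning_fibers(fs, a, peak_at(101000, 101200))),
               0L)
  expect_error(spanning_fibers(fs, a, peak_at(100, 200, chrom = "chrB")),
               "different chromosomes")

  # brute-force containment check on a random instance
  rfs <- random_fiber_set(80, seed = 23, chroms = "chrA")
  a <- peak_at(20000, 20200)
  b <- peak_at(24000, 24200)
  got <- sort(spanning_fibers(rfs, a, b)$fibers$fiber_id)
  want <- with(rfs$fibers,
               fiber_id[start <= 20000 & end >= 20200 &
                          start <= 24000 & end >= 24200])
  expect_equal(got, sort(want))
})

test_that("co-dependency score is observed minus expected co-accessibility", {
  a <- peak_at(1000, 1200)
  b <- peak_at(3000, 3200)
  both_open <- toy_fiber_set(
    starts = rep(0, 12), ends = rep(5000, 12),
    haps = rep(c("H1", "H2"), 6),
    msp_list = replicate(12, data.frame(start = c(1000, 3000),
                                        end = c(1200, 3200),
                                        precision = 0.97),
                         simplify = FALSE))
  res <- codependency_score(both_open, a, b)
  expect_equal(res$observed, 1)
  expect_equal(res$expected, 1)
  expect_equal(res$score, 0)
  expect_false(res$insufficient)

  # half open at A only, half at B only: observed 0, expected 0.25
  half <- toy_fiber_set(
    starts = rep(0, 20), ends = rep(5000, 20),
    haps = rep(c("H1", "H2"), 10),
    msp_list = c(replicate(10, data.frame(start = 1000, end = 1200,
                                          precision = 0.97),
                           simplify = FALSE),
                 replicate(10, data.frame(start = 3000, end = 3200,
                                          precision = 0.97),
                           simplify = FALSE)))
  res <- codependency_score(half, a, b)
  expect_equal(res$score, -0.25)

  # symmetry up to label swap
  swapped <- codependency_score(half, b, a)
  expect_equal(swapped$score, res$score)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(swapped$prop_a, res$prop_b)

  # brute-force per-fiber tally agreement on a random instance
  m <- coupled_cluster_model(corr = 0.5, n_candidates = 1, coupled_at = 1)
  fs <- simulate_fibers(m, 100, 1, seed = 5)
  pa <- peak_at(50000, 50200, "chr1")
  pb <- peak_at(51000, 51200, "chr1")
  res <- codependency_score(fs, pa, pb)
  sp <- spanning_fibers(fs, pa, pb)
  oa <- classify_fiber_at_peak(sp, pa, 0.95) == "ACCESSIBLE"
  ob <- classify_fiber_at_peak(sp, pb, 0.95) == "ACCESSIBLE"
  expect_equal(res$observed, mean(oa & ob))
  expect_equal(res$expected, mean(oa) * mean(ob))
  expect_equal(res$n_span, length(oa))

  expect_error(codependency_score(half, a, b, min_precision = 1.5),
               "min_precision")
})

test_that("sparse spanning coverage is flagged insufficient", {
  a <- peak_at(1000, 1200)
  b <- peak_at(3000, 3200)
  few <- toy_fiber_set(starts = rep(0, 3), ends = rep(5000, 3),
                       haps = c("H1", "H2", "H1"))
  res <- codependency_score(few, a, b, min_span = 10)
  expect_true(res$insufficient)
  expect_true(is.na(res$p_value))
  expect_equal(res$n_span, 3L)
})

test_that("the scan scores each candidate and rejects a self-anchor", {
  m <- coupled_cluster_model(corr = 0.8)
  fs <- simulate_fibers(m, 60, 1, seed = 41)
  anchor <- list(chrom = "chr1", start = 50000, end = 50200,
                 peak_id = "anchor")
  cands <- element_peaks(m)
  cands <- cands[cands$peak_id != "anchor", ]
  res <- codependency_scan(fs, anchor, cands)
  expect_equal(nrow(res), 8L)
  expect_equal(res$peak_b, cands$peak_id)
  expect_true(all(!is.na(res$q_value)))

  expect_equal(nrow(codependency_scan(fs, anchor, cands[0, ])), 0L)
  expect_error(codependency_scan(fs, anchor, element_peaks(m)),
               "anchor peak appears")

  # candidates beyond any fiber span are all insufficient
  far <- tibble::tibble(chrom = "chr1", start = 150000, end = 150200,
                        peak_id = "far")
  res_far <- codependency_scan(fs, anchor, far)
  expect_true(all(res_far$insufficient))
})
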