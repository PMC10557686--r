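test_that("aggregate signal matches the phred-scaled closed form", {
  fs <- toy_fiber_set(
    starts = c(0, 0, 0), ends = c(2000, 2000, 2000),
    haps = c("H1", "H2", "H1"),
    msp_list = list(data.frame(start = 100, end = 200, precision = 0.9),
                    data.frame(start = 150, end = 250, precision = 0.9),
                    NULL))
  tr <- aggregate_fire_signal(fs, "chrA", 0, 300)
  expect_equal(tr$values[120 + 1], 10)             # one p = 0.9 MSP
  expect_equal(tr$values[175 + 1], 20)             # two stacked
  expect_equal(tr$values[260 + 1], 0)              # covered, no MSP

  fs2 <- toy_fiber_set(
    starts = c(0, 0), ends = c(1000, 1000), haps = c("H1", "H2"),
    msp_list = list(data.frame(start = 10, end = 20, precision = 0.5),
                    data.frame(start = 10, end = 20, precision = 0.99)))
  tr2 <- aggregate_fire_signal(fs2, "chrA", 0, 30)
  expect_equal(tr2$values[15 + 1], -10 * (log10(0.5) + log10(0.01)),
               tolerance = 1e-12)

  # p = 1 stays finite via the 1e-10 clamp
  fs3 <- toy_fiber_set(starts = 0, ends = 100, haps = "H1",
                       msp_list = list(data.frame(start = 0, end = 50,
                                                  precision = 1)))
  expect_equal(aggregate_fire_signal(fs3, "chrA", 0, 10)$values[1], 100)
})

test_that("signal equals the per-base brute-force oracle on random instances", {
  for (seed in 1:20) {
    fs <- random_fiber_set(15, seed = seed, chroms = "chrA")
    lo <- min(fs$fibers$start)
    tr <- aggregate_fire_signal(fs, "chrA", lo, lo + 10000)
    expect_equal(tr$values, signal_by_base(fs, "chrA", lo, lo + 10000),
                 tolerance = 1e-10)
  }
})

test_that("signal is monotone in MSP count and precision", {
  fs <- random_fiber_set(10, seed = 3, chroms = "chrA")
  base <- aggregate_fire_signal(fs, "chrA", 0, 20000)$values
  # add an MSP to the first fiber with room for one
  fib <- fs$fibers[1, ]
  extra <- rbind(fs$msps,
                 data.frame(fiber_id = fib$fiber_id,
                            start = fib$end - 40, end = fib$end - 10,
                            precision = 0.7))
  more <- fiber_set(fs$fibers, extra)
  expect_true(all(aggregate_fire_signal(more, "chrA", 0, 20000)$values >=
                    base - 1e-12))
  # raise every precision
  up <- fs$msps
  up$precision <- pmin(1, up$precision + 0.2)
  expect_true(all(aggregate_fire_signal(fiber_set(fs$fibers, up),
                                        "chrA", 0, 20000)$values >=
                    base - 1e-12))
})

test_that("the Bonferroni score threshold follows -10 log10(alpha/G)", {
  expect_equal(peak_score_threshold(0.01, 1e4), 60)
  expect_equal(peak_score_threshold(0.01, 1), 20)
  expect_equal(peak_score_threshold(0.05, 3.1e9),
               -10 * log10(0.05 / 3.1e9), tolerance = 1e-12)
  expect_error(peak_score_threshold(0, 100), "alpha")
  expect_error(peak_score_threshold(1.2, 100), "alpha")
})

test_that("peak calling extracts maximal runs and honours merge_gap", {
  mk <- function(v) structure(list(chrom = "chrA", start = 0, values = v),
                              class = "signal_track")
  expect_equal(nrow(call_fire_peaks(mk(rep(0, 100)), 10)), 0L)

  v <- c(rep(0, 20), rep(15, 50), rep(0, 30))
  pk <- call_fire_peaks(mk(v), 10)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$end - pk$start, 50)
  expect_equal(pk$max_signal, 15)

  v2 <- c(rep(15, 5), 3, rep(15, 5))
  expect_equal(nrow(call_fire_peaks(mk(v2), 10, merge_gap = 0)), 2L)
  merged <- call_fire_peaks(mk(v2), 10, merge_gap = 1)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(0, 11))
})

test_that("called peaks agree with a run-length oracle on random tracks", {
  withr::with_seed(7, {
    for (i in 1:20) {
      v <- round(runif(500) * 30)
      thr <- runif(1, 5, 25)
      tr <- structure(list(chrom = "chrA", start = 0, values = v),
                      class = "signal_track")
      pk <- call_fire_peaks(tr, thr)
      truth <- runs_of(v >= thr)
      expect_equal(pk$start, truth$start)
      expect_equal(pk$end, truth$end)
      # threshold consistency: inside >= thr, flanking bases < thr
      for (j in seq_len(nrow(pk))) {
        expect_true(all(v[(pk$start[j] + 1):pk$end[j]] >= thr))
        if (pk$start[j] > 0) expect_lt(v[pk$start[j]], thr)
        if (pk$end[j] < length(v)) expect_lt(v[pk$end[j] + 1], thr)
      }
    }
  })
})
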