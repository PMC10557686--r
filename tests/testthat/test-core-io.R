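test_that("fiber table parsing handles empty files, empty MSP fields and triples", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tstart\tend\tfiber_id\thaplotype\tmsps", tf)
  fs <- read_fiber_table(tf)
  expect_s3_class(fs, "fiber_set")
  expect_equal(n_fibers(fs), 0L)

  writeLines(c("chrom\tstart\tend\tfiber_id\thaplotype\tmsps",
               "chrA\t0\t18000\tf1\tH1\t"), tf)
  fs <- read_fiber_table(tf)
  expect_equal(n_fibers(fs), 1L)
  expect_equal(nrow(fs$msps), 0L)

  writeLines(c("chrom\tstart\tend\tfiber_id\thaplotype\tmsps",
               "chrA\t0\t18000\tf1\tH1\t100-300:0.95,900-1100:0.10"), tf)
  fs <- read_fiber_table(tf)
  expect_equal(nrow(fs$msps), 2L)
  expect_equal(fs$msps$start, c(100, 900))
  expect_equal(fs$msps$end, c(300, 1100))
  expect_equal(fs$msps$precision, c(0.95, 0.10))
})

test_that("malformed fiber rows fail with the offending line named", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tfiber_id\thaplotype\tmsps",
               "chrA\t0\t18000\tf1\tH1\t100-300:0.95",
               "chrA\t0\t18000\tf2\tH1\tnot-an-msp"), tf)
  expect_error(read_fiber_table(tf), "line 2")

  writeLines(c("chrom\tstart\tend\tfiber_id\thaplotype\tmsps",
               "chrA\t0\t18000\tf1\tH1\t100-300:1.5"), tf)
  expect_error(read_fiber_table(tf), "precision")

  writeLines(c("chrom\tstart\tend\tfiber_id\thaplotype\tmsps",
               "chrA\t0\t1000\tf1\tH1\t900-1200:0.5"), tf)
  expect_error(read_fiber_table(tf), "outside fiber")
})

test_that("fiber/CpG/transcript tables round-trip through disk unchanged", {
  fs <- random_fiber_set(100, seed = 11)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fiber_table(fs, tf)
  back <- read_fiber_table(tf)
  expect_equal(back$fibers[names(fs$fibers)], fs$fibers,
               ignore_attr = TRUE)
  expect_equal(back$msps, fs$msps, ignore_attr = TRUE)

  # empty set -> header-only file
  write_fiber_table(fiber_set(fs$fibers[0, ]), tf)
  expect_length(readLines(tf), 1L)

  cpg <- tibble::tibble(chrom = "chrA", pos = c(10, 10, 30),
                        fiber_id = c("f1", "f2", "f1"),
                        haplotype = c("H1", "H2", "UNASSIGNED"),
                        methylated = c(TRUE, FALSE, TRUE))
  write_cpg_table(cpg, tf)
  expect_equal(read_cpg_table(tf), cpg, ignore_attr = TRUE)

  reads <- tibble::tibble(read_id = sprintf("r%d", 1:5),
                          gene_id = c("g1", "g1", "g2", "g2", "g2"),
                          haplotype = c("H1", "H2", "H1", "UNASSIGNED",
                                        "H2"))
  write_transcript_table(reads, tf)
  expect_equal(read_transcript_table(tf), reads, ignore_attr = TRUE)
})

test_that("BED round-trips and rejects inverted intervals", {
  peaks <- tibble::tibble(chrom = c("chrA", "chrA", "chrB"),
                          start = c(10, 500, 0),
                          end = c(60, 900, 100),
                          peak_id = c("p1", "p2", "p3"),
                          max_signal = c(12.5, 60, 0))
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(peaks, tf)
  line1 <- readLines(tf)[1]
  expect_match(line1, "^chrA\t10\t60\tp1")
  back <- read_bed(tf)
  expect_equal(back, peaks, ignore_attr = TRUE)

  expect_error(write_bed(tibble::tibble(chrom = "chrA", start = 60,
                                        end = 10, peak_id = "bad"), tf),
               "start >= end")
})

test_that("bedGraph output run-length encodes and omits zero runs", {
  tf <- withr::local_tempfile(fileext = ".bedGraph")
  # values [0,0,5,5,3] at positions 0..4 -> rows 2-4:5 and 4-5:3
  tr <- structure(list(chrom = "chrA", start = 0,
                       values = c(0, 0, 5, 5, 3)),
                  class = "signal_track")
  write_bedgraph(tr, tf)
  body <- grep("^chrA", readLines(tf), value = TRUE)
  expect_equal(body, c("chrA\t2\t4\t5", "chrA\t4\t5\t3"))

  tr$values <- rep(0, 5)
  write_bedgraph(tr, tf)
  expect_length(grep("^chrA", readLines(tf)), 0L)
})

test_that("the shared overlap predicates agree with set intersection on random intervals", {
  withr::with_seed(5, {
    for (i in 1:200) {
      s1 <- sample.int(50, 1); e1 <- s1 + sample.int(20, 1)
      s2 <- sample.int(50, 1); e2 <- s2 + sample.int(20, 1)
      truth <- length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1))) > 0
      expect_identical(interval_overlaps(s1, e1, s2, e2), truth)
      expect_identical(interval_contains(s1, e1, s2, e2),
                       all(seq(s2, e2 - 1) %in% seq(s1, e1 - 1)))
    }
  })
})

test_that("fiber_set validation enforces the MSP invariants", {
  fib <- data.frame(chrom = "chrA", start = 0, end = 1000,
                    fiber_id = "f1", haplotype = "H1")
  expect_error(fiber_set(fib, data.frame(fiber_id = "f1", start = 10,
                                         end = 5, precision = 0.5)),
               "start >= end")
  expect_error(fiber_set(fib, data.frame(fiber_id = "f1",
                                         start = c(10, 50),
                                         end = c(60, 90),
                                         precision = c(0.5, 0.5))),
               "overlap")
  expect_error(fiber_set(fib, data.frame(fiber_id = "f2", start = 10,
                                         end = 20, precision = 0.5)),
               "unknown fiber_id")
  expect_error(fiber_set(rbind(fib, fib)), "unique")
})
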