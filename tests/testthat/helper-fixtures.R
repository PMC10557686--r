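# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk.

# Minimal fiber set: one haplotyped fiber per row of `spec`, with MSPs
# given as list entries of data.frames (start, end, precision).
toy_fiber_set <- function(chrom = "chrA", starts, ends, haps,
                          msp_list = NULL) {
  n <- length(starts)
  fib <- data.frame(chrom = chrom, start = starts, end = ends,
                    fiber_id = sprintf("f%03d", seq_len(n)),
                    haplotype = haps)
  msps <- NULL
  if (!is.null(msp_list)) {
    pieces <- lapply(seq_len(n), function(i) {
      m <- msp_list[[i]]
      if (is.null(m) || nrow(m) == 0) return(NULL)
      cbind(fiber_id = fib$fiber_id[i], m)
    })
    msps <- do.call(rbind, pieces)
  }
  fiber_set(fib, msps)
}

# Random but valid fiber set for round-trip / oracle tests.
random_fiber_set <- function(n_fibers, seed, chroms = c("chrA", "chrB")) {
  withr::with_seed(seed, {
    chrom <- sample(chroms, n_fibers, replace = TRUE)
    start <- sample.int(50000, n_fibers)
    len <- sample(2000:20000, n_fibers, replace = TRUE)
    fib <- data.frame(chrom = chrom, start = start, end = start + len,
                      fiber_id = sprintf("rf%04d", seq_len(n_fibers)),
                      haplotype = sample(c("H1", "H2", "UNASSIGNED"),
                                         n_fibers, replace = TRUE,
                                         prob = c(0.45, 0.45, 0.1)))
    pieces <- lapply(seq_len(n_fibers), function(i) {
      k <- sample(0:4, 1)
      if (k == 0) return(NULL)
      w <- sample(50:300, k, replace = TRUE)
      gap <- sample(100:800, k, replace = TRUE)
      s <- fib$start[i] + cumsum(gap + w) - w
      keep <- s + w <= fib$end[i]
      if (!any(keep)) return(NULL)
      data.frame(fiber_id = fib$fiber_id[i], start = s[keep],
                 end = (s + w)[keep],
                 precision = round(runif(sum(keep)), 6))
    })
    fiber_set(fib, do.call(rbind, pieces))
  })
}

# One chromosome tiled with identical, well-separated elements --
# the workhorse for peak-scale recovery scenarios. Elements are spaced
# far enough apart that each is its own locus.
tiled_model <- function(n_elements, actuation_h1, actuation_h2,
                        chrom = "chr1", spacing = 20000, width = 200,
                        start0 = 10000, silencing = NULL, ...) {
  starts <- start0 + (seq_len(n_elements) - 1) * spacing
  el <- element_spec(chrom, starts[1], starts[1] + width,
                     actuation_h1, actuation_h2,
                     element_id = "e0001")[0, ]
  el <- dplyr::bind_rows(lapply(seq_len(n_elements), function(i) {
    element_spec(chrom, starts[i], starts[i] + width, actuation_h1,
                 actuation_h2, element_id = sprintf("e%04d", i))
  }))
  size <- max(starts) + width + 50000
  genome_model(setNames(size, chrom), elements = el,
               silencing = silencing, ...)
}

# Peak table matching a model's elements (the truth intervals).
element_peaks <- function(model) {
  tibble::tibble(chrom = model$elements$chrom,
                 start = model$elements$start,
                 end = model$elements$end,
                 peak_id = model$elements$element_id)
}

# Cluster of candidate elements around an anchor, one of them coupled to
# it, all within a single locus so fibers span everything.
coupled_cluster_model <- function(corr = 0.8, n_candidates = 8,
                                  coupled_at = 4, actuation = 0.5) {
  starts <- 50000 + (0:(n_candidates)) * 1000
  specs <- list(element_spec("chr1", starts[1], starts[1] + 200,
                             actuation, actuation,
                             element_id = "anchor"))
  for (i in seq_len(n_candidates)) {
    specs[[i + 1]] <- element_spec(
      "chr1", starts[i + 1], starts[i + 1] + 200, actuation, actuation,
      element_id = sprintf("cand%02d", i),
      couple_to = if (i == coupled_at) "anchor" else NA_character_,
      couple_corr = if (i == coupled_at) corr else 0)
  }
  genome_model(c(chr1 = 200000), elements = specs,
               locus_merge_gap = 5000)
}
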