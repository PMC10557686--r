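#' Per-peak haplotype accessibility deltas
#'
#' Converts haplotype counts into the signed per-peak difference in
#' percent accessibility, `delta = pct_h1 - pct_h2`, together with the
#' summed phased coverage used by [coverage_filter()]. Peaks lacking
#' spanning fibers on either haplotype are dropped.
#'
#' @param counts Tibble from [peak_haplotype_counts()].
#' @return Tibble with `peak_id`, `delta` (percentage points), `pct_h1`,
#'   `pct_h2`, `coverage`.
#' @export
peak_deltas <- function(counts) {
  keep <- counts$total_h1 > 0 & counts$total_h2 > 0
  counts <- counts[keep, , drop = FALSE]
  pct_h1 <- 100 * counts$acc_h1 / counts$total_h1
  pct_h2 <- 100 * counts$acc_h2 / counts$total_h2
  tibble::tibble(peak_id = counts$peak_id, delta = pct_h1 - pct_h2,
                 pct_h1 = pct_h1, pct_h2 = pct_h2,
                 coverage = counts$total_h1 + counts$total_h2)
}

#' Exclude low-coverage peaks
#'
#' Removes peaks whose phased coverage falls below
#' `max(min_reads, median(coverage) - sd_mult * sd(coverage))` — the
#' screen for mapping, assembly and phasing artifacts. The median and
#' standard deviation are computed once, on the full input set, before
#' any peak is removed (so reapplying the filter to its own output can
#' only shrink the cutoff, never move it up).
#'
#' @param deltas Tibble with a `coverage` column (e.g. [peak_deltas()]).
#' @param min_reads Absolute minimum coverage (default 10 reads).
#' @param sd_mult Standard-deviation multiplier (default 3).
#' @return The filtered tibble.
#' @export
coverage_filter <- function(deltas, min_reads = 10, sd_mult = 3) {
  if (nrow(deltas) == 0L) return(deltas)
  s <- sd(deltas$coverage)
  cutoff <- max(min_reads,
                median(deltas$coverage) - if (is.na(s)) Inf else sd_mult * s)
  deltas[deltas$coverage >= cutoff, , drop = FALSE]
}

#' Mann-Whitney U test for regional imbalance
#'
#' Compares the signed per-peak delta distribution of a region against
#' the background (rest of the genome) with a two-sided Mann-Whitney U
#' test: exact enumeration for small tie-free samples (both sides
#' <= 20), the tie-corrected normal approximation otherwise.
#'
#' @param region_deltas,background_deltas Numeric vectors of signed
#'   per-peak deltas (percentage points).
#' @return List with `u_statistic` (U for the region sample) and
#'   `p_value`.
#' @export
region_imbalance_test <- function(region_deltas, background_deltas) {
  if (length(region_deltas) == 0L || length(background_deltas) == 0L) {
    stop("region and background delta sets must both be non-empty",
         call. = FALSE)
  }
  exact <- length(region_deltas) <= 20 && length(background_deltas) <= 20 &&
    !any(duplicated(c(region_deltas, background_deltas)))
  wt <- suppressWarnings(
    wilcox.test(region_deltas, background_deltas, exact = exact,
                correct = !exact))
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Estimate the silenced-cell fraction from regional counts
#'
#' If the region's `direction` haplotype is epigenetically silenced (with
#' no residual accessibility) in a fraction `f` of cells, its
#' accessible-fiber proportion at every peak is scaled by `1 - f` relative
#' to the active haplotype. The estimator inverts that relation per peak —
#' relative actuation loss `r_i = (pct_active - pct_silenced)/pct_active`
#' wherever `pct_active > 0` — and returns the median over peaks, clipped
#' to \[0, 1\], for robustness to per-peak sampling noise.
#'
#' @param region_counts [peak_haplotype_counts()] rows for peaks in the
#'   region (after coverage filtering).
#' @param direction `"H1"` or `"H2"`: the putatively silenced haplotype;
#'   `"auto"` infers it from the sign of the median delta.
#' @return Estimated silenced-cell fraction in \[0, 1\].
#' @export
estimate_silenced_fraction <- function(region_counts,
                                       direction = c("auto", "H1", "H2")) {
  direction <- match.arg(direction)
  d <- peak_deltas(region_counts)
  if (nrow(d) == 0L) {
    stop("no peaks with phased coverage on both haplotypes", call. = FALSE)
  }
  if (direction == "auto") {
    direction <- if (median(d$delta) >= 0) "H2" else "H1"
  }
  if (direction == "H2") {
    active <- d$pct_h1; silenced <- d$pct_h2
  } else {
    active <- d$pct_h2; silenced <- d$pct_h1
  }
  ok <- active > 0
  if (!any(ok)) {
    stop("silenced-fraction estimator undefined: active haplotype has no ",
         "accessibility at any peak", call. = FALSE)
  }
  r <- (active[ok] - silenced[ok]) / active[ok]
  min(1, max(0, median(r)))
}

#' Region-scale allelic-imbalance report
#'
#' The genome-wide screen for chromosome- or region-scale haplotype
#' imbalance (XCI skewing and XCI spreading into translocated autosomal
#' DNA): per-peak signed deltas are computed once, coverage-filtered once
#' over the full peak set, and each named region is compared against the
#' background — all filtered peaks outside every named region and outside
#' `exclude_chroms` — with the Mann-Whitney test. Each region also gets a
#' silenced-cell fraction estimate.
#'
#' @param fibers A [fiber_set].
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `peak_id`).
#' @param regions Tibble of named regions: `chrom`, `start`, `end`,
#'   `name`.
#' @param min_precision Accessible-patch cutoff (0.90 by convention for
#'   this analysis).
#' @param min_reads,sd_mult Passed to [coverage_filter()].
#' @param exclude_chroms Chromosomes excluded from the background.
#' @return List with `results` (one row per region: `name`, `n_peaks_region`,
#'   `n_peaks_background`, `u_statistic`, `p_value`,
#'   `median_delta_region`, `silenced_fraction_estimate`, `flagged`) and
#'   `peak_deltas` (the filtered per-peak delta table with region labels,
#'   ready for a swarm plot).
#' @export
genome_imbalance_report <- function(fibers, peaks, regions,
                                    min_precision = 0.9, min_reads = 10,
                                    sd_mult = 3,
                                    exclude_chroms = character()) {
  counts <- peak_haplotype_counts(fibers, peaks, min_precision)
  d <- peak_deltas(counts)
  d <- coverage_filter(d, min_reads, sd_mult)
  pidx <- match(d$peak_id, peaks$peak_id)
  d$chrom <- peaks$chrom[pidx]
  d$start <- peaks$start[pidx]
  d$end <- peaks$end[pidx]
  d$region <- NA_character_
  if (nrow(regions)) {
    ov <- overlap_join(d$chrom, d$start, d$end,
                       regions$chrom, regions$start, regions$end)
    d$region[ov$q] <- regions$name[ov$s]
  }
  bg <- is.na(d$region) & !d$chrom %in% exclude_chroms
  d$region[bg & is.na(d$region)] <- "background"
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    in_reg <- which(!is.na(d$region) & d$region == regions$name[i])
    base <- tibble::tibble(
      name = regions$name[i], n_peaks_region = length(in_reg),
      n_peaks_background = sum(bg), u_statistic = NA_real_,
      p_value = NA_real_, median_delta_region = NA_real_,
      silenced_fraction_estimate = NA_real_, flagged = TRUE)
    if (length(in_reg) == 0L || sum(bg) == 0L) return(base)
    test <- region_imbalance_test(d$delta[in_reg], d$delta[bg])
    base$u_statistic <- test$u_statistic
    base$p_value <- test$p_value
    base$median_delta_region <- median(d$delta[in_reg])
    fhat <- tryCatch(
      estimate_silenced_fraction(
        counts[match(d$peak_id[in_reg], counts$peak_id), ]),
      error = function(e) NA_real_)
    base$silenced_fraction_estimate <- fhat
    base$flagged <- FALSE
    base
  })
  list(results = dplyr::bind_rows(rows), peak_deltas = d)
}
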