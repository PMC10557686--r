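#' Classify fibers at a peak
#'
#' A fiber is informative for a peak only if it fully contains the peak
#' interval (`NOT_SPANNING` otherwise) — a partially overlapping molecule
#' cannot distinguish closed chromatin from truncation. A spanning fiber
#' is `ACCESSIBLE` iff at least one of its MSPs with precision
#' `>= min_precision` overlaps the peak by at least one base, else
#' `INACCESSIBLE`.
#'
#' @param fibers A [fiber_set].
#' @param peak One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param min_precision FIRE precision cutoff defining an accessible
#'   patch. The reference conventions are 0.90 for haplotype/imbalance
#'   analyses and 0.95 for co-dependency.
#' @return Character vector (one per fiber, named by `fiber_id`) with
#'   values `"ACCESSIBLE"`, `"INACCESSIBLE"` or `"NOT_SPANNING"`.
#' @export
classify_fiber_at_peak <- function(fibers, peak, min_precision = 0.9) {
  fibers <- as_fiber_set(fibers)
  stopifnot(min_precision >= 0, min_precision <= 1)
  fib <- fibers$fibers
  spans <- fib$chrom == peak$chrom &
    interval_contains(fib$start, fib$end, peak$start, peak$end)
  msps <- fibers$msps
  hit <- msps$precision >= min_precision &
    interval_overlaps(msps$start, msps$end, peak$start, peak$end)
  open_ids <- unique(msps$fiber_id[hit])
  open_on_chrom <- fib$fiber_id %in% open_ids
  out <- ifelse(!spans, "NOT_SPANNING",
                ifelse(open_on_chrom, "ACCESSIBLE", "INACCESSIBLE"))
  setNames(out, fib$fiber_id)
}

#' Per-peak accessible/total fiber counts by haplotype
#'
#' For every peak, counts spanning fibers and accessible spanning fibers
#' (per [classify_fiber_at_peak()]) separately for haplotypes H1 and H2;
#' `UNASSIGNED` fibers are excluded. This table is the unit of every
#' haplotype test in the package.
#'
#' @param fibers A [fiber_set].
#' @param peaks Tibble with `chrom`, `start`, `end`, `peak_id` (unique).
#' @param min_precision Accessible-patch precision cutoff.
#' @return Tibble with `peak_id`, `acc_h1`, `total_h1`, `acc_h2`,
#'   `total_h2`, one row per peak (zero counts when nothing spans).
#' @export
peak_haplotype_counts <- function(fibers, peaks, min_precision = 0.9) {
  fibers <- as_fiber_set(fibers)
  if (anyDuplicated(peaks$peak_id)) {
    stop("duplicate peak_id", call. = FALSE)
  }
  fib <- fibers$fibers
  phased <- fib$haplotype %in% c("H1", "H2")
  # spanning (peak within fiber) pairs, phased fibers only
  sp <- overlap_join(peaks$chrom, peaks$start, peaks$end,
                     fib$chrom[phased], fib$start[phased], fib$end[phased],
                     type = "within")
  fib_idx <- which(phased)[sp$s]
  # accessible: high-precision MSP of that fiber overlapping that peak
  msps <- fibers$msps
  # per-chromosome join between peaks and high-precision MSPs
  midx <- which(msps$precision >= min_precision)
  mchrom <- fib$chrom[match(msps$fiber_id[midx], fib$fiber_id)]
  mo <- overlap_join(peaks$chrom, peaks$start, peaks$end,
                     mchrom, msps$start[midx], msps$end[midx])
  open_key <- unique(paste0(mo$q, "|", msps$fiber_id[midx[mo$s]]))
  span_key <- paste0(sp$q, "|", fib$fiber_id[fib_idx])
  acc <- span_key %in% open_key
  hap <- fib$haplotype[fib_idx]
  tally <- function(mask) {
    t <- table(factor(sp$q[mask], seq_len(nrow(peaks))))
    as.integer(t)
  }
  tibble::tibble(
    peak_id = peaks$peak_id,
    acc_h1 = tally(hap == "H1" & acc),
    total_h1 = tally(hap == "H1"),
    acc_h2 = tally(hap == "H2" & acc),
    total_h2 = tally(hap == "H2"))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: with both margins
#' fixed, sum the hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7, matching the convention of standard
#' statistical libraries). The odds ratio is the sample estimate
#' `(a d)/(b c)`, reported as `Inf` when only `b c` is zero and `NaN`
#' when the table is degenerate.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as
#'   `rbind(c(a, b), c(c, d))` — e.g. rows = haplotypes, columns =
#'   accessible/inaccessible.
#' @return List with `p_value` and `odds_ratio`.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)$p_value  # 2/252
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0) return(list(p_value = 1, odds_ratio = NaN))
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p_value = p, odds_ratio = or)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (order-preserving, capped at 1).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Haplotype-specific accessibility tests across peaks
#'
#' For every peak with spanning phased fibers on both haplotypes, compares
#' accessible-fiber proportions between H1 and H2 with Fisher's exact test
#' and applies BH correction across the peak set — the genome-wide volcano
#' analysis. Peaks with zero spanning fibers on either haplotype carry no
#' information about imbalance and are dropped (a message reports how
#' many).
#'
#' @param counts Tibble from [peak_haplotype_counts()].
#' @param fdr_level BH significance level for `fdr_sig`.
#' @param nominal_p Nominal significance line for `nominal_sig`.
#' @return Tibble with `peak_id`, `pct_h1`, `pct_h2`, `abs_delta`
#'   (percentage points), `odds_ratio`, `p_value`, `q_value`,
#'   `nominal_sig`, `fdr_sig`.
#' @export
haplotype_specific_accessibility <- function(counts, fdr_level = 0.05,
                                             nominal_p = 0.01) {
  stopifnot(all(counts$acc_h1 <= counts$total_h1),
            all(counts$acc_h2 <= counts$total_h2))
  drop <- counts$total_h1 == 0 | counts$total_h2 == 0
  if (any(drop)) {
    message(sum(drop), " peak(s) dropped: no spanning phased fibers on ",
            "one haplotype")
  }
  counts <- counts[!drop, , drop = FALSE]
  if (!nrow(counts)) {
    return(tibble::tibble(peak_id = character(), pct_h1 = numeric(),
                          pct_h2 = numeric(), abs_delta = numeric(),
                          odds_ratio = numeric(), p_value = numeric(),
                          q_value = numeric(), nominal_sig = logical(),
                          fdr_sig = logical()))
  }
  tests <- mapply(function(a, ta, c, tc) {
    fisher_exact_2x2(a, ta - a, c, tc - c)
  }, counts$acc_h1, counts$total_h1, counts$acc_h2, counts$total_h2,
  SIMPLIFY = FALSE)
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  q <- bh_fdr(p)
  pct_h1 <- 100 * counts$acc_h1 / counts$total_h1
  pct_h2 <- 100 * counts$acc_h2 / counts$total_h2
  tibble::tibble(
    peak_id = counts$peak_id, pct_h1 = pct_h1, pct_h2 = pct_h2,
    abs_delta = abs(pct_h1 - pct_h2),
    odds_ratio = vapply(tests, `[[`, numeric(1), "odds_ratio"),
    p_value = p, q_value = q,
    nominal_sig = p < nominal_p, fdr_sig = q <= fdr_level)
}
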