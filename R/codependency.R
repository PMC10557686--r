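#' Fibers spanning two peaks
#'
#' Single-molecule co-accessibility is only defined on molecules that
#' fully contain both element intervals; peaks on different chromosomes
#' can never share a fiber and raise an error.
#'
#' @param fibers A [fiber_set].
#' @param peak_a,peak_b One-row data frames (or lists) with `chrom`,
#'   `start`, `end`.
#' @return A [fiber_set] restricted to fibers containing both peaks.
#' @export
spanning_fibers <- function(fibers, peak_a, peak_b) {
  fibers <- as_fiber_set(fibers)
  if (peak_a$chrom != peak_b$chrom) {
    stop("peaks lie on different chromosomes; no fiber can span both",
         call. = FALSE)
  }
  fib <- fibers$fibers
  keep <- fib$chrom == peak_a$chrom &
    interval_contains(fib$start, fib$end, peak_a$start, peak_a$end) &
    interval_contains(fib$start, fib$end, peak_b$start, peak_b$end)
  subset_fibers(fibers, fib$fiber_id[keep])
}

#' Single-molecule co-dependency between two peaks
#'
#' Among fibers spanning both peaks, the co-dependency score is the
#' observed rate of joint accessibility minus the rate expected under
#' independence (the product of the two accessible proportions):
#' `score = P(A and B) - P(A) P(B)`. Significance comes from Fisher's
#' exact test on the 2x2 (both / A-only / B-only / neither) table.
#' Marginal proportions default to the jointly spanning denominator
#' (`marginals = "joint"`), under which `observed <= min(prop_a, prop_b)`
#' holds exactly and the Fisher table is self-consistent; `"per-peak"`
#' computes each marginal among fibers spanning that peak alone.
#'
#' @param fibers A [fiber_set].
#' @param peak_a,peak_b One-row peak data frames (`chrom`, `start`,
#'   `end`, optionally `peak_id`).
#' @param min_precision Accessible-patch precision cutoff (0.95 for this
#'   analysis by convention, i.e. 1 - precision <= 0.05).
#' @param min_span Minimum number of jointly spanning fibers; below it the
#'   result is flagged `insufficient` and no p-value is reported.
#' @param marginals `"joint"` or `"per-peak"` (see above).
#' @return One-row tibble: `peak_a`, `peak_b`, `n_span`, `prop_a`,
#'   `prop_b`, `observed`, `expected`, `score`, `p_value`,
#'   `insufficient`.
#' @export
codependency_score <- function(fibers, peak_a, peak_b,
                               min_precision = 0.95, min_span = 10,
                               marginals = c("joint", "per-peak")) {
  marginals <- match.arg(marginals)
  if (min_precision < 0 || min_precision > 1) {
    stop("min_precision must lie in [0, 1]", call. = FALSE)
  }
  fibers <- as_fiber_set(fibers)
  span <- spanning_fibers(fibers, peak_a, peak_b)
  n_span <- n_fibers(span)
  id_a <- if (!is.null(peak_a$peak_id)) peak_a$peak_id else
    sprintf("%s:%d-%d", peak_a$chrom, peak_a$start, peak_a$end)
  id_b <- if (!is.null(peak_b$peak_id)) peak_b$peak_id else
    sprintf("%s:%d-%d", peak_b$chrom, peak_b$start, peak_b$end)
  acc_a <- classify_fiber_at_peak(span, peak_a, min_precision) ==
    "ACCESSIBLE"
  acc_b <- classify_fiber_at_peak(span, peak_b, min_precision) ==
    "ACCESSIBLE"
  insufficient <- n_span < min_span
  if (n_span == 0) {
    return(tibble::tibble(peak_a = id_a, peak_b = id_b, n_span = 0L,
                          prop_a = NA_real_, prop_b = NA_real_,
                          observed = NA_real_, expected = NA_real_,
                          score = NA_real_, p_value = NA_real_,
                          insufficient = TRUE))
  }
  if (marginals == "joint") {
    prop_a <- mean(acc_a)
    prop_b <- mean(acc_b)
  } else {
    cls_a <- classify_fiber_at_peak(fibers, peak_a, min_precision)
    cls_b <- classify_fiber_at_peak(fibers, peak_b, min_precision)
    prop_a <- mean(cls_a[cls_a != "NOT_SPANNING"] == "ACCESSIBLE")
    prop_b <- mean(cls_b[cls_b != "NOT_SPANNING"] == "ACCESSIBLE")
  }
  observed <- mean(acc_a & acc_b)
  expected <- prop_a * prop_b
  p <- if (insufficient) NA_real_ else {
    fisher_exact_2x2(sum(acc_a & acc_b), sum(acc_a & !acc_b),
                     sum(!acc_a & acc_b), sum(!acc_a & !acc_b))$p_value
  }
  tibble::tibble(peak_a = id_a, peak_b = id_b, n_span = n_span,
                 prop_a = prop_a, prop_b = prop_b, observed = observed,
                 expected = expected, score = observed - expected,
                 p_value = p, insufficient = insufficient)
}

#' Scan candidate peaks for co-dependency with an anchor
#'
#' Scores every candidate against the anchor (e.g. every neighbouring
#' accessibility peak against a promoter) and attaches BH q-values across
#' the candidates with a reported p-value.
#'
#' @param fibers A [fiber_set].
#' @param anchor_peak One-row peak data frame.
#' @param candidate_peaks Tibble of candidate peaks (`chrom`, `start`,
#'   `end`, optionally `peak_id`), sorted by position.
#' @param min_precision,min_span,marginals Passed to
#'   [codependency_score()].
#' @return Tibble, one row per candidate, with a `q_value` column.
#' @export
codependency_scan <- function(fibers, anchor_peak, candidate_peaks,
                              min_precision = 0.95, min_span = 10,
                              marginals = c("joint", "per-peak")) {
  marginals <- match.arg(marginals)
  if (nrow(candidate_peaks) == 0L) {
    out <- codependency_score(as_fiber_set(fibers),
                              anchor_peak, anchor_peak,
                              min_precision, min_span, marginals)[0, ]
    out$q_value <- numeric(0)
    return(out)
  }
  same <- candidate_peaks$chrom == anchor_peak$chrom &
    candidate_peaks$start == anchor_peak$start &
    candidate_peaks$end == anchor_peak$end
  if (any(same)) {
    stop("anchor peak appears among the candidates", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(candidate_peaks)), function(i) {
    codependency_score(fibers, anchor_peak, candidate_peaks[i, ],
                       min_precision, min_span, marginals)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out
}
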