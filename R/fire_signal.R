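#' Aggregate FIRE accessibility signal
#'
#' Sums the per-molecule evidence that a genomic position lies in a
#' regulatory element across all fibers covering it. With `p_k` the FIRE
#' precision of the k-th MSP overlapping position `g`, the signal is the
#' phred-scaled product of the per-molecule null probabilities,
#' \deqn{S_g = -10 \sum_k \log_{10}(1 - p_k).}
#' Covering fibers without an MSP at `g` contribute a `p = 0` term
#' (i.e. nothing), and `1 - p` is clamped below at `1e-10` so a precision
#' of exactly 1 stays finite. Every MSP contributes with its precision,
#' whatever its value; restrict with `min_precision` to reproduce a
#' FIRE-elements-only track (numerically the low-precision terms are
#' negligible either way).
#'
#' @param fibers A [fiber_set].
#' @param chrom,start,end Region to compute over (0-based half-open).
#' @param min_precision Optional lower precision cutoff for contributing
#'   MSPs (default 0: all MSPs contribute).
#' @return A `signal_track`: list with `chrom`, `start` and per-base
#'   `values` of length `end - start`.
#' @examples
#' fs <- fiber_set(
#'   data.frame(chrom = "chrA", start = 0, end = 2000, fiber_id = "f1",
#'              haplotype = "H1"),
#'   data.frame(fiber_id = "f1", start = 100, end = 200, precision = 0.9))
#' tr <- aggregate_fire_signal(fs, "chrA", 0, 300)
#' tr$values[151]  # 10: -10 * log10(1 - 0.9)
#' @export
aggregate_fire_signal <- function(fibers, chrom, start, end,
                                  min_precision = 0) {
  fibers <- as_fiber_set(fibers)
  check_intervals(chrom, start, end, "region")
  width <- as.integer(end - start)
  msps <- fibers$msps
  idx <- match(msps$fiber_id, fibers$fibers$fiber_id)
  on_chrom <- fibers$fibers$chrom[idx] == chrom &
    msps$precision >= min_precision &
    interval_overlaps(msps$start, msps$end, start, end)
  msps <- msps[on_chrom, , drop = FALSE]
  values <- numeric(width)
  if (nrow(msps)) {
    w <- -10 * log10(pmax(1 - msps$precision, 1e-10))
    s_rel <- pmax(msps$start, start) - start
    e_rel <- pmin(msps$end, end) - start
    # difference-array accumulation: add w at s_rel, remove at e_rel
    d <- numeric(width + 1L)
    add <- rowsum(c(w, -w), c(s_rel + 1L, e_rel + 1L))
    d[as.integer(rownames(add))] <- add[, 1]
    values <- cumsum(d)[seq_len(width)]
    values[values < 0] <- 0  # guard against float drift
  }
  structure(list(chrom = chrom, start = as.numeric(start), values = values),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s:%d-%d, max S = %.3f\n", x$chrom,
              as.integer(x$start), as.integer(x$start + length(x$values)),
              if (length(x$values)) max(x$values) else 0))
  invisible(x)
}

#' Genome-wide Bonferroni score threshold for peak calling
#'
#' The aggregate signal is a phred-scaled per-base null probability
#' (`S_g = -10 log10 P_g` with `P_g` the probability that no overlapping
#' MSP is a true regulatory element). Bonferroni-correcting that
#' probability over `genome_size` assayed bases at level `alpha` gives the
#' score cutoff \deqn{S^* = -10 \log_{10}(\alpha / G);} a base is
#' significant iff `S_g >= S*`.
#'
#' @param alpha Significance level (the reference analysis uses 0.01).
#' @param genome_size Total assayed bases the correction spans.
#' @return The score threshold `S*`.
#' @examples
#' peak_score_threshold(0.01, 1e4)  # 60
#' @export
peak_score_threshold <- function(alpha, genome_size) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (genome_size < 1) stop("genome_size must be >= 1", call. = FALSE)
  -10 * log10(alpha / genome_size)
}

#' Call peaks from a signal track
#'
#' Peaks are maximal runs of consecutive bases with `S_g >= threshold`;
#' runs separated by sub-threshold gaps of at most `merge_gap` bases are
#' merged. Each peak records the maximum signal it contains.
#'
#' @param track A `signal_track` from [aggregate_fire_signal()].
#' @param threshold Score cutoff, typically [peak_score_threshold()].
#' @param merge_gap Maximum sub-threshold gap (bp) bridged between runs.
#' @return Tibble of peaks: `chrom`, `start`, `end`, `peak_id`,
#'   `max_signal`.
#' @export
call_fire_peaks <- function(track, threshold, merge_gap = 0) {
  stopifnot(inherits(track, "signal_track"), threshold >= 0, merge_gap >= 0)
  sig <- track$values >= threshold
  if (merge_gap > 0 && any(sig)) {
    r <- rle(sig)
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    bridge <- interior[!r$values[interior] &
                         r$lengths[interior] <= merge_gap]
    r$values[bridge] <- TRUE
    sig <- inverse.rle(r)
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  out <- tibble::tibble(
    chrom = rep(track$chrom, length(keep)),
    start = track$start + starts[keep],
    end = track$start + ends[keep])
  out$peak_id <- sprintf("%s_%d_%d", out$chrom, as.integer(out$start),
                         as.integer(out$end))
  out$max_signal <- vapply(keep, function(i) {
    max(track$values[(starts[i] + 1):ends[i]])
  }, numeric(1))
  out
}
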