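#' Interval overlap and containment (0-based half-open)
#'
#' Every module in the package routes interval comparisons through these
#' two predicates so the coordinate convention cannot drift: intervals are
#' 0-based, half-open `[start, end)`, exactly as in BED. Both functions are
#' vectorised and recycle their arguments.
#'
#' @param start1,end1,start2,end2 Integer-valued vectors of interval bounds.
#' @return Logical vector: does interval 1 overlap interval 2 by at least
#'   one base?
#' @examples
#' interval_overlaps(0, 10, 9, 20)   # TRUE  (share base 9)
#' interval_overlaps(0, 10, 10, 20)  # FALSE (half-open: abut, no overlap)
#' @export
interval_overlaps <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

#' @rdname interval_overlaps
#' @param outer_start,outer_end,inner_start,inner_end Interval bounds.
#' @return For `interval_contains()`: logical vector, is the inner interval
#'   fully contained in the outer one?
#' @export
interval_contains <- function(outer_start, outer_end, inner_start, inner_end) {
  outer_start <= inner_start & inner_end <= outer_end
}

# Shared validator for (chrom, start, end) triples. `what` names the
# offending object in error messages.
check_intervals <- function(chrom, start, end, what = "interval") {
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop(what, ": chrom must be non-empty", call. = FALSE)
  }
  if (any(is.na(start)) || any(is.na(end))) {
    stop(what, ": start/end must not be NA", call. = FALSE)
  }
  if (any(start < 0)) stop(what, ": start must be >= 0", call. = FALSE)
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("%s: start >= end (row %d: [%s, %s))", what, bad,
                 format(start[bad], scientific = FALSE),
                 format(end[bad], scientific = FALSE)), call. = FALSE)
  }
  invisible(TRUE)
}

# Overlap join between two interval tables on the same chromosome set.
# Returns a data.frame with columns `q` and `s`: row indices into query
# and subject. `type` is "any" (>= 1 bp overlap) or "within" (query inside
# subject). Thin wrapper over IRanges::findOverlaps, applied per chromosome.
overlap_join <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end,
                         type = c("any", "within")) {
  type <- match.arg(type)
  if (length(q_chrom) == 0L || length(s_chrom) == 0L) {
    return(data.frame(q = integer(), s = integer()))
  }
  out_q <- vector("list", 0L)
  out_s <- vector("list", 0L)
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (length(si) == 0L) next
    # half-open [start, end) -> closed 1-based [start + 1, end]
    qr <- IRanges::IRanges(q_start[qi] + 1L, q_end[qi])
    sr <- IRanges::IRanges(s_start[si] + 1L, s_end[si])
    hits <- IRanges::findOverlaps(qr, sr, type = type)
    out_q <- c(out_q, list(qi[S4Vectors::queryHits(hits)]))
    out_s <- c(out_s, list(si[S4Vectors::subjectHits(hits)]))
  }
  data.frame(q = unlist(out_q, use.names = FALSE),
             s = unlist(out_s, use.names = FALSE))
}

HAPLOTYPE_LEVELS <- c("H1", "H2", "UNASSIGNED")

check_haplotype <- function(haplotype, what = "haplotype") {
  bad <- !haplotype %in% HAPLOTYPE_LEVELS
  if (any(bad)) {
    stop(sprintf("%s: invalid label '%s' (expected H1, H2 or UNASSIGNED)",
                 what, haplotype[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}
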