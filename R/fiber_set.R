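#' Construct a fiber set
#'
#' A `fiber_set` holds one genome's worth of phased chromatin fibers in
#' relational form: a `fibers` table (one row per sequenced molecule) and
#' an `msps` table (one row per methyltransferase-sensitive patch, keyed by
#' `fiber_id`). Each MSP carries the FIRE precision `p`, the upstream
#' classifier's confidence that the patch is a regulatory element rather
#' than an internucleosomal linker; `p` drives every accessibility decision
#' downstream.
#'
#' @param fibers Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `fiber_id` (unique), `haplotype`
#'   (`"H1"`, `"H2"` or `"UNASSIGNED"`). Extra columns (e.g. simulation
#'   metadata) are kept.
#' @param msps Data frame with columns `fiber_id`, `start`, `end`,
#'   `precision`. MSPs must lie inside their fiber, be non-overlapping and
#'   have precision in \[0, 1\].
#' @return An object of class `fiber_set`: a list with elements `fibers`
#'   and `msps` (tibbles).
#' @examples
#' fs <- fiber_set(
#'   data.frame(chrom = "chrA", start = 0, end = 18000,
#'              fiber_id = "f1", haplotype = "H1"),
#'   data.frame(fiber_id = "f1", start = 100, end = 300, precision = 0.95)
#' )
#' fs
#' @export
fiber_set <- function(fibers, msps = NULL) {
  fibers <- tibble::as_tibble(fibers)
  required <- c("chrom", "start", "end", "fiber_id", "haplotype")
  missing_cols <- setdiff(required, names(fibers))
  if (length(missing_cols)) {
    stop("fibers: missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(msps)) {
    msps <- tibble::tibble(fiber_id = character(), start = numeric(),
                           end = numeric(), precision = numeric())
  }
  msps <- tibble::as_tibble(msps)
  missing_cols <- setdiff(c("fiber_id", "start", "end", "precision"),
                          names(msps))
  if (length(missing_cols)) {
    stop("msps: missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(fibers)) {
    check_intervals(fibers$chrom, fibers$start, fibers$end, "fiber")
    check_haplotype(fibers$haplotype, "fiber haplotype")
    if (anyDuplicated(fibers$fiber_id)) {
      stop("fiber_id values must be unique", call. = FALSE)
    }
  }
  if (nrow(msps)) {
    check_intervals(rep("m", nrow(msps)), msps$start, msps$end, "MSP")
    if (any(msps$precision < 0 | msps$precision > 1)) {
      stop("MSP precision must lie in [0, 1]", call. = FALSE)
    }
    idx <- match(msps$fiber_id, fibers$fiber_id)
    if (anyNA(idx)) {
      stop("MSP references unknown fiber_id '",
           msps$fiber_id[which(is.na(idx))[1]], "'", call. = FALSE)
    }
    inside <- interval_contains(fibers$start[idx], fibers$end[idx],
                                msps$start, msps$end)
    if (!all(inside)) {
      bad <- which(!inside)[1]
      stop(sprintf("MSP [%d, %d) extends outside fiber '%s'",
                   as.integer(msps$start[bad]), as.integer(msps$end[bad]),
                   msps$fiber_id[bad]), call. = FALSE)
    }
    msps <- msps[order(idx, msps$start), , drop = FALSE]
    same <- msps$fiber_id[-1] == msps$fiber_id[-nrow(msps)]
    if (nrow(msps) > 1 &&
        any(same & msps$start[-1] < msps$end[-nrow(msps)])) {
      stop("MSPs overlap within a fiber", call. = FALSE)
    }
  }
  structure(list(fibers = fibers, msps = msps), class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  hap <- table(factor(x$fibers$haplotype, HAPLOTYPE_LEVELS))
  cat(sprintf("<fiber_set> %d fibers (%s), %d MSPs on %d chromosome(s)\n",
              nrow(x$fibers),
              paste(sprintf("%s: %d", names(hap), hap), collapse = ", "),
              nrow(x$msps), length(unique(x$fibers$chrom))))
  invisible(x)
}

#' Number of fibers in a fiber set
#' @param fibers A `fiber_set`.
#' @return Integer count.
#' @export
n_fibers <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  nrow(fibers$fibers)
}

#' Subset a fiber set by fiber id
#' @param fibers A `fiber_set`.
#' @param fiber_ids Character vector of fiber ids to keep.
#' @return A `fiber_set` restricted to those fibers (MSPs follow).
#' @export
subset_fibers <- function(fibers, fiber_ids) {
  stopifnot(inherits(fibers, "fiber_set"))
  fiber_set(fibers$fibers[fibers$fibers$fiber_id %in% fiber_ids, ,
                          drop = FALSE],
            fibers$msps[fibers$msps$fiber_id %in% fiber_ids, ,
                        drop = FALSE])
}

as_fiber_set <- function(x) {
  if (!inherits(x, "fiber_set")) stop("expected a fiber_set", call. = FALSE)
  x
}
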