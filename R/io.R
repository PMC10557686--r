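#' Read and write fiber tables
#'
#' The fiber table is the package's on-disk contract for phased Fiber-seq
#' molecules: a tab-separated file with header
#' `chrom  start  end  fiber_id  haplotype  msps`, coordinates 0-based
#' half-open, and `msps` a comma-separated list of `start-end:precision`
#' triples (empty string for a fiber with no accessible patches). No
#' quoting; one row per fiber.
#'
#' @param path File path.
#' @return `read_fiber_table()`: a [fiber_set].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstart\tend\tfiber_id\thaplotype\tmsps",
#'              "chrA\t0\t18000\tf1\tH1\t100-300:0.95,900-1100:0.10"), tf)
#' read_fiber_table(tf)
#' @export
read_fiber_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_tsv(
    path, na = character(),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), fiber_id = readr::col_character(),
      haplotype = readr::col_character(), msps = readr::col_character()),
    progress = FALSE)
  required <- c("chrom", "start", "end", "fiber_id", "haplotype", "msps")
  if (!all(required %in% names(tab))) {
    stop("fiber table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  msps <- parse_msp_field(tab$msps, tab$fiber_id)
  fiber_set(tab[required[1:5]], msps)
}

# "100-300:0.95,900-1100:0.10" -> long table. Errors name the data line.
parse_msp_field <- function(field, fiber_id) {
  nonempty <- which(!is.na(field) & nzchar(field))
  if (!length(nonempty)) {
    return(tibble::tibble(fiber_id = character(), start = numeric(),
                          end = numeric(), precision = numeric()))
  }
  parts <- strsplit(field[nonempty], ",", fixed = TRUE)
  n_per <- lengths(parts)
  row_of <- rep(nonempty, n_per)
  triple <- unlist(parts, use.names = FALSE)
  m <- regmatches(triple,
                  regexec("^([0-9]+)-([0-9]+):([0-9.eE+-]+)$", triple))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed msp entry '%s' on data line %d",
                 triple[bad[1]], row_of[bad[1]]), call. = FALSE)
  }
  m <- matrix(unlist(m, use.names = FALSE), ncol = 4L, byrow = TRUE)
  prec <- as.numeric(m[, 4])
  if (any(is.na(prec) | prec < 0 | prec > 1)) {
    bad <- which(is.na(prec) | prec < 0 | prec > 1)[1]
    stop(sprintf("msp precision out of [0, 1] on data line %d: '%s'",
                 row_of[bad], triple[bad]), call. = FALSE)
  }
  tibble::tibble(fiber_id = fiber_id[row_of],
                 start = as.numeric(m[, 2]),
                 end = as.numeric(m[, 3]),
                 precision = prec)
}

# Shortest decimal string that round-trips the double exactly.
format_num <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

#' @rdname read_fiber_table
#' @param fibers A [fiber_set].
#' @return `write_fiber_table()`: the path, invisibly. Reading the file
#'   back reproduces the fiber set field for field.
#' @export
write_fiber_table <- function(fibers, path) {
  fibers <- as_fiber_set(fibers)
  ftab <- fibers$fibers
  msps <- fibers$msps
  enc <- character(nrow(ftab))
  if (nrow(msps)) {
    idx <- match(msps$fiber_id, ftab$fiber_id)
    triples <- sprintf("%d-%d:%s", as.integer(msps$start),
                       as.integer(msps$end), format_num(msps$precision))
    grouped <- vapply(split(triples, factor(idx, seq_len(nrow(ftab)))),
                      paste, "", collapse = ",")
    enc <- unname(grouped)
  }
  out <- data.frame(chrom = ftab$chrom, start = as.integer(ftab$start),
                    end = as.integer(ftab$end), fiber_id = ftab$fiber_id,
                    haplotype = ftab$haplotype, msps = enc)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write CpG call tables
#'
#' Tab-separated, one row per (fiber, CpG site) call: columns `chrom`,
#' `pos` (0-based position of the CpG cytosine), `fiber_id`, `haplotype`,
#' `methylated` (0/1).
#'
#' @param path File path.
#' @return A tibble of CpG calls (`methylated` as logical).
#' @export
read_cpg_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      fiber_id = readr::col_character(),
      haplotype = readr::col_character(),
      methylated = readr::col_integer()),
    progress = FALSE)
  if (any(tab$pos < 0)) stop("CpG pos must be >= 0", call. = FALSE)
  check_haplotype(tab$haplotype, "CpG haplotype")
  if (nrow(tab) && any(!tab$methylated %in% c(0L, 1L))) {
    stop("methylated must be 0 or 1", call. = FALSE)
  }
  tab$methylated <- tab$methylated == 1L
  tab
}

#' @rdname read_cpg_table
#' @param calls Tibble of CpG calls as returned by [read_cpg_table()] or
#'   [simulate_cpg()].
#' @export
write_cpg_table <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, pos = as.integer(calls$pos),
                    fiber_id = calls$fiber_id, haplotype = calls$haplotype,
                    methylated = as.integer(calls$methylated))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write transcript tables
#'
#' Tab-separated, one row per full-length transcript read: columns
#' `read_id`, `gene_id`, `haplotype` (assigned from heterozygous variants
#' contained in the transcript; `UNASSIGNED` when none are informative).
#'
#' @param path File path.
#' @return A tibble of transcript reads.
#' @export
read_transcript_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(), gene_id = readr::col_character(),
      haplotype = readr::col_character()),
    progress = FALSE)
  check_haplotype(tab$haplotype, "transcript haplotype")
  if (anyDuplicated(tab$read_id)) {
    stop("read_id values must be unique", call. = FALSE)
  }
  tab
}

#' @rdname read_transcript_table
#' @param reads Tibble of transcript reads.
#' @export
write_transcript_table <- function(reads, path) {
  readr::write_tsv(reads[c("read_id", "gene_id", "haplotype")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write peaks as BED
#'
#' Peaks travel as BED4/BED5 (0-based half-open): name = `peak_id`,
#' score = `max_signal` (aggregate FIRE score; omitted when absent).
#' Parsing and serialisation go through rtracklayer.
#'
#' @param path File path.
#' @return `read_bed()`: a tibble with columns `chrom`, `start`, `end`,
#'   `peak_id` and, when present in the file, `max_signal`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr))
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) {
    nm <- sprintf("peak_%05d", seq_len(nrow(out)))
  }
  out$peak_id <- nm
  if (!is.null(gr$score)) out$max_signal <- as.numeric(gr$score)
  if (nrow(out)) check_intervals(out$chrom, out$start, out$end, "BED record")
  out
}

#' @rdname read_bed
#' @param peaks Tibble with `chrom`, `start`, `end` and optionally
#'   `peak_id`, `max_signal`.
#' @export
write_bed <- function(peaks, path) {
  if (nrow(peaks)) check_intervals(peaks$chrom, peaks$start, peaks$end,
                                   "BED record")
  gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  gr$name <- if ("peak_id" %in% names(peaks)) peaks$peak_id else
    sprintf("peak_%05d", seq_len(nrow(peaks)))
  if ("max_signal" %in% names(peaks)) gr$score <- peaks$max_signal
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' Adjacent positions with equal values are merged into one row and
#' zero-valued runs are omitted (the sparse bedGraph convention), so a
#' constant-zero track produces an empty-bodied file.
#'
#' @param track A [signal_track].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  r <- rle(track$values)
  ends <- track$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    rep(track$chrom, sum(keep)),
    IRanges::IRanges(starts[keep] + 1, ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
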