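#' Haplotype-resolved CpG pileup
#'
#' Summarises per-fiber CpG calls into per-site haplotype methylation
#' percentages, the single-base pileup view of the methylome. Calls from
#' `UNASSIGNED` fibers are tallied separately and excluded from the
#' haplotype percentages.
#'
#' @param calls CpG call tibble (`chrom`, `pos`, `fiber_id`, `haplotype`,
#'   `methylated`), e.g. from [read_cpg_table()] or [simulate_cpg()].
#' @return Tibble with one row per (chrom, pos) carrying at least one
#'   call: `n_h1`, `meth_h1`, `pct_h1`, `n_h2`, `meth_h2`, `pct_h2`,
#'   `n_unassigned`.
#' @export
cpg_pileup <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          n_h1 = integer(), meth_h1 = integer(),
                          pct_h1 = numeric(), n_h2 = integer(),
                          meth_h2 = integer(), pct_h2 = numeric(),
                          n_unassigned = integer()))
  }
  calls |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      n_h1 = sum(.data$haplotype == "H1"),
      meth_h1 = sum(.data$haplotype == "H1" & .data$methylated),
      n_h2 = sum(.data$haplotype == "H2"),
      meth_h2 = sum(.data$haplotype == "H2" & .data$methylated),
      n_unassigned = sum(.data$haplotype == "UNASSIGNED"),
      .groups = "drop") |>
    dplyr::mutate(
      pct_h1 = ifelse(.data$n_h1 > 0, 100 * .data$meth_h1 / .data$n_h1,
                      NA_real_),
      pct_h2 = ifelse(.data$n_h2 > 0, 100 * .data$meth_h2 / .data$n_h2,
                      NA_real_)) |>
    dplyr::select("chrom", "pos", "n_h1", "meth_h1", "pct_h1", "n_h2",
                  "meth_h2", "pct_h2", "n_unassigned") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Differential haplotype methylation over a region
#'
#' Tests whether a region (e.g. a promoter hypermethylated on one
#' derivative haplotype) is differentially CpG-methylated between
#' haplotypes. Calls inside the region are pooled per haplotype and
#' compared with Fisher's exact test. Because one fiber contributes calls
#' at many CpGs, the default unit is the fiber: each phased fiber votes
#' once with its majority methylation state across the region's sites
#' (ties count as methylated), which keeps the test's units independent.
#' `unit = "call"` pools raw calls instead (anti-conservative when fibers
#' span multiple sites, but matches a naive pileup comparison).
#'
#' @param calls CpG call tibble.
#' @param region One-row data frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param min_sites Minimum number of region CpG sites with calls on both
#'   haplotypes (default 3).
#' @param unit `"fiber"` or `"call"` (see above).
#' @return List with `delta_pct` (pooled `pct_h1 - pct_h2`), `p_value`,
#'   `n_sites`, and the pooled 2x2 `table`.
#' @export
region_methylation_test <- function(calls, region, min_sites = 3,
                                    unit = c("fiber", "call")) {
  unit <- match.arg(unit)
  inside <- calls$chrom == region$chrom &
    calls$pos >= region$start & calls$pos < region$end
  reg <- calls[inside & calls$haplotype %in% c("H1", "H2"), , drop = FALSE]
  n_sites <- length(intersect(unique(reg$pos[reg$haplotype == "H1"]),
                              unique(reg$pos[reg$haplotype == "H2"])))
  if (n_sites < min_sites) {
    stop(sprintf(paste0("region %s:%d-%d has %d CpG site(s) with calls on ",
                        "both haplotypes (need >= %d)"),
                 region$chrom, as.integer(region$start),
                 as.integer(region$end), n_sites, min_sites),
         call. = FALSE)
  }
  if (unit == "fiber") {
    per <- reg |>
      dplyr::group_by(.data$fiber_id, .data$haplotype) |>
      dplyr::summarise(meth = mean(.data$methylated) >= 0.5,
                       .groups = "drop")
    units_hap <- per$haplotype
    units_meth <- per$meth
  } else {
    units_hap <- reg$haplotype
    units_meth <- reg$methylated
  }
  a <- sum(units_hap == "H1" & units_meth)
  b <- sum(units_hap == "H1" & !units_meth)
  c_ <- sum(units_hap == "H2" & units_meth)
  d <- sum(units_hap == "H2" & !units_meth)
  ft <- fisher_exact_2x2(a, b, c_, d)
  delta <- 100 * a / max(1, a + b) - 100 * c_ / max(1, c_ + d)
  list(delta_pct = delta, p_value = ft$p_value, n_sites = n_sites,
       table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                      dimnames = list(c("H1", "H2"),
                                      c("methylated", "unmethylated"))))
}
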