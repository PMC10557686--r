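#' Per-gene haplotype transcript counts
#'
#' Tallies phased full-length transcript reads per gene: H1, H2 and
#' unassigned (reads without an informative heterozygous variant).
#'
#' @param reads Transcript read tibble (`read_id`, `gene_id`,
#'   `haplotype`).
#' @return Tibble with `gene_id`, `n_h1`, `n_h2`, `n_unassigned`.
#' @export
gene_haplotype_counts <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble::tibble(gene_id = character(), n_h1 = integer(),
                          n_h2 = integer(), n_unassigned = integer()))
  }
  reads |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_h1 = sum(.data$haplotype == "H1"),
      n_h2 = sum(.data$haplotype == "H2"),
      n_unassigned = sum(.data$haplotype == "UNASSIGNED"),
      .groups = "drop") |>
    dplyr::arrange(.data$gene_id)
}

#' Exact binomial test for allelic expression imbalance
#'
#' Two-sided exact binomial test of the phased read counts against the
#' balanced null proportion 0.5 (summing outcome probabilities no larger
#' than the observed point probability).
#'
#' @param n_h1,n_h2 Haplotype-assigned read counts (sum must be >= 1).
#' @return The two-sided p-value.
#' @examples
#' allelic_expression_test(10, 0)  # 2 * 0.5^10
#' @export
allelic_expression_test <- function(n_h1, n_h2) {
  stopifnot(n_h1 >= 0, n_h2 >= 0)
  if (n_h1 + n_h2 < 1) {
    stop("need at least one phased read", call. = FALSE)
  }
  binom.test(n_h1, n_h1 + n_h2, p = 0.5)$p.value
}

#' Allele-specific expression across genes
#'
#' Combines [gene_haplotype_counts()] and [allelic_expression_test()]
#' into the per-gene ASE table.
#'
#' @param reads Transcript read tibble.
#' @return Tibble with `gene_id`, `n_h1`, `n_h2`, `n_unassigned`,
#'   `allelic_ratio` (`n_h1 / (n_h1 + n_h2)`, `NA` when no phased reads)
#'   and `p_value` (`NA` when no phased reads).
#' @export
allele_specific_expression <- function(reads) {
  counts <- gene_haplotype_counts(reads)
  phased <- counts$n_h1 + counts$n_h2
  counts$allelic_ratio <- ifelse(phased > 0, counts$n_h1 / phased,
                                 NA_real_)
  counts$p_value <- NA_real_
  ok <- which(phased >= 1)
  counts$p_value[ok] <- mapply(allelic_expression_test,
                               counts$n_h1[ok], counts$n_h2[ok])
  counts
}
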