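#' Specify a regulatory element for simulation
#'
#' An element actuates (carries a high-precision MSP) on each fiber
#' independently with a haplotype-specific Bernoulli probability, so
#' imprinted-like elements are expressed as skewed
#' (`actuation_h1` vs `actuation_h2`) pairs. Two elements can be coupled so
#' their actuation on the same fiber is correlated (single-molecule
#' co-dependency); the coupled pair is drawn from the exact joint Bernoulli
#' distribution with the stated marginals and correlation.
#'
#' @param chrom,start,end Element interval (0-based half-open).
#' @param actuation_h1,actuation_h2 Per-fiber actuation probabilities for
#'   haplotypes H1 and H2.
#' @param high_precision FIRE precision written onto actuated MSPs.
#' @param element_id Unique id (defaults to `chrom:start-end`).
#' @param couple_to Optional id of a partner element for correlated
#'   actuation.
#' @param couple_corr Pearson correlation targeted for the coupled pair.
#' @return One-row tibble understood by [genome_model()].
#' @export
element_spec <- function(chrom, start, end, actuation_h1, actuation_h2,
                         high_precision = 0.97, element_id = NULL,
                         couple_to = NA_character_, couple_corr = 0) {
  check_intervals(chrom, start, end, "element")
  stopifnot(actuation_h1 >= 0, actuation_h1 <= 1,
            actuation_h2 >= 0, actuation_h2 <= 1,
            high_precision >= 0, high_precision <= 1,
            abs(couple_corr) <= 1)
  if (is.null(element_id)) {
    element_id <- sprintf("%s:%d-%d", chrom, as.integer(start),
                          as.integer(end))
  }
  tibble::tibble(element_id = element_id, chrom = chrom, start = start,
                 end = end, actuation_h1 = actuation_h1,
                 actuation_h2 = actuation_h2,
                 high_precision = high_precision,
                 couple_to = as.character(couple_to),
                 couple_corr = couple_corr)
}

#' Specify a cell-level silencing scenario
#'
#' Emulates regional epigenetic silencing such as the spread of
#' X-inactivation into autosomal DNA on a derivative chromosome: in a
#' fraction `fraction` of cells (drawn once per cell, so all fibers, CpG
#' calls and transcripts of that cell are jointly affected) the stated
#' haplotype of the region is silenced — element actuation drops to
#' `residual_actuation` and CpG methylation rises to
#' `silenced_methylation`.
#'
#' @param chrom,start,end Silenced region (0-based half-open).
#' @param haplotype `"H1"` or `"H2"`: the copy that is silenced.
#' @param fraction Proportion of cells carrying the silenced state.
#' @param residual_actuation Element actuation probability when silenced.
#' @param silenced_methylation Per-CpG methylation probability when
#'   silenced.
#' @return One-row tibble understood by [genome_model()].
#' @export
silencing_spec <- function(chrom, start, end, haplotype, fraction,
                           residual_actuation = 0,
                           silenced_methylation = 0.9) {
  check_intervals(chrom, start, end, "silencing region")
  if (!haplotype %in% c("H1", "H2")) {
    stop("silencing haplotype must be H1 or H2", call. = FALSE)
  }
  stopifnot(fraction >= 0, fraction <= 1, residual_actuation >= 0,
            residual_actuation <= 1, silenced_methylation >= 0,
            silenced_methylation <= 1)
  tibble::tibble(chrom = chrom, start = start, end = end,
                 haplotype = haplotype, fraction = fraction,
                 residual_actuation = residual_actuation,
                 silenced_methylation = silenced_methylation)
}

#' Define a synthetic genome scenario
#'
#' The model is the single source of truth for a simulation: chromosome
#' sizes, regulatory elements with per-haplotype actuation, CpG sites with
#' per-haplotype baseline methylation, cell-level region silencing, gene
#' expression means, and the fiber sampling parameters.
#'
#' @param chrom_sizes Named numeric vector, chromosome length in bp.
#' @param elements List of [element_spec()] rows (or a bound data frame).
#'   Elements must be pairwise non-overlapping.
#' @param cpg_sites Data frame with `chrom`, `pos`, `baseline_h1`,
#'   `baseline_h2` (per-haplotype methylation probability).
#' @param silencing List of [silencing_spec()] rows.
#' @param genes Data frame with `gene_id`, `mean_h1`, `mean_h2` (expected
#'   transcripts per cell per haplotype) and optionally `chrom`, `start`,
#'   `end` so region silencing can zero a gene's silenced copy.
#' @param fiber_length_mean,fiber_length_sd Fiber length distribution in
#'   bp (Normal, truncated from below; HiFi Fiber-seq molecules run
#'   10-20 kb, hence the defaults).
#' @param background_msp_rate Expected low-precision (linker) MSPs per kb
#'   of fiber.
#' @param background_precision Range of the uniform distribution that
#'   linker MSP precisions are drawn from.
#' @param unassigned_rate Probability a fiber or transcript read carries
#'   no informative heterozygous variant and is tagged `UNASSIGNED`.
#' @param locus_merge_gap Elements/CpG sites closer than this are grouped
#'   into one locus, and each simulated fiber is placed to span one whole
#'   locus.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chrom_sizes, elements = NULL, cpg_sites = NULL,
                         silencing = NULL, genes = NULL,
                         fiber_length_mean = 15000, fiber_length_sd = 3000,
                         background_msp_rate = 1,
                         background_precision = c(0, 0.3),
                         unassigned_rate = 0.05, locus_merge_gap = 5000) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) >= 1,
            !is.null(names(chrom_sizes)), all(chrom_sizes > 0),
            fiber_length_mean >= 1000, fiber_length_sd >= 0,
            background_msp_rate >= 0,
            length(background_precision) == 2,
            background_precision[1] >= 0, background_precision[2] <= 1,
            background_precision[1] <= background_precision[2],
            unassigned_rate >= 0, unassigned_rate <= 1)
  bind_specs <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) tibble::as_tibble(x) else dplyr::bind_rows(x)
  }
  elements <- bind_specs(elements)
  silencing <- bind_specs(silencing)
  if (is.null(elements)) elements <- element_spec("z", 0, 1, 0, 0)[0, ]
  if (is.null(silencing)) silencing <- silencing_spec("z", 0, 1, "H1", 0)[0, ]
  if (is.null(cpg_sites)) {
    cpg_sites <- tibble::tibble(chrom = character(), pos = numeric(),
                                baseline_h1 = numeric(),
                                baseline_h2 = numeric())
  } else {
    cpg_sites <- tibble::as_tibble(cpg_sites)
    stopifnot(all(c("chrom", "pos", "baseline_h1", "baseline_h2") %in%
                    names(cpg_sites)),
              all(cpg_sites$pos >= 0),
              all(cpg_sites$baseline_h1 >= 0 & cpg_sites$baseline_h1 <= 1),
              all(cpg_sites$baseline_h2 >= 0 & cpg_sites$baseline_h2 <= 1))
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = character(), mean_h1 = numeric(),
                            mean_h2 = numeric(), chrom = character(),
                            start = numeric(), end = numeric())
  } else {
    genes <- tibble::as_tibble(genes)
    stopifnot(all(c("gene_id", "mean_h1", "mean_h2") %in% names(genes)))
    if (any(genes$mean_h1 < 0 | genes$mean_h2 < 0)) {
      stop("gene expected counts must be >= 0", call. = FALSE)
    }
    if (!"chrom" %in% names(genes)) {
      genes$chrom <- NA_character_
      genes$start <- NA_real_
      genes$end <- NA_real_
    }
  }
  within_genome <- function(chrom, end, what) {
    sz <- chrom_sizes[chrom]
    if (anyNA(sz) || any(end > sz)) {
      stop(what, " outside declared chromosome sizes", call. = FALSE)
    }
  }
  if (nrow(elements)) {
    if (anyDuplicated(elements$element_id)) {
      stop("element ids must be unique", call. = FALSE)
    }
    within_genome(elements$chrom, elements$end, "element")
    ov <- overlap_join(elements$chrom, elements$start, elements$end,
                       elements$chrom, elements$start, elements$end)
    if (any(ov$q != ov$s)) {
      stop("elements must be pairwise non-overlapping", call. = FALSE)
    }
    check_coupling(elements)
  }
  if (nrow(silencing)) within_genome(silencing$chrom, silencing$end,
                                     "silencing region")
  if (nrow(cpg_sites)) within_genome(cpg_sites$chrom, cpg_sites$pos + 1,
                                     "cpg site")
  structure(list(chrom_sizes = chrom_sizes, elements = elements,
                 cpg_sites = cpg_sites, silencing = silencing,
                 genes = genes, fiber_length_mean = fiber_length_mean,
                 fiber_length_sd = fiber_length_sd,
                 background_msp_rate = background_msp_rate,
                 background_precision = background_precision,
                 unassigned_rate = unassigned_rate,
                 locus_merge_gap = locus_merge_gap),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(paste0("<genome_model> %d chromosome(s), %d element(s), ",
                     "%d CpG site(s), %d silencing region(s), %d gene(s)\n"),
              length(x$chrom_sizes), nrow(x$elements), nrow(x$cpg_sites),
              nrow(x$silencing), nrow(x$genes)))
  invisible(x)
}

# Coupling declarations: one-sided (A names B); no element may be named
# twice or both name a partner (keeps the coupling graph a matching).
check_coupling <- function(elements) {
  has <- !is.na(elements$couple_to)
  if (!any(has)) return(invisible(TRUE))
  tgt <- elements$couple_to[has]
  if (any(!tgt %in% elements$element_id)) {
    stop("couple_to references unknown element id", call. = FALSE)
  }
  src <- elements$element_id[has]
  if (any(tgt %in% src) || anyDuplicated(c(src, tgt))) {
    stop("coupling must form disjoint pairs (one declaration per pair)",
         call. = FALSE)
  }
  same_chrom <- elements$chrom[match(tgt, elements$element_id)] ==
    elements$chrom[has]
  if (!all(same_chrom)) {
    stop("coupled elements must share a chromosome", call. = FALSE)
  }
  # feasibility at the unsilenced marginals (re-checked per fiber later)
  a <- elements[has, ]
  b <- elements[match(tgt, elements$element_id), ]
  joint_bernoulli_p11(a$actuation_h1, b$actuation_h1, a$couple_corr)
  joint_bernoulli_p11(a$actuation_h2, b$actuation_h2, a$couple_corr)
  invisible(TRUE)
}

# P(X=1, Y=1) for correlated Bernoullis with marginals pa, pb and Pearson
# correlation rho; errors when the target lies outside the
# Frechet-Hoeffding bounds. Vectorised.
joint_bernoulli_p11 <- function(pa, pb, rho) {
  p11 <- pa * pb + rho * sqrt(pa * (1 - pa) * pb * (1 - pb))
  lo <- pmax(0, pa + pb - 1)
  hi <- pmin(pa, pb)
  eps <- 1e-9
  if (any(p11 < lo - eps | p11 > hi + eps)) {
    stop(sprintf(paste0("coupling infeasible: correlation %.3g with ",
                        "marginals (%.3g, %.3g) violates the ",
                        "Frechet-Hoeffding bounds"),
                 rho[1], pa[which(p11 < lo - eps | p11 > hi + eps)[1]],
                 pb[which(p11 < lo - eps | p11 > hi + eps)[1]]),
         call. = FALSE)
  }
  pmin(pmax(p11, lo), hi)
}

# Loci: merged footprint of elements and CpG sites; every simulated fiber
# spans one locus end-to-end.
model_loci <- function(model) {
  pieces <- rbind(
    data.frame(chrom = model$elements$chrom, start = model$elements$start,
               end = model$elements$end),
    data.frame(chrom = model$cpg_sites$chrom, start = model$cpg_sites$pos,
               end = model$cpg_sites$pos + 2))
  if (!nrow(pieces)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  }
  out <- lapply(split(pieces, pieces$chrom), function(p) {
    p <- p[order(p$start), ]
    grp <- cumsum(c(TRUE, p$start[-1] > cummax(p$end[-nrow(p)]) +
                      model$locus_merge_gap))
    data.frame(chrom = p$chrom[1],
               start = tapply(p$start, grp, min),
               end = tapply(p$end, grp, max))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate phased chromatin fibers
#'
#' Draws fibers locus by locus. Each cell receives a persistent silencing
#' state per [silencing_spec()] (Bernoulli with the spec's `fraction`), so
#' the regional signal is a coherent cell-level shift rather than
#' independent per-fiber noise. For every locus and haplotype,
#' `round(n_cells * coverage_per_hap)` fibers are drawn from uniformly
#' sampled cells; fiber lengths are Normal(`fiber_length_mean`,
#' `fiber_length_sd`) truncated below at max(1 kb, locus width), and each
#' fiber is positioned to span its locus. Elements overlapped by a fiber
#' actuate with their haplotype-specific probability (or the silencing
#' spec's `residual_actuation` in silenced cells), coupled pairs jointly;
#' actuated elements emit an MSP at the element interval with precision
#' `high_precision`. Background (linker) MSPs are scattered outside
#' element footprints at `background_msp_rate` per kb with precisions
#' drawn uniformly from `background_precision`.
#'
#' @param model A [genome_model()].
#' @param n_cells Number of cells in the simulated population.
#' @param coverage_per_hap Expected fibers per cell-haplotype per locus
#'   (may be < 1: a locus then samples a subset of cells).
#' @param seed Integer seed; identical arguments give identical output.
#' @return A [fiber_set] whose `fibers` table carries the extra
#'   simulation-metadata columns `cell` and `hap_true` (the haplotype
#'   before `UNASSIGNED` masking), plus the per-cell silencing states as
#'   attribute `"silencing_states"`.
#' @export
simulate_fibers <- function(model, n_cells, coverage_per_hap = 1, seed) {
  stopifnot(inherits(model, "genome_model"), n_cells >= 0,
            coverage_per_hap >= 0)
  withr::with_seed(as.integer(seed), {
    states <- draw_silencing_states(model, n_cells)
    fs <- sim_fibers_impl(model, n_cells, coverage_per_hap, states)
    attr(fs, "silencing_states") <- states
    fs
  })
}

draw_silencing_states <- function(model, n_cells) {
  matrix(runif(n_cells * nrow(model$silencing)) <
           rep(model$silencing$fraction, each = n_cells),
         nrow = n_cells, ncol = nrow(model$silencing))
}

# TRUE where fiber-row i is silenced for target interval overlap with
# silencing spec s, given its cell and true haplotype.
silenced_mask <- function(model, states, cell, hap_true, chrom, start, end,
                          spec_field = NULL) {
  out <- rep(FALSE, length(cell))
  val <- rep(NA_real_, length(cell))
  sil <- model$silencing
  for (s in seq_len(nrow(sil))) {
    hit <- chrom == sil$chrom[s] &
      interval_overlaps(start, end, sil$start[s], sil$end[s]) &
      hap_true == sil$haplotype[s] & states[cell, s]
    out <- out | hit
    if (!is.null(spec_field)) val[hit] <- sil[[spec_field]][s]
  }
  if (is.null(spec_field)) out else list(mask = out, value = val)
}

sim_fibers_impl <- function(model, n_cells, coverage_per_hap, states) {
  loci <- model_loci(model)
  per_lh <- if (n_cells > 0) round(n_cells * coverage_per_hap) else 0L
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), fiber_id = character(),
                          haplotype = character(), cell = integer(),
                          hap_true = character())
  if (nrow(loci) == 0L || per_lh == 0L) return(fiber_set(empty))

  n_loc <- nrow(loci)
  n_fib <- n_loc * 2L * per_lh
  loc_idx <- rep(seq_len(n_loc), each = 2L * per_lh)
  hap_true <- rep(rep(c("H1", "H2"), each = per_lh), times = n_loc)
  cell <- sample.int(n_cells, n_fib, replace = TRUE)
  width <- loci$end[loc_idx] - loci$start[loc_idx]
  len <- pmax(pmax(1000, width),
              round(rnorm(n_fib, model$fiber_length_mean,
                          model$fiber_length_sd)))
  chrom_size <- model$chrom_sizes[loci$chrom[loc_idx]]
  len <- pmin(len, chrom_size)
  offset <- floor(runif(n_fib) * (len - width + 1))
  fstart <- pmax(0, loci$start[loc_idx] - offset)
  fend <- fstart + len
  shift <- pmax(0, fend - chrom_size)
  fstart <- fstart - shift
  fend <- fend - shift
  fstart <- pmax(0, fstart)

  haplotype <- ifelse(runif(n_fib) < model$unassigned_rate, "UNASSIGNED",
                      hap_true)
  fiber_id <- sprintf("f%07d", seq_len(n_fib))
  fib <- tibble::tibble(chrom = loci$chrom[loc_idx], start = fstart,
                        end = fend, fiber_id = fiber_id,
                        haplotype = haplotype, cell = cell,
                        hap_true = hap_true)

  msps <- sim_element_msps(model, fib, states)
  bg <- sim_background_msps(model, fib)
  fiber_set(fib, rbind(msps, bg))
}

# Actuation draw for all elements; coupled pairs sampled from the exact
# joint Bernoulli. Returns the MSP table for actuated (fiber, element).
sim_element_msps <- function(model, fib, states) {
  el <- model$elements
  out <- tibble::tibble(fiber_id = character(), start = numeric(),
                        end = numeric(), precision = numeric())
  if (!nrow(el)) return(out)
  # one global containment join: element e is covered by fiber rows cov[[e]]
  ov <- overlap_join(el$chrom, el$start, el$end,
                     fib$chrom, fib$start, fib$end, type = "within")
  cov <- split(ov$s, factor(ov$q, seq_len(nrow(el))))
  # per-element effective actuation probability for each covering fiber
  eff_prob <- function(e, idx) {
    p <- ifelse(fib$hap_true[idx] == "H1", el$actuation_h1[e],
                el$actuation_h2[e])
    sil <- silenced_mask(model, states, fib$cell[idx], fib$hap_true[idx],
                         rep(el$chrom[e], length(idx)),
                         rep(el$start[e], length(idx)),
                         rep(el$end[e], length(idx)),
                         spec_field = "residual_actuation")
    p[sil$mask] <- sil$value[sil$mask]
    p
  }
  acc_fid <- vector("list", 0L)
  acc_e <- integer(0)
  emit <- function(e, idx, act) {
    acc_fid[[length(acc_fid) + 1L]] <<- fib$fiber_id[idx[act]]
    acc_e[[length(acc_e) + 1L]] <<- e
  }
  paired_b <- match(el$couple_to, el$element_id)
  done <- rep(FALSE, nrow(el))
  for (e in seq_len(nrow(el))) {
    if (done[e]) next
    b <- paired_b[e]
    if (!is.na(b)) {
      ia <- cov[[e]]
      ib <- cov[[b]]
      both <- intersect(ia, ib)
      pa <- eff_prob(e, both)
      pb <- eff_prob(b, both)
      p11 <- joint_bernoulli_p11(pa, pb, el$couple_corr[e])
      act_a <- runif(length(both)) < pa
      # conditional draw: P(B | A) = p11/pa, P(B | not A) = (pb-p11)/(1-pa)
      pb_given <- ifelse(act_a, p11 / pmax(pa, 1e-300),
                         (pb - p11) / pmax(1 - pa, 1e-300))
      act_b <- runif(length(both)) < pb_given
      emit(e, both, act_a)
      emit(b, both, act_b)
      # fibers covering only one of the pair fall back to the marginal
      only_a <- setdiff(ia, both)
      only_b <- setdiff(ib, both)
      if (length(only_a)) {
        emit(e, only_a, runif(length(only_a)) < eff_prob(e, only_a))
      }
      if (length(only_b)) {
        emit(b, only_b, runif(length(only_b)) < eff_prob(b, only_b))
      }
      done[c(e, b)] <- TRUE
    } else if (!el$element_id[e] %in% el$couple_to[!is.na(el$couple_to)]) {
      idx <- cov[[e]]
      emit(e, idx, runif(length(idx)) < eff_prob(e, idx))
      done[e] <- TRUE
    }
  }
  n_per <- lengths(acc_fid)
  e_of <- rep(acc_e, n_per)
  tibble::tibble(fiber_id = unlist(acc_fid, use.names = FALSE),
                 start = el$start[e_of], end = el$end[e_of],
                 precision = el$high_precision[e_of])
}

# Linker MSPs: one Bernoulli per 200-bp window of fiber (rate scaled per
# kb), each MSP confined to its window so background MSPs never overlap
# one another; those landing in an element footprint are discarded.
sim_background_msps <- function(model, fib) {
  out <- tibble::tibble(fiber_id = character(), start = numeric(),
                        end = numeric(), precision = numeric())
  win <- 200
  p_win <- model$background_msp_rate * win / 1000
  if (p_win <= 0 || nrow(fib) == 0L) return(out)
  if (p_win > 1) {
    stop("background_msp_rate too high for the 200-bp window scheme ",
         "(max 5 per kb)", call. = FALSE)
  }
  nwin <- as.integer((fib$end - fib$start) %/% win)
  cnt <- rbinom(nrow(fib), nwin, p_win)
  fidx <- rep(seq_len(nrow(fib)), cnt)
  if (!length(fidx)) return(out)
  wi <- floor(runif(length(fidx)) * nwin[fidx])
  keep <- !duplicated(fidx * (max(nwin) + 1) + wi)
  fidx <- fidx[keep]
  wi <- wi[keep]
  wdt <- 50 + floor(runif(length(fidx)) * 101)
  off <- floor(runif(length(fidx)) * (win - wdt + 1))
  bs <- fib$start[fidx] + wi * win + off
  be <- bs + wdt
  prec <- runif(length(fidx), model$background_precision[1],
                model$background_precision[2])
  if (nrow(model$elements)) {
    ov <- overlap_join(fib$chrom[fidx], bs, be, model$elements$chrom,
                       model$elements$start, model$elements$end)
    if (nrow(ov)) {
      drop <- unique(ov$q)
      fidx <- fidx[-drop]; bs <- bs[-drop]; be <- be[-drop]
      prec <- prec[-drop]
    }
  }
  tibble::tibble(fiber_id = fib$fiber_id[fidx], start = bs, end = be,
                 precision = prec)
}

#' Simulate per-fiber CpG methylation calls
#'
#' Emits one call per (fiber, overlapped CpG site). Methylation is
#' Bernoulli with the site's haplotype baseline, overridden by the
#' silencing spec's `silenced_methylation` for silenced cell-haplotypes
#' (promoter hypermethylation coupled to silencing, as in transcriptional
#' readthrough scenarios). Requires the in-memory fiber set from
#' [simulate_fibers()] since the cell identities and silencing states are
#' simulation metadata, not part of the fiber-table file contract.
#'
#' @param model The [genome_model()] the fibers were simulated from.
#' @param fibers [fiber_set] returned by [simulate_fibers()].
#' @param seed Integer seed.
#' @return Tibble of CpG calls (`chrom`, `pos`, `fiber_id`, `haplotype`,
#'   `methylated`).
#' @export
simulate_cpg <- function(model, fibers, seed) {
  stopifnot(inherits(model, "genome_model"))
  fibers <- as_fiber_set(fibers)
  fib <- fibers$fibers
  states <- attr(fibers, "silencing_states")
  if (is.null(states) || !all(c("cell", "hap_true") %in% names(fib))) {
    stop("simulate_cpg needs the fiber_set produced by simulate_fibers ",
         "(with cell/hap_true metadata)", call. = FALSE)
  }
  if (nrow(fib) && any(!fib$chrom %in% names(model$chrom_sizes))) {
    stop("fibers reference a chromosome missing from the model",
         call. = FALSE)
  }
  sites <- model$cpg_sites
  empty <- tibble::tibble(chrom = character(), pos = numeric(),
                          fiber_id = character(), haplotype = character(),
                          methylated = logical())
  if (!nrow(sites) || !nrow(fib)) return(empty)
  withr::with_seed(as.integer(seed), {
    ov <- overlap_join(sites$chrom, sites$pos, sites$pos + 1,
                       fib$chrom, fib$start, fib$end)
    if (!nrow(ov)) return(empty)
    si <- ov$q
    fi <- ov$s
    p <- ifelse(fib$hap_true[fi] == "H1", sites$baseline_h1[si],
                sites$baseline_h2[si])
    sil <- silenced_mask(model, states, fib$cell[fi], fib$hap_true[fi],
                         sites$chrom[si], sites$pos[si], sites$pos[si] + 1,
                         spec_field = "silenced_methylation")
    p[sil$mask] <- sil$value[sil$mask]
    out <- tibble::tibble(chrom = sites$chrom[si], pos = sites$pos[si],
                          fiber_id = fib$fiber_id[fi],
                          haplotype = fib$haplotype[fi],
                          methylated = runif(length(fi)) < p)
    out[order(out$chrom, out$pos, out$fiber_id), ]
  })
}

#' Simulate phased full-length transcript reads
#'
#' Per cell, gene and haplotype, transcript counts are Poisson with the
#' gene's haplotype mean, zeroed when the cell silences that haplotype at
#' the gene's locus. Cells are a fresh draw from the same population as
#' [simulate_fibers()] (no read-level linkage between assays). Reads are
#' tagged `UNASSIGNED` at the model's `unassigned_rate`.
#'
#' @param model A [genome_model()] with `genes` defined.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @return Tibble of transcript reads (`read_id`, `gene_id`, `haplotype`).
#' @export
simulate_transcripts <- function(model, n_cells, seed) {
  stopifnot(inherits(model, "genome_model"), n_cells >= 0)
  genes <- model$genes
  empty <- tibble::tibble(read_id = character(), gene_id = character(),
                          haplotype = character())
  if (!nrow(genes) || n_cells == 0) return(empty)
  withr::with_seed(as.integer(seed), {
    states <- draw_silencing_states(model, n_cells)
    grid <- expand.grid(cell = seq_len(n_cells),
                        gene = seq_len(nrow(genes)),
                        hap = c("H1", "H2"), stringsAsFactors = FALSE)
    lambda <- ifelse(grid$hap == "H1", genes$mean_h1[grid$gene],
                     genes$mean_h2[grid$gene])
    located <- !is.na(genes$chrom[grid$gene])
    if (any(located) && nrow(model$silencing)) {
      sil <- silenced_mask(model, states, grid$cell, grid$hap,
                           ifelse(located, genes$chrom[grid$gene], "?"),
                           ifelse(located, genes$start[grid$gene], 0),
                           ifelse(located, genes$end[grid$gene], 1))
      lambda[located & sil] <- 0
    }
    counts <- rpois(nrow(grid), lambda)
    gi <- rep(grid$gene, counts)
    hap <- rep(grid$hap, counts)
    n <- length(gi)
    if (!n) return(empty)
    obs <- ifelse(runif(n) < model$unassigned_rate, "UNASSIGNED", hap)
    tibble::tibble(read_id = sprintf("r%07d", seq_len(n)),
                   gene_id = genes$gene_id[gi], haplotype = obs)
  })
}
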