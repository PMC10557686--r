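#' Run the full haplotype-resolved fiber analysis pipeline
#'
#' Config-driven end-to-end execution: simulate (or read) fibers, CpG
#' calls and transcripts; compute the aggregate FIRE signal and call
#' Bonferroni peaks; test every peak for haplotype-specific
#' accessibility; scan for co-dependency around an anchor element; run
#' the regional allelic-imbalance report; test region methylation; and
#' test allele-specific expression. All stage outputs are plain-text
#' (TSV/BED/bedGraph/JSON) under `outdir`, and a `manifest.json` records
#' the package version, seed, config hash, per-stage row counts and the
#' md5 of every output, so two runs with the same config and seed are
#' byte-identical.
#'
#' See `system.file("extdata", "demo_config.yaml", package = "fiberhap")`
#' for the documented config schema.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param outdir Output directory (overrides the config's `outdir`).
#' @param seed Integer seed (overrides the config's `seed`).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  counts <- list()

  # --- inputs: simulate or read -------------------------------------
  if (!is.null(cfg$inputs)) {
    for (p in unlist(cfg$inputs)) {
      if (!file.exists(p)) stop("missing input: ", p, call. = FALSE)
    }
    fs <- read_fiber_table(cfg$inputs$fiber_table)
    cpg <- if (!is.null(cfg$inputs$cpg_table))
      read_cpg_table(cfg$inputs$cpg_table) else NULL
    reads <- if (!is.null(cfg$inputs$transcript_table))
      read_transcript_table(cfg$inputs$transcript_table) else NULL
    model <- NULL
  } else {
    model <- config_model(cfg$model)
    fs <- simulate_fibers(model, cfg$simulate$n_cells,
                          cfg$simulate$coverage_per_hap, cfg$seed)
    cpg <- simulate_cpg(model, fs, cfg$seed + 1L)
    reads <- simulate_transcripts(model, cfg$simulate$n_cells,
                                  cfg$seed + 2L)
    write_fiber_table(fs, out("fibers.tsv"))
    write_cpg_table(cpg, out("cpg_calls.tsv"))
    write_transcript_table(reads, out("transcripts.tsv"))
    truth <- model$elements
    write_bed(tibble::tibble(chrom = truth$chrom, start = truth$start,
                             end = truth$end, peak_id = truth$element_id),
              out("truth_elements.bed"))
    if (nrow(model$silencing)) {
      sil <- model$silencing
      write_bed(tibble::tibble(chrom = sil$chrom, start = sil$start,
                               end = sil$end,
                               peak_id = sprintf("silenced_%s_f%g",
                                                 sil$haplotype,
                                                 sil$fraction)),
                out("truth_silencing.bed"))
    }
  }
  counts$fibers <- n_fibers(fs)

  # --- aggregate signal + peak calling ------------------------------
  sizes <- if (!is.null(model)) model$chrom_sizes else
    vapply(split(fs$fibers$end, fs$fibers$chrom), max, numeric(1))
  genome_size <- if (!is.null(cfg$fire$genome_size)) cfg$fire$genome_size
    else sum(sizes)
  thr <- peak_score_threshold(cfg$fire$alpha, genome_size)
  peak_list <- list()
  for (ch in names(sizes)) {
    tr <- aggregate_fire_signal(fs, ch, 0, sizes[[ch]])
    write_bedgraph(tr, out(sprintf("signal_%s.bedGraph", ch)))
    peak_list[[ch]] <- call_fire_peaks(tr, thr, cfg$fire$merge_gap)
  }
  peaks <- dplyr::bind_rows(peak_list)
  write_bed(peaks, out("peaks.bed"))
  counts$peaks <- nrow(peaks)

  # --- haplotype-specific accessibility -----------------------------
  hap_counts <- peak_haplotype_counts(fs, peaks,
                                      cfg$hap_test$min_precision)
  hap_res <- suppressMessages(
    haplotype_specific_accessibility(hap_counts, cfg$hap_test$fdr_level,
                                     cfg$hap_test$nominal_p))
  readr::write_tsv(hap_res, out("hap_tests.tsv"), progress = FALSE)
  counts$hap_tests <- nrow(hap_res)

  # --- co-dependency scan around the anchor -------------------------
  if (!is.null(cfg$codependency)) {
    anchor <- resolve_anchor(cfg$codependency$anchor, model, peaks)
    cand <- peaks[peaks$chrom == anchor$chrom &
                    !(peaks$start < anchor$end &
                        anchor$start < peaks$end), , drop = FALSE]
    codep <- codependency_scan(fs, anchor, cand,
                               cfg$codependency$min_precision,
                               cfg$codependency$min_span)
    readr::write_tsv(codep, out("codependency.tsv"), progress = FALSE)
    counts$codependency <- nrow(codep)
  }

  # --- regional allelic imbalance -----------------------------------
  if (!is.null(cfg$imbalance)) {
    regions <- dplyr::bind_rows(lapply(cfg$imbalance$regions,
                                       tibble::as_tibble))
    imb <- genome_imbalance_report(
      fs, peaks, regions, cfg$imbalance$min_precision,
      cfg$imbalance$min_reads, cfg$imbalance$sd_mult,
      as.character(cfg$imbalance$exclude_chroms %||% character()))
    readr::write_tsv(imb$results, out("imbalance.tsv"), progress = FALSE)
    readr::write_tsv(imb$peak_deltas, out("imbalance_peak_deltas.tsv"),
                     progress = FALSE)
    counts$imbalance_regions <- nrow(imb$results)
  }

  # --- methylation --------------------------------------------------
  if (!is.null(cpg) && nrow(cpg)) {
    pile <- cpg_pileup(cpg)
    readr::write_tsv(pile, out("cpg_pileup.tsv"), progress = FALSE)
    counts$cpg_sites <- nrow(pile)
    if (!is.null(cfg$methylome$regions)) {
      mrows <- lapply(cfg$methylome$regions, function(r) {
        res <- region_methylation_test(cpg, r, cfg$methylome$min_sites,
                                       cfg$methylome$unit)
        tibble::tibble(name = r$name, chrom = r$chrom, start = r$start,
                       end = r$end, delta_pct = res$delta_pct,
                       p_value = res$p_value, n_sites = res$n_sites)
      })
      readr::write_tsv(dplyr::bind_rows(mrows),
                       out("methylation_tests.tsv"), progress = FALSE)
    }
  }

  # --- allele-specific expression -----------------------------------
  if (!is.null(reads) && nrow(reads)) {
    ase <- allele_specific_expression(reads)
    readr::write_tsv(ase, out("ase.tsv"), progress = FALSE)
    counts$ase_genes <- nrow(ase)
  }

  # --- manifest ------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$outdir), "manifest.json"))
  manifest <- list(
    package = "fiberhap",
    version = as.character(utils::packageVersion("fiberhap")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    row_counts = counts,
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(cfg$outdir, files))), files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Schema validation: fail before any stage runs.
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "fiberhap_out"
  if (is.null(cfg$inputs) && is.null(cfg$model)) {
    stop("config needs either 'inputs' paths or a 'model' to simulate",
         call. = FALSE)
  }
  cfg$simulate <- cfg$simulate %||% list()
  cfg$simulate$n_cells <- cfg$simulate$n_cells %||% 50L
  cfg$simulate$coverage_per_hap <- cfg$simulate$coverage_per_hap %||% 1
  cfg$fire <- cfg$fire %||% list()
  cfg$fire$alpha <- cfg$fire$alpha %||% 0.01
  cfg$fire$merge_gap <- cfg$fire$merge_gap %||% 0
  if (cfg$fire$alpha <= 0 || cfg$fire$alpha >= 1) {
    stop("config: fire$alpha must lie in (0, 1)", call. = FALSE)
  }
  cfg$hap_test <- cfg$hap_test %||% list()
  cfg$hap_test$min_precision <- cfg$hap_test$min_precision %||% 0.90
  cfg$hap_test$fdr_level <- cfg$hap_test$fdr_level %||% 0.05
  cfg$hap_test$nominal_p <- cfg$hap_test$nominal_p %||% 0.01
  if (!is.null(cfg$codependency)) {
    cfg$codependency$min_precision <-
      cfg$codependency$min_precision %||% 0.95
    cfg$codependency$min_span <- cfg$codependency$min_span %||% 10
  }
  if (!is.null(cfg$imbalance)) {
    cfg$imbalance$min_precision <- cfg$imbalance$min_precision %||% 0.90
    cfg$imbalance$min_reads <- cfg$imbalance$min_reads %||% 10
    cfg$imbalance$sd_mult <- cfg$imbalance$sd_mult %||% 3
  }
  cfg$methylome <- cfg$methylome %||% list()
  cfg$methylome$unit <- cfg$methylome$unit %||% "fiber"
  cfg$methylome$min_sites <- cfg$methylome$min_sites %||% 3
  for (field in c("min_precision")) {
    for (sec in c("hap_test", "codependency", "imbalance")) {
      v <- cfg[[sec]][[field]]
      if (!is.null(v) && (v < 0 || v > 1)) {
        stop(sprintf("config: %s$%s must lie in [0, 1]", sec, field),
             call. = FALSE)
      }
    }
  }
  if (cfg$hap_test$fdr_level <= 0 || cfg$hap_test$fdr_level >= 1) {
    stop("config: hap_test$fdr_level must lie in (0, 1)", call. = FALSE)
  }
  cfg
}

# Build a genome_model from the config's `model` section.
config_model <- function(m) {
  cpg_sites <- NULL
  if (!is.null(m$cpg_regions)) {
    cpg_sites <- dplyr::bind_rows(lapply(m$cpg_regions, function(r) {
      pos <- seq(r$start, r$end - 1, by = r$spacing %||% 20)
      tibble::tibble(chrom = r$chrom, pos = pos,
                     baseline_h1 = r$baseline_h1,
                     baseline_h2 = r$baseline_h2)
    }))
  }
  genome_model(
    chrom_sizes = unlist(m$chrom_sizes),
    elements = if (!is.null(m$elements))
      dplyr::bind_rows(lapply(m$elements, function(e)
        do.call(element_spec, e))) else NULL,
    cpg_sites = cpg_sites,
    silencing = if (!is.null(m$silencing))
      dplyr::bind_rows(lapply(m$silencing, function(s)
        do.call(silencing_spec, s))) else NULL,
    genes = if (!is.null(m$genes))
      dplyr::bind_rows(lapply(m$genes, tibble::as_tibble)) else NULL,
    fiber_length_mean = m$fiber_length_mean %||% 15000,
    fiber_length_sd = m$fiber_length_sd %||% 3000,
    background_msp_rate = m$background_msp_rate %||% 1,
    unassigned_rate = m$unassigned_rate %||% 0.05,
    locus_merge_gap = m$locus_merge_gap %||% 5000)
}

# Anchor may be a truth element id (when simulating) or an interval list.
resolve_anchor <- function(anchor, model, peaks) {
  if (is.character(anchor)) {
    if (is.null(model)) {
      stop("anchor by element id requires a simulated model", call. = FALSE)
    }
    i <- match(anchor, model$elements$element_id)
    if (is.na(i)) stop("unknown anchor element '", anchor, "'",
                       call. = FALSE)
    list(chrom = model$elements$chrom[i], start = model$elements$start[i],
         end = model$elements$end[i], peak_id = anchor)
  } else {
    anchor
  }
}
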