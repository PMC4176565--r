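# End-to-end orchestration: a validated run configuration, stage-tagged
# logging, standard-format outputs per stage, and a JSON manifest that
# suffices to reproduce a run.

RUN_PARAM_DEFAULTS <- list(
  min_len = 80L, threshold = 0.4, halfwidth = 600L, k = 6L,
  iterations = 10000L, restarts = 10L, motif = "RTAAAYA",
  sep_min = 60L, sep_max = 120L, proximal_max = 50L,
  window = 1000L, footprint = 147L, smoothing_level = 3L, max_dist = 150L)

#' Build a pipeline run configuration
#'
#' Either synthetic mode (a [sim_config()] generates all inputs) or file mode
#' (paths to a genome FASTA, gene GFF3, origin TSV and read BEDs). Analysis
#' parameters default to the pipeline's standard constants (NDR rule 80 bp /
#' 0.4, window half-width 600 bp, k = 6 with a 10,000-iteration budget,
#' motif RTAAAYA with 60-120 bp dual-site separation, 1000-bp copy-number
#' smoothing, 147-bp footprint). Unknown parameter names are rejected.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param sim a [sim_config()] (synthetic mode). Its seed is overridden by
#'   `seed`.
#' @param paths named list for file mode: `genome`, `genes`, `origins`,
#'   `reads_g1`, and optionally `reads_s`, `naked_g1`, `naked_s`.
#' @param params named list overriding analysis parameters.
#' @param seed integer seed for every stochastic stage.
#' @param write_reads write sampled reads as BED in synthetic mode.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"), sim = sim_config(),
                       paths = list(), params = list(), seed = 1L,
                       write_reads = FALSE) {
  mode <- match.arg(mode)
  unknown <- setdiff(names(params), names(RUN_PARAM_DEFAULTS))
  assert_that(length(unknown) == 0,
              paste0("unknown parameter key(s): ", paste(unknown, collapse = ", ")))
  p <- utils::modifyList(RUN_PARAM_DEFAULTS, params)
  assert_that(p$min_len >= 1 && p$threshold > 0 && p$halfwidth > 0 && p$k >= 1 &&
                p$iterations >= 1 && p$restarts >= 1 && p$sep_min <= p$sep_max &&
                p$window >= 1 && p$footprint > 0 && p$smoothing_level >= 1,
              "parameter out of documented bounds")
  if (mode == "files") {
    need <- c("genome", "genes", "origins", "reads_g1")
    missing_paths <- setdiff(need, names(paths))
    assert_that(length(missing_paths) == 0,
                paste0("file mode needs path(s): ", paste(missing_paths, collapse = ", ")))
    unknown_paths <- setdiff(names(paths),
                             c(need, "reads_s", "naked_g1", "naked_s"))
    assert_that(length(unknown_paths) == 0,
                paste0("unknown path key(s): ", paste(unknown_paths, collapse = ", ")))
  } else {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
  }
  structure(list(mode = mode, sim = sim, paths = paths, params = p,
                 seed = as.integer(seed), write_reads = isTRUE(write_reads)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys: `mode`, `seed`, `write_reads`, `params` (analysis
#' parameters), `sim` (synthetic-generator fields) and `paths` (file mode).
#' Unknown keys at any level are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), c("mode", "seed", "write_reads", "params", "sim", "paths"))
  assert_that(length(unknown) == 0,
              paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else sim_config()
  run_config(mode = y$mode %||% "synthetic", sim = sim,
             paths = y$paths %||% list(), params = y$params %||% list(),
             seed = y$seed %||% 1L, write_reads = y$write_reads %||% FALSE)
}

log_stage <- function(stage, msg, quiet = FALSE) {
  if (!quiet) message("[", stage, "] ", msg)
}

#' Run the full origin-chromatin pipeline
#'
#' Executes simulation (or input reading), coverage building, positioning-
#' profile construction, nucleosome and NDR calling, origin-architecture
#' clustering, timing composition, intergenic-context classification,
#' Forkhead-motif analysis and, when an S sample is present, the
#' replication-dynamics stage. Every product is written to `outdir` in
#' standard formats together with a JSON manifest of versions, seed and
#' parameters. Any stage error aborts with the stage name and removes the
#' partial outputs. Deterministic for a fixed seed.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress stage logging.
#' @return (invisibly) a named list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  fail <- function(stage, e) {
    unlink(written)
    rlang::abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  p <- config$params
  res <- list()

  stage("io", {
    if (config$mode == "synthetic") {
      log_stage("io", "generating synthetic genome and annotations", quiet)
      sim <- generate_genome_and_annotations(config$sim)
      genome <- sim$genome; genes <- sim$genes; origins <- sim$origins
      emit("genome.fa", function(f) write_genome_fasta(genome, f))
      emit("genes.gff3", function(f) write_gff_genes(genes, f))
      emit("origins.tsv", function(f) write_origin_table(origins, f))
      emit("architecture_truth.tsv", function(f)
        readr::write_tsv(dplyr::select(sim$architecture, -"dyads", -"fkh_offsets"), f,
                         progress = FALSE))
      starts_g1 <- sample_mononucleosome_reads(sim, "G1")
      starts_s <- sample_mononucleosome_reads(sim, "S")
      naked_g1 <- sample_naked_reads(sim, "G1")
      naked_s <- sample_naked_reads(sim, "S")
      if (config$write_reads) {
        emit("reads_g1.bed", function(f)
          write_bed_reads(start_track_to_reads(starts_g1, config$sim$read_length), f))
        emit("reads_s.bed", function(f)
          write_bed_reads(start_track_to_reads(starts_s, config$sim$read_length), f))
      }
      res$sim <- sim
    } else {
      log_stage("io", "reading inputs", quiet)
      genome <- read_genome_fasta(config$paths$genome)
      genes <- read_gff_genes(config$paths$genes)
      origins <- read_origin_table(config$paths$origins, genome)
      lens <- chrom_lengths(genome)
      starts_g1 <- reads_to_start_track(read_bed_reads(config$paths$reads_g1), lens)
      starts_s <- if (!is.null(config$paths$reads_s))
        reads_to_start_track(read_bed_reads(config$paths$reads_s), lens) else NULL
      naked_g1 <- if (!is.null(config$paths$naked_g1))
        reads_to_start_track(read_bed_reads(config$paths$naked_g1), lens) else NULL
      naked_s <- if (!is.null(config$paths$naked_s))
        reads_to_start_track(read_bed_reads(config$paths$naked_s), lens) else NULL
    }
    res$genome <- genome; res$genes <- genes; res$origins <- origins
    res$starts <- list(g1 = starts_g1, s = starts_s,
                        naked_g1 = naked_g1, naked_s = naked_s)
  })

  stage("coverage", {
    log_stage("coverage", "building normalized fragment coverage", quiet)
    res$coverage_g1 <- normalize_by_genome_mean(
      starts_to_raw_coverage(res$starts$g1, extension = p$footprint))
    emit("coverage_g1.bedgraph", function(f) write_bedgraph(res$coverage_g1, f))
  })

  stage("nucleosome_calling", {
    log_stage("nucleosome_calling", "boundary peaks, spacing, calls, combined profile", quiet)
    peaks <- boundary_peaks(res$starts$g1, smoothing_level = p$smoothing_level)
    spacing <- estimate_average_spacing(peaks)
    res$spacing <- spacing
    res$calls <- call_nucleosomes(res$starts$g1, spacing,
                                   smoothing_level = p$smoothing_level)
    res$profile_g1 <- combined_profile(res$starts$g1, spacing,
                                        smoothing_level = p$smoothing_level)
    emit("nucleosome_calls.bed", function(f) write_nucleosome_bed(res$calls, f))
    emit("profile_g1.bedgraph", function(f) write_bedgraph(res$profile_g1, f))
  })

  stage("ndr", {
    log_stage("ndr", paste0("calling NDRs (min_len=", p$min_len,
                            ", threshold=", p$threshold, ")"), quiet)
    ndrs <- call_ndrs(res$coverage_g1, min_len = p$min_len, threshold = p$threshold)
    assoc <- associate_ndrs_with_origins(ndrs, res$origins, max_dist = p$max_dist)
    res$ndrs <- assoc
    res$ndr_widths <- origin_ndr_width(res$origins, assoc$origin_ndrs)
    emit("ndrs.bed", function(f)
      write_ndr_bed(dplyr::bind_rows(assoc$origin_ndrs, assoc$nonorigin_ndrs), f))
    emit("ndr_widths.tsv", function(f) readr::write_tsv(res$ndr_widths, f, progress = FALSE))
  })

  stage("origin_architecture", {
    log_stage("origin_architecture", paste0("clustering origin windows (k=", p$k, ")"), quiet)
    mat <- origin_profile_matrix(res$profile_g1, res$origins, halfwidth = p$halfwidth)
    widths <- stats::setNames(res$ndr_widths$ndr_width, res$ndr_widths$name)
    classes <- cluster_origin_profiles(mat, widths[rownames(mat)], k = p$k,
                                       iterations = p$iterations,
                                       restarts = p$restarts, seed = config$seed)
    res$profile_matrix <- mat
    res$classes <- classes
    res$timing_composition <- class_timing_composition(classes, res$origins)
    emit("profile_matrix.tsv", function(f)
      readr::write_tsv(tibble::as_tibble(mat, rownames = "name"), f, progress = FALSE))
    emit("class_assignment.tsv", function(f)
      readr::write_tsv(classes$assignment, f, progress = FALSE))
    emit("class_timing.tsv", function(f)
      readr::write_tsv(res$timing_composition, f, progress = FALSE))
  })

  stage("genomic_context", {
    log_stage("genomic_context", "IGR classification and origin context", quiet)
    igrs <- build_igrs(res$genes)
    cats <- origin_igr_category(res$origins, igrs)
    res$igrs <- igrs
    res$igr_enrichment <- category_enrichment(cats)
    emit("igrs.bed", function(f) write_igr_bed(igrs, f))
    emit("igr_summary.tsv", function(f)
      readr::write_tsv(res$igr_enrichment, f, progress = FALSE))
  })

  stage("motifs", {
    log_stage("motifs", paste0("scanning ", p$motif, " and dual-site configurations"), quiet)
    hits <- scan_motif(res$genome, p$motif)
    res$motif_hits <- hits
    res$motif_density <- motif_density_profile(hits, res$origins,
                                                halfwidth = p$halfwidth)
    res$dual_site_fraction <- fraction_with_configuration(
      res$origins, hits, proximal_max = p$proximal_max,
      sep_min = p$sep_min, sep_max = p$sep_max, halfwidth = p$halfwidth)
    emit("motif_hits.bed", function(f)
      write_motif_bed(hits, f, width = nchar(p$motif)))
    emit("motif_density.tsv", function(f)
      readr::write_tsv(res$motif_density, f, progress = FALSE))
    emit("dual_site.tsv", function(f)
      readr::write_tsv(tibble::tibble(group = "early",
                                      fraction = res$dual_site_fraction), f,
                       progress = FALSE))
  })

  if (!is.null(res$starts$s)) {
    stage("replication_dynamics", {
      log_stage("replication_dynamics", "S-vs-G1 differential and copy-number correction", quiet)
      cov_s <- normalize_by_genome_mean(
        starts_to_raw_coverage(res$starts$s, extension = p$footprint))
      diff <- differential_track(cov_s, res$coverage_g1)
      res$differential <- diff
      emit("differential.bedgraph", function(f) write_bedgraph(diff, f))
      res$replicated_extent <- tibble::tibble(
        name = res$origins$name, timing = res$origins$timing,
        extent = vapply(seq_len(nrow(res$origins)), function(i)
          replicated_extent(diff, res$origins[i, ], window = p$window), 0L))
      emit("replicated_extent.tsv", function(f)
        readr::write_tsv(res$replicated_extent, f, progress = FALSE))
      if (!is.null(res$starts$naked_s)) {
        corr <- copy_number_correct(
          starts_to_raw_coverage(res$starts$s, extension = p$footprint),
          starts_to_raw_coverage(res$starts$naked_s, extension = p$footprint),
          window = p$window)
        res$corrected_s <- corr
      }
      peaks_s <- boundary_peaks(res$starts$s, smoothing_level = p$smoothing_level)
      spacing_s <- estimate_average_spacing(peaks_s)
      prof_s <- combined_profile(res$starts$s, spacing_s,
                                 smoothing_level = p$smoothing_level)
      mat_s <- origin_profile_matrix(prof_s, res$origins, halfwidth = p$halfwidth)
      res$shift_report <- origin_shift_report(res$profile_matrix, mat_s,
                                               res$origins, threshold = p$threshold)
      emit("shift_report.tsv", function(f)
        readr::write_tsv(res$shift_report, f, progress = FALSE))
    })
  }

  stage("manifest", {
    manifest <- list(
      package = "orichrom",
      version = as.character(utils::packageVersion("orichrom")),
      mode = config$mode,
      seed = config$seed,
      parameters = p,
      sim = if (config$mode == "synthetic")
        config$sim[setdiff(names(config$sim), "class_table")] else NULL,
      outputs = sort(basename(written)))
    emit("manifest.json", function(f)
      jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE, digits = NA))
  })

  log_stage("done", paste0(length(written), " file(s) in ", outdir), quiet)
  invisible(res)
}
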