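# End-to-end pipeline: validated configuration, staged reports, manifest.

#' Build and validate a pipeline run configuration
#'
#' All paths and numeric settings are validated up front, before any
#' computation. The configuration is serialized alongside the outputs for
#' provenance.
#'
#' @param fasta Path to the barcode FASTA (all batches together).
#' @param out_dir Output directory.
#' @param meta Optional metadata TSV (specimen_id, batch, site, habitat);
#'   required for the completeness stage.
#' @param morph Optional morphospecies TSV; required for the congruence
#'   stage.
#' @param thresholds Clustering thresholds (fractions; default 2-5%).
#' @param stability_grid Stability grid (default 1-3% in 0.5% steps); its
#'   maximum is the base threshold for LIT.
#' @param coverage_threshold Threshold for the completeness stage (default
#'   0.05).
#' @param expected_length Optional enforced sequence length.
#' @param min_overlap Minimum compared sites per pair (default 100).
#' @param genetic_code,frame_policy Stop-codon filter settings (see
#'   [qc_stop_codons()]); `frame_policy = "none"` skips the filter.
#' @param main_min_count Main-haplotype rule for [examination_plan()].
#' @param reps,seed Randomization settings for [randomization_test()].
#' @param verbose Emit progress messages to stderr.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(fasta, out_dir, meta = NULL, morph = NULL,
                       thresholds = c(0.02, 0.03, 0.04, 0.05),
                       stability_grid = c(0.01, 0.015, 0.02, 0.025, 0.03),
                       coverage_threshold = 0.05,
                       expected_length = NULL, min_overlap = 100L,
                       genetic_code = "5",
                       frame_policy = "any",
                       main_min_count = 2L,
                       reps = 100L, seed = 1L, verbose = TRUE) {
  if (!file.exists(fasta)) stop("fasta not found: ", fasta)
  for (f in c(meta, morph)) if (!file.exists(f)) stop("file not found: ", f)
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0 & thresholds < 1),
            !is.unsorted(stability_grid),
            all(stability_grid > 0 & stability_grid < 1),
            coverage_threshold > 0, coverage_threshold < 1,
            min_overlap >= 1L, reps >= 2L)
  structure(list(fasta = fasta, out_dir = out_dir, meta = meta,
                 morph = morph, thresholds = sort(thresholds),
                 stability_grid = stability_grid,
                 base_threshold = max(stability_grid),
                 coverage_threshold = coverage_threshold,
                 expected_length = expected_length,
                 min_overlap = as.integer(min_overlap),
                 genetic_code = genetic_code, frame_policy = frame_policy,
                 main_min_count = as.integer(main_min_count),
                 reps = as.integer(reps), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

pipeline_log <- function(config, ...) {
  if (config$verbose) message("[litmotu] ", ...)
}

write_tsv_out <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the computational stages in order: read + validate barcodes,
#' stop-codon QC, p-distance matrix, objective clustering at every
#' configured threshold, LIT stability classes and examination plan at the
#' base threshold, congruence + conflict resolution (if a morphospecies
#' table is configured), and batch-2 coverage with the randomization null
#' (if the metadata assigns batches 1 and 2). Stages whose inputs are not
#' configured are skipped with a logged notice. All outputs are written with
#' stable ordering, so re-running an identical configuration reproduces
#' byte-identical files; `manifest.json` lists every output with an MD5
#' checksum plus the configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`records`, `qc`,
#'   `pd`, `partitions`, `profile`, `stability`, `plan`, `congruence`,
#'   `resolution`, `coverage`, `randomization`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv_out(df, path)
    outputs <<- c(outputs, path)
  }

  pipeline_log(config, "reading barcodes from ", config$fasta)
  records <- read_barcode_fasta(config$fasta, config$expected_length)
  if (!is.null(config$meta)) records <- join_metadata(records, config$meta)

  qc <- NULL
  if (!identical(config$frame_policy, "none")) {
    qc <- qc_stop_codons(records, config$genetic_code, config$frame_policy)
    pipeline_log(config, nrow(qc$fail), " barcode(s) failed the stop-codon ",
                 "filter")
    if (nrow(qc$fail) > 0L)
      emit(qc$fail[, c("specimen_id", "stop_frames")], "qc_failed.tsv")
    records <- qc$pass
    if (nrow(records) < 2L) stop("stage qc: fewer than 2 barcodes left")
  }

  pipeline_log(config, "computing p-distances for ", nrow(records),
               " specimens")
  pd <- distance_matrix(records, min_overlap = config$min_overlap)

  all_th <- sort(unique(c(config$thresholds, config$stability_grid,
                          config$coverage_threshold)))
  partitions <- cluster_grid(pd, all_th)
  for (t in config$thresholds) {
    p <- partitions[[fmt_threshold(t)]]
    emit(as.data.frame(p), sprintf("motus_%s.tsv", fmt_threshold(t)))
  }
  profile <- threshold_profile(pd, all_th)
  emit(profile, "threshold_profile.tsv")

  pipeline_log(config, "classifying MOTU stability at base threshold ",
               config$base_threshold)
  grid_parts <- partitions[fmt_threshold(config$stability_grid)]
  base <- partitions[[fmt_threshold(config$base_threshold)]]
  stability <- classify_stability(grid_parts, config$base_threshold, pd)
  emit(stability, "stability.tsv")
  plan <- examination_plan(stability, base, pd,
                           main_min_count = config$main_min_count)
  emit(plan, "examination_plan.tsv")

  congruence <- resolution <- NULL
  if (!is.null(config$morph)) {
    pipeline_log(config, "integrating morphospecies labels")
    morph <- read_morphospecies(config$morph)
    morph <- morph[morph$specimen_id %in% records$specimen_id, , drop = FALSE]
    congruence <- congruence_summary(partitions, morph)
    emit(congruence, "congruence_summary.tsv")
    resolution <- resolve_conflicts(partitions, morph, base)
    emit(resolution$statuses, "species_status.tsv")
    emit(resolution$log, "resolution_log.tsv")
    emit(data.frame(specimen_id = names(resolution$species),
                    species = unname(resolution$species)),
         "accepted_species.tsv")
  } else {
    pipeline_log(config, "no morphospecies table; congruence stage skipped")
  }

  coverage <- randomization <- NULL
  batches <- setNames(records$batch, records$specimen_id)
  if (all(c("1", "2") %in% batches)) {
    pipeline_log(config, "assessing batch-2 coverage at threshold ",
                 config$coverage_threshold)
    cov_part <- partitions[[fmt_threshold(config$coverage_threshold)]]
    coverage <- coverage_stats(cov_part, batches)
    emit(data.frame(field = setdiff(names(coverage),
                                    c("new_motus", "abundance")),
                    value = vapply(setdiff(names(coverage),
                                           c("new_motus", "abundance")),
                                   function(f) as.character(coverage[[f]]),
                                   character(1))),
         "coverage.tsv")
    emit(coverage$abundance, "abundance_classes.tsv")
    randomization <- randomization_test(
      cov_part, sizes = c(sum(batches == "1"), sum(batches == "2")),
      n_reps = config$reps, seed = config$seed)
    emit(data.frame(rep = seq_len(randomization$n_reps),
                    motu_coverage = randomization$motu_coverage,
                    specimen_coverage = randomization$specimen_coverage),
         "randomization.tsv")
  } else {
    pipeline_log(config,
                 "metadata does not assign batches 1 and 2; ",
                 "completeness stage skipped")
  }

  manifest <- list(
    package = "litmotu",
    version = as.character(packageVersion("litmotu")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "verbose")],
    outputs = lapply(sort(outputs), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  pipeline_log(config, "done; manifest at ", manifest_path)

  invisible(list(records = records, qc = qc, pd = pd,
                 partitions = partitions, profile = profile,
                 stability = stability, plan = plan,
                 congruence = congruence, resolution = resolution,
                 coverage = coverage, randomization = randomization,
                 manifest = manifest))
}
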