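# End-to-end benchmark pipeline, run configuration and manifest.

#' Default run configuration
#'
#' All published method constants live here: probe length 50,
#' up to 6 probes per cluster, 0.80 clustering identity, Tm target 47 degC,
#' 60\% mapping identity floor, 4 matches per direction, 15 aa overlap
#' tolerance, E threshold 0.001, 630 bp inserts, 300 bp reads, weighted GC
#' targets {47, 50, 53, 57, 60, 63}, 0.90 binning cutoff.
#'
#' @param master_seed master seed; per-stage seeds are derived with
#'   \code{\link{stage_seed}}.
#' @param ... overrides for any config entry.
#' @return object of class \code{run_config} (a named list).
#' @export
run_config <- function(master_seed = 1L, ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    # probe design
    probe_k = 50, max_probes = 6, cluster_threshold = 0.80, tm_target = 47,
    probe_max_mismatch = 5,
    # target database synthesis
    n_codons = 200, n_variants = 8, variant_divergence = 0.10,
    # mock community
    gc_targets = c(47, 50, 53, 57, 60, 63), target_gc = 53,
    # capture
    n_fragments = 20000, mean_insert = 630, sd_insert = 60,
    capture = capture_model(),
    # sequencing
    read_len = 300, error_rate = 0.005,
    # classification
    min_identity = 60, max_per_direction = 4, max_overlap_aa = 15,
    e_threshold = 0.001,
    # evaluation
    bin_cutoff = 0.90
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Run the full benchmark pipeline
#'
#' registry -> synthetic target database -> probe panel -> mock design ->
#' genomes -> fragmentation -> hybridization capture -> paired reads ->
#' six-frame classification -> evaluation. Idempotent under identical
#' config: all stage seeds derive from the master seed.
#'
#' @param config a \code{run_config}.
#' @param out_dir optional output directory; when given, the manifest,
#'   panel, mock design, truth, FASTQ pair and evaluation report are
#'   written there.
#' @param pool strain pool (list with \code{strains}, \code{copies});
#'   default \code{\link{example_mock_pool}} restricted to the registry.
#' @param registry a \code{gene_registry}.
#' @return list with \code{manifest}, \code{panel}, \code{design},
#'   \code{reads}, \code{classification}, \code{evaluation}.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL,
                           pool = NULL, registry = default_registry()) {
  stopifnot(inherits(config, "run_config"))
  ms <- config$master_seed
  stage <- "init"
  result <- tryCatch({
    stage <- "reference"
    fams <- registry$families$name
    ref <- synth_family_sequences(registry,
                                  seed = stage_seed(ms, "reference"),
                                  n_codons = config$n_codons,
                                  n_variants = config$n_variants)
    stage <- "target_db"
    tdb <- dereplicate(ref$variants)
    stage <- "panel"
    panel <- design_panel(tdb, threshold = config$cluster_threshold,
                          k = config$probe_k, max_probes = config$max_probes,
                          tm_target = config$tm_target,
                          max_mismatch = config$probe_max_mismatch)
    stage <- "mock"
    pool <- pool %||% example_mock_pool(registry)
    design <- mock_design(pool$strains, pool$copies,
                          target_gc = config$target_gc,
                          prior = pool$strains$prior)
    stage <- "genomes"
    comm <- synth_community(pool$strains, pool$copies, ref$consensus,
                            seed = stage_seed(ms, "genomes"),
                            divergence = config$variant_divergence)
    stage <- "fragment"
    frags <- fragment_pool(design, comm$genomes, comm$truth,
                           n_fragments = config$n_fragments,
                           mean_len = config$mean_insert,
                           sd_len = config$sd_insert,
                           seed = stage_seed(ms, "fragment"))
    stage <- "capture"
    captured <- hybridize(frags, panel, config$capture,
                          seed = stage_seed(ms, "capture"))
    stage <- "sequence"
    reads <- sequence_reads(captured, read_len = config$read_len,
                            error_rate = config$error_rate,
                            seed = stage_seed(ms, "sequence"))
    stage <- "classify"
    pdb <- protein_db(ref$proteins,
                      family = names(ref$proteins))
    pdb <- calibrate_protein_db(pdb, seed = stage_seed(ms, "calibrate"))
    if (nrow(panel) == 0L) {
      warning("empty probe panel: nothing captured, abundance table empty")
    }
    cls <- classify_reads(reads, pdb, registry,
                          min_identity = config$min_identity,
                          max_per_direction = config$max_per_direction,
                          max_overlap_aa = config$max_overlap_aa,
                          e_threshold = config$e_threshold,
                          total_reads = max(nrow(reads), 1L),
                          families = fams)
    stage <- "evaluate"
    evaluation <- if (sum(cls$abundance$count) > 0 &&
                      sum(cls$abundance$count > 0) >= 3) {
      compare_abundance(design$expected_abundance, cls$abundance)
    } else {
      list(pearson_r = NA_real_, n_families = 0L, table = NULL)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("probecap")),
      master_seed = ms,
      stage_seeds = sapply(c("reference", "genomes", "fragment", "capture",
                             "sequence", "calibrate"),
                           function(s) stage_seed(ms, s)),
      parameters = config[setdiff(names(config), "capture")],
      capture_model = unclass(config$capture),
      families = fams,
      counts = list(target_db = nrow(tdb), probes = nrow(panel),
                    strains = nrow(pool$strains), fragments = nrow(frags),
                    captured = nrow(captured), reads = nrow(reads),
                    annotated_reads = length(unique(cls$annotations$read_id))),
      on_target_fraction = if (nrow(captured)) mean(nzchar(captured$truth))
      else NA_real_,
      pearson_r = evaluation$pearson_r
    )
    list(manifest = manifest, panel = panel, design = design, reads = reads,
         classification = cls, evaluation = evaluation)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(result$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_panel(result$panel, file.path(out_dir, "panel"))
    write_mock_design(result$design, file.path(out_dir, "mock_design"))
    write_fastq_pair(result$reads, file.path(out_dir, "reads"))
    write.table(result$classification$abundance,
                file.path(out_dir, "abundance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(pearson_r = result$evaluation$pearson_r,
           n_families = result$evaluation$n_families,
           table = result$evaluation$table),
      file.path(out_dir, "eval_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  result
}
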