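# End-to-end orchestration: simulate or ingest a cohort, then run burden,
# CNVR, rare-CNV and association stages, writing TSV outputs and a run
# manifest.

write_stage_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cnvcase %s", utils::packageVersion("cnvcase")), con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Either a simulation configuration (cohort generated in-run) or a set of
#' input paths (segment TSVs, manifest, panels), plus the analysis knobs
#' shared by all stages.
#'
#' @param simulation a [simulation_config()], or `NULL` when reading
#'   inputs from disk.
#' @param paths named list of input paths (`cases`, `controls` optional if
#'   `segments` covers both, `manifest`, `panel_freq`, `panel_known`,
#'   `caller2`), or `NULL` when simulating.
#' @param rule an [overlap_rule()] for the rare pipeline.
#' @param probe_thresholds length-2 loss/gain probe minimums applied to
#'   array call sets before analysis (NA probe counts pass).
#' @param ancestry_component ancestry covariate for all adjusted models.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in every output.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(), paths = NULL,
                       rule = overlap_rule(), probe_thresholds = c(25, 50),
                       ancestry_component = "afr", out_dir = tempfile("run"),
                       seed = 1L) {
  if (is.null(simulation) == is.null(paths)) {
    stop("exactly one of simulation / paths must be set", call. = FALSE)
  }
  structure(list(simulation = simulation, paths = paths, rule = rule,
                 probe_thresholds = probe_thresholds,
                 ancestry_component = ancestry_component,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' The YAML mirrors [run_config()] field-for-field; a `simulation` block
#' mirrors [simulation_config()] (with `risk_loci` entries mirroring
#' [risk_locus_spec()]).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sim_args <- y$simulation
    if (!is.null(sim_args$risk_loci)) {
      sim_args$risk_loci <- lapply(sim_args$risk_loci, function(rl) {
        do.call(risk_locus_spec, rl)
      })
    }
    sim <- do.call(simulation_config, sim_args)
  }
  rule <- if (is.null(y$rule)) overlap_rule() else do.call(overlap_rule,
                                                           y$rule)
  run_config(simulation = sim, paths = y$paths, rule = rule,
             probe_thresholds = if (is.null(y$probe_thresholds)) c(25, 50)
             else unlist(y$probe_thresholds),
             ancestry_component = if (is.null(y$ancestry_component)) "afr"
             else y$ancestry_component,
             out_dir = if (is.null(y$out_dir)) tempfile("run") else y$out_dir,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or ingest), burden
#' summaries and case-control burden tests, per-chromosome tests, CNVR
#' construction and per-region tests, the four-step rare-CNV pipeline, and
#' (for simulated cohorts with planted risk loci) the joint two-locus
#' association. Each stage writes a TSV under `out_dir`; the returned
#' manifest records seeds, stage outputs and the rare-pipeline count
#' cascade. Any stage failure halts with a stage-addressed error.
#'
#' @param config a [run_config()].
#' @return run manifest (list): `seed`, `stages` (named list of output
#'   paths), `counts` (rare cascade), `timings` (seconds per stage).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, package_version =
                     as.character(utils::packageVersion("cnvcase")),
                   stages = list(), timings = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }
  out <- function(name) file.path(config$out_dir, name)

  if (!is.null(config$simulation)) {
    config$simulation$seed <- config$seed
    cohort <- stage("simulate", simulate_cohort(config$simulation))
    samples <- cohort$samples
    seg1 <- cohort$segments_caller1
    seg2 <- cohort$segments_caller2
    freq_panel <- cohort$panels$frequency
    known_panel <- cohort$panels$known
    write_stage_tsv(seg1, out("segments_caller1.tsv"), config$seed)
    write_stage_tsv(seg2, out("segments_caller2.tsv"), config$seed)
    write_stage_tsv(samples, out("manifest.tsv"), config$seed)
    write_stage_tsv(cohort$ground_truth$rare_segments,
                    out("ground_truth_rare.tsv"), config$seed)
    write_stage_tsv(cohort$ground_truth$genotypes,
                    out("ground_truth_genotypes.tsv"), config$seed)
  } else {
    p <- config$paths
    cohort <- NULL
    samples <- stage("ingest", read_sample_manifest(p$manifest))
    seg1 <- stage("ingest", read_segments(p$segments))
    seg2 <- stage("ingest", read_segments(p$caller2,
                                          caller_id = "secondary_caller"))
    seg2$caller_id <- "secondary_caller"
    freq_panel <- stage("ingest", read_reference_panel(p$panel_freq))
    known_panel <- stage("ingest", read_reference_panel(p$panel_known))
  }

  burdens <- stage("burden", summarize_burden(seg1, samples))
  write_stage_tsv(burdens$per_sample, out("burden_per_sample.tsv"),
                  config$seed)
  btests <- stage("burden", do.call(rbind, lapply(
    c("n_total", "n_del", "n_dup", "size_del", "size_dup"),
    function(m) compare_burden(burdens, samples, m,
                               config$ancestry_component))))
  write_stage_tsv(btests, out("burden_tests.tsv"), config$seed)
  chrom_tests <- stage("burden", per_chromosome_tests(burdens, samples))
  write_stage_tsv(chrom_tests, out("per_chromosome.tsv"), config$seed)
  hist_tab <- stage("burden", size_range_histogram(seg1))
  write_stage_tsv(hist_tab, out("histogram.tsv"), config$seed)

  cnvrs <- stage("cnvr", build_cnvrs(seg1, samples))
  cnvr_tests <- stage("cnvr", do.call(rbind, lapply(
    seq_len(nrow(cnvrs)),
    function(i) test_cnvr(cnvrs[i, ], samples,
                          config$ancestry_component))))
  write_stage_tsv(cbind(cnvrs[, setdiff(names(cnvrs), "region_id")],
                        cnvr_tests),
                  out("cnvr.tsv"), config$seed)

  case_ids <- samples$sample_id[samples$group == "case"]
  rare <- stage("rare", run_rare_pipeline(
    seg1[seg1$sample_id %in% case_ids, ],
    seg1[!seg1$sample_id %in% case_ids, ],
    freq_panel, known_panel, seg2, rule = config$rule))
  write_stage_tsv(rare$table, out("rare_table.tsv"), config$seed)
  write_stage_tsv(data.frame(step = names(rare$counts),
                             retained = as.integer(rare$counts)),
                  out("rare_steps.tsv"), config$seed)
  manifest$counts <- rare$counts

  if (!is.null(cohort) && nrow(cohort$ground_truth$genotypes)) {
    gt <- cohort$ground_truth$genotypes
    loci <- unique(gt$locus_id)
    if (length(loci) >= 2) {
      a <- gt[gt$locus_id == loci[1], ]
      b <- gt[gt$locus_id == loci[2], ]
      cls <- function(g) ifelse(g == "del", 1L, ifelse(g == "dup", 3L, 2L))
      calls <- copy_number_calls(c(a$sample_id, b$sample_id),
                                 rep(c("A", "B"), c(nrow(a), nrow(b))),
                                 cls(c(a$genotype, b$genotype)), "array")
      jg <- stage("association", joint_genotype(calls, "A", "B"))
      assoc <- stage("association",
                     fit_association(jg, samples,
                                     config$ancestry_component))
      write_stage_tsv(assoc, out("association.tsv"), config$seed)
      write_stage_tsv(genotype_frequency_table(calls, samples),
                      out("genotype_freq.tsv"), config$seed)
    } else {
      message("association stage skipped: fewer than two risk loci")
    }
  } else if (is.null(cohort)) {
    message("association stage skipped: no planted risk loci in ingest mode")
  }

  manifest$stages <- as.list(list.files(config$out_dir, full.names = TRUE))
  manifest$out_dir <- config$out_dir
  manifest
}
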