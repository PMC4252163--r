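#' Assemble a full pipeline configuration
#'
#' Nested configuration for [runPipeline()]. Unknown keys in any block are
#' rejected, and every run writes the fully resolved configuration next to
#' its outputs.
#'
#' @param seed integer seed controlling simulation (when used).
#' @param simulate `NULL` to read inputs from `paths`, or a list of
#'   [simConfig()] arguments (the pipeline seed overrides the generator
#'   seed).
#' @param norm list of [normConfig()] arguments.
#' @param ranking list: `top_k` rows of the ranked DMP table to export
#'   (default 100).
#' @param variance list: `screen_alpha` (default 0.05) and `method`
#'   (`"signed_rank"`/`"rank_sum"`).
#' @param region list: `max_gap`, `min_probes`.
#' @param annotation list: `window`, `max_genes`.
#' @param paths list: `input_dir`/`input_prefix` for pre-existing intensity
#'   tables (see [readIntensityTables()]) and optional `tss_bed`.
#' @return a nested list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, simulate = list(), norm = list(),
                           ranking = list(), variance = list(),
                           region = list(), annotation = list(),
                           paths = list()) {
  mergeBlock <- function(given, defaults, block) {
    bad <- setdiff(names(given), names(defaults))
    stopIfNot(length(bad) == 0, "unknown key(s) in config block '", block,
              "': ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    seed = as.integer(seed),
    simulate = simulate,
    norm = mergeBlock(norm, unclass(normConfig()), "norm"),
    ranking = mergeBlock(ranking, list(top_k = 100L), "ranking"),
    variance = mergeBlock(variance,
                          list(screen_alpha = 0.05, method = "signed_rank"),
                          "variance"),
    region = mergeBlock(region, list(max_gap = 500, min_probes = 3L),
                        "region"),
    annotation = mergeBlock(annotation,
                            list(window = 250000, max_genes = 2L),
                            "annotation"),
    paths = mergeBlock(paths, list(input_dir = NULL, input_prefix = "data",
                                   tss_bed = NULL), "paths"))
  if (!is.null(cfg$simulate)) {
    simArgs <- mergeBlock(cfg$simulate, formals2defaults(simConfig),
                          "simulate")
    simArgs$seed <- cfg$seed
    cfg$simulate <- simArgs
  }
  structure(cfg, class = "PipelineConfig")
}

formals2defaults <- function(f) {
  d <- as.list(formals(f))
  lapply(d, function(x) if (is.language(x)) eval(x) else x)
}

stageLog <- function(quiet, ...) if (!quiet) message("[twindmp] ", ...)

writeResolvedConfig <- function(cfg, path) {
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(unclass(cfg)), path)
  } else {
    utils::capture.output(utils::str(unclass(cfg)), file = path)
  }
  invisible(path)
}

#' Run the full discordant-twin methylation pipeline
#'
#' Stages, in order: (optional) simulation -> sample QC -> probe QC ->
#' monozygosity check -> stratified normalization -> beta computation ->
#' summed-rank DMP ranking (SNP-control probes excluded) -> variance
#' heterogeneity analysis -> region calling -> (optional) nearest-TSS
#' annotation of the top probes. Each stage's outputs are written as TSV
#' under `outDir` before the next stage starts, and per-stage counts are
#' logged so the QC trail is auditable. A fixed seed makes the whole run
#' (simulation included) byte-reproducible.
#'
#' @param cfg a [pipelineConfig()] (or list of its arguments).
#' @param outDir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the key in-memory results:
#'   `data` (post-QC [MethylIntensitySet-class]), `betas`, `design`,
#'   `qcSamples`, `qcProbes`, `monozygosity`, `dmps`, `varianceRecords`,
#'   `varianceSummary`, `meanTest`, `regions`, `annotation` (or NULL),
#'   `truth` (or NULL), plus `outDir`.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir, quiet = FALSE) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- do.call(pipelineConfig, cfg)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeResolvedConfig(cfg, file.path(outDir, "resolved_config.yaml"))
  truth <- NULL

  if (!is.null(cfg$simulate)) {
    stageLog(quiet, "simulate: ", cfg$simulate$nProbes, " probes x ",
             2 * cfg$simulate$nPairs, " samples (seed ", cfg$seed, ")")
    sim <- simulateDataset(do.call(simConfig, cfg$simulate))
    mset <- sim$data; truth <- sim$truth
    writeIntensityTables(mset, file.path(outDir, "simulated_input"))
    utils::write.table(
      data.frame(probe_id = names(truth$trueDelta),
                 true_delta = truth$trueDelta),
      file.path(outDir, "ground_truth_dmps.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stopIfNot(!is.null(cfg$paths$input_dir),
              "either a simulate block or paths$input_dir is required")
    stageLog(quiet, "read: ", cfg$paths$input_dir)
    mset <- readIntensityTables(cfg$paths$input_dir, cfg$paths$input_prefix)
  }
  normCfg <- do.call(normConfig, cfg$norm)
  design <- buildDesign(sampleSheet(mset))
  stageLog(quiet, "input: ", nrow(mset), " probes, ", ncol(mset),
           " samples, ", nPairs(design), " pairs")

  qcS <- filterSamples(mset, normCfg)
  stageLog(quiet, "sample QC: removed ", nrow(qcS$report@samplesRemoved),
           ", retained ", qcS$report@nSamplesRetained)
  qcP <- filterProbes(qcS$data, normCfg)
  stageLog(quiet, "probe QC: removed ", nrow(qcP$report@probesRemoved),
           ", retained ", qcP$report@nProbesRetained)
  mset <- qcP$data
  design <- buildDesign(sampleSheet(mset))
  qcTable <- rbind(
    if (nrow(qcS$report@samplesRemoved))
      cbind(kind = "sample", qcS$report@samplesRemoved) else NULL,
    if (nrow(qcP$report@probesRemoved))
      cbind(kind = "probe", qcP$report@probesRemoved) else NULL)
  if (is.null(qcTable))
    qcTable <- data.frame(kind = character(), id = character(),
                          reason = character())
  writeTsv(qcTable, file.path(outDir, "qc_removals.tsv"))

  rawBetas <- computeBetas(mset, normCfg)
  man <- manifest(mset)
  mz <- tryCatch(checkMonozygosity(rawBetas, man, design),
                 error = function(e) {
                   stageLog(quiet, "monozygosity: skipped (", conditionMessage(e), ")")
                   NULL
                 })
  if (!is.null(mz)) {
    writeTsv(mz, file.path(outDir, "monozygosity.tsv"))
    stageLog(quiet, "monozygosity: ", sum(mz$pass), "/", nrow(mz),
             " pairs pass")
  }

  stageLog(quiet, "normalize: stratified background adjustment + quantile ",
           "normalization")
  mset <- normalizeDasen(mset, normCfg)
  betas <- computeBetas(mset, normCfg)
  writeMatrixTsv(betas, file.path(outDir, "betas.tsv"))

  analysisBetas <- betas[!rownames(betas) %in%
                           man$probe_id[man$is_snp_control], , drop = FALSE]
  stageLog(quiet, "rank: ", nrow(analysisBetas),
           " probes enter the DMP analysis")
  dmps <- rankDmps(analysisBetas, design)
  writeTsv(dmps, file.path(outDir, "dmps_ranked_full.tsv"))
  topK <- utils::head(dmps, cfg$ranking$top_k)
  writeTsv(topK, file.path(outDir, "dmps_top.tsv"))

  varRec <- probeVarianceFTests(analysisBetas, design)
  writeTsv(varRec, file.path(outDir, "variance_per_probe.tsv"))
  varSum <- globalVarianceTest(varRec, cfg$variance$screen_alpha,
                               cfg$variance$method)
  meanTest <- meanMethylationTest(analysisBetas, design)
  writeTsv(data.frame(wilcoxon_stat = varSum$wilcoxon_stat,
                      wilcoxon_p = varSum$wilcoxon_p,
                      prop_higher_affected = varSum$prop_higher_affected,
                      n_screened = varSum$n_screened,
                      mean_methylation_p = meanTest$p_value),
           file.path(outDir, "variance_summary.tsv"))
  stageLog(quiet, "variance: global p = ",
           format(varSum$wilcoxon_p, digits = 3), ", ",
           round(100 * varSum$prop_higher_affected), "% of ",
           varSum$n_screened, " screened probes higher in affected")

  regions <- callRegions(analysisBetas, design, man,
                         cfg$region$max_gap, cfg$region$min_probes)
  writeTsv(regions, file.path(outDir, "regions.tsv"))
  stageLog(quiet, "regions: ", nrow(regions), " called")

  annot <- NULL
  if (!is.null(cfg$paths$tss_bed)) {
    annot <- annotateProbes(topK$probe_id, man, cfg$paths$tss_bed,
                            cfg$annotation$window, cfg$annotation$max_genes)
    writeTsv(annot, file.path(outDir, "top_dmp_annotation.tsv"))
    stageLog(quiet, "annotation: ", nrow(annot), " probe-gene links")
  }

  invisible(list(data = mset, betas = betas, design = design,
                 qcSamples = qcS$report, qcProbes = qcP$report,
                 monozygosity = mz, dmps = dmps, varianceRecords = varRec,
                 varianceSummary = varSum, meanTest = meanTest,
                 regions = regions, annotation = annot, truth = truth,
                 outDir = outDir))
}
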