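# End-to-end orchestration: simulate -> DE -> PSBEG -> peaks -> loops ->
# overlap -> manifest. Every threshold is explicit in the config and echoed
# in the manifest; outputs are plain-text and checksummed, so a rerun with
# the same config and seed is byte-identical.

defaultThresholds <- function() {
  list(q = 0.05, lfc_min = 1.5, min_fraction = 0.20,
       min_reads = 12e6, min_rate = 0.70,
       window_bp = 5e5, flank_bp = 2e6,
       fetal_threshold = 1.0, fetal_fraction = 0.80,
       presence_rule = "all", min_mapped_fraction = 0.95,
       overlap_alpha = 0.05)
}

validateThresholds <- function(th) {
  dom <- list(q = c(0, 1), lfc_min = c(0, Inf), min_fraction = c(0, 1),
              min_reads = c(0, Inf), min_rate = c(0, 1),
              window_bp = c(0, Inf), flank_bp = c(0, Inf),
              fetal_threshold = c(0, Inf), fetal_fraction = c(0, 1),
              min_mapped_fraction = c(0, 1), overlap_alpha = c(0, 1))
  for (k in names(dom)) {
    v <- th[[k]]
    if (!is.numeric(v) || length(v) != 1 || v < dom[[k]][1] ||
        v > dom[[k]][2])
      stopf("threshold '%s' = %s outside its domain [%s, %s]",
            k, format(v), dom[[k]][1], dom[[k]][2])
  }
  if (th$q <= 0 || th$q >= 1) stopf("threshold 'q' must lie in (0, 1)")
  if (!th$presence_rule %in% c("all", "any", "fraction"))
    stopf("presence_rule must be all/any/fraction")
  th
}

#' Read and validate a pipeline configuration
#'
#' YAML with top-level keys \code{seed}, \code{outdir}, \code{simulation}
#' (fields of [simulationConfig()]) and \code{thresholds}. Unknown keys are
#' rejected; every threshold is checked against its domain before any stage
#' runs.
#'
#' @param path YAML path, or a list with the same structure.
#' @return Validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("seed", "outdir", "simulation", "thresholds")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  simKnown <- names(formals(simulationConfig))
  unknownSim <- setdiff(names(cfg$simulation), simKnown)
  if (length(unknownSim))
    stopf("unknown simulation key(s): %s", paste(unknownSim, collapse = ", "))
  th <- utils::modifyList(defaultThresholds(),
                          if (is.null(cfg$thresholds)) list()
                          else cfg$thresholds)
  unknownTh <- setdiff(names(th), names(defaultThresholds()))
  if (length(unknownTh))
    stopf("unknown threshold key(s): %s", paste(unknownTh, collapse = ", "))
  cfg$thresholds <- validateThresholds(th)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate, per-species differential expression, the PSBEG
#' decision tree with the fetal-zone filter, cross-species peak
#' classification, loop-to-promoter assignment and gene-set overlap
#' testing, writing plain-text outputs under the output directory and a
#' manifest (config echo, per-stage relative output paths, md5 checksums).
#' A rerun with the same config and seed reproduces every checksum.
#'
#' @param config a config list or YAML path (see [readPipelineConfig()]).
#' @param outdir output directory (overrides the config's).
#' @return The manifest, invisibly; written as \code{manifest.json}.
#' @export
runPipeline <- function(config, outdir = NULL) {
  cfg <- readPipelineConfig(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) stopf("config must provide an output directory")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  simArgs <- if (is.null(cfg$simulation)) list() else cfg$simulation
  simArgs$seed <- cfg$seed
  simCfg <- do.call(simulationConfig, simArgs)
  outputs <- list()
  put <- function(stage, file) {
    outputs[[stage]] <<- c(outputs[[stage]], file)
    file.path(cfg$outdir, file)
  }

  # stage: simulate
  sim <- runStage("simulate", simulateExpressionStudy(simCfg))
  gen <- runStage("simulate", simulateGenomesAndElements(simCfg))
  fetal <- runStage("simulate", simulateFetalZoneMatrix(simCfg))
  runStage("simulate", {
    for (sp in names(sim$studies)) {
      writeCounts(sim$studies[[sp]],
                  put("simulate", sprintf("counts_%s.tsv", sp)),
                  put("simulate", sprintf("meta_%s.tsv", sp)))
    }
    writeOrthologs(sim$orthologs, put("simulate", "orthologs.tsv"))
    writeBed(gen$refPeaks, put("simulate", "reference_peaks.bed"))
    writeBed(gen$recnes, put("simulate", "recnes.bed"))
    for (sp in names(gen$maps))
      writeBlockMap(gen$maps[[sp]],
                    put("simulate", sprintf("blockmap_%s.tsv", sp)))
    writeLoops(gen$loops, put("simulate", "loops.bedpe"))
    writeGeneAnnotation(gen$genes$primateA, put("simulate", "genes.tsv"))
    truth <- list(truePsbegIds = sim$groundTruth$truePsbegIds,
                  truePeakClass = as.list(gen$groundTruth$truePeakClass),
                  elementToGene = as.list(gen$groundTruth$elementToGene))
    jsonlite::write_json(truth, put("simulate", "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  # stage: differential expression per species
  de <- runStage("de", {
    lapply(sim$studies, function(study) {
      study <- qcFilterSamples(study, th$min_reads, th$min_rate)
      study <- filterLowExpression(study, th$min_fraction)
      screen <- covariateScreen(study)
      brainVsNonbrainDE(study,
                        covariates = screen$covariate[screen$flagged],
                        q = th$q, lfcMin = th$lfc_min)
    })
  })
  runStage("de", {
    for (sp in names(de)) {
      tab <- data.frame(gene_id = rownames(de[[sp]]),
                        as.data.frame(de[[sp]]))
      write.table(tab, put("de", sprintf("de_%s.tsv", sp)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  })

  # stage: PSBEG decision tree + fetal filter
  report <- runStage("psbeg", {
    summaries <- lapply(sim$studies, organSummary)
    runPsbegPipeline(de, summaries, sim$orthologs,
                     roles = c(reference = "primateA",
                               comparator = "primateB",
                               nonprimate = "nonprimate",
                               outgroup = "outgroup"))
  })
  fetalPass <- runStage("psbeg",
    fetalZoneFilter(fetal$fpkmHuman, fetal$fpkmMouse, finalSet(report),
                    threshold = th$fetal_threshold,
                    fraction = th$fetal_fraction))
  runStage("psbeg", {
    jsonlite::write_json(
      list(candidate_set = candidateSet(report),
           final_set = finalSet(report),
           experimental_subset = experimentalSubset(report),
           fetal_zone_pass = fetalPass),
      put("psbeg", "psbeg_report.json"), pretty = TRUE)
    write.table(as.data.frame(auditTrail(report)),
                put("psbeg", "psbeg_audit.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  # stage: cross-species peak classification
  classified <- runStage("peaks",
    classifyCrossSpeciesPeaks(gen$refPeaks, gen$samplePeaks, gen$maps,
                              reference = "primateA",
                              comparator = "primateB",
                              outgroup = "outgroup",
                              rule = th$presence_rule,
                              minMappedFraction = th$min_mapped_fraction))
  runStage("peaks", {
    out <- classified
    names(out) <- paste0(names(out), "|", mcols(out)$peak_class)
    writeBed(granges(out, use.names = TRUE),
             put("peaks", "classified_peaks.bed"))
  })

  # stage: loop assignment of human-specific elements to promoters
  assignments <- runStage("loops", {
    prom <- promoterWindows(gen$genes$primateA)
    hs <- classified[mcols(classified)$peak_class == "human_specific"]
    assignLoopsToPromoters(gen$loops, prom, hs)
  })
  runStage("loops", {
    write.table(as.data.frame(assignments),
                put("loops", "regulatory_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  # stage: gene-set overlap testing
  overlap <- runStage("overlap", {
    universe <- sim$orthologs$primateA
    linked <- linkElementsToGenes(gen$recnes, gen$genes$primateA,
                                  windowBp = th$window_bp)
    sets <- list(
      human_brain_up = intersect(deGenes(de$primateA, "up_in_brain"),
                                 universe),
      psbeg_final = finalSet(report),
      recne_linked = intersect(unique(linked$gene_id), universe))
    coll <- geneSetCollection(universe, sets)
    overlapMatrix(coll, rows = c("human_brain_up", "psbeg_final"),
                  cols = "recne_linked", alpha = th$overlap_alpha)
  })
  runStage("overlap", {
    write.table(overlap, put("overlap", "overlap_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  # manifest with relative paths and checksums (no timestamps, so reruns
  # with the same config and seed are byte-identical)
  allFiles <- unlist(outputs, use.names = FALSE)
  sums <- as.list(tools::md5sum(file.path(cfg$outdir, allFiles)))
  names(sums) <- allFiles
  manifest <- list(
    package = "brainReg",
    version = as.character(packageVersion("brainReg")),
    seed = cfg$seed,
    thresholds = th,
    simulation = simArgs,
    stages = lapply(outputs, as.list),
    checksums = sums)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
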