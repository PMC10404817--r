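# Shared fixtures: everything is generated in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

# tiny two-group study with explicit QC and covariate fields
makeTinyStudy <- function(counts = NULL, nGenes = 6, nPerGroup = 3,
                          seed = 42) {
  set.seed(seed)
  if (is.null(counts)) {
    counts <- matrix(rpois(nGenes * 2 * nPerGroup, 50), nrow = nGenes)
  }
  ns <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%02d", seq_len(ns))
  grp <- rep(c("brain", "nonbrain"), each = ns / 2)
  meta <- data.frame(
    sample_id = colnames(counts), species = "toy",
    tissue = ifelse(grp == "brain", "brain", "liver"), group = grp,
    age = seq_len(ns), sex = rep(c("M", "F"), length.out = ns),
    rin = 8, uniquely_mapped_reads = 2e7, unique_map_rate = 0.9)
  expressionStudy(counts, meta)
}

# clean-regime pipeline recovery: returns c(precision, recall)
psbegRecovery <- function(seed, nGenes = 2000, nTruePsbeg = 20,
                          foldEffect = 8, dispersion = 0.1,
                          samplesPerTissue = 10) {
  cfg <- simulationConfig(nGenes = nGenes, nTruePsbeg = nTruePsbeg,
                          foldEffect = foldEffect, dispersion = dispersion,
                          samplesPerTissue = samplesPerTissue, seed = seed)
  sim <- simulateExpressionStudy(cfg)
  de <- lapply(sim$studies, function(s) {
    s <- qcFilterSamples(s)
    s <- filterLowExpression(s)
    sc <- covariateScreen(s)
    brainVsNonbrainDE(s, covariates = sc$covariate[sc$flagged])
  })
  summaries <- lapply(sim$studies, organSummary)
  rep <- runPsbegPipeline(de, summaries, sim$orthologs)
  truth <- sim$groundTruth$truePsbegIds
  found <- finalSet(rep)
  c(precision = if (length(found)) mean(found %in% truth) else NA_real_,
    recall = mean(truth %in% found))
}
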