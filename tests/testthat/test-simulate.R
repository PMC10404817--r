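test_that("configs are validated", {
  expect_error(simulationConfig(nGenes = 10, nTruePsbeg = 10), "smaller")
  expect_error(simulationConfig(tissues = c(brain = TRUE)), "nonbrain")
  expect_error(simulationConfig(dispersion = 0), "positive")
  expect_error(simulationConfig(unmappableFraction = 1.5), "\\[0, 1\\]")
  expect_s4_class(simulationConfig(), "SimulationConfig")
})

test_that("the same seed reproduces every generator byte for byte", {
  cfg <- simulationConfig(nGenes = 200, nTruePsbeg = 5, nPeaks = 80,
                          samplesPerTissue = 4, seed = 9)
  a <- simulateExpressionStudy(cfg)
  b <- simulateExpressionStudy(cfg)
  expect_identical(assay(a$studies$primateA, "counts"),
                   assay(b$studies$primateA, "counts"))
  expect_identical(a$groundTruth, b$groundTruth)

  g1 <- simulateGenomesAndElements(cfg)
  g2 <- simulateGenomesAndElements(cfg)
  expect_identical(as.data.frame(g1$refPeaks), as.data.frame(g2$refPeaks))
  expect_identical(g1$groundTruth, g2$groundTruth)

  f1 <- simulateFetalZoneMatrix(cfg)
  f2 <- simulateFetalZoneMatrix(cfg)
  expect_identical(f1$fpkmHuman, f2$fpkmHuman)

  s1 <- simulateSinglecellClusters(cfg)
  s2 <- simulateSinglecellClusters(cfg)
  expect_identical(s1$expr, s2$expr)

  # serialized outputs hash identically
  p1 <- tempfile(); p2 <- tempfile()
  writeCounts(a$studies$primateA, p1, paste0(p1, ".meta"))
  writeCounts(b$studies$primateA, p2, paste0(p2, ".meta"))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # different seed, different data
  c2 <- simulateExpressionStudy(simulationConfig(
    nGenes = 200, nTruePsbeg = 5, samplesPerTissue = 4, seed = 10))
  expect_false(identical(assay(a$studies$primateA, "counts"),
                         assay(c2$studies$primateA, "counts")))
})

test_that("a unit fold effect plants no bias", {
  cfg <- simulationConfig(nGenes = 300, nTruePsbeg = 5, foldEffect = 1,
                          samplesPerTissue = 5, seed = 3)
  sim <- simulateExpressionStudy(cfg)
  cts <- assay(sim$studies$primateA, "counts")
  grp <- colData(sim$studies$primateA)$group == "brain"
  planted <- sim$groundTruth$truePsbegIds
  # planted genes' brain and nonbrain means are statistically equal
  ratio <- rowMeans(cts[planted, grp]) / rowMeans(cts[planted, !grp])
  expect_true(all(ratio > 0.6 & ratio < 1.6))
})

test_that("covariates are balanced by default, confounded on request", {
  cfg <- simulationConfig(nGenes = 100, nTruePsbeg = 5,
                          samplesPerTissue = 10, seed = 6)
  sim <- simulateExpressionStudy(cfg)
  scr <- covariateScreen(sim$studies$primateA)
  expect_false(any(scr$flagged))

  cfgC <- simulationConfig(nGenes = 100, nTruePsbeg = 5,
                           samplesPerTissue = 10, seed = 6,
                           confoundedCovariates = TRUE)
  simC <- simulateExpressionStudy(cfgC)
  scrC <- covariateScreen(simC$studies$primateA)
  expect_true(scrC$flagged[scrC$covariate == "age"])
})

test_that("planted genomic elements honor their class labels", {
  cfg <- simulationConfig(nGenes = 300, nTruePsbeg = 8, nPeaks = 120,
                          seed = 17)
  gen <- simulateGenomesAndElements(cfg)
  truth <- gen$groundTruth$truePeakClass
  # shared peaks map and overlap outgroup peaks; human-specific never do
  shared <- gen$refPeaks[names(truth)[truth == "human_all_shared"]]
  hs <- gen$refPeaks[names(truth)[truth == "human_specific"]]
  mapped <- mapIntervals(shared, gen$maps$outgroup)
  expect_true(all(lengths(mapped) == 1))
  pres <- presenceVerdict(unlist(mapped), gen$samplePeaks$outgroup)
  expect_true(all(pres))
  mhs <- mapIntervals(hs, gen$maps$outgroup)
  ok <- lengths(mhs) == 1
  if (any(ok))
    expect_false(any(presenceVerdict(unlist(mhs[ok]),
                                     gen$samplePeaks$outgroup)))

  # every planted loop joins its gene's promoter to its element
  prom <- promoterWindows(gen$genes$primateA)
  truthLoops <- gen$groundTruth$loopElementToGene
  asg <- assignLoopsToPromoters(gen$loops, prom,
                                gen$refPeaks[names(truthLoops)])
  distal <- asg[asg$route == "loop_distal", ]
  found <- setNames(distal$gene_id, distal$element_id)
  expect_true(all(names(truthLoops) %in% names(found)))
  expect_identical(unname(found[names(truthLoops)]),
                   unname(truthLoops))
})

test_that("with no unmappable fraction all mappable-class peaks convert", {
  cfg <- simulationConfig(nGenes = 200, nTruePsbeg = 5, nPeaks = 60,
                          unmappableFraction = 0, seed = 21)
  gen <- simulateGenomesAndElements(cfg)
  truth <- gen$groundTruth$truePeakClass
  mappableIdx <- truth[names(gen$refPeaks)] != "human_specific"
  m <- mapIntervals(gen$refPeaks[mappableIdx], gen$maps$primateB)
  expect_true(all(lengths(m) == 1))
  flat <- unlist(m)
  # identity-coordinate maps: intervals map to themselves
  expect_equal(start(flat), start(gen$refPeaks[mappableIdx]))
})

test_that("fetal-zone tables pass exactly the planted genes", {
  cfg <- simulationConfig(nGenes = 400, nTruePsbeg = 10, seed = 31)
  fet <- simulateFetalZoneMatrix(cfg)
  pass <- fetalZoneFilter(fet$fpkmHuman, fet$fpkmMouse,
                          rownames(fet$fpkmHuman))
  expect_setequal(pass, fet$groundTruth$passingIds)
  # all-zero genes fail
  expect_false(any(fet$groundTruth$zeroIds %in% pass))
})
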