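test_that("QC sample filter applies strict thresholds", {
  study <- makeTinyStudy(nPerGroup = 3)
  cd <- colData(study)
  cd$uniquely_mapped_reads <- c(12e6, 15e6, 15e6, 2e7, 2e7, 2e7)
  cd$unique_map_rate <- c(0.9, 0.69, 0.71, 0.9, 0.9, 0.9)
  colData(study) <- cd
  kept <- suppressMessages(qcFilterSamples(study))
  # s1: exactly 12M reads -> removed (strict >); s2: rate 0.69 -> removed;
  # s3: 15M / 0.71 -> retained
  expect_setequal(colnames(kept), c("s03", "s04", "s05", "s06"))

  cd$uniquely_mapped_reads <- NULL
  colData(study) <- cd
  expect_error(qcFilterSamples(study), "uniquely_mapped_reads")
})

test_that("low-expression filter uses a strict fraction boundary", {
  counts <- rbind(
    at20 = c(rep(1L, 2), rep(0L, 8)),   # 2/10 = 20% -> removed
    above = c(rep(1L, 3), rep(0L, 7)),  # 3/10 -> retained
    zero = rep(0L, 10))
  study <- makeTinyStudy(counts = counts, nPerGroup = 5)
  kept <- filterLowExpression(study)
  expect_identical(rownames(kept), "above")
})

test_that("covariate screen reproduces exact rank-sum and Fisher results", {
  counts <- matrix(rpois(6 * 6, 30), 6)
  study <- makeTinyStudy(counts = counts, nPerGroup = 3)
  cd <- colData(study)
  # ages brain (1,2,3) vs nonbrain (10,11,12): exact two-sided U p = 0.1
  cd$age <- c(1, 2, 3, 10, 11, 12)
  cd$rin <- rep(7, 6)                 # constant -> p = 1, never flagged
  cd$sex <- c("M", "M", "M", "F", "F", "F")  # confounded 3v3: Fisher p = 0.1
  colData(study) <- cd
  scr <- covariateScreen(study)
  expect_equal(scr$p[scr$covariate == "age"], 0.1)
  expect_false(scr$flagged[scr$covariate == "age"])
  expect_equal(scr$p[scr$covariate == "rin"], 1)
  expect_equal(scr$p[scr$covariate == "sex"],
               fisher.test(matrix(c(3, 0, 0, 3), 2))$p.value)
  # balanced covariates are not flagged
  expect_false(any(scr$flagged))
})

test_that("confounded covariates large enough to matter are flagged", {
  counts <- matrix(rpois(5 * 12, 30), 5)
  study <- makeTinyStudy(counts = counts, nPerGroup = 6)
  cd <- colData(study)
  cd$age <- c(1:6, 21:26)   # strongly group-separated
  colData(study) <- cd
  scr <- covariateScreen(study)
  expect_true(scr$flagged[scr$covariate == "age"])
})

test_that("DE without covariates equals a Welch t-test on log counts", {
  set.seed(21)
  counts <- matrix(rnbinom(50 * 10, mu = 100, size = 10), 50)
  study <- makeTinyStudy(counts = counts, nPerGroup = 5)
  sf <- sizeFactorsMedianOfRatios(assay(study, "counts"))
  de <- brainVsNonbrainDE(study, sizeFactors = sf)
  y <- log2(sweep(assay(study, "counts"), 2, sf, "/") + 1)
  grp <- colData(study)$group == "brain"
  for (g in c(1, 17, 50)) {
    tt <- t.test(y[g, grp], y[g, !grp])
    expect_equal(de$p[g], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[g],
                 unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-12)
  }
})

test_that("DE calls require both the FDR and the fold-change gate", {
  # gene with huge |t| but log2fc below 1.5 stays ns
  brain <- matrix(rep(c(400L, 401L, 399L, 400L, 400L), each = 1), 1)
  nonbr <- matrix(rep(c(200L, 201L, 199L, 200L, 200L), each = 1), 1)
  counts <- rbind(gate = cbind(brain, nonbr)[1, ],
                  flat = rep(100L, 10))
  study <- makeTinyStudy(counts = counts, nPerGroup = 5)
  de <- brainVsNonbrainDE(study, sizeFactors = setNames(rep(1, 10),
                                                        colnames(study)))
  expect_lt(de["gate", "p"], 1e-6)
  expect_lt(abs(de["gate", "log2fc"]), 1.5)
  expect_identical(de["gate", "call"], "ns")

  # planted strong effect is called up_in_brain
  set.seed(5)
  counts2 <- rbind(up = c(rpois(5, 800), rpois(5, 100)),
                   none = rpois(10, 100))
  study2 <- makeTinyStudy(counts = counts2, nPerGroup = 5)
  de2 <- brainVsNonbrainDE(study2, sizeFactors = setNames(rep(1, 10),
                                                          colnames(study2)))
  expect_identical(de2["up", "call"], "up_in_brain")
})

test_that("covariates enter the design and collinear ones are dropped", {
  set.seed(77)
  n <- 12
  counts <- matrix(rnbinom(40 * n, mu = 100, size = 10), 40)
  study <- makeTinyStudy(counts = counts, nPerGroup = n / 2)
  cd <- colData(study)
  cd$age <- rnorm(n, 10)
  colData(study) <- cd
  sf <- setNames(rep(1, n), colnames(study))
  de <- brainVsNonbrainDE(study, sizeFactors = sf, covariates = "age")
  expect_s4_class(de, "DEResult")
  expect_identical(metadata(de)$covariates, "age")
  # adjusted fit must equal lm() per gene
  y <- log2(assay(study, "counts") + 1)
  grp <- factor(colData(study)$group, c("nonbrain", "brain"))
  ref <- summary(lm(y[7, ] ~ grp + cd$age))$coefficients
  expect_equal(de$p[7], ref["grpbrain", "Pr(>|t|)"], tolerance = 1e-10)

  # a covariate identical to the group indicator is collinear
  cd$dup <- as.numeric(cd$group == "brain")
  colData(study) <- cd
  expect_warning(
    brainVsNonbrainDE(study, sizeFactors = sf,
                      covariates = c("age", "dup")),
    "collinear")
})

test_that("BH adjustment matches hand computation and rejects bad input", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.9, 0.001, 0.02, 0.5)
  adj <- bhAdjust(p)
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  expect_true(all(adj >= p))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, NA)), "\\[0, 1\\]")
})
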