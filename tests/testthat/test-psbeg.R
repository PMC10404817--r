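test_that("candidate set logic follows the cross-species algebra", {
  u <- letters[1:10]
  expect_equal(candidateSetLogic(c("a", "b", "c"), c("b", "c", "d"), "c", u),
               c("a", "b"))
  # nonprimate superset of the reference: empty result
  expect_equal(candidateSetLogic(c("a", "b"), c("a", "b"),
                                 c("a", "b", "c"), u), character(0))
  # empty comparator and nonprimate: identity on H
  expect_equal(candidateSetLogic(c("b", "a"), character(0), character(0), u),
               c("a", "b"))
  expect_error(candidateSetLogic("zz", character(0), character(0), u),
               "universe")
})

test_that("adding to the nonprimate up-set never grows the candidates", {
  set.seed(14)
  u <- sprintf("g%03d", 1:60)
  for (i in 1:50) {
    H <- sample(u, 20); M <- sample(u, 20); T1 <- sample(u, 10)
    T2 <- union(T1, sample(u, 5))
    c1 <- candidateSetLogic(H, M, T1, u)
    c2 <- candidateSetLogic(H, M, T2, u)
    expect_true(all(c2 %in% c1))
  }
})

test_that("organ-top filter requires a strict unique argmax", {
  vals <- rbind(kept = c(brain = 10, liver = 5, heart = 3),
                tie = c(brain = 5, liver = 5, heart = 1),
                nonb = c(brain = 2, liver = 9, heart = 1))
  summ <- list(values = vals,
               brainOrgan = c(brain = TRUE, liver = FALSE, heart = FALSE),
               stat = "median")
  expect_equal(organTopFilter(summ, "brain_top",
                              c("kept", "tie", "nonb")), "kept")
  expect_equal(organTopFilter(summ, "nonbrain_top",
                              c("kept", "tie", "nonb")), "nonb")
  expect_warning(out <- organTopFilter(summ, "brain_top",
                                       c("kept", "ghost")),
                 "absent")
  expect_equal(out, "kept")
})

test_that("fetal-zone filter enforces strict fractions and thresholds", {
  # human: 4/5 samples above threshold = exactly 80% -> fails (strict >)
  h <- matrix(c(3, 3, 3, 3, 0.5), 1,
              dimnames = list("g1", paste0("h", 1:5)))
  m <- matrix(rep(0.1, 5), 1, dimnames = list("g1", paste0("m", 1:5)))
  expect_equal(fetalZoneFilter(h, m, "g1"), character(0))

  # all human samples high, all mouse low -> kept
  h2 <- matrix(rep(3, 5), 1, dimnames = dimnames(h))
  expect_equal(fetalZoneFilter(h2, m, "g1"), "g1")

  # a mouse sample exactly at log2(FPKM+1) = 1 (FPKM = 1) counts against
  # the mouse criterion: with 5 samples, one at the boundary leaves
  # 4/5 = 80%, not strictly more
  m2 <- matrix(c(0.1, 0.1, 0.1, 0.1, 1), 1, dimnames = dimnames(m))
  expect_equal(fetalZoneFilter(h2, m2, "g1"), character(0))

  # all-zero gene fails the human criterion
  hz <- matrix(rep(0, 5), 1, dimnames = dimnames(h))
  expect_equal(fetalZoneFilter(hz, m, "g1"), character(0))

  expect_warning(res <- fetalZoneFilter(h2, m, c("g1", "nope")), "missing")
  expect_equal(res, "g1")
})

test_that("the decision tree recovers planted genes exactly", {
  pr <- psbegRecovery(seed = 101, nGenes = 600, nTruePsbeg = 12,
                      samplesPerTissue = 10)
  expect_equal(unname(pr["precision"]), 1)
  expect_equal(unname(pr["recall"]), 1)
})

test_that("a gene that is brain-top in the outgroup is excluded with audit", {
  cfg <- simulationConfig(nGenes = 300, nTruePsbeg = 6,
                          samplesPerTissue = 8, seed = 55)
  sim <- simulateExpressionStudy(cfg)
  de <- lapply(sim$studies, function(s)
    brainVsNonbrainDE(filterLowExpression(s)))
  summaries <- lapply(sim$studies, organSummary)
  victim <- sim$groundTruth$truePsbegIds[1]
  # force the outgroup organ summary to make the victim's ortholog brain-top
  og <- summaries$outgroup
  victimOg <- sim$orthologs$outgroup[match(victim, sim$orthologs$primateA)]
  og$values[victimOg, "brain"] <- max(og$values[victimOg, ]) * 10
  summaries$outgroup <- og
  rep <- runPsbegPipeline(de, summaries, sim$orthologs)
  expect_false(victim %in% finalSet(rep))
  audit <- auditTrail(rep)
  expect_equal(audit$disposition[audit$gene == victim],
               "eliminated_outgroup_organ_filter")
  # every other planted gene still passes
  expect_setequal(finalSet(rep),
                  setdiff(sim$groundTruth$truePsbegIds, victim))
})

test_that("the audit trail assigns every universe gene one disposition", {
  cfg <- simulationConfig(nGenes = 300, nTruePsbeg = 6,
                          samplesPerTissue = 6, seed = 77)
  sim <- simulateExpressionStudy(cfg)
  de <- lapply(sim$studies, function(s)
    brainVsNonbrainDE(filterLowExpression(s)))
  summaries <- lapply(sim$studies, organSummary)
  rep <- runPsbegPipeline(de, summaries, sim$orthologs)
  audit <- auditTrail(rep)
  expect_setequal(audit$gene, sim$orthologs$primateA)
  expect_false(anyDuplicated(audit$gene) > 0)
  expect_true(all(audit$disposition %in%
    c("not_candidate", "candidate", "eliminated_reference_organ_filter",
      "eliminated_nonprimate_organ_filter",
      "eliminated_outgroup_organ_filter", "psbeg")))
  # terminal dispositions: no gene may remain merely 'candidate'
  expect_false(any(audit$disposition == "candidate"))
  # the experimental subset is contained in the final set on simulated data
  expect_true(all(experimentalSubset(rep) %in% finalSet(rep)))
})
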