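# helpers to build tiny presence/absence scenarios ---------------------------

peakAt <- function(pos, width = 100, chrom = "chr1") {
  GRanges(chrom, IRanges(pos, width = width))
}

test_that("presence verdicts follow the replicate-consensus rule", {
  q <- peakAt(1000)
  hit <- peakAt(1050); miss <- peakAt(5000)
  all16 <- GRangesList(rep(list(hit), 16))
  miss1 <- GRangesList(c(rep(list(hit), 15), list(miss)))
  expect_true(presenceVerdict(q, all16, rule = "all"))
  expect_false(presenceVerdict(q, miss1, rule = "all"))
  expect_true(presenceVerdict(q, miss1, rule = "any"))
  expect_true(presenceVerdict(q, miss1, rule = "fraction",
                              fraction = 0.9))   # 15/16 = 0.9375
  expect_error(presenceVerdict(q, GRangesList(), rule = "all"), "sample")
  expect_error(presenceVerdict(q, all16, rule = "fraction"), "fraction")
})

test_that("peak classification matches the nine-combination truth table", {
  # Oracle: enumerate every (comparator, outgroup) evidence pair and apply
  # the stated rule independently of the implementation.
  oracle <- function(comp, outg) {
    absentish <- function(v) v %in% c("absent", "unmappable")
    if (absentish(comp) && absentish(outg)) return("human_specific")
    if (comp == "present" && absentish(outg)) return("primate_specific")
    "human_all_shared"
  }
  states <- c("present", "absent", "unmappable")
  combos <- expand.grid(comp = states, outg = states,
                        stringsAsFactors = FALSE)

  # Build one reference peak per combination. Peaks sit at 10 kb intervals;
  # 'unmappable' is realized by leaving the peak out of the map blocks,
  # 'absent' by mapping it to a location with no species peak.
  n <- nrow(combos)
  pos <- 10000 * seq_len(n)
  refPeaks <- peakAt(pos)
  names(refPeaks) <- sprintf("pk%02d", seq_len(n))

  buildSide <- function(state) {
    blocks <- list(); peaks <- list()
    for (i in seq_len(n)) {
      if (state[i] != "unmappable")
        blocks[[length(blocks) + 1]] <- c(pos[i] - 500, pos[i] + 600)
      if (state[i] == "present")
        peaks[[length(peaks) + 1]] <- c(pos[i], pos[i] + 99)
    }
    bl <- do.call(rbind, blocks)
    map <- blockCoordinateMap(GRanges("chr1", IRanges(bl[, 1], bl[, 2])),
                              GRanges("chr1", IRanges(bl[, 1], bl[, 2])))
    pk <- do.call(rbind, peaks)
    pgr <- if (is.null(pk)) GRanges() else
      GRanges("chr1", IRanges(pk[, 1], pk[, 2]))
    list(map = map, peaks = GRangesList(list(pgr, pgr)))
  }
  comp <- buildSide(combos$comp)
  outg <- buildSide(combos$outg)

  cls <- classifyCrossSpeciesPeaks(
    refPeaks,
    samplePeaks = list(primateB = comp$peaks, outgroup = outg$peaks),
    maps = list(primateB = comp$map, outgroup = outg$map))

  expected <- mapply(oracle, combos$comp, combos$outg)
  expect_equal(unname(mcols(cls)$peak_class), unname(expected))
  expect_equal(unname(mcols(cls)$verdict_primateB), combos$comp)
  expect_equal(unname(mcols(cls)$verdict_outgroup), combos$outg)
  # the three classes partition the reference-present peaks
  expect_equal(length(cls), n)
})

test_that("classification on a synthetic genome is exact against truth", {
  cfg <- simulationConfig(nGenes = 400, nTruePsbeg = 10, nPeaks = 300,
                          seed = 11)
  gen <- simulateGenomesAndElements(cfg)
  cls <- classifyCrossSpeciesPeaks(gen$refPeaks, gen$samplePeaks, gen$maps)
  truth <- gen$groundTruth$truePeakClass[names(cls)]
  expect_equal(unname(mcols(cls)$peak_class), unname(truth))
})

test_that("missing maps or sample peaks are configuration errors", {
  refPeaks <- peakAt(1000)
  names(refPeaks) <- "p1"
  m <- blockCoordinateMap(GRanges("chr1", IRanges(1, 2000)),
                          GRanges("chr1", IRanges(1, 2000)))
  sp <- GRangesList(list(peakAt(1000)))
  expect_error(
    classifyCrossSpeciesPeaks(refPeaks, list(primateB = sp),
                              maps = list(primateB = m)),
    "outgroup")
})

test_that("the focal-gene scan respects the 2 Mb window and outgroup peaks", {
  gene <- GRanges("chr1", IRanges(5e6, 5.01e6))
  inWin <- peakAt(5e6 - 1.9e6)       # 1.9 Mb upstream: in scope
  outWin <- peakAt(5e6 - 2.1e6)      # 2.1 Mb upstream: out of scope
  sharedPk <- peakAt(5.5e6)          # maps onto an outgroup peak
  refPeaks <- c(inWin, outWin, sharedPk)
  names(refPeaks) <- c("specific", "outside", "shared")
  map <- blockCoordinateMap(GRanges("chr1", IRanges(1, 1e7)),
                            GRanges("chr1", IRanges(1, 1e7)))
  outPeaks <- GRangesList(list(peakAt(5.5e6)))
  got <- focalGeneRegulatoryScan(gene, refPeaks, outPeaks, map)
  expect_identical(names(got), "specific")

  # an unmappable in-window peak is specifically activated too
  gapMap <- blockCoordinateMap(GRanges("chr1", IRanges(4e6, 1e7)),
                               GRanges("chr1", IRanges(4e6, 1e7)))
  got2 <- focalGeneRegulatoryScan(gene, refPeaks, outPeaks, gapMap)
  expect_identical(names(got2), "specific")
})

test_that("loop assignment reports promoter and distal routes", {
  genes <- GRanges("chr1", IRanges(c(100001, 200001), width = 5000),
                   strand = "+")
  names(genes) <- c("G1", "G2")
  prom <- promoterWindows(genes)
  loop <- Pairs(GRanges("chr1", IRanges(98500, 99500)),   # in G1 promoter
                GRanges("chr1", IRanges(500001, 501000)), # distal anchor
                names = "L1")
  elInAnchor <- GRanges("chr1", IRanges(500200, 500300))
  elNowhere <- GRanges("chr1", IRanges(900001, 900100))
  els <- c(elInAnchor, elNowhere)
  names(els) <- c("e1", "e2")
  asg <- assignLoopsToPromoters(loop, prom, els)
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$element_id, "e1")
  expect_equal(asg$gene_id, "G1")
  expect_equal(asg$route, "loop_distal")
  expect_equal(asg$loop_id, "L1")
})

test_that("a promoter-promoter loop yields assignments in both directions", {
  genes <- GRanges("chr1", IRanges(c(100001, 200001), width = 5000),
                   strand = "+")
  names(genes) <- c("G1", "G2")
  prom <- promoterWindows(genes)
  # one anchor in each promoter; the element sits inside G2's anchor
  loop <- Pairs(prom[1], prom[2], names = "LL")
  el <- GRanges("chr1", IRanges(start(prom[2]) + 10,
                                start(prom[2]) + 100))
  names(el) <- "e"
  asg <- as.data.frame(assignLoopsToPromoters(loop, prom, el))
  # route promoter_overlap to G2 (direct), route loop_distal to G1
  expect_setequal(paste(asg$gene_id, asg$route),
                  c("G2 promoter_overlap", "G1 loop_distal"))
})

test_that("conservation profiles count coverage and similarity per column", {
  rows <- c(ref = "ACGT", r2 = "ACGT", r3 = "ACGT", r4 = "ACGT")
  prof <- conservationProfile(rows)
  expect_equal(prof$score, rep(1, 4))

  # one row gapped at column 2, others match: coverage 0.75, similarity 1
  rows2 <- c(ref = "ACGT", r2 = "A-GT", r3 = "ACGT", r4 = "ACGT")
  p2 <- conservationProfile(rows2)
  expect_equal(p2$coverage[2], 0.75)
  expect_equal(p2$similarity[2], 1)
  expect_equal(p2$score[2], 0.75)

  # all covered, 2 of 4 match the reference: score 0.5
  rows3 <- c(ref = "AAAA", r2 = "AAAA", r3 = "CCCC", r4 = "CCCC")
  p3 <- conservationProfile(rows3)
  expect_equal(p3$score, rep(0.5, 4))

  # reference-gapped columns are skipped; positions index ungapped bases
  rows4 <- c(ref = "A-GT", r2 = "ACGT", r3 = "ACGT")
  p4 <- conservationProfile(rows4)
  expect_equal(p4$column, c(1, 3, 4))
  expect_equal(p4$position, 1:3)

  expect_error(conservationProfile(c("AC", "ACG")), "equal length")
})

test_that("conservation scores ignore the order of non-reference rows", {
  set.seed(8)
  mk <- function() paste(sample(c("A", "C", "G", "T", "-"), 30,
                                replace = TRUE), collapse = "")
  ref <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  rows <- c(ref, replicate(5, mk()))
  shuffled <- c(rows[1], rows[c(4, 2, 6, 3, 5)])
  expect_equal(conservationProfile(rows)$score,
               conservationProfile(shuffled)$score)
})
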