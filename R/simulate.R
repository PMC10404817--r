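# Synthetic multi-species data with planted ground truth. Counts are
# negative binomial with log-normal baseline means; brain-biased genes are
# planted with the primate/nonprimate pattern (brain mean multiplied by the
# fold effect in primates, divided by it in nonprimates); peaks, coordinate
# maps, loops and fetal-zone tables are planted consistently so every
# downstream stage can be validated against the ground truth. One master
# seed drives labeled sub-streams, so each generator is independently
# reproducible.

#' SimulationConfig: parameters of the synthetic study
#'
#' @slot nGenes number of ortholog genes.
#' @slot nSpecies 3 (two primates + nonprimate) or 4 (+ mouse-like outgroup).
#' @slot samplesPerTissue bulk samples per tissue per species.
#' @slot tissues named logical vector; TRUE marks brain tissues.
#' @slot nTruePsbeg number of planted brain-biased genes.
#' @slot foldEffect expression multiplier of the planted bias (>= 1).
#' @slot dispersion negative-binomial overdispersion.
#' @slot peakWidthBp width of planted peaks.
#' @slot nPeaks number of reference peaks.
#' @slot unmappableFraction fraction of the source assembly without map
#'   blocks.
#' @slot confoundedCovariates if TRUE, inject a group-confounded age
#'   covariate to exercise the covariate screen.
#' @slot seed master seed; fully determines all outputs.
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
         representation(nGenes = "integer", nSpecies = "integer",
                        samplesPerTissue = "integer", tissues = "logical",
                        nTruePsbeg = "integer", foldEffect = "numeric",
                        dispersion = "numeric", peakWidthBp = "integer",
                        nPeaks = "integer", unmappableFraction = "numeric",
                        confoundedCovariates = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nTruePsbeg >= object@nGenes)
    msg <- c(msg, "nTruePsbeg must be smaller than nGenes")
  if (!any(object@tissues) || all(object@tissues))
    msg <- c(msg, "need at least one brain and one nonbrain tissue")
  if (is.null(names(object@tissues)))
    msg <- c(msg, "tissues must be named")
  if (!object@nSpecies %in% 3:4)
    msg <- c(msg, "nSpecies must be 3 or 4")
  if (object@foldEffect <= 0) msg <- c(msg, "foldEffect must be positive")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
  if (object@unmappableFraction < 0 || object@unmappableFraction > 1)
    msg <- c(msg, "unmappableFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe the clean validation regime: 2000 ortholog genes, four
#' species (reference primate, comparator primate, nonprimate, mouse-like
#' outgroup), 10 samples per tissue, one brain and three nonbrain organs,
#' 20 planted brain-biased genes at fold 8 with dispersion 0.1.
#'
#' @param nGenes,nSpecies,samplesPerTissue,tissues,nTruePsbeg,foldEffect
#'   see [SimulationConfig-class].
#' @param dispersion,peakWidthBp,nPeaks,unmappableFraction,seed
#'   see [SimulationConfig-class].
#' @param confoundedCovariates inject a brain/nonbrain-confounded age
#'   covariate (default FALSE: covariates are balanced).
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nGenes = 2000, nSpecies = 4,
                             samplesPerTissue = 10,
                             tissues = c(brain = TRUE, liver = FALSE,
                                         kidney = FALSE, heart = FALSE),
                             nTruePsbeg = 20, foldEffect = 8,
                             dispersion = 0.1, peakWidthBp = 500,
                             nPeaks = 300, unmappableFraction = 0.1,
                             confoundedCovariates = FALSE, seed = 1) {
  cfg <- new("SimulationConfig", nGenes = as.integer(nGenes),
             nSpecies = as.integer(nSpecies),
             samplesPerTissue = as.integer(samplesPerTissue),
             tissues = tissues, nTruePsbeg = as.integer(nTruePsbeg),
             foldEffect = as.numeric(foldEffect),
             dispersion = as.numeric(dispersion),
             peakWidthBp = as.integer(peakWidthBp),
             nPeaks = as.integer(nPeaks),
             unmappableFraction = as.numeric(unmappableFraction),
             confoundedCovariates = isTRUE(confoundedCovariates),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,", object@nSpecies,
      "species,", object@nTruePsbeg, "planted genes at fold",
      object@foldEffect, "(seed", paste0(object@seed, ")\n"))
})

# Species roles and id prefixes. The reference primate is human-like, the
# comparator macaque-like, the nonprimate tree-shrew-like, the outgroup
# mouse-like.
speciesRoles <- function(config) {
  c("primateA", "primateB", "nonprimate", "outgroup")[seq_len(config@nSpecies)]
}

speciesPrefix <- c(primateA = "hsa", primateB = "mml",
                   nonprimate = "tbe", outgroup = "mmu")

speciesGeneIds <- function(config, role) {
  sprintf("%s_g%05d", speciesPrefix[[role]], seq_len(config@nGenes))
}

#' One-to-one ortholog table of the synthetic study
#' @param config a [SimulationConfig-class].
#' @return data.frame, one column per species role.
#' @export
simulatedOrthologs <- function(config) {
  cols <- lapply(speciesRoles(config),
                 function(r) speciesGeneIds(config, r))
  names(cols) <- speciesRoles(config)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# Indices of planted brain-biased genes; shared across generators so the
# expression, fetal-zone and genome plants are consistent.
truePsbegIndices <- function(config) {
  withSeed(streamSeed(config@seed, "plant"),
           sort(sample.int(config@nGenes, config@nTruePsbeg)))
}

#' Simulate per-species expression studies with planted brain-biased genes
#'
#' Counts are negative binomial with gene-specific log-normal baseline
#' means shared across species. Planted genes have their brain-tissue means
#' multiplied by \code{foldEffect} in the primates and divided by it in the
#' nonprimate and outgroup; all other genes have identical means across
#' tissues (so label-permuted data are exchangeable). Sample metadata carry
#' balanced age, sex and RIN covariates (group-confounded age when
#' configured) and QC fields that pass the default thresholds.
#'
#' @param config a [SimulationConfig-class].
#' @return List: \code{studies} (named list of [ExpressionStudy-class] per
#'   role), \code{orthologs} (data.frame) and \code{groundTruth} (list with
#'   \code{truePsbegIds} in reference-species ids and \code{plantIdx}).
#' @export
simulateExpressionStudy <- function(config) {
  roles <- speciesRoles(config)
  plantIdx <- truePsbegIndices(config)
  tissues <- config@tissues
  n <- config@samplesPerTissue
  withSeed(streamSeed(config@seed, "expression"), {
    baseMean <- rlnorm(config@nGenes, meanlog = log(100), sdlog = 1)
    lens <- round(runif(config@nGenes, 300, 10000))
    studies <- lapply(roles, function(role) {
      ids <- speciesGeneIds(config, role)
      primate <- role %in% c("primateA", "primateB")
      cols <- list(); metas <- list()
      for (t in names(tissues)) {
        mu <- baseMean
        if (tissues[[t]]) {
          mu[plantIdx] <- if (primate) mu[plantIdx] * config@foldEffect
                          else mu[plantIdx] / config@foldEffect
        }
        for (k in seq_len(n)) {
          sid <- sprintf("%s_%s_%02d", speciesPrefix[[role]], t, k)
          cols[[sid]] <- rnbinom(config@nGenes, mu = mu,
                                 size = 1 / config@dispersion)
          age <- runif(1, 1, 20)
          if (config@confoundedCovariates && tissues[[t]]) age <- age + 15
          metas[[sid]] <- data.frame(
            sample_id = sid, species = role, tissue = t,
            group = if (tissues[[t]]) "brain" else "nonbrain",
            age = round(age, 2),
            sex = if (k %% 2 == 0) "F" else "M",
            rin = round(runif(1, 6, 10), 2),
            uniquely_mapped_reads = round(runif(1, 1.5e7, 4e7)),
            unique_map_rate = round(runif(1, 0.75, 0.95), 3))
        }
      }
      counts <- do.call(cbind, cols)
      rownames(counts) <- ids
      expressionStudy(counts, do.call(rbind, metas),
                      geneLengths = setNames(lens, ids))
    })
    names(studies) <- roles
    refIds <- speciesGeneIds(config, "primateA")
    list(studies = studies,
         orthologs = simulatedOrthologs(config),
         groundTruth = list(truePsbegIds = refIds[plantIdx],
                            plantIdx = plantIdx))
  })
}

# Carve gaps out of [1, chromLen] so that `targetLen` bases are unmappable,
# always covering `forceGaps` and never touching `protect` (both GRanges).
carveGaps <- function(chromLen, chrom, targetLen, forceGaps, protect) {
  gaps <- forceGaps
  need <- targetLen - sum(width(reduce(gaps)))
  if (need > 0) {
    chunk <- 5000L
    starts <- seq(1L, chromLen - chunk, by = chunk)
    cand <- GRanges(chrom, IRanges(starts, width = chunk))
    free <- cand[countOverlaps(cand, protect, ignore.strand = TRUE) == 0 &
                   countOverlaps(cand, gaps, ignore.strand = TRUE) == 0]
    take <- min(length(free), ceiling(need / chunk))
    if (take > 0) {
      sel <- sort(sample.int(length(free), take))
      gaps <- c(gaps, free[sel])
    }
  }
  reduce(gaps)
}

#' Simulate toy genomes, peaks, maps, conserved elements and loops
#'
#' Genes are laid out every 50 kb on one chromosome per species with
#' alternating strand. Reference peaks are placed on a non-overlapping grid
#' and assigned planted classes (roughly 50% shared, 30% primate-specific,
#' 20% human-specific). Block maps from the reference to the comparator and
#' outgroup are identity-coordinate maps with gaps: gaps always cover the
#' peaks planted as unmappable and never the peaks that must convert, and
#' random extra gaps bring the unmappable share of the assembly up to
#' \code{unmappableFraction}. Comparator samples carry peaks at the mapped
#' positions of shared + primate-specific peaks; outgroup samples only at
#' shared positions. Conserved noncoding elements are planted near genes,
#' and loops connect enhancer peaks to the promoters of planted genes.
#'
#' @param config a [SimulationConfig-class].
#' @return List: genes (named list of GRanges per role), refPeaks (named
#'   GRanges), samplePeaks (named list of GRangesList per species), maps
#'   (named list of [BlockCoordinateMap-class]), recnes (GRanges), loops
#'   (Pairs), groundTruth (list: truePeakClass, elementToGene,
#'   focalGene, focalSpecific).
#' @export
simulateGenomesAndElements <- function(config) {
  roles <- speciesRoles(config)
  plantIdx <- truePsbegIndices(config)
  spacing <- 50000L
  geneWidth <- 5000L
  chromLen <- max((config@nGenes + 2L) * spacing,
                  (config@nPeaks + 2L) * (4L * config@peakWidthBp + 1000L))
  nSamples <- c(primateA = 4L, primateB = 3L, nonprimate = 3L,
                outgroup = 4L)
  withSeed(streamSeed(config@seed, "genomes"), {
    genes <- lapply(roles, function(role) {
      g <- GRanges("chr1",
                   IRanges(start = (seq_len(config@nGenes) - 1L) * spacing +
                             10000L, width = geneWidth),
                   strand = rep(c("+", "-"),
                                length.out = config@nGenes))
      names(g) <- speciesGeneIds(config, role)
      g
    })
    names(genes) <- roles

    # reference peaks on a jitter-free grid covering the gene territory
    gap <- max(4L * config@peakWidthBp + 1000L,
               floor((chromLen - 20000L) / (config@nPeaks + 1L)))
    pos <- 5000L + seq_len(config@nPeaks) * gap
    pos <- pos[pos + config@peakWidthBp < chromLen]
    refPeaks <- GRanges("chr1", IRanges(pos, width = config@peakWidthBp))
    names(refPeaks) <- sprintf("peak_%05d", seq_along(refPeaks))
    nP <- length(refPeaks)
    classes <- sample(rep(c("human_all_shared", "primate_specific",
                            "human_specific"),
                          times = c(ceiling(nP * 0.5),
                                    ceiling(nP * 0.3), nP))[seq_len(nP)])
    # peaks designated unmappable (half of each absent class, per map)
    hsIdx <- which(classes == "human_specific")
    psIdx <- which(classes == "primate_specific")
    unmapComparator <- hsIdx[seq_along(hsIdx) %% 2 == 0]
    unmapOutgroup <- sort(c(hsIdx[seq_along(hsIdx) %% 2 == 0],
                            psIdx[seq_along(psIdx) %% 2 == 0]))

    mustMap <- function(unmapIdx) refPeaks[setdiff(seq_len(nP), unmapIdx)]
    gapFor <- function(unmapIdx) {
      if (!length(unmapIdx)) return(GRanges())
      g <- refPeaks[unmapIdx] + 200L
      start(g) <- pmax(start(g), 1L)
      granges(g)
    }
    targetGapLen <- round(config@unmappableFraction * chromLen)
    buildMap <- function(unmapIdx) {
      gaps <- carveGaps(chromLen, "chr1", targetGapLen,
                        gapFor(unmapIdx), mustMap(unmapIdx) + 1000L)
      blocks <- GenomicRanges::setdiff(GRanges("chr1", IRanges(1, chromLen)),
                                       gaps, ignore.strand = TRUE)
      blockCoordinateMap(blocks,
                         GRanges("chr1", IRanges(start(blocks),
                                                 end(blocks))),
                         rep("+", length(blocks)))
    }
    maps <- list(primateB = buildMap(unmapComparator),
                 outgroup = buildMap(unmapOutgroup))

    presentIn <- list(
      primateA = seq_len(nP),
      primateB = which(classes %in% c("human_all_shared",
                                      "primate_specific")),
      nonprimate = integer(0),
      outgroup = which(classes == "human_all_shared"))
    samplePeaks <- lapply(roles, function(role) {
      idx <- presentIn[[role]]
      GRangesList(lapply(seq_len(nSamples[[role]]), function(s) {
        granges(refPeaks[idx])
      }))
    })
    names(samplePeaks) <- roles

    # conserved noncoding elements planted 10 kb upstream of a gene subset
    nRec <- min(config@nGenes, max(10L, config@nGenes %/% 100L))
    recGene <- sort(sample.int(config@nGenes, nRec))
    recnes <- GRanges("chr1",
                      IRanges(start = pmax(start(genes$primateA)[recGene] -
                                             10000L, 1L), width = 250L))
    names(recnes) <- sprintf("recne_%04d", seq_len(nRec))
    recTruth <- setNames(names(genes$primateA)[recGene], names(recnes))

    # loops: enhancer peaks (human-specific, mappable side) wired to the
    # promoters of the planted genes
    nLoops <- min(length(plantIdx), length(hsIdx))
    loopGenes <- plantIdx[seq_len(nLoops)]
    loopPeaks <- hsIdx[seq_len(nLoops)]
    prom <- promoterWindows(genes$primateA[loopGenes])
    anchorA <- granges(prom)
    anchorB <- granges(refPeaks[loopPeaks] + 250L)
    start(anchorB) <- pmax(start(anchorB), 1L)
    loops <- Pairs(anchorA, anchorB,
                   names = sprintf("loop_%03d", seq_len(nLoops)))
    loopTruth <- setNames(names(genes$primateA)[loopGenes],
                          names(refPeaks)[loopPeaks])

    # focal-gene configuration: the first planted gene; the peaks inside
    # its 2 Mb neighborhood that are absent from the outgroup (i.e. the
    # human-specific and primate-specific ones) are the expected output of
    # the outgroup-directed regulatory scan
    focalGene <- names(genes$primateA)[plantIdx[1]]
    fg <- genes$primateA[focalGene]
    win <- GRanges("chr1", IRanges(max(1, start(fg) - 2e6), end(fg) + 2e6))
    inWin <- which(countOverlaps(refPeaks, win) > 0)
    focalSpecific <- names(refPeaks)[intersect(inWin,
                                               sort(c(hsIdx, psIdx)))]

    list(genes = genes, refPeaks = refPeaks, samplePeaks = samplePeaks,
         maps = maps, recnes = recnes, loops = loops,
         groundTruth = list(
           truePeakClass = setNames(classes, names(refPeaks)),
           elementToGene = c(recTruth, loopTruth),
           loopElementToGene = loopTruth,
           focalGene = focalGene, focalSpecific = focalSpecific))
  })
}

#' Simulate fetal-zone FPKM tables for a human-like and mouse-like species
#'
#' Zones SVZ, VZ, aRG and bRG with \code{samplesPerZone} samples each.
#' Planted genes are high in the human-like samples
#' (\code{log2(FPKM+1) > 1} in essentially all samples) and near zero in the
#' mouse-like samples; all other genes have a shared moderate level in both
#' species, so they fail the mouse criterion; a trailing 5% of genes are
#' zero everywhere and fail the human criterion.
#'
#' @param config a [SimulationConfig-class].
#' @param samplesPerZone samples per zone (default 5).
#' @return List: fpkmHuman, fpkmMouse (genes x samples, reference-species
#'   gene ids), zones (per-sample zone labels), groundTruth.
#' @export
simulateFetalZoneMatrix <- function(config, samplesPerZone = 5) {
  plantIdx <- truePsbegIndices(config)
  ids <- speciesGeneIds(config, "primateA")
  zones <- rep(c("SVZ", "VZ", "aRG", "bRG"), each = samplesPerZone)
  nS <- length(zones)
  nG <- config@nGenes
  withSeed(streamSeed(config@seed, "fetal"), {
    zeroIdx <- setdiff(seq(floor(nG * 0.95) + 1, nG), plantIdx)
    base <- matrix(rlnorm(nG * nS, meanlog = log(5), sdlog = 0.5), nG, nS)
    h <- base; m <- base
    h[plantIdx, ] <- rlnorm(length(plantIdx) * nS, log(8), 0.3)
    m[plantIdx, ] <- rlnorm(length(plantIdx) * nS, log(0.2), 0.3)
    h[zeroIdx, ] <- 0
    m[zeroIdx, ] <- 0
    dimnames(h) <- list(ids, sprintf("hsa_fetal_%s_%02d", zones,
                                     sequence(rle(zones)$lengths)))
    dimnames(m) <- list(ids, sprintf("mmu_fetal_%s_%02d", zones,
                                     sequence(rle(zones)$lengths)))
    list(fpkmHuman = h, fpkmMouse = m, zones = zones,
         groundTruth = list(passingIds = ids[plantIdx],
                            zeroIds = ids[zeroIdx]))
  })
}

#' Simulate integrated single-cell clusters with planted cross-species DEGs
#'
#' Clusters are consumed downstream as given (no clustering is simulated).
#' Cells from the reference primate, comparator primate and nonprimate are
#' generated per cluster with negative-binomial expression; in the
#' designated cluster a planted gene set is shifted by \code{foldEffect} in
#' the primates relative to the nonprimate. Comparator-primate cells carry
#' reference cell-type labels (with a minority admixture) for annotation
#' transfer.
#'
#' @param config a [SimulationConfig-class].
#' @param nClusters number of clusters (default 5).
#' @param cellsPerCluster cells per species per cluster (default 60).
#' @param nGenes genes in the single-cell panel (default min(300, nGenes)).
#' @param nPlantedDeg planted DEGs in the designated cluster (default 10).
#' @param degCluster cluster receiving the planted DEGs (default 3).
#' @return List: expr (genes x cells), cellMeta (data.frame), groundTruth
#'   (list: degCluster, plantedDegs, clusterType).
#' @export
simulateSinglecellClusters <- function(config, nClusters = 5,
                                       cellsPerCluster = 60,
                                       nGenes = min(300L, config@nGenes),
                                       nPlantedDeg = 10,
                                       degCluster = 3) {
  species <- c("primateA", "primateB", "nonprimate")
  types <- c("NPC", "ExN", "IntN", "Astro", "Oligo", "OPC", "MSN")
  clusterType <- setNames(types[(seq_len(nClusters) - 1) %% length(types) + 1],
                          seq_len(nClusters))
  withSeed(streamSeed(config@seed, "singlecell"), {
    geneIds <- speciesGeneIds(config, "primateA")[seq_len(nGenes)]
    base <- rlnorm(nGenes, log(2), 1)
    planted <- if (config@foldEffect > 1 && nPlantedDeg > 0)
      sort(sample.int(nGenes, nPlantedDeg)) else integer(0)
    cols <- list(); metas <- list()
    for (cl in seq_len(nClusters)) {
      clShift <- rlnorm(nGenes, 0, 0.2)
      for (sp in species) {
        mu <- base * clShift
        if (cl == degCluster && sp %in% c("primateA", "primateB"))
          mu[planted] <- mu[planted] * config@foldEffect
        for (k in seq_len(cellsPerCluster)) {
          cid <- sprintf("%s_c%d_%03d", speciesPrefix[[sp]], cl, k)
          cols[[cid]] <- rnbinom(nGenes, mu = mu, size = 2)
          metas[[cid]] <- data.frame(
            cell_id = cid, species = sp, cluster = cl,
            reference_label = if (sp == "primateB") {
              if (k <= ceiling(0.9 * cellsPerCluster)) clusterType[[cl]]
              else types[(match(clusterType[[cl]], types)) %% length(types) + 1]
            } else NA_character_)
        }
      }
    }
    expr <- do.call(cbind, cols)
    rownames(expr) <- geneIds
    list(expr = expr, cellMeta = do.call(rbind, metas),
         groundTruth = list(degCluster = degCluster,
                            plantedDegs = geneIds[planted],
                            clusterType = clusterType))
  })
}
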