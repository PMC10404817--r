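# Cross-species epigenetic peak classification, focal regulatory scans,
# loop-to-promoter assignment, and per-column conservation profiles.

#' Replicate-consensus presence verdict for intervals against sample peaks
#'
#' Under the default \code{rule = "all"} an interval is present iff it
#' overlaps (>= 1 bp) at least one peak in EVERY sample; \code{"any"}
#' requires one sample and \code{"fraction"} requires at least
#' \code{fraction} of the samples. "all" is the strictest reading of
#' replicate consensus and the default.
#'
#' @param x GRanges of query intervals.
#' @param samplePeaks GRangesList, one element per sample.
#' @param rule "all", "any" or "fraction".
#' @param fraction required sample fraction when \code{rule = "fraction"}
#'   (presence iff overlap in >= fraction of samples).
#' @return Logical vector: is each interval present.
#' @export
presenceVerdict <- function(x, samplePeaks, rule = c("all", "any", "fraction"),
                            fraction = NULL) {
  rule <- match.arg(rule)
  if (length(samplePeaks) == 0) stopf("presenceVerdict needs >= 1 sample")
  if (rule == "fraction" &&
      (is.null(fraction) || fraction <= 0 || fraction > 1))
    stopf("rule 'fraction' needs a fraction in (0, 1]")
  hitsPerSample <- vapply(seq_along(samplePeaks), function(j) {
    countOverlaps(x, samplePeaks[[j]], ignore.strand = TRUE) > 0
  }, logical(length(x)))
  hitsPerSample <- matrix(hitsPerSample, nrow = length(x))
  frac <- rowMeans(hitsPerSample)
  switch(rule,
         all = frac == 1,
         any = frac > 0,
         fraction = frac >= fraction)
}

#' Classify reference peaks as species-specific, primate-specific or shared
#'
#' Each reference peak (present in the reference species under the chosen
#' replicate rule) is mapped to the comparator primate and the outgroup; the
#' per-species verdict is \code{present}, \code{absent} (mapped but no
#' overlapping peak) or \code{unmappable} (failed conversion). Failed
#' conversion counts as absence. Classes: \code{human_specific} when absent
#' in both other species, \code{primate_specific} when present in the
#' comparator but absent in the outgroup, \code{human_all_shared} otherwise.
#' The three classes partition the reference-present peaks.
#'
#' @param refPeaks GRanges of reference peaks (named).
#' @param samplePeaks named list of GRangesList: per-sample peaks for the
#'   comparator and outgroup species (and optionally the reference, used to
#'   restrict to reference-present peaks).
#' @param maps named list of [BlockCoordinateMap-class] keyed by species.
#' @param reference,comparator,outgroup species names.
#' @param rule,fraction replicate-consensus rule (see [presenceVerdict()]).
#' @param minMappedFraction conversion threshold (see [mapIntervals()]).
#' @return GRanges of the classified reference-present peaks with metadata
#'   columns \code{peak_class} and one \code{verdict_<species>} per species.
#' @export
classifyCrossSpeciesPeaks <- function(refPeaks, samplePeaks, maps,
                                      reference = "primateA",
                                      comparator = "primateB",
                                      outgroup = "outgroup",
                                      rule = "all", fraction = NULL,
                                      minMappedFraction = 0.95) {
  for (sp in c(comparator, outgroup)) {
    if (!sp %in% names(maps))
      stopf("no coordinate map provided for species '%s'", sp)
    if (!sp %in% names(samplePeaks))
      stopf("no sample peaks provided for species '%s'", sp)
  }
  if (reference %in% names(samplePeaks)) {
    present <- presenceVerdict(refPeaks, samplePeaks[[reference]],
                               rule = rule, fraction = fraction)
    refPeaks <- refPeaks[present]
  }
  verdicts <- list()
  for (sp in c(comparator, outgroup)) {
    grl <- mapIntervals(refPeaks, maps[[sp]],
                        minMappedFraction = minMappedFraction)
    fm <- flattenMapped(grl)
    v <- rep("unmappable", length(refPeaks))
    if (length(fm$index)) {
      pres <- presenceVerdict(fm$ranges, samplePeaks[[sp]],
                              rule = rule, fraction = fraction)
      v[fm$index] <- ifelse(pres, "present", "absent")
    }
    verdicts[[sp]] <- v
  }
  absentish <- function(v) v %in% c("absent", "unmappable")
  cls <- ifelse(absentish(verdicts[[comparator]]) &
                  absentish(verdicts[[outgroup]]), "human_specific",
         ifelse(verdicts[[comparator]] == "present" &
                  absentish(verdicts[[outgroup]]), "primate_specific",
                "human_all_shared"))
  mcols(refPeaks)$peak_class <- cls
  for (sp in names(verdicts))
    mcols(refPeaks)[[paste0("verdict_", sp)]] <- verdicts[[sp]]
  refPeaks
}

#' Scan the neighborhood of a focal gene for specifically activated peaks
#'
#' Reference peaks intersecting the gene region extended by \code{flankBp}
#' on each side are mapped to the outgroup; peaks that fail to convert, or
#' convert without overlapping any outgroup peak, are returned as
#' specifically activated. The default 2 Mb flank matches the standard
#' cis-regulatory scan range around a focal gene.
#'
#' @param gene a length-one GRanges (the gene body).
#' @param refPeaks GRanges of reference peaks.
#' @param outgroupSamplePeaks GRangesList of per-sample outgroup peaks.
#' @param map [BlockCoordinateMap-class] reference -> outgroup.
#' @param flankBp scan flank in bp (default 2e6).
#' @param rule,fraction,minMappedFraction see [classifyCrossSpeciesPeaks()].
#' @return GRanges of specifically activated peaks in the scan window.
#' @export
focalGeneRegulatoryScan <- function(gene, refPeaks, outgroupSamplePeaks, map,
                                    flankBp = 2e6, rule = "all",
                                    fraction = NULL,
                                    minMappedFraction = 0.95) {
  if (length(gene) != 1) stopf("exactly one focal gene is required")
  window <- GRanges(seqnames(gene),
                    IRanges(max(1, start(gene) - flankBp),
                            end(gene) + flankBp))
  cand <- refPeaks[countOverlaps(refPeaks, window,
                                 ignore.strand = TRUE) > 0]
  if (!length(cand)) return(cand)
  grl <- mapIntervals(cand, map, minMappedFraction = minMappedFraction)
  fm <- flattenMapped(grl)
  specific <- rep(TRUE, length(cand))
  if (length(fm$index)) {
    pres <- presenceVerdict(fm$ranges, outgroupSamplePeaks,
                            rule = rule, fraction = fraction)
    specific[fm$index] <- !pres
  }
  cand[specific]
}

#' Assign regulatory elements to genes through promoter-anchored loops
#'
#' Elements overlapping a gene's promoter window directly are assigned with
#' route \code{promoter_overlap}. For each loop with one anchor overlapping
#' a promoter window, elements overlapping the other anchor are assigned to
#' that gene with route \code{loop_distal} and the loop's id. Both anchors
#' are considered symmetrically, so a loop joining two promoters yields
#' assignments in both directions.
#'
#' @param loops a Pairs of anchor GRanges (see [readLoops()]).
#' @param promoters GRanges of promoter windows named by gene id (see
#'   [promoterWindows()]).
#' @param elements GRanges of candidate elements (named).
#' @return DataFrame with columns element_id, gene_id, route, loop_id.
#' @export
assignLoopsToPromoters <- function(loops, promoters, elements) {
  if (is.null(names(elements)))
    names(elements) <- sprintf("element_%d", seq_along(elements))
  res <- list()
  direct <- findOverlaps(elements, promoters, ignore.strand = TRUE)
  if (length(direct))
    res[[length(res) + 1]] <- DataFrame(
      element_id = names(elements)[queryHits(direct)],
      gene_id = names(promoters)[subjectHits(direct)],
      route = "promoter_overlap", loop_id = NA_character_)
  loopIds <- if (is.null(names(loops)))
    sprintf("loop_%d", seq_along(loops)) else names(loops)
  promAnchor <- c(first(loops), second(loops))
  otherAnchor <- c(second(loops), first(loops))
  ids2 <- rep(loopIds, 2)
  ph <- findOverlaps(promAnchor, promoters, ignore.strand = TRUE)
  if (length(ph)) {
    for (k in seq_along(ph)) {
      li <- queryHits(ph)[k]
      gene <- names(promoters)[subjectHits(ph)[k]]
      eh <- findOverlaps(elements, otherAnchor[li], ignore.strand = TRUE)
      if (length(eh))
        res[[length(res) + 1]] <- DataFrame(
          element_id = names(elements)[queryHits(eh)],
          gene_id = gene, route = "loop_distal", loop_id = ids2[li])
    }
  }
  if (!length(res))
    return(DataFrame(element_id = character(), gene_id = character(),
                     route = character(), loop_id = character()))
  out <- do.call(rbind, res)
  out[!duplicated(paste(out$element_id, out$gene_id, out$route,
                        out$loop_id)), , drop = FALSE]
}

#' Per-column conservation profile of an alignment
#'
#' For each alignment column where the reference row has a residue:
#' coverage = fraction of rows with a residue; similarity = fraction of
#' covered rows whose residue matches the reference (the reference row
#' counts); score = coverage x similarity. Columns gapped in the reference
#' are skipped. All values lie in [0, 1].
#'
#' @param alignment character vector of equal-length gapped sequences, a
#'   \link[Biostrings]{DNAStringSet} or a DNAMultipleAlignment.
#' @param reference index (or name) of the reference row (default 1).
#' @return data.frame with columns column (alignment column index),
#'   position (ungapped reference position), coverage, similarity, score.
#' @export
conservationProfile <- function(alignment, reference = 1) {
  if (is(alignment, "DNAMultipleAlignment"))
    alignment <- as.character(alignment)
  if (is(alignment, "XStringSet")) alignment <- as.character(alignment)
  alignment <- toupper(as.character(alignment))
  if (length(alignment) < 2)
    stopf("conservation profile requires >= 2 aligned rows")
  if (length(unique(nchar(alignment))) != 1)
    stopf("aligned rows must have equal length")
  m <- do.call(rbind, strsplit(alignment, ""))
  if (is.character(reference)) reference <- match(reference, names(alignment))
  ref <- m[reference, ]
  scored <- which(ref != "-")
  gap <- m == "-"
  covCount <- colSums(!gap)
  matchCount <- colSums(m == matrix(ref, nrow(m), ncol(m), byrow = TRUE) &
                          !gap)
  coverage <- covCount[scored] / nrow(m)
  similarity <- matchCount[scored] / covCount[scored]
  data.frame(column = scored,
             position = seq_along(scored),
             coverage = coverage,
             similarity = similarity,
             score = coverage * similarity,
             row.names = NULL)
}

#' Read an aligned FASTA into a character alignment
#' @param path aligned FASTA path.
#' @return Named character vector of gapped sequences.
#' @export
readAlignedFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}
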